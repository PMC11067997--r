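# S4 classes shared across the package.

## ---- HVR constants -------------------------------------------------------

# Residues observed in the hypervariable region (HVR) and the codons the
# generator uses for them.  The HVR is encoded almost exclusively by ANT/NAT
# codons; tryptophan's unique codon (TGG) is the one residue that cannot
# follow that pattern, so the generator's default alphabet is {N,H,S,Y} while
# validation additionally tolerates W/TGG in user data.
.HVR_AA <- c("N", "H", "S", "W", "Y")
.HVR_PATTERN <- "^(A[ACGT]T|[ACGT]AT)$"
.HVR_GEN_CODONS <- c(N = "AAT", H = "CAT", S = "AGT", Y = "TAT")
.HVR_GEN_WEIGHTS <- c(N = 0.60, H = 0.15, S = 0.15, Y = 0.10)

.isHvrCodon <- function(codon) {
  grepl(.HVR_PATTERN, codon) | codon == "TGG"
}

.splitCodons <- function(x) {
  x <- as.character(x)
  n <- nchar(x) %/% 3L
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

## ---- HaplotypeSet --------------------------------------------------------

#' Set of sex-locus haplotypes with annotated hypervariable regions
#'
#' Holds unaligned nucleotide haplotypes of the E8--E9 fragment of the
#' sex-determining locus together with, for each haplotype, the codon
#' interval of its hypervariable region (HVR) and an optional population
#' label.  Validity enforces the structural constraints of the locus:
#' coding-frame length, no internal stop codons, HVR residues drawn from
#' {N, H, S, W, Y}, and HVR codons following the ANT/NAT pattern (with TGG
#' tolerated as tryptophan's only codon).
#'
#' @slot dna A [Biostrings::DNAStringSet] of ungapped coding sequences.
#' @slot hvr An [IRanges::IRanges] of HVR spans in codon coordinates
#'   (1-based, closed), parallel to `dna`.
#' @slot population Character vector of population labels (may be empty).
#'
#' @seealso [HaplotypeSet()], [generateFounderAlleles()]
#' @export
setClass("HaplotypeSet",
  representation(dna = "DNAStringSet", hvr = "IRanges",
                 population = "character"))

setValidity("HaplotypeSet", function(object) {
  n <- length(object@dna)
  if (length(object@hvr) != n)
    return("'hvr' must be parallel to 'dna'")
  if (length(object@population) &&
      length(object@population) != n)
    return("'population' must be empty or parallel to 'dna'")
  if (n == 0L) return(TRUE)
  if (is.null(names(object@dna)) || anyDuplicated(names(object@dna)))
    return("haplotypes must carry unique allele ids as names")
  w <- Biostrings::width(object@dna)
  if (any(w %% 3L != 0L))
    return("haplotype lengths must be multiples of 3")
  seqs <- as.character(object@dna)
  if (any(grepl("-", seqs, fixed = TRUE)))
    return("haplotypes must be ungapped")
  ncodon <- w %/% 3L
  s <- IRanges::start(object@hvr); e <- IRanges::end(object@hvr)
  if (any(s < 1L) || any(e > ncodon) || any(s > e + 1L))
    return("hvr span outside the coding sequence")
  aa <- as.character(Biostrings::translate(object@dna))
  if (any(grepl("*", aa, fixed = TRUE)))
    return("internal stop codon in haplotype")
  for (i in seq_len(n)) {
    if (s[i] > e[i]) next   # empty HVR span is permitted
    res <- strsplit(substr(aa[i], s[i], e[i]), "")[[1L]]
    if (!all(res %in% .HVR_AA))
      return(sprintf("haplotype '%s': HVR residue outside {N,H,S,W,Y}",
                     names(object@dna)[i]))
    cod <- .splitCodons(seqs[i])[s[i]:e[i]]
    if (!all(.isHvrCodon(cod)))
      return(sprintf("haplotype '%s': HVR codon not ANT/NAT (or TGG)",
                     names(object@dna)[i]))
  }
  TRUE
})

#' Construct a HaplotypeSet
#'
#' @param dna A [Biostrings::DNAStringSet] or named character vector of
#'   ungapped coding sequences (allele ids as names).
#' @param hvr An [IRanges::IRanges] of HVR spans in codon coordinates
#'   (1-based closed), parallel to `dna`.
#' @param population Optional character vector of population labels.
#' @return A [HaplotypeSet-class] object.
#' @examples
#' h <- HaplotypeSet(c(a1 = "ATGAAAAATAATCATGGG"),
#'                   IRanges::IRanges(3, 5))
#' hvrAA(h)
#' @export
HaplotypeSet <- function(dna, hvr, population = character()) {
  if (!is(dna, "DNAStringSet")) dna <- Biostrings::DNAStringSet(dna)
  new("HaplotypeSet", dna = dna, hvr = hvr, population = population)
}

#' @describeIn HaplotypeSet Nucleotide sequences as a DNAStringSet.
#' @param x A `HaplotypeSet`.
#' @export
dnaSeqs <- function(x) x@dna

#' @describeIn HaplotypeSet Translated amino-acid sequences.
#' @export
aaSeqs <- function(x) Biostrings::translate(x@dna)

#' @describeIn HaplotypeSet HVR spans in codon coordinates.
#' @export
hvrRanges <- function(x) x@hvr

#' @describeIn HaplotypeSet HVR amino-acid strings (one per haplotype).
#' @export
hvrAA <- function(x) {
  aa <- as.character(aaSeqs(x))
  setNames(substr(aa, IRanges::start(x@hvr), IRanges::end(x@hvr)),
           names(x@dna))
}

#' @describeIn HaplotypeSet Population labels (possibly empty).
#' @export
population <- function(x) x@population

setMethod("length", "HaplotypeSet", function(x) length(x@dna))

setMethod("show", "HaplotypeSet", function(object) {
  cat(sprintf("HaplotypeSet with %d haplotype(s)\n", length(object)))
  if (length(object)) {
    hl <- IRanges::width(object@hvr)
    cat(sprintf("  HVR length: %d-%d residues\n", min(hl), max(hl)))
    cat("  alleles:", paste(head(names(object@dna), 5L), collapse = ", "),
        if (length(object) > 5L) "..." else "", "\n")
  }
})

setMethod("[", "HaplotypeSet", function(x, i, j, ..., drop = TRUE) {
  new("HaplotypeSet", dna = x@dna[i], hvr = x@hvr[i],
      population = if (length(x@population)) x@population[i] else character())
})

## ---- CodingAlignment -----------------------------------------------------

#' Codon-aware multiple alignment of coding sequences
#'
#' A gapped multiple alignment of in-frame coding sequences in which every
#' gap run is a whole number of codons starting on a codon boundary (indels
#' at this locus always occur in multiples of three nucleotides).  Region
#' annotations (e.g. E8, HVR, E9) are stored as named nucleotide ranges in
#' alignment coordinates.
#'
#' @slot aln A [Biostrings::DNAStringSet] of equal-width gapped rows.
#' @slot regions A named [IRanges::IRanges] of annotated regions
#'   (1-based closed alignment coordinates).
#'
#' @seealso [validateAlignment()], [readFastaAlignment()],
#'   [slidingWindowDiversity()]
#' @export
setClass("CodingAlignment",
  representation(aln = "DNAStringSet", regions = "IRanges"))

setValidity("CodingAlignment", function(object) {
  n <- length(object@aln)
  if (n < 2L) return("an alignment needs at least 2 sequences")
  if (is.null(names(object@aln)) || anyDuplicated(names(object@aln)))
    return("alignment rows must carry unique ids")
  w <- Biostrings::width(object@aln)
  if (length(unique(w)) != 1L) {
    bad <- which(w != w[1L])[1L]
    return(sprintf("ragged alignment: row %d ('%s') has width %d, not %d",
                   bad, names(object@aln)[bad], w[bad], w[1L]))
  }
  if (w[1L] %% 3L != 0L)
    return("alignment width must be a multiple of 3")
  seqs <- as.character(object@aln)
  for (i in seq_len(n)) {
    r <- rle(strsplit(seqs[i], "")[[1L]] == "-")
    pos <- cumsum(c(1L, r$lengths))
    gap <- which(r$values)
    for (g in gap) {
      if (r$lengths[g] %% 3L != 0L || (pos[g] - 1L) %% 3L != 0L)
        return(sprintf(
          "row %d ('%s'): gap at column %d is not whole codons on frame",
          i, names(object@aln)[i], pos[g]))
    }
    cod <- .splitCodons(seqs[i])
    cod <- cod[!grepl("-", cod, fixed = TRUE) & grepl("^[ACGT]{3}$", cod)]
    aa <- Biostrings::GENETIC_CODE[cod]
    if (length(aa) > 1L && any(aa[-length(aa)] == "*"))
      return(sprintf("row %d ('%s'): internal stop codon", i,
                     names(object@aln)[i]))
  }
  if (length(object@regions)) {
    if (is.null(names(object@regions)))
      return("regions must be named")
    if (any(IRanges::start(object@regions) < 1L) ||
        any(IRanges::end(object@regions) > w[1L]))
      return("region outside the alignment")
  }
  TRUE
})

#' @describeIn CodingAlignment Alignment rows as a DNAStringSet.
#' @param x A `CodingAlignment`.
#' @export
alignedSeqs <- function(x) x@aln

#' @describeIn CodingAlignment Named region annotations.
#' @export
regions <- function(x) x@regions

setMethod("length", "CodingAlignment", function(x) length(x@aln))

setMethod("show", "CodingAlignment", function(object) {
  cat(sprintf("CodingAlignment: %d sequences x %d nt (%d codons)\n",
              length(object@aln), Biostrings::width(object@aln)[1L],
              Biostrings::width(object@aln)[1L] %/% 3L))
  if (length(object@regions))
    cat("  regions:", paste(names(object@regions), collapse = ", "), "\n")
})

## ---- SimConfig -----------------------------------------------------------

#' Configuration of the forward simulator
#'
#' Parameters of the zygosity-based sex-determination simulator: census
#' sizes, founder allele number, HVR mutation process, the Z0 female route,
#' and run length.  See [simulatePopulation()] for the life cycle.
#'
#' @slot nFemales,nMales Adult census sizes maintained each generation.
#' @slot k Number of founder alleles (>= 2).
#' @slot muPoint Per-codon, per-transmission HVR point-substitution rate
#'   (substitutions stay within the ANT/NAT alphabet).
#' @slot muSlip Per-transmission probability of a single-codon slippage
#'   (+/- 1 codon), rejected at the HVR length bounds.
#' @slot muE9 Per-codon, per-transmission nonsynonymous substitution rate
#'   outside the HVR (E9 portion).
#' @slot hvrLenBounds Inclusive HVR length bounds in residues.
#' @slot z0Rate Probability that an egg destined to inherit W instead
#'   carries no sex chromosome from the mother (Z0 female route).
#' @slot generations Number of discrete, non-overlapping generations.
#' @slot seed RNG seed for the run.
#' @slot broodSize Eggs per female in [simulateBrood()]-style sampling.
#' @export
setClass("SimConfig",
  representation(nFemales = "integer", nMales = "integer", k = "integer",
                 muPoint = "numeric", muSlip = "numeric", muE9 = "numeric",
                 hvrLenBounds = "integer", z0Rate = "numeric",
                 generations = "integer", seed = "integer",
                 broodSize = "integer"),
  prototype(nFemales = 200L, nMales = 200L, k = 10L,
            muPoint = 0, muSlip = 0, muE9 = 0,
            hvrLenBounds = c(7L, 24L), z0Rate = 0.004,
            generations = 50L, seed = 1L, broodSize = 40L))

setValidity("SimConfig", function(object) {
  rates <- c(object@muPoint, object@muSlip, object@muE9, object@z0Rate)
  if (any(rates < 0) || any(rates > 1))
    return("all rates must lie in [0, 1]")
  if (object@k < 2L) return("k (founder alleles) must be >= 2")
  b <- object@hvrLenBounds
  if (length(b) != 2L || b[1L] > b[2L] || b[1L] < 1L || b[2L] > 64L)
    return("hvrLenBounds must be an ordered pair within [1, 64]")
  if (object@nFemales < 1L || object@nMales < 1L)
    return("census sizes must be positive")
  if (object@generations < 1L) return("generations must be >= 1")
  if (object@broodSize < 1L) return("broodSize must be >= 1")
  TRUE
})

#' Construct a simulator configuration
#'
#' @param nFemales,nMales Adult census sizes (default 200 each).
#' @param k Number of founder alleles.
#' @param muPoint,muSlip,muE9 Mutation rates; see [SimConfig-class].
#' @param hvrLenBounds Inclusive HVR residue-length bounds (default 7--24).
#' @param z0Rate Z0 female route probability (default 0.004, the rate at
#'   which W-less females occur in the wild).
#' @param generations Number of generations (default 50).
#' @param seed RNG seed.
#' @param broodSize Eggs per female (default 40).
#' @return A [SimConfig-class] object.
#' @examples
#' cfg <- SimConfig(k = 5, generations = 10, seed = 42)
#' @export
SimConfig <- function(nFemales = 200, nMales = 200, k = 10,
                      muPoint = 0, muSlip = 0, muE9 = 0,
                      hvrLenBounds = c(7, 24), z0Rate = 0.004,
                      generations = 50, seed = 1, broodSize = 40) {
  new("SimConfig", nFemales = as.integer(nFemales),
      nMales = as.integer(nMales), k = as.integer(k),
      muPoint = muPoint, muSlip = muSlip, muE9 = muE9,
      hvrLenBounds = as.integer(hvrLenBounds), z0Rate = z0Rate,
      generations = as.integer(generations), seed = as.integer(seed),
      broodSize = as.integer(broodSize))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0(
    "SimConfig: %d females / %d males, k = %d founder alleles\n",
    "  mutation: point %.2g, slip %.2g, E9 %.2g; HVR bounds [%d, %d]\n",
    "  z0Rate %.3g, %d generations, seed %d\n"),
    object@nFemales, object@nMales, object@k,
    object@muPoint, object@muSlip, object@muE9,
    object@hvrLenBounds[1L], object@hvrLenBounds[2L],
    object@z0Rate, object@generations, object@seed))
})

## ---- SimState ------------------------------------------------------------

#' Result of a forward simulation
#'
#' @slot config The [SimConfig-class] used.
#' @slot alleleTraj List (one element per generation) of named integer
#'   vectors: allele copy counts among adults.
#' @slot females data.frame of surviving adult females
#'   (karyotype, allele).
#' @slot males data.frame of surviving adult males (allele1, allele2).
#' @slot haplotypes [HaplotypeSet-class] of every allele segregating in the
#'   final generation.
#' @slot extinct Logical: did the population die out?
#' @slot extinctGeneration Generation of extinction (NA if none).
#' @export
setClass("SimState",
  representation(config = "SimConfig", alleleTraj = "list",
                 females = "data.frame", males = "data.frame",
                 haplotypes = "HaplotypeSet", extinct = "logical",
                 extinctGeneration = "integer"))

setMethod("show", "SimState", function(object) {
  if (object@extinct) {
    cat(sprintf("SimState: EXTINCT at generation %d\n",
                object@extinctGeneration))
  } else {
    tr <- object@alleleTraj[[length(object@alleleTraj)]]
    cat(sprintf(
      "SimState: %d generations, %d females + %d males, %d alleles\n",
      length(object@alleleTraj), nrow(object@females),
      nrow(object@males), length(tr)))
  }
})

#' @describeIn SimState Per-generation allele copy counts among adults.
#' @param x A `SimState`.
#' @export
alleleTrajectory <- function(x) x@alleleTraj

#' @describeIn SimState Adult females of the final generation.
#' @export
simFemales <- function(x) x@females

#' @describeIn SimState Adult males of the final generation.
#' @export
simMales <- function(x) x@males

#' @describeIn SimState Haplotypes segregating in the final generation.
#' @export
simHaplotypes <- function(x) x@haplotypes

#' @describeIn SimState TRUE if the simulated population went extinct.
#' @export
isExtinct <- function(x) x@extinct

## ---- BroodRecord ---------------------------------------------------------

#' One brood from a single-pair cross
#'
#' Egg-category bookkeeping for a brood: zygote classes (WZ and Z0
#' hemizygous daughters, ZZ heterozygous sons, ZZ homozygotes) and
#' phenotypic outcomes.  Homozygous ZZ zygotes die as late embryos and
#' surface as "black eggs"; they never appear among hatched larvae.
#'
#' @slot mother,father Parent descriptors (list with `karyotype` and
#'   `alleles`).
#' @slot classCounts Named integer: WZ_hem, Z0_hem, ZZ_het, ZZ_hom counts
#'   among developed eggs.
#' @slot outcomeCounts Named integer: hatched, black_egg, white_egg,
#'   collapsed.
#' @slot nEggs Total eggs laid.
#' @export
setClass("BroodRecord",
  representation(mother = "list", father = "list",
                 classCounts = "integer", outcomeCounts = "integer",
                 nEggs = "integer"))

setValidity("BroodRecord", function(object) {
  cc <- object@classCounts; oc <- object@outcomeCounts
  need <- c("WZ_hem", "Z0_hem", "ZZ_het", "ZZ_hom")
  if (!all(need %in% names(cc)))
    return("classCounts must cover WZ_hem, Z0_hem, ZZ_het, ZZ_hom")
  needo <- c("hatched", "black_egg", "white_egg", "collapsed")
  if (!all(needo %in% names(oc)))
    return("outcomeCounts must cover hatched, black_egg, white_egg, collapsed")
  if (sum(oc) != object@nEggs)
    return("outcome counts must sum to the number of eggs")
  if (sum(cc) + oc[["white_egg"]] + oc[["collapsed"]] != object@nEggs)
    return("class counts + undeveloped eggs must sum to total eggs")
  if (oc[["hatched"]] != sum(cc) - cc[["ZZ_hom"]])
    return("homozygous ZZ zygotes must never hatch")
  TRUE
})

setMethod("show", "BroodRecord", function(object) {
  cat(sprintf("BroodRecord: %d eggs\n", object@nEggs))
  cat("  classes: ", paste(names(object@classCounts),
                           object@classCounts, sep = "=", collapse = " "),
      "\n  outcomes:", paste(names(object@outcomeCounts),
                             object@outcomeCounts, sep = "=", collapse = " "),
      "\n")
})

#' @describeIn BroodRecord Zygote class counts.
#' @param x A `BroodRecord`.
#' @export
broodClasses <- function(x) x@classCounts

#' @describeIn BroodRecord Phenotypic outcome counts.
#' @export
broodOutcomes <- function(x) x@outcomeCounts

## ---- AlleleCounts --------------------------------------------------------

#' Allele observation counts
#'
#' A haplotype-to-count table with optional per-observation provenance used
#' by the richness analyses.
#'
#' @slot counts Named positive integer vector (allele id -> count).
#' @export
setClass("AlleleCounts", representation(counts = "integer"))

setValidity("AlleleCounts", function(object) {
  if (length(object@counts) == 0L) return("empty allele count table")
  if (is.null(names(object@counts)) || anyDuplicated(names(object@counts)))
    return("counts must be uniquely named by allele id")
  if (any(object@counts < 1L)) return("counts must be >= 1")
  TRUE
})

#' Construct an AlleleCounts table
#'
#' @param counts Named positive integer vector, or a character vector of
#'   per-observation allele ids (tabulated internally).
#' @return An [AlleleCounts-class] object.
#' @examples
#' AlleleCounts(c(a = 2, b = 1))
#' AlleleCounts(c("a", "a", "b"))
#' @export
AlleleCounts <- function(counts) {
  if (is.character(counts)) {
    tb <- table(counts)
    counts <- setNames(as.integer(tb), names(tb))
  }
  new("AlleleCounts", counts = setNames(as.integer(counts), names(counts)))
}

#' @describeIn AlleleCounts Named count vector.
#' @param x An `AlleleCounts`.
#' @export
alleleCounts <- function(x) x@counts

#' @describeIn AlleleCounts Total number of observations.
#' @export
alleleN <- function(x) sum(x@counts)

setMethod("length", "AlleleCounts", function(x) length(x@counts))

setMethod("show", "AlleleCounts", function(object) {
  cat(sprintf("AlleleCounts: %d alleles, %d observations\n",
              length(object@counts), sum(object@counts)))
})
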