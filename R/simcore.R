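# Forward simulator of zygosity-based sex determination.
#
# Life cycle: discrete non-overlapping generations, equal fecundity.
# Females carry one Z allele (WZ or Z0 karyotype), males two distinct
# alleles.  A WZ mother transmits W or her Z allele with equal probability
# (with a small probability z0Rate the W is lost, yielding a Z0 daughter);
# a Z0 mother transmits her Z or no sex chromosome with equal probability
# (the unpaired Z univalent is assumed to segregate randomly).  Fathers
# transmit either allele equally.  Zygotes with two identical alleles die
# before adulthood; allele identity is amino-acid identity.

# Conserved left flank preceding the HVR (E8 portion), 12 codons.
.E8_FLANK <- c("ATG", "GAG", "CCT", "AAA", "CGT", "TGC", "AAG", "CGC",
               "AAA", "CTT", "GAT", "CAA")
.E9_LEN <- 99L

.SENSE_CODONS <- names(Biostrings::GENETIC_CODE)[
  Biostrings::GENETIC_CODE != "*"]

# codons that can never create a stop on substitution handling is done by
# resampling; draw a random sense codon for a different amino acid
.randomNonsynCodon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  pool <- .SENSE_CODONS[Biostrings::GENETIC_CODE[.SENSE_CODONS] != aa]
  sample(pool, 1L)
}

.drawHvrLen <- function(bounds) {
  span <- bounds[2L] - bounds[1L]
  if (span == 0L) return(bounds[1L])
  bounds[1L] + rbinom(1L, span, 0.5)
}

.drawHvrCodons <- function(len) {
  sample(.HVR_GEN_CODONS, len, replace = TRUE, prob = .HVR_GEN_WEIGHTS)
}

# internal haplotype record: list(codons, s, e) with s..e the HVR codon span
.recToHap <- function(rec) {
  paste(rec$codons, collapse = "")
}

.recAA <- function(rec) {
  paste(Biostrings::GENETIC_CODE[rec$codons], collapse = "")
}

## ---- allele registry -----------------------------------------------------

# Allele registry: integer ids internally (labels "A%04d" at the surface).
# Records live in hashed environments keyed by id so registration never
# copies the store; the per-transmission mutation probability of each new
# allele is queued in small "pending" vectors that the simulator flushes
# into its lookup vector in bulk.
.newRegistry <- function(config = NULL) {
  reg <- new.env(parent = emptyenv())
  reg$haps <- new.env(parent = emptyenv())   # id string -> record
  reg$aaKey <- new.env(parent = emptyenv())  # aa string -> integer id
  reg$pendIds <- integer(0)
  reg$pendP <- numeric(0)
  reg$nextId <- 1L
  reg$config <- config
  reg
}

.transmissionMutProb <- function(rec, config) {
  L <- rec$e - rec$s + 1L
  nE9 <- length(rec$codons) - rec$e
  min(1, config@muPoint * L + config@muSlip + config@muE9 * nE9)
}

.regGet <- function(reg, id) reg$haps[[as.character(id)]]

.registerHap <- function(reg, rec) {
  aa <- .recAA(rec)
  hit <- reg$aaKey[[aa]]
  if (!is.null(hit)) return(hit)
  id <- reg$nextId
  reg$nextId <- id + 1L
  reg$haps[[as.character(id)]] <- rec
  reg$aaKey[[aa]] <- id
  if (!is.null(reg$config)) {
    reg$pendIds <- c(reg$pendIds, id)
    reg$pendP <- c(reg$pendP, .transmissionMutProb(rec, reg$config))
  }
  id
}

.alleleLabel <- function(id) sprintf("A%04d", id)

.registryHapSet <- function(reg, ids, population = character()) {
  recs <- lapply(ids, function(i) .regGet(reg, i))
  dna <- Biostrings::DNAStringSet(vapply(recs, .recToHap, ""))
  names(dna) <- .alleleLabel(ids)
  hvr <- IRanges::IRanges(vapply(recs, function(r) r$s, 1L),
                          vapply(recs, function(r) r$e, 1L))
  HaplotypeSet(dna, hvr, population)
}

## ---- founders ------------------------------------------------------------

.makeFounderRec <- function(e9base, config) {
  len <- .drawHvrLen(config@hvrLenBounds)
  hvr <- .drawHvrCodons(len)
  e9 <- e9base
  flip <- runif(length(e9)) < 0.25   # founder-specific E9 variation
  for (i in which(flip)) e9[i] <- .randomNonsynCodon(e9[i])
  s <- length(.E8_FLANK) + 1L
  list(codons = c(.E8_FLANK, hvr, e9), s = s, e = s + len - 1L)
}

.makeFounders <- function(config, reg) {
  e9base <- sample(.SENSE_CODONS, .E9_LEN, replace = TRUE)
  ids <- integer(0)
  guard <- 0L
  while (length(ids) < config@k && guard < 100L * config@k) {
    id <- .registerHap(reg, .makeFounderRec(e9base, config))
    ids <- unique(c(ids, id))
    guard <- guard + 1L
  }
  if (length(ids) < config@k)
    stop("could not generate ", config@k, " distinct founder alleles")
  ids
}

#' Generate founder alleles
#'
#' Draws `k` mutually distinct haplotypes of the E8--HVR--E9 structure: a
#' conserved E8 flank, an HVR of ANT/NAT codons with a bell-shaped length
#' distribution within the configured bounds, and a variable E9 portion.
#' Distinctness is at the amino-acid level.
#'
#' @param k Number of alleles (>= 2); defaults to `config@k`.
#' @param config A [SimConfig-class]; its seed initialises the RNG.
#' @return A [HaplotypeSet-class] of `k` distinct haplotypes.
#' @examples
#' generateFounderAlleles(config = SimConfig(k = 5, seed = 1))
#' @export
generateFounderAlleles <- function(k = config@k, config = SimConfig()) {
  validObject(config)
  if (k < 2L) stop("invalid config: k must be >= 2")
  if (k != config@k) {
    config@k <- as.integer(k)
    validObject(config)
  }
  set.seed(config@seed)
  reg <- .newRegistry()
  ids <- .makeFounders(config, reg)
  .registryHapSet(reg, ids)
}

#' Canonical high-richness ("csd-like") simulation conditions
#'
#' A preset [SimConfig-class] placing the simulated population in the
#' singleton-dominated high-richness regime characteristic of csd-type
#' balancing selection: census 1000 + 1000, 20 founder alleles, 150
#' generations, and mutation rates (point 2e-3 per HVR codon, slippage
#' 4e-3, E9 4e-4 per codon per transmission) chosen as a standard
#' population-genetic rescaling -- census scaled far below the wild
#' effective population size with mutation scaled up so that the product,
#' which governs the equilibrium allele number, stays in the regime
#' holding many hundreds of alleles.  Samples of a few hundred females
#' from these conditions show >75% singleton alleles with no allele seen
#' more than a handful of times.
#'
#' @param seed RNG seed for the run.
#' @return A [SimConfig-class].
#' @examples
#' csdConfig(seed = 1)
#' @export
csdConfig <- function(seed = 1) {
  SimConfig(nFemales = 1000, nMales = 1000, k = 20,
            muPoint = 2e-3, muSlip = 4e-3, muE9 = 4e-4,
            generations = 150, seed = seed)
}

## ---- mutation ------------------------------------------------------------

# Apply the mutation model to one internal record.  If 'single' is TRUE
# exactly one event of a type drawn proportionally to the rates is applied
# (used for gated per-transmission mutation inside the simulator).
.mutateRec <- function(rec, config, single = FALSE) {
  L <- rec$e - rec$s + 1L
  nE9 <- length(rec$codons) - rec$e
  if (single) {
    w <- c(point = config@muPoint * L, slip = config@muSlip,
           e9 = config@muE9 * nE9)
    if (sum(w) <= 0) return(rec)
    ev <- sample(names(w), 1L, prob = w)
    nPoint <- if (ev == "point") 1L else 0L
    doSlip <- ev == "slip"
    nE9mut <- if (ev == "e9") 1L else 0L
  } else {
    nPoint <- rbinom(1L, L, config@muPoint)
    doSlip <- runif(1L) < config@muSlip
    nE9mut <- rbinom(1L, nE9, config@muE9)
  }
  if (nPoint > 0L) {
    pos <- rec$s - 1L + sample.int(L, min(nPoint, L))
    for (p in pos) {
      cur <- rec$codons[p]
      pool <- setdiff(.HVR_GEN_CODONS, cur)
      rec$codons[p] <- sample(pool, 1L,
        prob = .HVR_GEN_WEIGHTS[match(pool, .HVR_GEN_CODONS)])
    }
  }
  if (doSlip) {
    expand <- runif(1L) < 0.5
    if (expand && L < config@hvrLenBounds[2L]) {
      p <- rec$s - 1L + sample.int(L, 1L)
      rec$codons <- append(rec$codons, rec$codons[p], after = p)
      rec$e <- rec$e + 1L
    } else if (!expand && L > config@hvrLenBounds[1L]) {
      p <- rec$s - 1L + sample.int(L, 1L)
      rec$codons <- rec$codons[-p]
      rec$e <- rec$e - 1L
    } # at a bound the drawn step is rejected (no-op)
  }
  if (nE9mut > 0L) {
    pos <- rec$e + sample.int(nE9, min(nE9mut, nE9))
    for (p in pos) rec$codons[p] <- .randomNonsynCodon(rec$codons[p])
  }
  rec
}

#' Mutate a haplotype
#'
#' Applies the three-part mutation model to a single haplotype: HVR point
#' substitutions confined to the ANT/NAT alphabet, single-codon slippage
#' (expansion or contraction, rejected at the configured length bounds),
#' and nonsynonymous substitutions in the E9 portion beyond the HVR.  With
#' all rates zero the input is returned unchanged.  Uses the current RNG
#' stream.
#'
#' @param h A [HaplotypeSet-class] with exactly one haplotype.
#' @param config A [SimConfig-class] holding the rates and bounds.
#' @return A [HaplotypeSet-class] with the (possibly) mutated haplotype.
#' @examples
#' h <- generateFounderAlleles(config = SimConfig(k = 2, seed = 1))[1]
#' set.seed(1)
#' mutateHaplotype(h, SimConfig(muSlip = 1))
#' @export
mutateHaplotype <- function(h, config = SimConfig()) {
  stopifnot(is(h, "HaplotypeSet"), length(h) == 1L)
  validObject(config)
  rec <- list(codons = .splitCodons(as.character(h@dna[[1L]])),
              s = IRanges::start(h@hvr), e = IRanges::end(h@hvr))
  rec <- .mutateRec(rec, config)
  dna <- Biostrings::DNAStringSet(.recToHap(rec))
  names(dna) <- names(h@dna)
  HaplotypeSet(dna, IRanges::IRanges(rec$s, rec$e),
               if (length(h@population)) h@population else character())
}

## ---- forward simulation --------------------------------------------------

#' Simulate a population under zygosity-based sex determination
#'
#' Runs a forward Wright-Fisher-style simulation with homozygote lethality
#' at the sex locus.  Every generation, eggs are formed by random mating;
#' zygotes with two identical alleles are removed before adulthood, and the
#' adult census (`nFemales`, `nMales`) is refilled from surviving zygotes.
#' Per-generation allele copy counts among adults are recorded.  If the
#' census cannot be refilled (e.g. a single allele remains, making
#' heterozygous males impossible), the run terminates with an explicit
#' extinction flag rather than an error.
#'
#' @param config A [SimConfig-class]; `config@seed` seeds the run.
#' @return A [SimState-class].
#' @examples
#' st <- simulatePopulation(SimConfig(k = 4, nFemales = 50, nMales = 50,
#'                                    generations = 5, seed = 7))
#' head(alleleTrajectory(st)[[5]])
#' @export
simulatePopulation <- function(config = SimConfig()) {
  validObject(config)
  set.seed(config@seed)
  reg <- .newRegistry(config)
  ids <- .makeFounders(config, reg)
  nF <- config@nFemales; nM <- config@nMales

  femAl <- sample(ids, nF, replace = TRUE)
  femKar <- rep("WZ", nF)
  maleMat <- t(vapply(seq_len(nM),
                      function(i) sample(ids, 2L), integer(2L)))

  anyMut <- config@muPoint > 0 || config@muSlip > 0 || config@muE9 > 0
  mutP <- numeric(1024L)
  flushMutP <- function() {
    if (!length(reg$pendIds)) return(invisible())
    top <- max(reg$pendIds)
    if (top > length(mutP))
      mutP <<- c(mutP, numeric(max(top, 2L * length(mutP)) - length(mutP)))
    mutP[reg$pendIds] <<- reg$pendP
    reg$pendIds <- integer(0)
    reg$pendP <- numeric(0)
    invisible()
  }
  flushMutP()
  maybeMutate <- function(alleles) {
    if (!anyMut || length(alleles) == 0L) return(alleles)
    hit <- which(runif(length(alleles)) < mutP[alleles])
    for (i in hit) {
      rec <- .mutateRec(.regGet(reg, alleles[i]), config, single = TRUE)
      alleles[i] <- .registerHap(reg, rec)
    }
    alleles
  }

  countAdults <- function(femAl, maleMat) {
    tb <- tabulate(c(femAl, maleMat[, 1L], maleMat[, 2L]),
                   nbins = reg$nextId - 1L)
    pos <- which(tb > 0L)
    setNames(tb[pos], .alleleLabel(pos))
  }

  traj <- vector("list", config@generations)
  extinct <- FALSE; extGen <- NA_integer_

  for (g in seq_len(config@generations)) {
    newFemAl <- integer(0); newFemKar <- character(0)
    newM1 <- integer(0); newM2 <- integer(0)
    attempts <- 0L
    while ((length(newFemAl) < nF || length(newM1) < nM) && attempts < 50L) {
      attempts <- attempts + 1L
      flushMutP()
      b <- 2L * (nF + nM)
      mi <- sample.int(length(femAl), b, replace = TRUE)
      fi <- sample.int(nrow(maleMat), b, replace = TRUE)
      transmitsZ <- runif(b) < 0.5
      patAl <- ifelse(runif(b) < 0.5, maleMat[fi, 1L], maleMat[fi, 2L])
      patAl <- maybeMutate(patAl)
      matAl <- femAl[mi]
      matAl[transmitsZ] <- maybeMutate(matAl[transmitsZ])
      motherZ0 <- femKar[mi] == "Z0"

      isFemaleEgg <- !transmitsZ
      # W loss on the WZ route produces a Z0 daughter
      wLost <- isFemaleEgg & !motherZ0 & runif(b) < config@z0Rate
      kar <- ifelse(isFemaleEgg & (motherZ0 | wLost), "Z0", "WZ")

      fsel <- which(isFemaleEgg)
      if (length(fsel)) {
        newFemAl <- c(newFemAl, patAl[fsel])
        newFemKar <- c(newFemKar, kar[fsel])
      }
      msel <- which(!isFemaleEgg & matAl != patAl)  # homozygotes die
      if (length(msel)) {
        newM1 <- c(newM1, matAl[msel])
        newM2 <- c(newM2, patAl[msel])
      }
      if (length(unique(c(femAl, maleMat))) < 2L) break
    }
    if (length(newFemAl) < nF || length(newM1) < nM) {
      extinct <- TRUE; extGen <- g
      traj <- traj[seq_len(g - 1L)]
      break
    }
    keepF <- seq_len(nF); keepM <- seq_len(nM)
    femAl <- newFemAl[keepF]; femKar <- newFemKar[keepF]
    maleMat <- cbind(newM1[keepM], newM2[keepM])
    traj[[g]] <- countAdults(femAl, maleMat)
  }

  finalIds <- sort(unique(c(femAl, maleMat[, 1L], maleMat[, 2L])))
  new("SimState", config = config, alleleTraj = traj,
      females = data.frame(karyotype = femKar,
                           allele = .alleleLabel(femAl),
                           stringsAsFactors = FALSE),
      males = data.frame(allele1 = .alleleLabel(maleMat[, 1L]),
                         allele2 = .alleleLabel(maleMat[, 2L]),
                         stringsAsFactors = FALSE),
      haplotypes = .registryHapSet(reg, finalIds),
      extinct = extinct, extinctGeneration = extGen)
}

## ---- broods --------------------------------------------------------------

#' Simulate a single brood
#'
#' Mendelian segregation for one mother x father pairing.  A WZ mother
#' transmits W or her Z allele equally; a Z0 mother transmits her Z or no
#' sex chromosome equally; the father transmits either allele equally.
#' Zygotes with two identical alleles are scored as black eggs (late
#' embryonic death); all other developed zygotes hatch.  Optional
#' background rates produce white (early death) and collapsed
#' (unfertilised) eggs before genetic classification.
#'
#' @param mother List with `karyotype` ("WZ" or "Z0") and `alleles`
#'   (one allele id).
#' @param father List with `alleles` (two distinct allele ids).
#' @param nEggs Number of eggs.
#' @param whiteRate,collapsedRate Background egg-failure probabilities
#'   (default 0).
#' @param seed Optional RNG seed.
#' @return A [BroodRecord-class].
#' @examples
#' b <- simulateBrood(list(karyotype = "WZ", alleles = "a"),
#'                    list(alleles = c("a", "b")), nEggs = 400, seed = 1)
#' broodOutcomes(b)
#' @export
simulateBrood <- function(mother, father, nEggs,
                          whiteRate = 0, collapsedRate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mother$karyotype) ||
      !mother$karyotype %in% c("WZ", "Z0") ||
      length(mother$alleles) != 1L)
    stop("invalid cross: mother must be a WZ or Z0 female with one allele")
  if (length(father$alleles) != 2L ||
      father$alleles[1L] == father$alleles[2L])
    stop("invalid cross: father must be a ZZ male with two distinct alleles")
  nEggs <- as.integer(nEggs)
  fate <- runif(nEggs)
  collapsed <- fate < collapsedRate
  white <- !collapsed & fate < collapsedRate + whiteRate
  dev <- which(!collapsed & !white)
  nd <- length(dev)
  transmitsZ <- runif(nd) < 0.5
  patAl <- ifelse(runif(nd) < 0.5, father$alleles[1L], father$alleles[2L])
  femClass <- if (mother$karyotype == "WZ") "WZ_hem" else "Z0_hem"
  cls <- ifelse(!transmitsZ, femClass,
                ifelse(patAl == mother$alleles, "ZZ_hom", "ZZ_het"))
  cc <- setNames(integer(4L), c("WZ_hem", "Z0_hem", "ZZ_het", "ZZ_hom"))
  tb <- table(cls)
  cc[names(tb)] <- as.integer(tb)
  oc <- c(hatched = sum(cc) - cc[["ZZ_hom"]],
          black_egg = cc[["ZZ_hom"]],
          white_egg = sum(white), collapsed = sum(collapsed))
  new("BroodRecord",
      mother = mother, father = father,
      classCounts = cc, outcomeCounts = oc, nEggs = nEggs)
}

## ---- expression matrices -------------------------------------------------

#' Simulate a dosage-compensation expression matrix
#'
#' Generates a TPM-like gene x sample abundance matrix emulating the
#' Z-chromosome dosage-compensation pattern: autosomal genes share one
#' baseline distribution across all zygosity classes; Z-linked genes in
#' hemizygous (hem) and heterozygous (het) samples sit at a compensated
#' level (`zaRatio` times the autosomal baseline), while Z-linked genes in
#' homozygous (hom) samples fail male-mode compensation and are elevated by
#' `homFactor` relative to hem.  Noise is multiplicative lognormal.
#'
#' @param nAuto,nZ Numbers of autosomal and Z-linked genes.
#' @param classes Named integer vector of replicates per zygosity class;
#'   names must be among "hem", "het", "hom".
#' @param homFactor Z-gene elevation of hom relative to hem (default 1.87,
#'   the observed median hom/hem differential across the Z chromosome).
#' @param zaRatio Compensated Z:A median ratio for hem/het (default 0.6,
#'   centre of the observed 0.5--0.7 range).
#' @param noiseSd Lognormal noise sd on the log scale (default 0.25; 0
#'   disables noise).
#' @param baseMeanLog,baseSdLog Log-scale mean and sd of the per-gene
#'   baseline abundance distribution.
#' @param seed Optional RNG seed.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"tpm"`, `rowData(x)$geneClass` in {A, Z} and
#'   `colData(x)$zygosity` in {hem, het, hom}.
#' @examples
#' se <- simulateExpressionMatrix(200, 50, seed = 1)
#' table(SummarizedExperiment::rowData(se)$geneClass)
#' @export
simulateExpressionMatrix <- function(nAuto, nZ,
                                     classes = c(hem = 3, het = 3, hom = 6),
                                     homFactor = 1.87, zaRatio = 0.6,
                                     noiseSd = 0.25,
                                     baseMeanLog = log(20), baseSdLog = 1.2,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nAuto > 0, nZ > 0)
  if (is.null(names(classes)) || !all(names(classes) %in%
                                      c("hem", "het", "hom")))
    stop("invalid config: class labels must be among hem/het/hom")
  nGene <- nAuto + nZ
  geneClass <- c(rep("A", nAuto), rep("Z", nZ))
  base <- rlnorm(nGene, baseMeanLog, baseSdLog)
  sampClass <- rep(names(classes), classes)
  nSamp <- length(sampClass)
  classLevel <- function(cl) {
    lv <- base
    isZ <- geneClass == "Z"
    fac <- switch(cl, hem = zaRatio, het = zaRatio,
                  hom = zaRatio * homFactor)
    lv[isZ] <- lv[isZ] * fac
    lv
  }
  mat <- vapply(sampClass, classLevel, numeric(nGene))
  if (noiseSd > 0)
    mat <- mat * exp(matrix(stats::rnorm(nGene * nSamp, 0, noiseSd),
                            nGene, nSamp))
  rownames(mat) <- c(sprintf("autoG%05d", seq_len(nAuto)),
                     sprintf("zG%05d", seq_len(nZ)))
  colnames(mat) <- sprintf("%s_%d", sampClass,
                           stats::ave(seq_len(nSamp), sampClass,
                                      FUN = seq_along))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = mat),
    rowData = S4Vectors::DataFrame(geneClass = geneClass),
    colData = S4Vectors::DataFrame(zygosity = sampClass,
                                   row.names = colnames(mat)))
}

## ---- alignment of simulated haplotypes -----------------------------------

#' Align a HaplotypeSet by padding the HVR
#'
#' Builds a codon-aware [CodingAlignment-class] from haplotypes whose only
#' length variation lies in the HVR (as the simulator generates): the HVR
#' of each haplotype is right-padded with whole-codon gaps to the maximum
#' HVR length.  Region annotations E8 (left flank), HVR and E9 are added.
#'
#' @param haps A [HaplotypeSet-class] whose non-HVR flanks have equal
#'   lengths across haplotypes.
#' @return A [CodingAlignment-class].
#' @examples
#' alignHaplotypes(generateFounderAlleles(config = SimConfig(k = 3)))
#' @export
alignHaplotypes <- function(haps) {
  stopifnot(is(haps, "HaplotypeSet"), length(haps) >= 2L)
  s <- IRanges::start(haps@hvr); e <- IRanges::end(haps@hvr)
  ncod <- Biostrings::width(haps@dna) %/% 3L
  leftLen <- s - 1L; rightLen <- ncod - e
  if (length(unique(leftLen)) != 1L || length(unique(rightLen)) != 1L)
    stop("non-HVR flanks differ in length; cannot gap-align on the HVR alone")
  hvrLen <- e - s + 1L
  maxH <- max(hvrLen)
  rows <- vapply(seq_along(haps@dna), function(i) {
    cod <- .splitCodons(as.character(haps@dna[[i]]))
    pad <- rep("---", maxH - hvrLen[i])
    paste(c(cod[seq_len(leftLen[1L])], cod[s[i]:e[i]], pad,
            if (rightLen[1L] > 0L) cod[(e[i] + 1L):ncod[i]]),
          collapse = "")
  }, "")
  dna <- Biostrings::DNAStringSet(rows)
  names(dna) <- names(haps@dna)
  regs <- IRanges::IRanges(
    start = c(1L, 3L * leftLen[1L] + 1L, 3L * (leftLen[1L] + maxH) + 1L),
    end = c(3L * leftLen[1L], 3L * (leftLen[1L] + maxH),
            3L * (leftLen[1L] + maxH + rightLen[1L])))
  names(regs) <- c("E8", "HVR", "E9")
  new("CodingAlignment", aln = dna, regions = regs)
}
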