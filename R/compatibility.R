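# Functional-heterozygosity analysis: pairwise haplotype distances, the
# simulated-heterozygous-male resampling null, distribution comparison and
# the per-position zygosity screen.

#' Pairwise haplotype distances
#'
#' The four distances used to characterise allele pairs in viable
#' heterozygous males: (i) absolute HVR length difference in residues;
#' (ii) Levenshtein distance between the unaligned HVR amino-acid strings;
#' (iii) Levenshtein distance between the non-HVR amino-acid sequences;
#' and (iv) a composite distance (the HVR edit distance normalised by the
#' maximum HVR length plus the non-HVR p-distance, equal weights) standing
#' in for a mixed-model tree distance.  Conclusions drawn from (iv) should
#' be treated as approximate.
#'
#' @param hvr1,hvr2 Unaligned HVR amino-acid strings.
#' @param nonhvr1,nonhvr2 Non-HVR amino-acid sequences (aligned E8--E9 with
#'   HVR columns removed); may be `NULL`, yielding a partial result with
#'   `nonhvrEdit` and `combined` set to `NA`.
#' @param maxHvrLen Normalising HVR length for the composite (default 24).
#' @return List with `hvrLenDiff`, `hvrEdit`, `nonhvrEdit`, `combined`.
#' @examples
#' pairDistances("NNNNNNN", "NNNNNNNNN")  # length diff 2, edit 2
#' @export
pairDistances <- function(hvr1, hvr2, nonhvr1 = NULL, nonhvr2 = NULL,
                          maxHvrLen = 24L) {
  hvrLenDiff <- abs(nchar(hvr1) - nchar(hvr2))
  hvrEdit <- drop(adist(hvr1, hvr2))
  nonhvrEdit <- NA_integer_; combined <- NA_real_
  if (!is.null(nonhvr1) && !is.null(nonhvr2)) {
    a <- gsub("-", "", nonhvr1, fixed = TRUE)
    b <- gsub("-", "", nonhvr2, fixed = TRUE)
    nonhvrEdit <- drop(adist(a, b))
    combined <- 0.5 * hvrEdit / maxHvrLen +
      0.5 * nonhvrEdit / max(nchar(a), nchar(b), 1L)
  }
  list(hvrLenDiff = hvrLenDiff, hvrEdit = as.integer(hvrEdit),
       nonhvrEdit = as.integer(nonhvrEdit), combined = combined)
}

#' Pairwise distances for all male genotypes in a haplotype set
#'
#' Convenience wrapper applying [pairDistances()] to a table of allele
#' pairs, drawing HVR and non-HVR sequences from a [HaplotypeSet-class]
#' (and its gap alignment from [alignHaplotypes()] when the flanks permit).
#'
#' @param pairs Two-column matrix or data.frame of allele ids.
#' @param haps A [HaplotypeSet-class] containing every id in `pairs`.
#' @return data.frame with one row per pair and the four distance columns.
#' @export
genotypePairDistances <- function(pairs, haps) {
  stopifnot(is(haps, "HaplotypeSet"))
  pairs <- as.matrix(pairs)
  ids <- names(haps@dna)
  if (!all(pairs %in% ids)) stop("pair contains unknown allele id")
  hvr <- hvrAA(haps)
  aa <- as.character(aaSeqs(haps))
  s <- IRanges::start(haps@hvr); e <- IRanges::end(haps@hvr)
  nonhvr <- setNames(paste0(substr(aa, 1L, s - 1L),
                            substr(aa, e + 1L, nchar(aa))), ids)
  out <- lapply(seq_len(nrow(pairs)), function(r) {
    a <- pairs[r, 1L]; b <- pairs[r, 2L]
    as.data.frame(pairDistances(hvr[[a]], hvr[[b]],
                                nonhvr[[a]], nonhvr[[b]]))
  })
  cbind(data.frame(allele1 = pairs[, 1L], allele2 = pairs[, 2L]),
        do.call(rbind, out))
}

#' Resample heterozygous males from an allele frequency distribution
#'
#' Simulates a population of heterozygous males by repeatedly sampling
#' allele pairs with replacement from an empirical haplotype frequency
#' distribution and discarding homozygous draws (which would be inviable).
#'
#' @param counts An [AlleleCounts-class] or named count vector giving the
#'   empirical haplotype frequencies.
#' @param nMales Number of heterozygous males to produce (default 1000).
#' @param seed Optional RNG seed.
#' @return Character matrix `nMales` x 2 of allele ids; no row has two
#'   identical entries.
#' @examples
#' simulateHeterozygousMales(c(a = 3, b = 1), nMales = 5, seed = 1)
#' @export
simulateHeterozygousMales <- function(counts, nMales = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is(counts, "AlleleCounts")) counts <- counts@counts
  if (length(counts) < 2L)
    stop("impossible sample: need at least 2 distinct alleles")
  ids <- names(counts)
  p <- counts / sum(counts)
  out1 <- character(0); out2 <- character(0)
  while (length(out1) < nMales) {
    b <- 2L * (nMales - length(out1)) + 16L
    a1 <- sample(ids, b, replace = TRUE, prob = p)
    a2 <- sample(ids, b, replace = TRUE, prob = p)
    keep <- a1 != a2
    out1 <- c(out1, a1[keep]); out2 <- c(out2, a2[keep])
  }
  cbind(allele1 = out1[seq_len(nMales)], allele2 = out2[seq_len(nMales)])
}

#' Compare observed and simulated distance distributions
#'
#' For each shared distance metric, compares the observed distribution
#' (viable heterozygous males) with the resampling null via a two-sample
#' Kolmogorov-Smirnov test.  Non-rejection supports the null hypothesis
#' that all allele pairs in the sample are mutually compatible; it does not
#' prove it.
#'
#' @param observed,simulated data.frames of per-pair distances (as from
#'   [genotypePairDistances()]); metrics are their shared numeric columns.
#' @return List per metric with `ks` (statistic), `p`, and `histogram`
#'   (observed and simulated relative-frequency tables), plus a `note`
#'   field recording the interpretation caveat.
#' @export
compareDistanceDistributions <- function(observed, simulated) {
  mets <- intersect(names(observed), names(simulated))
  mets <- mets[vapply(mets, function(m)
    is.numeric(observed[[m]]) && is.numeric(simulated[[m]]), TRUE)]
  if (nrow(observed) < 5L || nrow(simulated) < 5L)
    stop("need at least 5 observations per sample")
  out <- lapply(mets, function(m) {
    o <- observed[[m]]; s <- simulated[[m]]
    o <- o[!is.na(o)]; s <- s[!is.na(s)]
    kt <- suppressWarnings(ks.test(o, s))
    brks <- sort(unique(c(o, s)))
    list(ks = unname(kt$statistic), p = kt$p.value,
         histogram = list(observed = table(o) / length(o),
                          simulated = table(s) / length(s)))
  })
  names(out) <- mets
  out$note <- paste("non-rejection is consistent with the null that all",
                    "sampled allele pairs are compatible")
  out
}

#' Per-position zygosity screen across male genotypes
#'
#' Classifies each aligned amino-acid column across a set of heterozygous
#' males as always-het (the two haplotypes differ there in every male),
#' always-hom (they never differ), or mixed.  The HVR, whose internal
#' alignment is unreliable, is additionally treated as a single unit-level
#' locus: a male is heterozygous for the unit if his two HVR strings
#' differ at all.
#'
#' @param aln1,aln2 Character vectors of aligned amino-acid haplotypes
#'   (first and second allele per male), all of equal nchar.
#' @param hvrColumns Optional integer vector of alignment columns forming
#'   the HVR unit.
#' @return List with `column` (factor vector over alignment columns with
#'   levels always_het / always_hom / mixed) and, when `hvrColumns` is
#'   given, `hvrUnit` (one of the same levels).
#' @export
positionalZygosityScreen <- function(aln1, aln2, hvrColumns = NULL) {
  if (length(aln1) != length(aln2) || !length(aln1))
    stop("need one aligned haplotype pair per male")
  w <- unique(nchar(c(aln1, aln2)))
  if (length(w) != 1L) stop("aligned haplotypes must have equal length")
  m1 <- do.call(rbind, strsplit(aln1, ""))
  m2 <- do.call(rbind, strsplit(aln2, ""))
  diffs <- m1 != m2
  classify <- function(colDiff) {
    if (all(colDiff)) "always_het" else if (!any(colDiff)) "always_hom"
    else "mixed"
  }
  colClass <- factor(apply(diffs, 2L, classify),
                     levels = c("always_het", "always_hom", "mixed"))
  out <- list(column = colClass)
  if (!is.null(hvrColumns)) {
    unitDiff <- vapply(seq_along(aln1), function(i)
      !identical(substring(aln1[i], min(hvrColumns), max(hvrColumns)),
                 substring(aln2[i], min(hvrColumns), max(hvrColumns))),
      TRUE)
    out$hvrUnit <- classify(unitDiff)
  }
  out
}
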