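# Codon-aware sequence diversity: sliding-window Nei-Gojobori statistics
# with triplet-indel counting, exon-level diversity, codon usage, HVR
# length distribution, haplotype diversity and AMOVA Phi-ST.

#' Validate a raw alignment into a CodingAlignment
#'
#' Enforces the structural invariants of a codon-aware coding alignment:
#' equal row widths, width a multiple of 3, every gap run a whole number of
#' codons starting on a codon boundary, and no internal stop codons.
#' Violations raise errors naming the offending row and column.
#'
#' @param x A [Biostrings::DNAStringSet] or named character vector of
#'   aligned (gapped) sequences; at least 2 rows.
#' @param regions Optional named [IRanges::IRanges] of region annotations
#'   (1-based closed alignment coordinates).
#' @return A [CodingAlignment-class].
#' @examples
#' validateAlignment(c(h1 = "ATGAAATTT", h2 = "ATGAAATTC"))
#' @export
validateAlignment <- function(x, regions = IRanges::IRanges()) {
  if (!is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  new("CodingAlignment", aln = x, regions = regions)
}

# gap-codon indicator matrix (TRUE where a codon column is entirely "---")
.gapCodonMatrix <- function(seqs) {
  t(vapply(seqs, function(s) .splitCodons(s) == "---",
           logical(nchar(seqs[1L]) %/% 3L)))
}

#' Pairwise triplet-indel count
#'
#' Counts codon columns (within an optional window) gapped in exactly one
#' of two aligned rows.  A shared gap is not a pairwise difference.  Under
#' the default `"per-codon"` mode a maximal gap run of m codons counts as m
#' triplet indels; `"per-event"` counts each maximal one-sided gap run
#' once.  Normalisation by the window codon count (e.g. 33 triplets in a
#' 99-nt window) is left to the caller.
#'
#' @param row1,row2 Aligned sequences (gapped strings of equal length).
#' @param start,end Window in nt alignment coordinates (1-based closed,
#'   codon boundaries); defaults to the full alignment.
#' @param mode `"per-codon"` (default) or `"per-event"`.
#' @return Integer indel count.
#' @examples
#' tripletIndelPair("ATGAAATTT", "ATG------")  # 2 gapped codons
#' @export
tripletIndelPair <- function(row1, row2, start = 1L, end = nchar(row1),
                             mode = c("per-codon", "per-event")) {
  mode <- match.arg(mode)
  if ((start - 1L) %% 3L != 0L || end %% 3L != 0L)
    stop("window must lie on codon boundaries")
  c1 <- .splitCodons(substr(as.character(row1), start, end)) == "---"
  c2 <- .splitCodons(substr(as.character(row2), start, end)) == "---"
  state <- ifelse(c1 & !c2, 1L, ifelse(c2 & !c1, 2L, 0L))
  if (mode == "per-codon") return(sum(state > 0L))
  r <- rle(state)
  sum(r$values > 0L)
}

# window bookkeeping: step left-to-right from position 0; the final partial
# window is reported with its true length
.windowStarts <- function(widthNt, windowNt, stepNt) {
  starts <- integer(0); s <- 1L
  repeat {
    starts <- c(starts, s)
    if (s + windowNt - 1L >= widthNt) break
    s <- s + stepNt
  }
  starts
}

#' Sliding-window synonymous/nonsynonymous diversity with triplet indels
#'
#' Computes, for each window, the mean pairwise Nei-Gojobori synonymous and
#' nonsynonymous p-distances over all sequence pairs at equal weight, and
#' the mean pairwise triplet-indel count per codon.  Bootstrap standard
#' errors resample codon columns within the window.
#'
#' @param aln A [CodingAlignment-class].
#' @param windowNt Window size in nt (multiple of 3; default 99).
#' @param overlapNt Overlap between consecutive windows (default 75; the
#'   step `windowNt - overlapNt` must be a multiple of 3).
#' @param bootReps Bootstrap replicates for SEs (default 100; 0 disables).
#' @param indelMode Passed to [tripletIndelPair()].
#' @param seed Optional RNG seed for the bootstrap.
#' @return data.frame with columns `start`, `end` (0-based half-open nt
#'   coordinates), `nNt`, `piSyn`, `piNonsyn`, `indelPerTriplet`, `seSyn`,
#'   `seNonsyn`.
#' @examples
#' aln <- validateAlignment(c(a = "ATGAAATTTGGG", b = "ATGAAATTCGGG"))
#' slidingWindowDiversity(aln, windowNt = 6, overlapNt = 3, bootReps = 0)
#' @export
slidingWindowDiversity <- function(aln, windowNt = 99L, overlapNt = 75L,
                                   bootReps = 100L,
                                   indelMode = c("per-codon", "per-event"),
                                   seed = NULL) {
  stopifnot(is(aln, "CodingAlignment"))
  indelMode <- match.arg(indelMode)
  windowNt <- as.integer(windowNt); overlapNt <- as.integer(overlapNt)
  if (windowNt %% 3L != 0L) stop("window must be a multiple of 3")
  if (overlapNt >= windowNt) stop("overlap must be smaller than the window")
  stepNt <- windowNt - overlapNt
  if (stepNt %% 3L != 0L) stop("window step must be a multiple of 3")
  W <- Biostrings::width(aln@aln)[1L]
  if (W < windowNt)
    stop(sprintf("alignment (%d nt) is shorter than one %d-nt window",
                 W, windowNt))
  if (!is.null(seed)) set.seed(seed)
  seqs <- as.character(aln@aln)
  enc <- .encodeCodons(seqs)
  gap <- .gapCodonMatrix(seqs)
  n <- nrow(enc)
  pairs <- utils::combn(n, 2L)

  meanPairStats <- function(cols) {
    ps <- pn <- numeric(ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
      st <- .pairNG(enc, pairs[1L, k], pairs[2L, k], cols)
      ps[k] <- if (st[["S"]] > 0) st[["sd"]] / st[["S"]] else NA_real_
      pn[k] <- if (st[["N"]] > 0) st[["nd"]] / st[["N"]] else NA_real_
    }
    c(piSyn = mean(ps, na.rm = TRUE), piNonsyn = mean(pn, na.rm = TRUE))
  }

  starts <- .windowStarts(W, windowNt, stepNt)
  out <- lapply(starts, function(s) {
    e <- min(s + windowNt - 1L, W)
    cols <- ((s - 1L) %/% 3L + 1L):(e %/% 3L)
    base <- meanPairStats(cols)
    # triplet indels per codon: fixed window codon count in the denominator
    ind <- vapply(seq_len(ncol(pairs)), function(k) {
      g1 <- gap[pairs[1L, k], cols]; g2 <- gap[pairs[2L, k], cols]
      state <- ifelse(g1 & !g2, 1L, ifelse(g2 & !g1, 2L, 0L))
      cnt <- if (indelMode == "per-codon") sum(state > 0L) else
        sum(rle(state)$values > 0L)
      cnt / length(cols)
    }, 0)
    ses <- c(seSyn = NA_real_, seNonsyn = NA_real_)
    if (bootReps > 0L) {
      reps <- vapply(seq_len(bootReps), function(r)
        meanPairStats(sample(cols, length(cols), replace = TRUE)),
        numeric(2L))
      ses <- c(seSyn = sd(reps[1L, ], na.rm = TRUE),
               seNonsyn = sd(reps[2L, ], na.rm = TRUE))
    }
    data.frame(start = s - 1L, end = e, nNt = e - s + 1L,
               piSyn = base[["piSyn"]], piNonsyn = base[["piNonsyn"]],
               indelPerTriplet = mean(ind),
               seSyn = ses[["seSyn"]], seNonsyn = ses[["seNonsyn"]])
  })
  do.call(rbind, out)
}

.resolveRegion <- function(aln, region) {
  if (is.character(region)) {
    if (!region %in% names(aln@regions))
      stop("unknown region '", region, "'")
    r <- aln@regions[names(aln@regions) == region]
    c(IRanges::start(r), IRanges::end(r))
  } else if (length(region) == 2L) {
    as.integer(region)
  } else stop("region must be a name or a (start, end) pair")
}

#' Exon-level nucleotide diversity
#'
#' Computes mean pairwise nucleotide diversity (p-distance, optionally
#' Jukes-Cantor corrected) and Nei-Gojobori synonymous/nonsynonymous
#' p-distances over a region of a coding alignment, with bootstrap SEs
#' over codon columns.
#'
#' @param aln A [CodingAlignment-class].
#' @param region Region name (see [regions()]) or 1-based closed
#'   `c(start, end)` nt coordinates on codon boundaries; default the whole
#'   alignment.
#' @param bootReps Bootstrap replicates (default 100).
#' @param jc Apply the Jukes-Cantor correction to total pi (default FALSE:
#'   plain p-distance).
#' @param seed Optional RNG seed for the bootstrap.
#' @return List with `pi`, `piSyn`, `piNonsyn` and bootstrap `sePi`,
#'   `seSyn`, `seNonsyn`.
#' @examples
#' aln <- validateAlignment(c(a = "TTTAAA", b = "TTCAAA"))
#' exonDiversity(aln, bootReps = 0)
#' @export
exonDiversity <- function(aln, region = NULL, bootReps = 100L, jc = FALSE,
                          seed = NULL) {
  stopifnot(is(aln, "CodingAlignment"))
  W <- Biostrings::width(aln@aln)[1L]
  se <- if (is.null(region)) c(1L, W) else .resolveRegion(aln, region)
  if (se[2L] < se[1L]) stop("empty region")
  if ((se[1L] - 1L) %% 3L != 0L || se[2L] %% 3L != 0L)
    stop("region must lie on codon boundaries")
  if (!is.null(seed)) set.seed(seed)
  seqs <- as.character(aln@aln)
  enc <- .encodeCodons(seqs)
  ntMat <- t(vapply(seqs, function(s) strsplit(s, "")[[1L]],
                    character(nchar(seqs[1L]))))
  n <- nrow(enc)
  pairs <- utils::combn(n, 2L)
  cols <- ((se[1L] - 1L) %/% 3L + 1L):(se[2L] %/% 3L)

  statsFor <- function(cc) {
    ntIdx <- as.vector(vapply(cc, function(cl) (3L * (cl - 1L) + 1L):(3L * cl),
                              integer(3L)))
    pAll <- ps <- pn <- numeric(ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1L, k]; j <- pairs[2L, k]
      a <- ntMat[i, ntIdx]; b <- ntMat[j, ntIdx]
      ok <- a %in% .BASES & b %in% .BASES
      pAll[k] <- if (any(ok)) sum(a[ok] != b[ok]) / sum(ok) else NA_real_
      if (jc && !is.na(pAll[k]))
        pAll[k] <- if (pAll[k] < 0.75) -0.75 * log(1 - 4 * pAll[k] / 3)
                   else NA_real_
      st <- .pairNG(enc, i, j, cc)
      ps[k] <- if (st[["S"]] > 0) st[["sd"]] / st[["S"]] else NA_real_
      pn[k] <- if (st[["N"]] > 0) st[["nd"]] / st[["N"]] else NA_real_
    }
    c(pi = mean(pAll, na.rm = TRUE), piSyn = mean(ps, na.rm = TRUE),
      piNonsyn = mean(pn, na.rm = TRUE))
  }

  base <- statsFor(cols)
  ses <- c(NA_real_, NA_real_, NA_real_)
  if (bootReps > 0L) {
    reps <- vapply(seq_len(bootReps), function(r)
      statsFor(sample(cols, length(cols), replace = TRUE)), numeric(3L))
    ses <- apply(reps, 1L, sd, na.rm = TRUE)
  }
  list(pi = base[["pi"]], piSyn = base[["piSyn"]],
       piNonsyn = base[["piNonsyn"]],
       sePi = ses[1L], seSyn = ses[2L], seNonsyn = ses[3L])
}

#' Codon usage inside versus outside the HVR
#'
#' Per-haplotype proportions over the 61 sense codons, separately for the
#' HVR and the non-HVR portion, plus a flag recording whether every HVR
#' codon follows the ANT/NAT pattern.
#'
#' @param haps A [HaplotypeSet-class] with annotated HVR spans.
#' @return List with matrices `hvr` and `nonHvr` (haplotype x 61 sense
#'   codons; rows of empty regions are NA and flagged in `emptyHvr` /
#'   `emptyNonHvr`), and logical `antNatOnly` (all HVR codons match
#'   ANT/NAT across the set).
#' @examples
#' h <- HaplotypeSet(c(a = "ATGAATAATCATGGG"), IRanges::IRanges(2, 4))
#' codonUsageProfile(h)$hvr[, c("AAT", "CAT")]
#' @export
codonUsageProfile <- function(haps) {
  stopifnot(is(haps, "HaplotypeSet"))
  sense <- .SENSE_CODONS
  n <- length(haps)
  mk <- function() matrix(NA_real_, n, length(sense),
                          dimnames = list(names(haps@dna), sense))
  hvrM <- mk(); nonM <- mk()
  allAntNat <- TRUE
  for (i in seq_len(n)) {
    cod <- .splitCodons(as.character(haps@dna[[i]]))
    s <- IRanges::start(haps@hvr)[i]; e <- IRanges::end(haps@hvr)[i]
    inHvr <- seq_along(cod) >= s & seq_along(cod) <= e
    for (reg in c("hvr", "non")) {
      cc <- cod[if (reg == "hvr") inHvr else !inHvr]
      cc <- cc[cc %in% sense]
      if (length(cc)) {
        tb <- table(factor(cc, levels = sense))
        pr <- as.numeric(tb) / length(cc)
        if (reg == "hvr") hvrM[i, ] <- pr else nonM[i, ] <- pr
      }
    }
    hvrCod <- cod[inHvr]
    if (length(hvrCod) && !all(grepl(.HVR_PATTERN, hvrCod)))
      allAntNat <- FALSE
  }
  list(hvr = hvrM, nonHvr = nonM,
       emptyHvr = apply(hvrM, 1L, function(r) all(is.na(r))),
       emptyNonHvr = apply(nonM, 1L, function(r) all(is.na(r))),
       antNatOnly = allAntNat)
}

#' HVR length distribution
#'
#' @param haps A [HaplotypeSet-class].
#' @return List with `counts` (table keyed by residue length), `min`,
#'   `max`.
#' @examples
#' hvrLengthDistribution(generateFounderAlleles(config = SimConfig(k = 5)))
#' @export
hvrLengthDistribution <- function(haps) {
  stopifnot(is(haps, "HaplotypeSet"), length(haps) >= 1L)
  len <- IRanges::width(haps@hvr)
  list(counts = table(len), min = min(len), max = max(len))
}

#' Haplotype (gene) diversity
#'
#' Unbiased haplotype diversity H = n/(n-1) (1 - sum p_i^2).
#'
#' @param counts An [AlleleCounts-class], named count vector, or character
#'   vector of per-observation allele ids.
#' @return Haplotype diversity in [0, 1].
#' @examples
#' haplotypeDiversity(c(a = 1, b = 1))  # 1
#' @export
haplotypeDiversity <- function(counts) {
  if (is(counts, "AlleleCounts")) counts <- counts@counts
  if (is.character(counts)) counts <- alleleCounts(AlleleCounts(counts))
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity needs n >= 2 observations")
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

## ---- AMOVA Phi-ST --------------------------------------------------------

.phiFromD2 <- function(d2, groups) {
  N <- length(groups)
  lv <- unique(groups)
  ng <- vapply(lv, function(g) sum(groups == g), 0)
  lower <- lower.tri(d2)
  ssT <- sum(d2[lower]) / N
  ssW <- 0
  for (g in lv) {
    idx <- which(groups == g)
    ssW <- ssW + sum(d2[idx, idx][lower.tri(d2[idx, idx])]) / length(idx)
  }
  ssA <- ssT - ssW
  dfA <- length(lv) - 1L; dfW <- N - length(lv)
  msA <- ssA / dfA; msW <- ssW / dfW
  n0 <- (N - sum(ng^2) / N) / dfA
  s2a <- (msA - msW) / n0
  s2a / (s2a + msW)
}

#' AMOVA Phi-ST with permutation test
#'
#' Computes the AMOVA fixation index Phi-ST (proportion of molecular
#' variance among populations) from a pairwise distance matrix, overall and
#' for every population pair, with a permutation p-value obtained by
#' shuffling population labels.
#'
#' @param d Square symmetric distance matrix (or `dist`) over individuals.
#' @param populations Population label per individual.
#' @param nPerm Number of label permutations (default 1000).
#' @param seed Optional RNG seed.
#' @return List with `phiST` (overall), `pairwise` (matrix of pairwise
#'   Phi-ST), `p` (permutation p for the overall statistic, in (0, 1]),
#'   `nPerm`, and `excluded` (labels of singleton populations dropped with
#'   a warning).
#' @examples
#' d <- as.matrix(dist(c(0, 0.1, 5, 5.1)))
#' amovaPhiSt(d, c("x", "x", "y", "y"), nPerm = 99, seed = 1)$phiST
#' @export
amovaPhiSt <- function(d, populations, nPerm = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || nrow(d) != length(populations))
    stop("distance matrix and population labels do not match")
  populations <- as.character(populations)
  tb <- table(populations)
  excluded <- names(tb)[tb < 2L]
  if (length(excluded)) {
    warning("excluding singleton population(s): ",
            paste(excluded, collapse = ", "))
    keep <- !(populations %in% excluded)
    d <- d[keep, keep, drop = FALSE]
    populations <- populations[keep]
  }
  if (length(unique(populations)) < 2L)
    stop("need at least 2 populations with >= 2 members each")
  d2 <- d^2
  obs <- .phiFromD2(d2, populations)
  ge <- 0L
  for (r in seq_len(nPerm)) {
    if (.phiFromD2(d2, sample(populations)) >= obs) ge <- ge + 1L
  }
  lv <- unique(populations)
  pw <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (a in seq_along(lv)) for (b in seq_along(lv)) {
    if (a < b) {
      idx <- populations %in% lv[c(a, b)]
      pw[a, b] <- pw[b, a] <-
        .phiFromD2(d2[idx, idx, drop = FALSE], populations[idx])
    }
  }
  list(phiST = obs, pairwise = pw, average = mean(pw[upper.tri(pw)]),
       p = (ge + 1L) / (nPerm + 1L), nPerm = nPerm, excluded = excluded)
}
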