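# Allele frequency spectra and Chao1/iChao1 richness extrapolation.

#' Effective-wild-sample correction
#'
#' Lab-reared G1 populations descend from a restricted number of wild
#' families, so repeated copies of an allele within a G1 population carry
#' no independent information about wild frequencies.  This correction
#' counts each allele within a G1-flagged population at most once; truly
#' wild observations are left unchanged.
#'
#' @param observations data.frame with columns `population`, `g1`
#'   (logical), `allele` (one row per observed allele copy).
#' @return An [AlleleCounts-class] over the corrected sample, with the
#'   effective sample size attached as attribute `effectiveN`.
#' @examples
#' obs <- data.frame(population = c("p", "p", "p", "p"),
#'                   g1 = TRUE, allele = c("a", "a", "a", "b"))
#' alleleCounts(effectiveWildCorrection(obs))  # a = 1, b = 1
#' @export
effectiveWildCorrection <- function(observations) {
  need <- c("population", "g1", "allele")
  if (!all(need %in% names(observations)))
    stop("observations need columns: ", paste(need, collapse = ", "))
  parts <- split(observations, observations$population)
  kept <- lapply(parts, function(p) {
    if (isTRUE(p$g1[1L]) || all(p$g1)) unique(p$allele) else p$allele
  })
  alleles <- unlist(kept, use.names = FALSE)
  out <- AlleleCounts(alleles)
  attr(out, "effectiveN") <- length(alleles)
  out
}

#' Allele abundance frequency spectrum
#'
#' Tabulates the abundance-frequency counts f_k (f1 singletons, f2
#' doubletons, ...) of an allele sample.
#'
#' @param counts An [AlleleCounts-class], named count vector, or character
#'   vector of per-observation allele ids.
#' @return List with `fk` (named integer vector indexed by abundance k),
#'   `sObs` (observed richness), `n` (sample size), and
#'   `singletonProportion` (f1 / sObs).
#' @examples
#' frequencySpectrum(c(a = 1, b = 1, c = 2))
#' @export
frequencySpectrum <- function(counts) {
  if (is.character(counts) && is.null(names(counts)))
    counts <- alleleCounts(AlleleCounts(counts))
  if (is(counts, "AlleleCounts")) counts <- counts@counts
  counts <- as.integer(counts)
  if (length(counts) < 1L || any(counts < 1L))
    stop("need a non-empty table of positive counts")
  tb <- table(counts)
  fk <- setNames(as.integer(tb), names(tb))
  list(fk = fk, sObs = length(counts), n = sum(counts),
       singletonProportion = sum(counts == 1L) / length(counts))
}

.fkGet <- function(fk, k) {
  v <- fk[as.character(k)]
  ifelse(is.na(v), 0, as.numeric(v))
}

# point estimators on (possibly non-integer) f1..f4 and sObs
.chao1Point <- function(f1, f2, sObs) {
  if (f2 > 0) sObs + f1^2 / (2 * f2) else sObs + f1 * (f1 - 1) / 2
}

.ichao1Point <- function(f1, f2, f3, f4, sObs) {
  ch <- .chao1Point(f1, f2, sObs)
  if (f3 <= 0) return(ch)
  f4 <- max(f4, 1)  # published f4 = 0 modification
  ch + f3 / (4 * f4) * max(f1 - f2 * f3 / (2 * f4), 0)
}

#' Chao1 and iChao1 allele richness estimators
#'
#' Nonparametric lower-bound richness estimation from the abundance
#' frequency counts: Chao1 (with the standard bias-corrected form when
#' f2 = 0) and the improved iChao1 estimator, which adds an f3/f4 term
#' (with f4 replaced by 1 when f4 = 0).  The 95% confidence interval uses
#' the standard log-transform on (estimate - sObs), with the estimator
#' variance obtained by the delta method on the frequency counts
#' (Cov(fi, fj) = -fi fj / S-hat, Var(fi) = fi (1 - fi / S-hat)).
#'
#' @param x A spectrum as returned by [frequencySpectrum()], an
#'   [AlleleCounts-class], or a named count vector.
#' @param conf Confidence level (default 0.95).
#' @return List with `chao1`, `ichao1`, `ciLow`, `ciHigh` (CI for iChao1),
#'   `se`, `sObs`, `n`.
#' @examples
#' iChao1(c(a = 1, b = 1, c = 2))
#' @export
iChao1 <- function(x, conf = 0.95) {
  spec <- if (is.list(x) && !is.null(x$fk)) x else frequencySpectrum(x)
  fk <- spec$fk
  if (spec$sObs < 1L) stop("empty spectrum")
  f <- vapply(1:4, function(k) .fkGet(fk, k), 0)
  sObs <- spec$sObs
  chao1 <- .chao1Point(f[1L], f[2L], sObs)
  est <- .ichao1Point(f[1L], f[2L], f[3L], f[4L], sObs)
  if (f[1L] == 0) {  # no unseen-class signal
    return(list(chao1 = sObs, ichao1 = sObs, ciLow = sObs, ciHigh = sObs,
                se = 0, sObs = sObs, n = spec$n))
  }
  # delta-method variance over all observed abundance classes: perturbing
  # f_k moves sObs one-for-one and, for k <= 4, also the improvement terms
  allk <- sort(unique(c(as.integer(names(fk)), 1:4)))
  fAll <- vapply(allk, function(k) .fkGet(fk, k), 0)
  grad <- vapply(allk, function(k) {
    if (k > 4L) return(1)
    h <- 1e-4
    fp <- f; fp[k] <- fp[k] + h
    (.ichao1Point(fp[1L], fp[2L], fp[3L], fp[4L], sObs + h) - est) / h
  }, 0)
  covM <- -outer(fAll, fAll) / est
  diag(covM) <- fAll * (1 - fAll / est)
  v <- max(drop(t(grad) %*% covM %*% grad), 0)
  T0 <- est - sObs
  if (T0 <= 0 || v <= 0) {
    ciLow <- ciHigh <- est
  } else {
    K <- exp(qnorm(1 - (1 - conf) / 2) * sqrt(log(1 + v / T0^2)))
    ciLow <- sObs + T0 / K
    ciHigh <- sObs + T0 * K
  }
  list(chao1 = chao1, ichao1 = est,
       ciLow = min(ciLow, est), ciHigh = max(ciHigh, est),
       se = sqrt(v), sObs = sObs, n = spec$n)
}
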