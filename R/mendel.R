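# Genetic models and tests: cross expectations under the zygosity rule,
# sex/viability classification, segregation chi-square, Hardy-Weinberg
# homozygote-deficit test, Fisher exact sex-linkage test, and the
# knockdown contingency test.

#' Expected offspring classes under the zygosity rule
#'
#' Enumerates the zygote classes of a mother x father cross under equal
#' Mendelian segregation.  A WZ mother transmits W or her Z allele with
#' probability 1/2 each; a Z0 mother transmits her Z or no sex chromosome
#' with probability 1/2 each (random segregation of the unpaired Z
#' univalent); the father transmits either allele equally.  ZZ zygotes with
#' two identical alleles are flagged inviable: when the parents share an
#' allele the inviable fraction is 1/4 (half of all ZZ zygotes), otherwise
#' zero.
#'
#' @param mother List with `karyotype` ("WZ" or "Z0") and `alleles` (one
#'   allele id).
#' @param father List with `alleles` (two distinct allele ids).
#' @return List with `classes` (data.frame: karyotype, genotype,
#'   proportion, viable) and `inviableFraction`.
#' @examples
#' expectedOffspring(list(karyotype = "WZ", alleles = "a"),
#'                   list(alleles = c("a", "b")))$inviableFraction  # 0.25
#' @export
expectedOffspring <- function(mother, father) {
  if (is.null(mother$karyotype) ||
      !mother$karyotype %in% c("WZ", "Z0") ||
      length(mother$alleles) != 1L)
    stop("malformed genotype: mother must be WZ or Z0 with one allele")
  if (length(father$alleles) != 2L ||
      father$alleles[1L] == father$alleles[2L])
    stop("malformed genotype: father must carry two distinct alleles")
  m <- mother$alleles
  femKar <- mother$karyotype  # daughters inherit the mother's route
  rows <- list()
  for (fa in father$alleles) {
    rows[[length(rows) + 1L]] <- data.frame(
      karyotype = femKar, genotype = fa, proportion = 0.25, viable = TRUE)
    gt <- paste(sort(c(m, fa)), collapse = "/")
    rows[[length(rows) + 1L]] <- data.frame(
      karyotype = "ZZ", genotype = gt, proportion = 0.25,
      viable = m != fa)
  }
  cl <- do.call(rbind, rows)
  cl <- stats::aggregate(proportion ~ karyotype + genotype + viable,
                         data = cl, FUN = sum)
  cl <- cl[order(cl$karyotype, cl$genotype), ]
  rownames(cl) <- NULL
  list(classes = cl,
       inviableFraction = sum(cl$proportion[!cl$viable]))
}

#' Classify an individual from sexing markers
#'
#' Decision table mapping W-chromosome presence, the number of distinct
#' alleles at the sex locus, and (when needed) Z dose to a sex/viability
#' class.  The function is total: insufficient inputs yield "ambiguous",
#' never an error.
#'
#' @param wPresent "yes", "no", or "unknown".
#' @param nDistinctAlleles 1 or 2.
#' @param zDose Optional Z-chromosome dose (1 or 2); `NA` if unknown.
#' @return One of "WZ-female", "Z0-female", "ZZ-het-male",
#'   "ZZ-hom-inviable", "WZZ-male", "ambiguous".
#' @examples
#' classifyIndividual("yes", 1)        # WZ-female
#' classifyIndividual("no", 1, 2)      # ZZ-hom-inviable
#' classifyIndividual("no", 1)         # ambiguous (Z dose unknown)
#' @export
classifyIndividual <- function(wPresent = c("yes", "no", "unknown"),
                               nDistinctAlleles, zDose = NA) {
  wPresent <- match.arg(as.character(wPresent),
                        c("yes", "no", "unknown"))
  n <- as.integer(nDistinctAlleles)
  if (!n %in% c(1L, 2L)) stop("nDistinctAlleles must be 1 or 2")
  if (wPresent == "unknown") {
    # two distinct alleles imply a male either way; W decides WZZ vs ZZ
    return("ambiguous")
  }
  if (wPresent == "yes") {
    if (n == 1L) return("WZ-female") else return("WZZ-male")
  }
  if (n == 2L) return("ZZ-het-male")
  if (is.na(zDose)) return("ambiguous")
  if (zDose == 1) "Z0-female" else "ZZ-hom-inviable"
}

#' Segregation goodness-of-fit test
#'
#' Pearson chi-square (no continuity correction) of observed offspring
#' class counts against the expectation of a cross.  Classes with expected
#' proportion zero (e.g. homozygotes in a non-sharing cross) are validated
#' as hard constraints: a nonzero observation there is reported as a rule
#' violation, not absorbed into the statistic.
#'
#' @param observed Named integer vector of class counts.
#' @param expectation Either a result of [expectedOffspring()] or a named
#'   vector of expected proportions (matching `names(observed)`).
#' @return List with `statistic`, `df`, `p`, and `violations` (names of
#'   zero-expectation classes with nonzero observations; empty when none).
#' @examples
#' segregationChisq(c(f = 30, m = 30), c(f = 0.5, m = 0.5))$statistic  # 0
#' @export
segregationChisq <- function(observed, expectation) {
  if (is.list(expectation) && !is.null(expectation$classes)) {
    cl <- expectation$classes
    exp <- setNames(cl$proportion, paste(cl$karyotype, cl$genotype,
                                         sep = ":"))
  } else exp <- expectation
  if (is.null(names(observed)) || !all(names(observed) %in% names(exp)))
    stop("observed classes must match the expectation classes")
  full <- setNames(rep(0, length(exp)), names(exp))
  full[names(observed)] <- observed
  zero <- names(exp)[exp == 0]
  violations <- zero[full[zero] > 0]
  keep <- exp > 0
  x <- full[keep]; p <- exp[keep] / sum(exp[keep])
  e <- sum(x) * p
  stat <- sum((x - e)^2 / e)
  df <- length(x) - 1L
  list(statistic = stat, df = df,
       p = pchisq(stat, df, lower.tail = FALSE),
       violations = violations)
}

#' Hardy-Weinberg homozygote-deficit test
#'
#' Tests an adult male sample for the deficit of sex-locus homozygotes
#' expected under Hardy-Weinberg equilibrium, with allele frequencies
#' estimated from a contemporary female sample.  The male sample is
#' treated as a hom/het binary split against the expected homozygote
#' proportion sum(p_i^2).
#'
#' @param freqs Named numeric allele frequencies (must sum to 1).
#' @param n Male sample size.
#' @param observedHom Observed number of homozygous males (zero is the
#'   expected finding at a lethal-homozygote locus).
#' @return List with `expectedHomProportion`, `expectedHom`, `statistic`,
#'   `df`, `p`, and `underpowered` (TRUE when the expected homozygote
#'   count is below 5, where the chi-square approximation is weak and the
#'   test has little power).
#' @examples
#' hwHomozygoteDeficit(rep(0.2, 5), n = 100, observedHom = 0)
#' @export
hwHomozygoteDeficit <- function(freqs, n, observedHom) {
  if (abs(sum(freqs) - 1) > 1e-6) stop("allele frequencies must sum to 1")
  if (n <= 0) stop("male sample size must be positive")
  pHom <- sum(freqs^2)
  eHom <- n * pHom
  obs <- c(observedHom, n - observedHom)
  expd <- c(eHom, n - eHom)
  stat <- sum((obs - expd)^2 / expd)
  list(expectedHomProportion = pHom, expectedHom = eHom,
       statistic = stat, df = 1L,
       p = pchisq(stat, 1L, lower.tail = FALSE),
       underpowered = eHom < 5)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric test with the standard two-sided definition: the
#' p-value sums the probabilities of all tables (at fixed margins) whose
#' point probability does not exceed that of the observed table.  For a
#' marker present in all 8 daughters and absent in all 8 sons this yields
#' p = 2/12870.
#'
#' @param tab 2x2 matrix (or 4-vector, column-major) of nonnegative
#'   counts with positive margins.
#' @return Two-sided p-value.
#' @examples
#' fisherExact2x2(matrix(c(8, 0, 0, 8), 2))  # 2/12870
#' @export
fisherExact2x2 <- function(tab) {
  tab <- matrix(as.numeric(tab), 2L, 2L)
  if (any(tab < 0)) stop("counts must be nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("undefined test: zero margin")
  fisher.test(tab, alternative = "two.sided")$p.value
}

#' Knockdown contingency test
#'
#' Pearson chi-square on a 2x2 success/total contingency (e.g. the number
#' of ZZ heterozygotes expressing the female isoform in control versus
#' knockdown treatments).  The default applies no continuity correction:
#' Yates' correction is exposed for contrast but is not the default, since
#' the uncorrected statistic is the conventional one for these sample
#' sizes.
#'
#' @param controlSucc,controlTot Control successes and total.
#' @param treatedSucc,treatedTot Treated successes and total.
#' @param correct Apply Yates' continuity correction (default FALSE).
#' @return List with `statistic`, `df`, `p`, and the 2x2 `table`.
#' @examples
#' knockdownContingency(0, 14, 11, 20)$p  # < 0.001
#' @export
knockdownContingency <- function(controlSucc, controlTot,
                                 treatedSucc, treatedTot,
                                 correct = FALSE) {
  if (controlTot <= 0 || treatedTot <= 0) stop("totals must be positive")
  tab <- matrix(c(controlSucc, controlTot - controlSucc,
                  treatedSucc, treatedTot - treatedSucc),
                nrow = 2L,
                dimnames = list(c("success", "failure"),
                                c("control", "treated")))
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab)
}
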