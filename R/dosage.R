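# Dosage-compensation analysis on expression tables: filtering, Z and
# autosome medians, Z:A ratios under cutoff sweeps, pairwise relative
# expression, and Wilcoxon tests with Bonferroni correction.

.checkExprSE <- function(se) {
  stopifnot(is(se, "SummarizedExperiment"))
  if (!"geneClass" %in% names(SummarizedExperiment::rowData(se)))
    stop("rowData(se)$geneClass (A/Z) is required")
  if (!"zygosity" %in% names(SummarizedExperiment::colData(se)))
    stop("colData(se)$zygosity (hem/het/hom) is required")
  m <- SummarizedExperiment::assay(se)
  if (any(m < 0)) stop("abundances must be nonnegative")
  invisible(se)
}

#' Filter an expression table on abundance cutoffs
#'
#' Keeps a gene if its abundance is strictly greater than `minAbund` in at
#' least `minSamples` samples (the inclusion rule "> 1 TPM in at least
#' three samples" with the defaults).
#'
#' @param se A [SummarizedExperiment::SummarizedExperiment] with
#'   `rowData(se)$geneClass` (A/Z) and `colData(se)$zygosity`
#'   (hem/het/hom).
#' @param minAbund Abundance threshold (default 1).
#' @param minSamples Minimum number of samples exceeding it (default 3).
#' @return The filtered SummarizedExperiment; the retained per-class gene
#'   counts are attached as `metadata(se)$retained`.
#' @examples
#' se <- simulateExpressionMatrix(100, 30, seed = 1)
#' filterExpression(se)
#' @export
filterExpression <- function(se, minAbund = 1, minSamples = 3) {
  .checkExprSE(se)
  if (minAbund < 0 || minSamples < 0) stop("thresholds must be >= 0")
  m <- SummarizedExperiment::assay(se)
  keep <- rowSums(m > minAbund) >= minSamples
  out <- se[keep, ]
  gc <- SummarizedExperiment::rowData(out)$geneClass
  S4Vectors::metadata(out)$retained <-
    c(nA = sum(gc == "A"), nZ = sum(gc == "Z"))
  out
}

# per-gene within-class mean of replicate samples
.classMeans <- function(se) {
  m <- SummarizedExperiment::assay(se)
  zy <- SummarizedExperiment::colData(se)$zygosity
  vapply(unique(zy), function(cl)
    rowMeans(m[, zy == cl, drop = FALSE]), numeric(nrow(m)))
}

#' Z and autosome medians and Z:A ratios per zygosity class
#'
#' Summarises each gene by the mean of its replicate samples within each
#' zygosity class, then takes the median across genes separately for
#' autosomal (A) and Z-linked (Z) genes.  The Z:A ratio of a class is
#' median(Z) / median(A).
#'
#' @param se A filtered expression SummarizedExperiment (see
#'   [filterExpression()]).
#' @return List with `medians` (matrix geneClass x zygosity class) and
#'   `zaRatio` (named vector per zygosity class).  An empty A or Z set
#'   yields `NA` ratios.
#' @examples
#' zaMedians(simulateExpressionMatrix(100, 30, seed = 1))$zaRatio
#' @export
zaMedians <- function(se) {
  .checkExprSE(se)
  cm <- .classMeans(se)
  gc <- SummarizedExperiment::rowData(se)$geneClass
  meds <- rbind(A = apply(cm[gc == "A", , drop = FALSE], 2L, median),
                Z = apply(cm[gc == "Z", , drop = FALSE], 2L, median))
  ratio <- if (sum(gc == "A") == 0L || sum(gc == "Z") == 0L)
    setNames(rep(NA_real_, ncol(cm)), colnames(cm))
  else meds["Z", ] / meds["A", ]
  list(medians = meds, zaRatio = ratio)
}

#' Per-gene relative expression between two zygosity classes
#'
#' For each gene, the ratio of its within-class replicate means between
#' two zygosity classes, reported separately for autosomal and Z-linked
#' genes.  Genes with zero mean in the denominator class are excluded
#' (reported, not treated as infinite).
#'
#' @param se An expression SummarizedExperiment.
#' @param class1,class2 Zygosity class labels (numerator, denominator).
#' @return List with `ratios` (data.frame gene, geneClass, ratio),
#'   `medianA`, `medianZ`, and `nExcluded` (zero-denominator genes).
#' @examples
#' pairwiseRelativeExpression(
#'   simulateExpressionMatrix(100, 30, seed = 1), "hom", "hem")$medianZ
#' @export
pairwiseRelativeExpression <- function(se, class1, class2) {
  .checkExprSE(se)
  zy <- SummarizedExperiment::colData(se)$zygosity
  if (!class1 %in% zy || !class2 %in% zy)
    stop("both classes must be present among the samples")
  m <- SummarizedExperiment::assay(se)
  num <- rowMeans(m[, zy == class1, drop = FALSE])
  den <- rowMeans(m[, zy == class2, drop = FALSE])
  keep <- den > 0
  gc <- SummarizedExperiment::rowData(se)$geneClass
  ratios <- data.frame(gene = rownames(se)[keep],
                       geneClass = gc[keep],
                       ratio = num[keep] / den[keep])
  list(ratios = ratios,
       medianA = median(ratios$ratio[ratios$geneClass == "A"]),
       medianZ = median(ratios$ratio[ratios$geneClass == "Z"]),
       nExcluded = sum(!keep))
}

#' Wilcoxon rank-sum test of Z versus autosomal relative expression
#'
#' Two-sample rank-sum test comparing the log2 relative-expression
#' distributions of Z-linked and autosomal genes, with Bonferroni
#' correction for the number of zygosity-class comparisons.
#'
#' @param ratiosA,ratiosZ Positive per-gene ratios for autosomal and
#'   Z-linked genes (at least 3 each).
#' @param mTests Bonferroni multiplier (default 3: the three pairwise
#'   zygosity comparisons).
#' @return List with `statistic`, `p` (raw), `pAdjusted`
#'   (min(1, mTests * p)).
#' @examples
#' wilcoxonZA(runif(50, 0.9, 1.1), runif(50, 1.8, 2.2))
#' @export
wilcoxonZA <- function(ratiosA, ratiosZ, mTests = 3L) {
  if (length(ratiosA) < 3L || length(ratiosZ) < 3L)
    stop("need at least 3 values per group")
  wt <- suppressWarnings(wilcox.test(log2(ratiosZ), log2(ratiosA)))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       pAdjusted = min(1, mTests * wt$p.value))
}

#' Z:A ratio sweep over filtering cutoffs
#'
#' Evaluates the per-class Z:A median ratio over a grid of minimum-sample
#' and minimum-abundance inclusion thresholds, making explicit how cutoff
#' choices move the ratio estimates.
#'
#' @param se An (unfiltered) expression SummarizedExperiment.
#' @param minSamplesGrid Integer grid (default 1:12).
#' @param minAbundGrid Numeric grid (default c(0, 1, 2)).
#' @return data.frame with columns `minAbund`, `minSamples`, `nA`, `nZ`,
#'   and one Z:A ratio column per zygosity class.
#' @examples
#' head(zaCutoffSweep(simulateExpressionMatrix(100, 30, seed = 1),
#'                    minSamplesGrid = 1:3))
#' @export
zaCutoffSweep <- function(se, minSamplesGrid = 1:12,
                          minAbundGrid = c(0, 1, 2)) {
  .checkExprSE(se)
  if (!length(minSamplesGrid) || !length(minAbundGrid))
    stop("grids must be nonempty")
  grid <- expand.grid(minAbund = minAbundGrid,
                      minSamples = minSamplesGrid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    f <- filterExpression(se, grid$minAbund[i], grid$minSamples[i])
    ret <- S4Vectors::metadata(f)$retained
    if (ret[["nA"]] == 0L || ret[["nZ"]] == 0L) {
      zr <- setNames(rep(NA_real_,
                         length(unique(SummarizedExperiment::colData(se)$zygosity))),
                     unique(SummarizedExperiment::colData(se)$zygosity))
    } else zr <- zaMedians(f)$zaRatio
    cbind(grid[i, , drop = FALSE],
          data.frame(nA = ret[["nA"]], nZ = ret[["nZ"]]),
          as.data.frame(as.list(zr)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
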