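# Nei-Gojobori (1986) unweighted pathway counting of synonymous and
# nonsynonymous sites and differences, at codon granularity.
#
# Conventions (documented in the methods vignette):
#  * a position's synonymous fraction counts substitutions to stop codons
#    as nonsynonymous, so per-codon sites always sum to 3;
#  * multi-hit codon pairs average the synonymous/nonsynonymous step counts
#    over all minimal substitution pathways that avoid stop-codon
#    intermediates (with a fallback to all pathways in the degenerate case
#    where every pathway is blocked);
#  * codons containing gaps or ambiguity codes, and stop codons, are
#    non-comparable and are skipped pairwise (pairwise deletion).

.CODONS <- names(Biostrings::GENETIC_CODE)
.BASES <- c("A", "C", "G", "T")

.ngEnv <- new.env(parent = emptyenv())

.codonAA <- function(codon) Biostrings::GENETIC_CODE[[codon]]

# per-codon synonymous site count (sum over the 3 positions of the fraction
# of single-base changes that preserve the amino acid)
.synSiteCount <- function(codon) {
  if (.codonAA(codon) == "*") return(NA_real_)
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(.BASES, substr(codon, p, p))) {
      alt <- codon
      substr(alt, p, p) <- b
      if (.codonAA(alt) == .codonAA(codon)) s <- s + 1 / 3
    }
  }
  s
}

# mean (syn, nonsyn) step counts over minimal pathways between two codons
.pathwayCounts <- function(c1, c2, allowStops = FALSE) {
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  d <- length(pos)
  if (d == 0L) return(c(0, 0))
  perms <- if (d == 1L) list(pos) else
    if (d == 2L) list(pos, rev(pos)) else
    lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
           function(o) pos[o])
  acc <- matrix(NA_real_, length(perms), 2L)
  for (k in seq_along(perms)) {
    cur <- c1; sd <- 0; nd <- 0; ok <- TRUE
    for (step in seq_len(d)) {
      p <- perms[[k]][step]
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (step < d && .codonAA(nxt) == "*" && !allowStops) {
        ok <- FALSE; break
      }
      if (.codonAA(nxt) == .codonAA(cur)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) acc[k, ] <- c(sd, nd)
  }
  if (all(is.na(acc[, 1L]))) {
    if (allowStops) stop("pathway enumeration failed")  # cannot happen
    return(.pathwayCounts(c1, c2, allowStops = TRUE))
  }
  colMeans(acc, na.rm = TRUE)
}

# lazily built lookup tables over the 64 codons (stop rows/cols are NA)
.ngTables <- function() {
  if (!is.null(.ngEnv$SD)) return(as.list(.ngEnv))
  n <- length(.CODONS)
  S <- vapply(.CODONS, .synSiteCount, 0)
  SD <- matrix(NA_real_, n, n, dimnames = list(.CODONS, .CODONS))
  ND <- SD
  sense <- which(!is.na(S))
  for (i in sense) for (j in sense) {
    cnt <- .pathwayCounts(.CODONS[i], .CODONS[j])
    SD[i, j] <- cnt[1L]; ND[i, j] <- cnt[2L]
  }
  .ngEnv$SD <- SD; .ngEnv$ND <- ND
  .ngEnv$S <- S; .ngEnv$N <- ifelse(is.na(S), NA_real_, 3 - S)
  as.list(.ngEnv)
}

# integer codon encoding of alignment rows; NA for gap/ambiguity/stop codons
.encodeCodons <- function(seqs) {
  tabs <- .ngTables()
  sense <- !is.na(tabs$S)
  m <- t(vapply(seqs, function(s) {
    idx <- match(.splitCodons(s), .CODONS)
    idx[!is.na(idx) & !sense[idx]] <- NA_integer_
    idx
  }, integer(nchar(seqs[1L]) %/% 3L)))
  rownames(m) <- names(seqs)
  m
}

#' Nei-Gojobori synonymous/nonsynonymous counts for a sequence pair
#'
#' Counts synonymous and nonsynonymous differences (averaged over all
#' minimal substitution pathways for multi-hit codons) and synonymous and
#' nonsynonymous sites (averaged over the two sequences) for a pair of
#' in-frame coding sequences.  Codon pairs in which either member contains
#' a gap or ambiguity code, or is a stop codon, are skipped (pairwise
#' deletion at codon granularity).
#'
#' @param codons1,codons2 Character vectors of codons, or single strings
#'   whose length is a multiple of 3.  Must be equal length.
#' @return A list with `synDiffs`, `nonsynDiffs`, `synSites`,
#'   `nonsynSites`, `nCodons` (comparable codons), and the p-distances
#'   `pSyn` and `pNonsyn` (`NA` when the corresponding site count is zero:
#'   an undefined distance, not 0).
#' @examples
#' neiGojoboriPair("TTT", "TTC")  # Phe->Phe: 1 synonymous difference
#' @export
neiGojoboriPair <- function(codons1, codons2) {
  if (length(codons1) == 1L && nchar(codons1) > 3L)
    codons1 <- .splitCodons(codons1)
  if (length(codons2) == 1L && nchar(codons2) > 3L)
    codons2 <- .splitCodons(codons2)
  if (length(codons1) != length(codons2))
    stop("codon lists must have equal length")
  tabs <- .ngTables()
  i1 <- match(codons1, .CODONS); i2 <- match(codons2, .CODONS)
  i1[!is.na(i1) & is.na(tabs$S[i1])] <- NA_integer_
  i2[!is.na(i2) & is.na(tabs$S[i2])] <- NA_integer_
  ok <- !is.na(i1) & !is.na(i2)
  sd <- sum(tabs$SD[cbind(i1[ok], i2[ok])])
  nd <- sum(tabs$ND[cbind(i1[ok], i2[ok])])
  S <- sum((tabs$S[i1[ok]] + tabs$S[i2[ok]]) / 2)
  N <- sum((tabs$N[i1[ok]] + tabs$N[i2[ok]]) / 2)
  list(synDiffs = sd, nonsynDiffs = nd, synSites = S, nonsynSites = N,
       nCodons = sum(ok),
       pSyn = if (S > 0) sd / S else NA_real_,
       pNonsyn = if (N > 0) nd / N else NA_real_)
}

# fast pairwise stats on encoded codon matrices; cols = codon column subset
.pairNG <- function(enc, i, j, cols) {
  tabs <- .ngTables()
  a <- enc[i, cols]; b <- enc[j, cols]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok))
    return(c(sd = 0, nd = 0, S = 0, N = 0, n = 0))
  a <- a[ok]; b <- b[ok]
  c(sd = sum(tabs$SD[cbind(a, b)]), nd = sum(tabs$ND[cbind(a, b)]),
    S = sum((tabs$S[a] + tabs$S[b]) / 2),
    N = sum((tabs$N[a] + tabs$N[b]) / 2), n = length(a))
}
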