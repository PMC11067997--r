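# Independent oracles used across the suite.  These deliberately share no
# code with the package implementation.

GC <- Biostrings::GENETIC_CODE

# --- brute-force Nei-Gojobori oracle --------------------------------------

# synonymous site count of one codon: fraction of the 3 single-base changes
# per position that preserve the amino acid (stop-producing changes count
# as nonsynonymous)
oracleSynSites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  total <- 0
  for (p in 1:3) {
    for (b in bases) {
      if (b == substr(codon, p, p)) next
      alt <- codon
      substr(alt, p, p) <- b
      if (GC[[alt]] == GC[[codon]]) total <- total + 1 / 3
    }
  }
  total
}

# recursive enumeration of minimal substitution pathways between codons,
# skipping pathways through stop intermediates; returns mean (syn, nonsyn)
oraclePathway <- function(c1, c2) {
  recurse <- function(cur) {
    pos <- which(strsplit(cur, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(pos)) return(list(c(syn = 0, nonsyn = 0)))
    out <- list()
    for (p in pos) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (GC[[nxt]] == "*" && nxt != c2) next  # blocked intermediate
      step <- if (GC[[nxt]] == GC[[cur]]) c(syn = 1, nonsyn = 0)
              else c(syn = 0, nonsyn = 1)
      for (tail in recurse(nxt)) out[[length(out) + 1]] <- step + tail
    }
    out
  }
  paths <- recurse(c1)
  if (!length(paths)) {  # all pathways blocked: allow stop intermediates
    recurse2 <- function(cur) {
      pos <- which(strsplit(cur, "")[[1]] != strsplit(c2, "")[[1]])
      if (!length(pos)) return(list(c(syn = 0, nonsyn = 0)))
      out <- list()
      for (p in pos) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        step <- if (GC[[nxt]] == GC[[cur]]) c(syn = 1, nonsyn = 0)
                else c(syn = 0, nonsyn = 1)
        for (tail in recurse2(nxt)) out[[length(out) + 1]] <- step + tail
      }
      out
    }
    paths <- recurse2(c1)
  }
  Reduce(`+`, paths) / length(paths)
}

# --- Levenshtein oracles --------------------------------------------------

# quadratic dynamic-programming edit distance
oracleLevDP <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m))
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                           d[i, j] + (x[i] != y[j]))
  d[n + 1, m + 1]
}

# exponential recursive edit distance (strings <= 8)
oracleLevRec <- function(a, b) {
  if (nchar(a) == 0) return(nchar(b))
  if (nchar(b) == 0) return(nchar(a))
  cost <- substr(a, 1, 1) != substr(b, 1, 1)
  min(oracleLevRec(substr(a, 2, nchar(a)), b) + 1,
      oracleLevRec(a, substr(b, 2, nchar(b))) + 1,
      oracleLevRec(substr(a, 2, nchar(a)), substr(b, 2, nchar(b))) + cost)
}

# --- exhaustive Fisher 2x2 oracle -----------------------------------------

# two-sided p by full enumeration of tables with the observed margins
oracleFisher <- function(tab) {
  tab <- matrix(tab, 2, 2)
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  prob <- function(a) dhyper(a, r1, r2, c1)
  pObs <- prob(tab[1, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  sum(vapply(support, prob, 0)[vapply(support, prob, 0) <= pObs * (1 + 1e-7)])
}

# --- misc fixtures --------------------------------------------------------

# a tiny valid gapped alignment: 4 rows x 12 nt, one triplet indel,
# one synonymous and one nonsynonymous substitution
toyAlignment <- function() {
  validateAlignment(c(
    h1 = "ATGAAATTTGGG",
    h2 = "ATGAAATTCGGG",   # TTT->TTC synonymous
    h3 = "ATGAAATTTGGG",
    h4 = "ATG---TTTGGG"),  # one triplet deletion
    regions = IRanges::IRanges(start = c(1, 4), end = c(12, 6),
                               names = c("all", "mid")))
}
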