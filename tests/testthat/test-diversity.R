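# Codon-aware diversity statistics.

test_that("alignment validation enforces the codon-aware invariants", {
  expect_s4_class(validateAlignment(c(a = "ATGAAATTT", b = "ATGAAATTT")),
                  "CodingAlignment")
  expect_error(validateAlignment(c(a = "ATGAAATTT", b = "ATGAAA")),
               "ragged")
  expect_error(validateAlignment(c(a = "ATGAA--TT", b = "ATGAAATTT")),
               "column 6")
  expect_error(validateAlignment(c(a = "ATGTAATTT", b = "ATGAAATTT")),
               "stop")
  expect_error(validateAlignment(c(a = "ATGAAATTT")), "at least 2")
})

test_that("Nei-Gojobori pair counts match hand and oracle values", {
  r <- neiGojoboriPair("TTT", "TTT")
  expect_equal(r$synDiffs + r$nonsynDiffs, 0)
  expect_equal(r$synSites + r$nonsynSites, 3)
  r <- neiGojoboriPair("TTTAAA", "TTTAAA")
  expect_equal(r$synSites + r$nonsynSites, 6)
  # Phe -> Phe third-position change
  r <- neiGojoboriPair("TTT", "TTC")
  expect_equal(r$synDiffs, 1)
  expect_equal(r$nonsynDiffs, 0)
  # 2-step codon averages over the two minimal pathways
  r <- neiGojoboriPair("TTT", "GTA")
  o <- oraclePathway("TTT", "GTA")
  expect_equal(r$synDiffs, unname(o["syn"]))
  expect_equal(r$nonsynDiffs, unname(o["nonsyn"]))
  # random subsample of sense-codon pairs against the brute-force oracle
  sense <- names(GC)[GC != "*"]
  set.seed(42)
  for (i in 1:150) {
    c1 <- sample(sense, 1); c2 <- sample(sense, 1)
    r <- neiGojoboriPair(c1, c2)
    o <- oraclePathway(c1, c2)
    expect_equal(r$synDiffs, unname(o["syn"]), info = paste(c1, c2))
    expect_equal(r$nonsynDiffs, unname(o["nonsyn"]), info = paste(c1, c2))
    expect_equal(r$synSites,
                 (oracleSynSites(c1) + oracleSynSites(c2)) / 2,
                 info = paste(c1, c2))
  }
  # gap and ambiguity codons are skipped pairwise; all-gap is undefined
  r <- neiGojoboriPair(c("TTT", "---"), c("TTC", "AAA"))
  expect_equal(r$nCodons, 1)
  expect_equal(r$synDiffs, 1)
  r <- neiGojoboriPair("---", "AAA")
  expect_identical(r$pSyn, NA_real_)
  expect_identical(r$pNonsyn, NA_real_)
})

test_that("triplet indels are counted codon-wise with shared gaps ignored", {
  expect_equal(tripletIndelPair("ATGAAATTT", "ATGAAATTT"), 0)
  expect_equal(tripletIndelPair("ATGAAATTTCCC", "ATG------CCC"), 2)
  expect_equal(tripletIndelPair("ATG---TTT", "ATG---TTT"), 0)
  expect_equal(tripletIndelPair("ATGAAATTTCCC", "ATG------CCC",
                                mode = "per-event"), 1)
  # window restriction
  expect_equal(tripletIndelPair("ATGAAATTTCCC", "ATG------CCC",
                                start = 1, end = 6), 1)
  expect_error(tripletIndelPair("ATGAAA", "ATGAAA", start = 2, end = 6),
               "codon boundaries")
})

test_that("sliding windows tile correctly and localise variation", {
  rows <- c(a = strrep("ATGAAATTTGGGCCCAAA", 10),
            b = strrep("ATGAAATTTGGGCCCAAA", 10))
  aln <- validateAlignment(rows)
  win <- slidingWindowDiversity(aln, bootReps = 0)
  expect_true(all(win$piSyn == 0))
  expect_true(all(win$piNonsyn == 0))
  expect_true(all(win$indelPerTriplet == 0))
  # consecutive full windows share exactly 75 nt
  full <- win[win$nNt == 99, ]
  expect_true(all(diff(full$start) == 24))
  # a single synonymous SNP appears only in windows covering its codon
  rows2 <- rows
  substr(rows2["b"], 9, 9) <- "C"   # TTT -> TTC at nt 7-9
  win2 <- slidingWindowDiversity(validateAlignment(rows2), bootReps = 0)
  hit <- win2$piSyn > 0
  covers <- win2$start < 9 & win2$end >= 9
  expect_identical(hit, covers)
  expect_true(all(win2$piNonsyn == 0))
  expect_error(slidingWindowDiversity(validateAlignment(
    c(a = "ATGAAA", b = "ATGAAA"))), "shorter")
  expect_error(slidingWindowDiversity(aln, windowNt = 100), "multiple of 3")
})

test_that("window statistics are invariant to row order and relabeling", {
  h <- generateFounderAlleles(config = SimConfig(k = 5, seed = 8))
  aln <- alignHaplotypes(h)
  w1 <- slidingWindowDiversity(aln, bootReps = 0)
  perm <- c(3, 1, 5, 2, 4)
  seqs <- as.character(alignedSeqs(aln))[perm]
  names(seqs) <- paste0("x", seq_along(seqs))
  w2 <- slidingWindowDiversity(validateAlignment(seqs), bootReps = 0)
  expect_equal(w1$piSyn, w2$piSyn)
  expect_equal(w1$piNonsyn, w2$piNonsyn)
  expect_equal(w1$indelPerTriplet, w2$indelPerTriplet)
})

test_that("exon diversity matches hand computations and zeroes on identity", {
  aln <- validateAlignment(c(a = "TTTAAA", b = "TTTAAA"))
  ed <- exonDiversity(aln, bootReps = 0)
  expect_equal(ed$pi, 0)
  expect_equal(ed$piSyn, 0)
  expect_equal(ed$piNonsyn, 0)
  # one synonymous change in one codon: p-dist 1/6; NG p_s = 1/(1/3) = 3
  aln2 <- validateAlignment(c(a = "TTTAAA", b = "TTCAAA"))
  ed2 <- exonDiversity(aln2, bootReps = 0)
  expect_equal(ed2$pi, 1 / 6)
  expect_equal(ed2$piSyn, 1 / ((oracleSynSites("TTT") +
                                oracleSynSites("TTC")) / 2 +
                               oracleSynSites("AAA")))
  expect_equal(ed2$piNonsyn, 0)
  expect_error(exonDiversity(aln2, c(4, 3)), "empty region")
  # bootstrap SEs shrink with window size on a heterogeneous alignment
  h <- generateFounderAlleles(config = SimConfig(k = 6, seed = 9))
  aln3 <- alignHaplotypes(h)
  e9 <- regions(aln3)["E9"]
  s <- IRanges::start(e9)
  shortSE <- exonDiversity(aln3, c(s, s + 98), bootReps = 60,
                           seed = 1)$seSyn
  longSE <- exonDiversity(aln3, c(s, s + 296), bootReps = 60,
                          seed = 1)$seSyn
  expect_lt(longSE, shortSE)
})

test_that("codon usage splits HVR and non-HVR and flags the ANT/NAT pattern", {
  h <- HaplotypeSet(c(a = "ATGAATAATCATGGG"), IRanges::IRanges(2, 4))
  cu <- codonUsageProfile(h)
  expect_equal(unname(cu$hvr[1, "AAT"]), 2 / 3)
  expect_equal(unname(cu$hvr[1, "CAT"]), 1 / 3)
  expect_equal(sum(cu$hvr[1, ]), 1)
  expect_equal(sum(cu$nonHvr[1, ]), 1)
  expect_true(cu$antNatOnly)
  # empty HVR is flagged, not a zero division
  h0 <- HaplotypeSet(c(a = "ATGGGG"), IRanges::IRanges(2, 1))
  cu0 <- codonUsageProfile(h0)
  expect_true(cu0$emptyHvr[1])
  # simulator output always satisfies the pattern flag
  hs <- generateFounderAlleles(config = SimConfig(k = 6, seed = 10))
  expect_true(codonUsageProfile(hs)$antNatOnly)
})

test_that("HVR length distribution reports support and simulated bounds hold", {
  h <- HaplotypeSet(c(a = paste0("ATG", strrep("AAT", 10), "GGG")),
                    IRanges::IRanges(2, 11))
  d <- hvrLengthDistribution(h)
  expect_identical(as.integer(names(d$counts)), 10L)
  expect_identical(unname(d$counts[1]), 1L)
  hs <- generateFounderAlleles(config = SimConfig(k = 12, seed = 14))
  ds <- hvrLengthDistribution(hs)
  expect_gte(ds$min, 7L)
  expect_lte(ds$max, 24L)
})

test_that("haplotype diversity follows the unbiased formula", {
  expect_equal(haplotypeDiversity(c(a = 2)), 0)
  expect_equal(haplotypeDiversity(c(a = 1, b = 1)), 1)
  expect_equal(haplotypeDiversity(rep(1, 30)), 1)  # all singletons
  expect_equal(haplotypeDiversity(c(a = 3, b = 1)),
               4 / 3 * (1 - (9 + 1) / 16))
  expect_error(haplotypeDiversity(c(a = 1)), "n >= 2")
})

test_that("Phi-ST behaves at the exchangeable and fully-separated extremes", {
  # swapped labels over identical internal structure: phi ~ 0, p large
  set.seed(31)
  x <- rnorm(16)
  d <- as.matrix(dist(x))
  r <- amovaPhiSt(d, rep(c("p1", "p2"), 8), nPerm = 199, seed = 1)
  expect_lt(abs(r$phiST), 0.35)
  expect_gt(r$p, 0.05)
  # zero within, positive between: phi = 1
  d2 <- matrix(1, 8, 8) - diag(8)
  d2[1:4, 1:4] <- 0; d2[5:8, 5:8] <- 0
  r2 <- amovaPhiSt(d2, rep(c("x", "y"), each = 4), nPerm = 99, seed = 2)
  expect_equal(r2$phiST, 1)
  expect_lt(r2$p, 0.05)
  # singleton population excluded with a warning
  expect_warning(
    r3 <- amovaPhiSt(as.matrix(dist(rnorm(9))),
                     c(rep("a", 4), rep("b", 4), "c"), nPerm = 49),
    "singleton")
  expect_false("c" %in% rownames(r3$pairwise))
})
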