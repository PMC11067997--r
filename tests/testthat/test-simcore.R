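# Forward simulator: founders, mutation model, broods, populations,
# expression matrices.

test_that("founder alleles are distinct, well-formed and deterministic", {
  for (k in c(2L, 18L)) {
    h <- generateFounderAlleles(config = SimConfig(k = k, seed = 11))
    expect_s4_class(h, "HaplotypeSet")
    expect_length(h, k)
    aa <- as.character(aaSeqs(h))
    expect_equal(length(unique(aa)), k)
    # HVR codons all ANT/NAT and lengths within bounds
    for (i in seq_len(k)) {
      cod <- substring(as.character(dnaSeqs(h)[[i]]),
                       seq(1, nchar(as.character(dnaSeqs(h)[[i]])), 3),
                       seq(3, nchar(as.character(dnaSeqs(h)[[i]])), 3))
      sp <- hvrRanges(h)[i]
      hvrCod <- cod[IRanges::start(sp):IRanges::end(sp)]
      expect_true(all(grepl("^(A[ACGT]T|[ACGT]AT)$", hvrCod)))
      expect_gte(IRanges::width(sp), 7L)
      expect_lte(IRanges::width(sp), 24L)
    }
  }
  h1 <- generateFounderAlleles(config = SimConfig(k = 6, seed = 99))
  h2 <- generateFounderAlleles(config = SimConfig(k = 6, seed = 99))
  expect_identical(as.character(dnaSeqs(h1)), as.character(dnaSeqs(h2)))
  expect_error(generateFounderAlleles(k = 1, config = SimConfig(seed = 1)),
               "k")
})

test_that("mutation model respects its alphabet, bounds and zero-rate identity", {
  h <- generateFounderAlleles(config = SimConfig(k = 2, seed = 4))[1]
  set.seed(1)
  expect_identical(as.character(dnaSeqs(mutateHaplotype(h, SimConfig()))),
                   as.character(dnaSeqs(h)))
  # saturating slippage never leaves the bounds; forced expansion at the
  # upper bound is a no-op or contraction
  cfgSlip <- SimConfig(muSlip = 1, hvrLenBounds = c(7, 24))
  cur <- h
  set.seed(2)
  lens <- integer(300)
  for (i in seq_len(300)) {
    cur <- mutateHaplotype(cur, cfgSlip)
    lens[i] <- IRanges::width(hvrRanges(cur))
  }
  expect_true(all(lens >= 7L & lens <= 24L))
  expect_true(any(lens == 24L))  # the walk actually visits the bound
  # point mutations stay inside the ANT/NAT alphabet
  cfgPoint <- SimConfig(muPoint = 0.5)
  set.seed(3)
  for (i in seq_len(200)) {
    m <- mutateHaplotype(h, cfgPoint)
    cod <- substring(as.character(dnaSeqs(m)[[1]]),
                     seq(1, Biostrings::width(dnaSeqs(m)), 3),
                     seq(3, Biostrings::width(dnaSeqs(m)), 3))
    sp <- hvrRanges(m)
    hvrCod <- cod[IRanges::start(sp):IRanges::end(sp)]
    expect_true(all(grepl("^(A[ACGT]T|[ACGT]AT)$", hvrCod)))
  }
  # E9 mutations fall outside the HVR span
  cfgE9 <- SimConfig(muE9 = 0.2)
  set.seed(4)
  m <- mutateHaplotype(h, cfgE9)
  expect_identical(hvrAA(m), setNames(hvrAA(h), names(hvrAA(m))))
})

test_that("brood segregation matches Mendelian expectations", {
  b <- simulateBrood(list(karyotype = "WZ", alleles = "a"),
                     list(alleles = c("a", "b")), nEggs = 40000, seed = 1)
  fr <- broodClasses(b) / sum(broodClasses(b))
  expect_equal(unname(fr[["WZ_hem"]]), 0.5, tolerance = 0.03)
  expect_equal(unname(fr[["ZZ_het"]]), 0.25, tolerance = 0.06)
  expect_equal(unname(fr[["ZZ_hom"]]), 0.25, tolerance = 0.06)
  expect_identical(unname(broodOutcomes(b)[["black_egg"]]),
                   unname(broodClasses(b)[["ZZ_hom"]]))
  # non-sharing cross: zero homozygotes
  b2 <- simulateBrood(list(karyotype = "WZ", alleles = "c"),
                      list(alleles = c("a", "b")), nEggs = 5000, seed = 2)
  expect_identical(unname(broodClasses(b2)[["ZZ_hom"]]), 0L)
  # Z0 mother: daughters are Z0, classes near 1/4 each of the four
  b3 <- simulateBrood(list(karyotype = "Z0", alleles = "a"),
                      list(alleles = c("a", "b")), nEggs = 40000, seed = 3)
  fr3 <- broodClasses(b3) / sum(broodClasses(b3))
  expect_identical(unname(broodClasses(b3)[["WZ_hem"]]), 0L)
  expect_equal(unname(fr3[["Z0_hem"]]), 0.5, tolerance = 0.03)
  expect_equal(unname(fr3[["ZZ_hom"]]), 0.25, tolerance = 0.06)
  # background egg failure is bookkept before genetic classes
  b4 <- simulateBrood(list(karyotype = "WZ", alleles = "a"),
                      list(alleles = c("a", "b")), nEggs = 1000,
                      whiteRate = 0.1, collapsedRate = 0.1, seed = 4)
  expect_identical(sum(broodOutcomes(b4)), 1000L)
  expect_gt(broodOutcomes(b4)[["white_egg"]], 0L)
  expect_error(simulateBrood(list(karyotype = "WZ", alleles = "a"),
                             list(alleles = c("a", "a")), 10),
               "invalid cross")
  expect_error(simulateBrood(list(karyotype = "ZZ", alleles = "a"),
                             list(alleles = c("a", "b")), 10),
               "invalid cross")
})

test_that("no surviving individual is ever homozygous and seeds reproduce", {
  st <- simulatePopulation(SimConfig(k = 4, nFemales = 80, nMales = 80,
                                     generations = 15, seed = 21))
  m <- simMales(st)
  expect_true(all(m$allele1 != m$allele2))
  expect_false(isExtinct(st))
  st2 <- simulatePopulation(SimConfig(k = 4, nFemales = 80, nMales = 80,
                                      generations = 15, seed = 21))
  expect_identical(alleleTrajectory(st), alleleTrajectory(st2))
  expect_identical(simFemales(st), simFemales(st2))
  expect_identical(as.character(dnaSeqs(simHaplotypes(st))),
                   as.character(dnaSeqs(simHaplotypes(st2))))
})

test_that("symmetric k-allele model hovers at 1/k and deviation shrinks with N", {
  devFor <- function(nF, seed) {
    st <- simulatePopulation(SimConfig(k = 4, nFemales = nF, nMales = nF,
                                       generations = 40, seed = seed))
    tr <- alleleTrajectory(st)
    # mean absolute deviation from 1/k over the last 20 generations
    mean(vapply(tr[21:40], function(ct) {
      p <- ct / sum(ct)
      full <- rep(0, 4); full[seq_along(p)] <- sort(p, decreasing = TRUE)
      mean(abs(full - 0.25))
    }, 0))
  }
  small <- mean(vapply(1:4, function(s) devFor(60, s), 0))
  large <- mean(vapply(1:4, function(s) devFor(600, s), 0))
  expect_lt(large, small)
  # k = 2: frequencies oscillate around 1/2
  st <- simulatePopulation(SimConfig(k = 2, nFemales = 150, nMales = 150,
                                     generations = 30, seed = 3))
  tr <- alleleTrajectory(st)
  p1 <- vapply(tr, function(ct) ct[1] / sum(ct), 0)
  expect_equal(mean(p1), 0.5, tolerance = 0.1)
})

test_that("all five alleles are retained under balancing selection", {
  kept <- vapply(1:6, function(s) {
    st <- simulatePopulation(SimConfig(k = 5, nFemales = 500, nMales = 500,
                                       generations = 250, seed = 100 + s))
    tr <- alleleTrajectory(st)
    length(tr[[length(tr)]]) == 5L
  }, TRUE)
  expect_gte(mean(kept), 0.95)
})

test_that("expression generator obeys its contract", {
  # zero noise, hom factor 1: Z:A identical across classes
  se0 <- simulateExpressionMatrix(300, 100, homFactor = 1, noiseSd = 0,
                                  seed = 5)
  za0 <- zaMedians(se0)$zaRatio
  expect_equal(unname(za0["hom"]), unname(za0["hem"]))
  expect_equal(unname(za0["het"]), unname(za0["hem"]))
  # autosomal medians equal across classes (noise-free)
  med0 <- zaMedians(se0)$medians
  expect_equal(unname(med0["A", "hem"]), unname(med0["A", "hom"]))
  # reproducible under seed
  seA <- simulateExpressionMatrix(50, 20, seed = 7)
  seB <- simulateExpressionMatrix(50, 20, seed = 7)
  expect_identical(SummarizedExperiment::assay(seA),
                   SummarizedExperiment::assay(seB))
  expect_error(simulateExpressionMatrix(10, 5, classes = c(weird = 3)),
               "invalid config")
})

test_that("simulated haplotypes align by HVR padding into a valid alignment", {
  h <- generateFounderAlleles(config = SimConfig(k = 7, seed = 13))
  aln <- alignHaplotypes(h)
  expect_s4_class(aln, "CodingAlignment")
  expect_setequal(names(regions(aln)), c("E8", "HVR", "E9"))
  # round-trip property: simulator output always validates
  expect_silent(validateAlignment(alignedSeqs(aln), regions(aln)))
})
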