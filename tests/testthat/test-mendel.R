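# Cross expectations, classification and the statistical tests.

test_that("cross expectations follow the zygosity rule", {
  shared <- expectedOffspring(list(karyotype = "WZ", alleles = "a"),
                              list(alleles = c("a", "b")))
  expect_equal(sum(shared$classes$proportion), 1)
  expect_equal(shared$inviableFraction, 0.25)
  zz <- shared$classes[shared$classes$karyotype == "ZZ", ]
  expect_equal(sum(zz$proportion[!zz$viable]) / sum(zz$proportion), 0.5)
  nonshared <- expectedOffspring(list(karyotype = "WZ", alleles = "c"),
                                 list(alleles = c("a", "b")))
  expect_equal(nonshared$inviableFraction, 0)
  # Z0 mother: four classes of 1/4 each
  z0 <- expectedOffspring(list(karyotype = "Z0", alleles = "a"),
                          list(alleles = c("a", "b")))
  expect_equal(sort(z0$classes$proportion), rep(0.25, 4))
  expect_setequal(z0$classes$karyotype[z0$classes$proportion > 0],
                  c("Z0", "ZZ"))
  expect_equal(z0$inviableFraction, 0.25)
  expect_error(expectedOffspring(list(karyotype = "WZ",
                                      alleles = c("a", "b")),
                                 list(alleles = c("a", "b"))), "malformed")
  expect_error(expectedOffspring(list(karyotype = "WZ", alleles = "a"),
                                 list(alleles = c("a", "a"))), "malformed")
})

test_that("inviable fraction is 0 or 1/4 over all supported crosses", {
  alleles <- c("a", "b", "c")
  for (kar in c("WZ", "Z0")) for (m in alleles)
    for (f1 in alleles) for (f2 in alleles) {
      if (f1 == f2) next
      r <- expectedOffspring(list(karyotype = kar, alleles = m),
                             list(alleles = c(f1, f2)))
      expect_equal(sum(r$classes$proportion), 1)
      expect_true(r$inviableFraction %in% c(0, 0.25))
      expect_identical(r$inviableFraction == 0.25, m %in% c(f1, f2))
    }
})

test_that("individual classification is a total deterministic decision table", {
  expect_identical(classifyIndividual("yes", 1), "WZ-female")
  expect_identical(classifyIndividual("yes", 2), "WZZ-male")
  expect_identical(classifyIndividual("no", 2), "ZZ-het-male")
  expect_identical(classifyIndividual("no", 1, 1), "Z0-female")
  expect_identical(classifyIndividual("no", 1, 2), "ZZ-hom-inviable")
  expect_identical(classifyIndividual("no", 1), "ambiguous")
  expect_identical(classifyIndividual("unknown", 1), "ambiguous")
  # totality: every lattice point maps to exactly one known class
  classes <- c("WZ-female", "Z0-female", "ZZ-het-male",
               "ZZ-hom-inviable", "WZZ-male", "ambiguous")
  for (w in c("yes", "no", "unknown")) for (n in 1:2)
    for (z in list(NA, 1, 2)) {
      got <- classifyIndividual(w, n, z)
      expect_length(got, 1)
      expect_true(got %in% classes)
    }
})

test_that("segregation chi-square matches hand values and guards zero classes", {
  r <- segregationChisq(c(f = 30, m = 30), c(f = 0.5, m = 0.5))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  r2 <- segregationChisq(c(f = 45, m = 15), c(f = 0.5, m = 0.5))
  expect_equal(r2$statistic, 15)
  expect_equal(r2$df, 1L)
  # a zero-expectation class with observations is a rule violation
  r3 <- segregationChisq(c(het = 28, hom = 2),
                         c(het = 1, hom = 0))
  expect_identical(r3$violations, "hom")
  expect_error(segregationChisq(c(x = 3), c(y = 1)), "match")
})

test_that("Hardy-Weinberg homozygote deficit detects missing homozygotes", {
  r <- hwHomozygoteDeficit(c(0.5, 0.5), n = 10, observedHom = 5)
  expect_equal(r$expectedHomProportion, 0.5)
  r2 <- hwHomozygoteDeficit(rep(0.2, 5), n = 100, observedHom = 0)
  expect_equal(r2$expectedHom, 20)
  expect_lt(r2$p, 0.001)
  expect_false(r2$underpowered)
  # many rare alleles: tiny expectation, flagged underpowered
  r3 <- hwHomozygoteDeficit(rep(1 / 200, 200), n = 50, observedHom = 0)
  expect_lt(r3$expectedHom, 1)
  expect_true(r3$underpowered)
  expect_gt(r3$p, 0.05)
  expect_error(hwHomozygoteDeficit(c(0.5, 0.4), 10, 0), "sum to 1")
})

test_that("Fisher exact gives 2/12870 for complete W-linkage and matches the oracle", {
  expect_equal(fisherExact2x2(matrix(c(8, 0, 0, 8), 2)), 2 / 12870,
               tolerance = 1e-10)
  expect_equal(fisherExact2x2(matrix(c(4, 4, 4, 4), 2)), 1)
  expect_equal(fisherExact2x2(matrix(c(7, 1, 1, 7), 2)),
               oracleFisher(c(7, 1, 1, 7)), tolerance = 1e-10)
  # exhaustive-enumeration equality on random small tables
  set.seed(9)
  for (i in 1:40) {
    tb <- matrix(sample(0:10, 4, replace = TRUE), 2)
    if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) next
    expect_equal(fisherExact2x2(tb), oracleFisher(tb), tolerance = 1e-9,
                 info = paste(tb, collapse = ","))
  }
  expect_error(fisherExact2x2(matrix(c(0, 0, 3, 4), 2)), "zero margin")
})

test_that("knockdown contingency is significant uncorrected, not with Yates", {
  r <- knockdownContingency(0, 14, 11, 20)
  expect_lt(r$p, 0.001)
  # hand value: chi2 = 34 * (0*9 - 14*11)^2 / (14*20*11*23)
  expect_equal(r$statistic, 34 * (14 * 11)^2 / (14 * 20 * 11 * 23))
  rY <- knockdownContingency(0, 14, 11, 20, correct = TRUE)
  expect_gt(rY$p, 0.001)
  rEq <- knockdownContingency(5, 10, 10, 20)
  expect_equal(rEq$statistic, 0)
  expect_equal(rEq$p, 1)
  expect_error(knockdownContingency(1, 0, 1, 2), "positive")
})
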