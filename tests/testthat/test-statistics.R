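test_that("BMI follows weight/height^2", {
  expect_equal(bmi(90, 1.86), 90 / 1.86^2)
  expect_equal(bmi(90, 1.86), 26.0, tolerance = 1e-2)
  expect_equal(bmi(64, 1.71), 21.9, tolerance = 1e-2)
  expect_equal(bmi(1.7^2, 1.7), 1)
  expect_error(bmi(-60, 1.7), "positive")
  expect_error(bmi(60, 0), "positive")
})

test_that("the normality screen is calibrated under the null and catches gross departures", {
  passes <- vapply(1:50, function(s) {
    set.seed(s)
    testNormality(rnorm(50))$isNormal
  }, TRUE)
  expect_gte(mean(passes), 0.86)  # nominal pass rate 0.95
  # two-point mass distribution, n = 20: decisively non-normal
  twoPoint <- rep(c(0, 0.001, 10, 10.001, 10.002), 4)  # jittered to avoid ties
  res <- testNormality(twoPoint)
  expect_false(res$isNormal)
  expect_lt(res$pValue, 0.001)
  const <- testNormality(rep(5, 10))
  expect_false(const$testable)
  expect_false(const$isNormal)
  expect_error(testNormality(c(1, 2)), "at least 3")
})

test_that("Mann-Whitney matches enumeration exactly for small tie-free samples", {
  res <- mannWhitney(c(1, 2), c(3, 4))
  expect_equal(res$u, 0)
  expect_equal(res$pValue, 1 / 3, tolerance = 1e-12)
  expect_equal(res$method, "exact")
  expect_equal(mwEnumerationP(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)
  # a handful of randomized tie-free cases against the enumeration oracle
  set.seed(14)
  for (i in 1:20) {
    a <- runif(sample(2:6, 1)); b <- runif(sample(2:6, 1))
    expect_equal(mannWhitney(a, b)$pValue, mwEnumerationP(a, b),
                 tolerance = 1e-12)
  }
  # identical multisets: no separation
  expect_gte(mannWhitney(c(1, 2, 3), c(1, 2, 3))$pValue, 0.99)
  expect_error(mannWhitney(numeric(0), 1), "non-empty")
})

test_that("the tie-corrected normal approximation tracks the exact p for n = 10 + 10", {
  set.seed(41)
  a <- rnorm(10); b <- rnorm(10, mean = 0.8)
  res <- mannWhitney(a, b)  # n_a + n_b > 16 -> approximation branch
  expect_equal(res$method, "normal_approximation")
  expect_lt(abs(res$pValue - mwEnumerationP(a, b)), 0.02)
})

test_that("the pooled t-test reproduces the closed-form worked example and its symmetries", {
  idt <- tTestUnpaired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(idt$t, 0)
  expect_equal(idt$pValue, 1)
  # pooled sd = 1, se = sqrt(2/3), df = 4
  res <- tTestUnpaired(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(res$t, -3.674, tolerance = 1e-3)
  expect_equal(res$pValue, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(res$pValue, 0.0214, tolerance = 5e-3)
  expect_equal(res$df, 4)
  swapped <- tTestUnpaired(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$pValue, res$pValue)
  # invariance under common affine transforms
  set.seed(17)
  a <- rnorm(8); b <- rnorm(9, 1)
  p0 <- tTestUnpaired(a, b)$pValue
  expect_equal(tTestUnpaired(3 * a + 7, 3 * b + 7)$pValue, p0,
               tolerance = 1e-12)
  # degenerate zero-variance limits
  expect_equal(tTestUnpaired(rep(1, 3), rep(1, 4))$pValue, 1)
  expect_equal(tTestUnpaired(rep(1, 3), rep(2, 4))$pValue, 0)
})

test_that("group comparison routing honours context, normality and variance homogeneity", {
  set.seed(23)
  a <- rnorm(12, 100, 10); b <- rnorm(12, 105, 10)
  # gender context: always Mann-Whitney, whatever the samples look like
  expect_equal(compareGroups(a, b, "gender")$test_used, "mann_whitney")
  # age context with well-behaved normal samples: t-test
  expect_equal(compareGroups(a, b, "age")$test_used, "t_test")
  # heavy-tailed samples that verifiably fail the normality screen
  set.seed(29)
  h <- exp(rnorm(12, 0, 2))
  stopifnot(!testNormality(h)$isNormal)
  expect_equal(compareGroups(a, h, "age")$test_used, "mann_whitney")
  # grossly unequal variances push the parametric branch away too
  set.seed(37)
  wide <- rnorm(12, 100, 60)
  if (testNormality(wide)$isNormal && !var.test(a, wide)$p.value > 0.05)
    expect_equal(compareGroups(a, wide, "age")$test_used, "mann_whitney")
  # percent change is computed on means with group a as baseline
  cg <- compareGroups(c(10, 10), c(15, 15), "gender")
  expect_equal(cg$percent_change, 50)
  expect_true(cg$p_value >= 0 && cg$p_value <= 1)
  expect_identical(cg$significant, cg$p_value <= 0.05)
})

test_that("age contrast pools 20s+30s vs 50s+60s with the design's recording counts", {
  cohort <- paramCohort(seed = 301, muscles = c("biceps", "gastrocnemius"))
  gast <- ageContrast(cohort, "gastrocnemius", "re", "men")
  expect_equal(gast$n_a, 20)  # both sides contribute
  expect_equal(gast$n_b, 20)
  bic <- ageContrast(cohort, "biceps", "re", "men")
  expect_equal(bic$n_a, 10)   # 5 subjects x 2 decades, unilateral
  expect_equal(bic$n_b, 10)
  expect_equal(bic$group_a, "20s+30s")
  # missing decade -> incomplete design
  sub <- cohort[, colData(cohort)$age_decade != "20s"]
  expect_error(ageContrast(sub, "biceps", "re", "men"), "incomplete design")
})

test_that("gender contrast averages gastrocnemius sides so each subject counts once", {
  cohort <- paramCohort(seed = 302, muscles = "gastrocnemius")
  gc <- genderContrast(cohort, "gastrocnemius", "ri")
  expect_equal(gc$n_a, 25)
  expect_equal(gc$n_b, 25)
  expect_equal(gc$test_used, "mann_whitney")
  expect_equal(gc$group_a, "men")
  # the calibrated gender effect on Ri is large and detected
  expect_true(gc$significant)
  expect_gt(gc$percent_change, 0)
})
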