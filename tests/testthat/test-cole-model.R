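test_that("evaluateCole reproduces the model limits and the semicircle apex", {
  p <- ColeParameters(r0 = 114, rinf = 63, fc = 42.3, alpha = 1)
  lowf <- evaluateCole(p, 1e-9)
  expect_equal(lowf$resistance, 114, tolerance = 1e-9)
  expect_equal(lowf$reactance, 0, tolerance = 1e-6)
  highf <- evaluateCole(p, 1e12)
  expect_equal(highf$resistance, 63, tolerance = 1e-9)
  expect_equal(highf$reactance, 0, tolerance = 1e-6)
  apex <- evaluateCole(p, 42.3)
  expect_equal(apex$resistance, (114 + 63) / 2)
  expect_equal(apex$reactance, (114 - 63) / 2)
  expect_error(evaluateCole(p, -1), "positive")
  expect_error(evaluateCole(p, 0), "positive")
})

test_that("reactance magnitude is non-negative across the sweep for valid parameters", {
  set.seed(11)
  for (i in 1:20) {
    rinfV <- runif(1, 10, 100)
    p <- ColeParameters(r0 = rinfV + runif(1, 5, 120), rinf = rinfV,
                        fc = runif(1, 5, 120), alpha = runif(1, 0.3, 1))
    m <- evaluateCole(p, exp(seq(log(0.1), log(5000), length.out = 60)))
    expect_true(all(m$reactance >= 0))
    expect_true(all(m$resistance > rinf(p) - 1e-9 & m$resistance < r0(p) + 1e-9))
  }
})

test_that("alpha = 1 traces the centred semicircle with apex at fc; alpha < 1 is depressed", {
  r0v <- 150; rinfv <- 60
  half <- (r0v - rinfv) / 2
  f <- exp(seq(log(0.5), log(4000), length.out = 200))
  m1 <- evaluateCole(ColeParameters(r0 = r0v, rinf = rinfv, fc = 40, alpha = 1), f)
  # circle: center ((r0+rinf)/2, 0), radius (r0-rinf)/2
  d <- sqrt((m1$resistance - (r0v + rinfv) / 2)^2 + m1$reactance^2)
  expect_equal(d, rep(half, length(f)), tolerance = 1e-10)
  # apex at f = fc
  expect_equal(m1$frequency[which.max(m1$reactance)], f[which.min(abs(f - 40))])
  for (a in c(0.9, 0.7, 0.5)) {
    ma <- evaluateCole(ColeParameters(r0 = r0v, rinf = rinfv, fc = 40, alpha = a), f)
    expect_lt(max(ma$reactance), half)
  }
})

test_that("Ri derivation matches the parallel-circuit closed form and round-trips", {
  expect_equal(riFrom(2, 1), 2)
  # algebraic inverse applied to the printed men-biceps pair round-trips
  expect_equal(riFrom(114.0, rinfFrom(114.0, 140.8)), 140.8, tolerance = 1e-12)
  expect_equal(riFrom(114.0, 63.0), 114 * 63 / 51, tolerance = 1e-12)
  expect_equal(rinfFrom(2, 2), 1)
  expect_equal(rinfFrom(114.0, 140.8), 114.0 * 140.8 / 254.8, tolerance = 1e-12)
  expect_error(riFrom(1, 1), "degenerate")
  expect_error(riFrom(1, 2), "degenerate")
  expect_error(rinfFrom(-1, 2), "positive")
  # monotone in rinf at fixed re
  expect_true(all(diff(riFrom(100, seq(10, 90, by = 5))) > 0))
  # property: round-trip over random pairs to 1e-10 relative
  set.seed(4)
  re <- runif(200, 20, 300)
  ri <- runif(200, 20, 900)
  expect_equal(riFrom(re, rinfFrom(re, ri)), ri, tolerance = 1e-10)
  expect_true(all(rinfFrom(re, ri) < re))
})

test_that("membrane capacitance inverts the centre-frequency relation", {
  # fc = 1/(2 pi) Hz with re + ri = 1 ohm gives exactly 1 F
  expect_equal(mcFrom(1 / (2 * pi) / 1000, 0.5, 0.5), 1, tolerance = 1e-12)
  # printed men-biceps means give ~14.8 nF
  expect_equal(mcFrom(42.3, 114.0, 140.8), 1.4767e-8, tolerance = 1e-4)
  expect_equal(mcFrom(42.3, 114.0, 140.8),
               1 / (2 * pi * 42300 * 254.8), tolerance = 1e-12)
  # inverse proportionality in fc and in (re + ri)
  expect_equal(mcFrom(84.6, 114, 140.8), mcFrom(42.3, 114, 140.8) / 2)
  expect_equal(mcFrom(42.3, 228, 281.6), mcFrom(42.3, 114, 140.8) / 2)
  expect_error(mcFrom(0, 1, 1), "positive")
  # round-trip: solving fc back from mc recovers fc to 1e-10 relative
  set.seed(9)
  fc <- runif(100, 5, 200); re <- runif(100, 30, 250); ri <- runif(100, 30, 800)
  mc <- mcFrom(fc, re, ri)
  expect_equal(1 / (2 * pi * mc * (re + ri)) / 1000, fc, tolerance = 1e-10)
})

test_that("impedance magnitude and phase angle follow their closed forms", {
  expect_equal(impedanceMagnitude(3, 4), 5)
  expect_equal(impedanceMagnitude(84.2, 0), 84.2)
  expect_equal(impedanceMagnitude(84.2, 18.1), sqrt(84.2^2 + 18.1^2))
  expect_equal(impedanceMagnitude(84.2, 18.1), 86.12, tolerance = 1e-4)
  expect_error(impedanceMagnitude(-1, 2), "non-negative")
  expect_equal(phaseAngle(84.2, 0), 0)
  expect_equal(phaseAngle(10, 10), 45)
  expect_equal(phaseAngle(84.2, 18.1), atan(18.1 / 84.2) * 180 / pi)
  expect_equal(phaseAngle(84.2, 18.1), 12.13, tolerance = 1e-3)
  expect_error(phaseAngle(0, 1), "r > 0")
})

test_that("deriveParameters composes the verified pieces at the 50 kHz readout", {
  # apex case: fc = 50 so the readout sits exactly at the apex
  d <- deriveParameters(ColeParameters(r0 = 2, rinf = 1, fc = 50, alpha = 1))
  v <- parameterVector(d, mcUnit = "F")
  expect_equal(v[["r"]], 1.5)
  expect_equal(v[["xc"]], 0.5)
  expect_equal(v[["z"]], sqrt(2.5))
  expect_equal(v[["pa"]], atan(1 / 3) * 180 / pi)
  expect_equal(v[["re"]], 2)
  expect_equal(v[["ri"]], 2)   # symmetric case
  # composition on the printed men-biceps state
  d2 <- deriveParameters(ColeParameters(r0 = 114.0, rinf = 63.0, fc = 42.3,
                                        alpha = 0.79))
  v2 <- parameterVector(d2, mcUnit = "F")
  expect_equal(v2[["re"]], 114.0)
  expect_equal(v2[["ri"]], 140.8, tolerance = 1e-3)
  expect_equal(v2[["mc"]], 1.478e-8, tolerance = 1e-3)
  # invariants over random valid parameter sets
  set.seed(21)
  for (i in 1:25) {
    rinfV <- runif(1, 20, 120)
    p <- ColeParameters(r0 = rinfV + runif(1, 10, 100), rinf = rinfV,
                        fc = runif(1, 10, 100), alpha = runif(1, 0.4, 1))
    vv <- parameterVector(deriveParameters(p))
    expect_true(all(vv > 0))
    expect_gte(vv[["z"]], vv[["r"]])
    expect_gte(vv[["z"]], vv[["xc"]])
    expect_true(vv[["pa"]] > 0 && vv[["pa"]] < 90)
  }
})

test_that("ColeParameters validity rejects degenerate states", {
  expect_error(ColeParameters(r0 = 1, rinf = 2, fc = 10, alpha = 1), "rinf < r0")
  expect_error(ColeParameters(r0 = 2, rinf = 1, fc = -1, alpha = 1), "fc")
  expect_error(ColeParameters(r0 = 2, rinf = 1, fc = 10, alpha = 1.2), "alpha")
  expect_error(ColeParameters(r0 = 2, rinf = 1, fc = 10, alpha = 0), "alpha")
})
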