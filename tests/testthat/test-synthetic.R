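test_that("calibration inverts the printed means into Cole state, cell by cell", {
  cal <- calibrateGenerator()
  expect_equal(nrow(cal), 16L)
  mb <- cal[cal$muscle == "biceps" & cal$gender == "men", ]
  expect_equal(mb$re_mean, 114.0)
  expect_equal(mb$ri_mean, 140.8)
  expect_equal(mb$fc_mean, 42.3)
  expect_equal(mb$rinf_mean, rinfFrom(114.0, 140.8), tolerance = 1e-12)
  # the undepressed semicircle overshoots the printed Xc, so alpha < 1
  xcAlpha1 <- evaluateCole(
    ColeParameters(r0 = 114.0, rinf = mb$rinf_mean, fc = 42.3, alpha = 1),
    50)$reactance
  expect_equal(xcAlpha1, 25.1, tolerance = 1e-2)
  expect_gt(xcAlpha1, 18.1)
  expect_lt(mb$alpha, 1)
  # by construction the solved alpha reproduces the printed Xc at 50 kHz
  for (i in seq_len(nrow(cal))) {
    xc <- evaluateCole(
      ColeParameters(r0 = cal$re_mean[i], rinf = cal$rinf_mean[i],
                     fc = cal$fc_mean[i], alpha = cal$alpha[i]),
      50)$reactance
    expect_equal(xc, cal$xc_target[i], tolerance = 1e-6)
  }
  # fc SD pathology (printed SD >= mean) is capped and flagged
  wt <- cal[cal$muscle == "triceps" & cal$gender == "women", ]
  expect_true(wt$fc_sd_capped)
  expect_equal(wt$fc_sd, wt$fc_mean)
  expect_false(cal$fc_sd_capped[cal$muscle == "biceps" & cal$gender == "men"])
})

test_that("geometrically infeasible reactance targets are refused with a clear error", {
  # Xc above the alpha = 1 semicircle value at 50 kHz cannot be reached
  expect_error(solveCellAlpha(114, 63, 42.3, 26), "infeasible")
  expect_error(solveCellAlpha(114, 63, 42.3, (114 - 63) / 2 + 1), "infeasible")
  expect_error(solveCellAlpha(114, 63, 42.3, 0), "infeasible")
  # a reachable target returns alpha in (0, 1]
  a <- solveCellAlpha(114, 63, 42.3, 18.1)
  expect_true(a > 0 && a < 1)
})

test_that("mean-corrected truncated sampling hits the printed means despite truncation", {
  cal <- calibrateGenerator()
  # worst cell: women abductor Ri, CV 1.6 — naive truncation would inflate
  # the mean by tens of ohms
  w <- cal[cal$muscle == "abductor_pollicis_brevis" & cal$gender == "women", ]
  set.seed(51)
  draws <- muscleBIA:::.rtruncnorm(2e5, w$ri_mu, w$ri_sd, w$ri_lower)
  expect_true(all(draws >= w$ri_lower))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - w$ri_mean), 3 * se)
})

test_that("generateSubject is deterministic and follows the recording design", {
  cfg <- biaGeneratorConfig(seed = 5)
  cal <- calibrateGenerator()
  s1 <- generateSubject("women", "40s", cfg, seed = 77, calibration = cal)
  s2 <- generateSubject("women", "40s", cfg, seed = 77, calibration = cal)
  expect_identical(s1$values, s2$values)
  expect_identical(s1$truth, s2$truth)
  expect_identical(lapply(s1$spectra, frequencies),
                   lapply(s2$spectra, frequencies))
  expect_identical(lapply(s1$spectra, resistance),
                   lapply(s2$spectra, resistance))
  # 8 muscles, gastrocnemius bilateral -> 9 recordings
  expect_equal(nrow(s1$recordings), 9L)
  expect_equal(sum(s1$recordings$muscle == "gastrocnemius"), 2L)
  expect_true(all(table(s1$recordings$muscle[
    s1$recordings$muscle != "gastrocnemius"]) == 1L))
  expect_true(all(s1$recordings$age >= 40 & s1$recordings$age <= 49))
})

test_that("fitting a subject's rendered spectra recovers the sampled parameters", {
  cfg <- biaGeneratorConfig(seed = 5)
  s <- generateSubject("men", "30s", cfg, seed = 123, muscles = "biceps",
                       calibration = calibrateGenerator())
  tr <- s$truth
  fit <- fitCole(s$spectra[[tr$recording_id[1]]])
  expect_lt(maxRelErr(fit, tr$r0[1], tr$rinf[1], tr$fc[1], tr$alpha[1]), 0.02)
})

test_that("the default cohort reproduces the study design arithmetic", {
  cohort <- paramCohort(seed = 61, muscles = biaMuscles())
  cd <- colData(cohort)
  expect_equal(length(unique(cd$subject_id)), 50L)
  expect_equal(ncol(cohort), 450L)   # 8 muscles + second gastrocnemius side
  expect_equal(sum(cd$gender == "men" & cd$muscle == "biceps"), 25L)
  expect_true(all(table(cd$age_decade, cd$gender)[, "men"] == 45L))
  expect_true(all(cd$age >= 20 & cd$age <= 69))
  expect_equal(cd$bmi, cd$weight_kg / cd$height_m^2, tolerance = 1e-12)
})

test_that("cell means of sampled cohorts converge to the printed targets", {
  cfg <- biaGeneratorConfig(seed = 71, n_per_cell = 200)
  cohort <- generateCohort(cfg, muscles = "biceps", genders = "men",
                           renderSpectra = FALSE)
  re <- assay(cohort)["re", ]
  expect_equal(length(re), 1000L)
  se <- sd(re) / sqrt(length(re))
  expect_lt(abs(mean(re) - 114.0), 2 * se)
  ri <- assay(cohort)["ri", ]
  expect_lt(abs(mean(ri) - 140.8), 2 * sd(ri) / sqrt(length(ri)))
})

test_that("emergent 50 kHz resistance and impedance agree with the printed norms within 10%", {
  # R and Z are not calibration targets; their agreement cross-validates the
  # single-dispersion model against the printed table structure
  ref <- loadReference()
  cohort <- paramCohort(seed = 81, nPerCell = 25, muscles = biaMuscles())
  cd <- colData(cohort)
  for (mus in biaMuscles()) {
    for (gen in c("men", "women")) {
      keep <- cd$muscle == mus & cd$gender == gen
      for (par in c("r", "z")) {
        printed <- referenceLookup(ref, mus, gen, par)$mean
        got <- mean(assay(cohort)[par, keep])
        expect_lt(abs(got - printed) / printed, 0.10,
                  label = sprintf("%s/%s/%s: |%.1f - %.1f|/mean", mus, gen,
                                  par, got, printed))
      }
    }
  }
})

test_that("changing only the seed changes the data but no calibration constant", {
  c1 <- paramCohort(seed = 91)
  c2 <- paramCohort(seed = 92)
  expect_false(identical(assay(c1), assay(c2)))
  expect_identical(metadata(c1)$calibration, metadata(c2)$calibration)
  c1b <- paramCohort(seed = 91)
  expect_identical(assay(c1), assay(c1b))
})

test_that("generator config validates its bounds", {
  expect_error(biaGeneratorConfig(n_per_cell = 0))
  expect_error(biaGeneratorConfig(noise_sd_fraction = 0.3))
  expect_error(biaGeneratorConfig(f_min = 100, f_max = 10))
  expect_error(biaGeneratorConfig(n_frequencies = 4))
})
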