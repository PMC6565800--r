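# Independent oracles and fixture builders used across the suite.

# Brute-force exact two-sided Mann-Whitney p: enumerate all C(m+n, m)
# assignments of the pooled ranks to group a, build the exact null
# distribution of U_a, and return min(1, 2 * min(P(U <= u), P(U >= u))).
# Independent of the package implementation (and of wilcox.test).
mwEnumerationP <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  uObs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  sets <- utils::combn(m + n, m)
  uAll <- apply(sets, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  pl <- mean(uAll <= uObs)
  pu <- mean(uAll >= uObs)
  min(1, 2 * min(pl, pu))
}

# Geometric (full nonlinear least-squares) circle fit: minimises the sum of
# squared distances from the points to the circle.  Used as the oracle for
# the algebraic initializer on noisy data.
circleFitGeometric <- function(r, x) {
  obj <- function(par) {
    d <- sqrt((r - par[1])^2 + (x - par[2])^2)
    sum((d - par[3])^2)
  }
  start <- c(mean(r), mean(x),
             mean(sqrt((r - mean(r))^2 + (x - mean(x))^2)))
  fit <- optim(start, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  list(centerR = fit$par[1], centerX = fit$par[2], radius = fit$par[3])
}

# Render an exact (noiseless) spectrum from Cole parameters on a log grid.
modelSpectrum <- function(r0, rinf, fc, alpha, nPoints = 256,
                          fMin = 4, fMax = 1000, meta = list()) {
  p <- ColeParameters(r0 = r0, rinf = rinf, fc = fc, alpha = alpha)
  f <- exp(seq(log(fMin), log(fMax), length.out = nPoints))
  m <- evaluateCole(p, f)
  ImpedanceSpectrum(f, m$resistance, m$reactance, meta = meta)
}

# Add proportional Gaussian noise to a noiseless spectrum (same noise model
# as the generator, but constructed independently here).
noisySpectrum <- function(spec, sdFraction, seed) {
  set.seed(seed)
  f <- frequencies(spec)
  ImpedanceSpectrum(
    f,
    resistance(spec) * (1 + sdFraction * rnorm(length(f))),
    reactance(spec) * (1 + sdFraction * rnorm(length(f))),
    meta = spectrumMeta(spec))
}

maxRelErr <- function(fit, trueR0, trueRinf, trueFc, trueAlpha) {
  p <- coleParameters(fit)
  max(abs(c(r0(p) / trueR0, rinf(p) / trueRinf,
            centerFrequency(p) / trueFc, dispersionAlpha(p) / trueAlpha) - 1))
}

# Independent second transcription of the normative table (printed order:
# Z, R, fc, PA, Ri, Re, Xc, Mc; men then women within each muscle), used to
# cross-check the packaged TSV value-by-value.
referenceTranscription <- local({
  rows <- list(
    biceps_men = c(86.4, 19.2, 84.2, 20.2, 42.3, 6.4, 13.1, 5.1,
                   140.8, 84.6, 114.0, 19.2, 18.1, 3.7, 17.5, 7.6),
    biceps_women = c(133.0, 27.6, 131.9, 28.1, 58.1, 8.0, 7.3, 3.1,
                     372.4, 211.7, 154.9, 26.9, 15.7, 4.3, 6.4, 3.0),
    triceps_men = c(102.8, 19.4, 101.4, 20.1, 30.9, 6.3, 9.1, 3.9,
                    258.9, 123.0, 131.8, 18.5, 15.2, 4.1, 15.5, 6.6),
    triceps_women = c(154.1, 31.2, 153.5, 31.4, 63.3, 95.4, 4.8, 2.1,
                      573.4, 288.4, 195.9, 116.0, 12.5, 4.1, 11.3, 28.6),
    abductor_pollicis_brevis_men = c(42.8, 6.4, 42.2, 6.2, 73.5, 14.1,
                                     8.8, 1.9, 78.6, 20.7, 50.6, 9.1,
                                     6.6, 2.0, 17.8, 4.0),
    abductor_pollicis_brevis_women = c(52.2, 25.8, 51.7, 25.8, 95.9, 19.8,
                                       7.3, 1.9, 133.9, 214.7, 59.2, 27.1,
                                       6.3, 1.9, 11.6, 3.7),
    trapezius_men = c(71.7, 15.4, 70.4, 15.9, 45.1, 7.2, 10.6, 4.6,
                      144.5, 90.9, 90.8, 15.1, 12.3, 3.6, 18.2, 8.5),
    trapezius_women = c(82.7, 17.4, 81.7, 17.8, 63.2, 18.9, 8.9, 3.7,
                        193.0, 148.0, 98.5, 17.7, 12.0, 3.7, 13.3, 12.1),
    rectus_femoris_men = c(83.1, 16.1, 81.7, 16.6, 33.2, 4.2, 10.5, 3.5,
                           173.9, 73.5, 108.5, 17.0, 14.4, 2.5, 18.8, 6.0),
    rectus_femoris_women = c(140.9, 19.2, 140.4, 19.1, 53.7, 69.3, 5.0, 1.2,
                             505.1, 164.2, 163.3, 23.9, 12.3, 3.4, 10.2, 19.7),
    vastus_lateralis_men = c(68.9, 15.9, 66.6, 16.4, 31.8, 4.2, 15.1, 4.4,
                             106.1, 65.7, 98.2, 18.3, 17.1, 3.4, 27.4, 7.8),
    vastus_lateralis_women = c(124.0, 23.0, 123.4, 23.0, 37.3, 8.4, 5.5, 2.0,
                               436.7, 155.6, 146.0, 27.2, 11.6, 3.9, 8.4, 3.6),
    gastrocnemius_men = c(68.2, 13.4, 66.6, 13.3, 52.5, 7.9, 12.2, 2.8,
                          100.3, 38.1, 85.6, 16.9, 14.2, 3.8, 17.7, 4.8),
    gastrocnemius_women = c(102.1, 20.6, 101.5, 20.6, 66.5, 20.3, 6.4, 1.7,
                            298.5, 116.7, 116.6, 22.4, 11.1, 2.8, 9.5, 13.9),
    tibialis_anterior_men = c(59.3, 8.0, 57.5, 7.8, 48.4, 5.2, 14.0, 1.8,
                              72.8, 18.4, 78.6, 10.6, 14.3, 2.4, 22.6, 4.5),
    tibialis_anterior_women = c(91.1, 20.5, 90.2, 20.6, 59.7, 16.3, 7.9, 2.5,
                                221.7, 105.7, 107.4, 22.3, 12.1, 2.8, 12.2, 12.8))
  pars <- c("z", "r", "fc", "pa", "ri", "re", "xc", "mc")
  out <- do.call(rbind, lapply(names(rows), function(key) {
    gender <- sub(".*_(men|women)$", "\\1", key)
    muscle <- sub("_(men|women)$", "", key)
    v <- rows[[key]]
    data.frame(muscle = muscle, gender = gender, parameter = pars,
               mean = v[seq(1, 16, by = 2)], sd = v[seq(2, 16, by = 2)],
               stringsAsFactors = FALSE)
  }))
  out
})

# Small parameter-level synthetic cohort shared by statistics tests.
paramCohort <- function(seed = 101, nPerCell = 5, muscles = "biceps",
                        genders = c("men", "women"), ...) {
  cfg <- biaGeneratorConfig(seed = seed, n_per_cell = nPerCell, ...)
  generateCohort(cfg, muscles = muscles, genders = genders,
                 renderSpectra = FALSE)
}
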