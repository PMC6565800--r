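## Synthetic cohort generator: the stand-in for human measurements.  The
## default configuration reproduces the reference study design: 5 men and
## 5 women per age decade from 20 to 69 (50 subjects), 8 muscles with
## bilateral gastrocnemius (9 recordings/subject, 450 spectra), 256
## log-spaced frequencies from 4 to 1000 kHz, 1% proportional noise.

#' Generator configuration
#'
#' @param n_per_cell subjects per gender x decade cell (default 5, the
#'   reference design).
#' @param seed integer seed; all randomness derives from it.
#' @param noise_sd_fraction SD of the proportional Gaussian noise applied
#'   independently to the resistance and reactance of every rendered sample
#'   (default 0.01, i.e. 1%).
#' @param n_frequencies points per sweep (default 256).
#' @param f_min,f_max sweep limits in kHz (defaults 4 and 1000).
#' @param age_effect multiplier applied to the sampled Re, Ri and fc of
#'   subjects in the old pooled-age group (50s/60s); 1.0 (default) is the
#'   null of no age effect, matching the reference finding.
#' @param truncation lower truncation bound for sampled parameters, as a
#'   fraction of the cell mean (default 0.1).
#' @param gastroc_correlation within-subject left/right correlation of the
#'   sampled gastrocnemius parameters (default 0.8; side-to-side similarity
#'   is biologically expected but unquantified, so it is a config knob).
#' @return validated config (list with class \code{BiaGeneratorConfig}).
#' @export
biaGeneratorConfig <- function(n_per_cell = 5L, seed = 1L,
                               noise_sd_fraction = 0.01,
                               n_frequencies = 256L, f_min = 4, f_max = 1000,
                               age_effect = 1.0, truncation = 0.1,
                               gastroc_correlation = 0.8) {
  cfg <- list(n_per_cell = as.integer(n_per_cell), seed = as.integer(seed),
              noise_sd_fraction = noise_sd_fraction,
              n_frequencies = as.integer(n_frequencies),
              f_min = f_min, f_max = f_max, age_effect = age_effect,
              truncation = truncation,
              gastroc_correlation = gastroc_correlation)
  stopifnot(cfg$n_per_cell >= 1L,
            cfg$noise_sd_fraction >= 0, cfg$noise_sd_fraction < 0.2,
            cfg$n_frequencies >= 8L,
            cfg$f_min > 0, cfg$f_min < cfg$f_max,
            cfg$age_effect > 0,
            cfg$truncation >= 0, cfg$truncation < 1,
            cfg$gastroc_correlation >= 0, cfg$gastroc_correlation <= 1)
  class(cfg) <- "BiaGeneratorConfig"
  cfg
}

#' Demographic targets per gender and decade
#'
#' Packaged cohort demographics (age, weight, height mean and SD per gender
#' and decade) used to sample subject covariates.
#'
#' @return data.frame with one row per gender x decade.
#' @export
loadDemographics <- function() {
  path <- system.file("extdata", "cohort_demographics.tsv",
                      package = "muscleBIA", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

.DECADES <- c("20s", "30s", "40s", "50s", "60s")
.decadeStart <- c("20s" = 20L, "30s" = 30L, "40s" = 40L,
                  "50s" = 50L, "60s" = 60L)

## truncated-normal draw through the Gaussian copula: z is standard normal
## (possibly correlated across sides); marginal is truncnorm(mu, sd, lower)
.truncFromZ <- function(z, mu, sd, lower) {
  pLow <- pnorm(lower, mean = mu, sd = sd)
  qnorm(pLow + pnorm(z) * (1 - pLow), mean = mu, sd = sd)
}

## sample Cole parameters for `nSides` correlated recordings of one muscle
.sampleCell <- function(cell, nSides = 1L, rho = 0, scale = 1) {
  zShared <- rnorm(3)
  draw <- function(side) {
    z <- sqrt(rho) * zShared + sqrt(1 - rho) * rnorm(3)
    re <- .truncFromZ(z[1], cell$re_mu, cell$re_sd, cell$re_lower) * scale
    ri <- .truncFromZ(z[2], cell$ri_mu, cell$ri_sd, cell$ri_lower) * scale
    fc <- .truncFromZ(z[3], cell$fc_mu, cell$fc_sd, cell$fc_lower) * scale
    list(r0 = re, rinf = rinfFrom(re, ri), fc = fc, alpha = cell$alpha,
         ri = ri)
  }
  lapply(seq_len(nSides), draw)
}

.renderSpectrum <- function(pars, config, meta) {
  f <- exp(seq(log(config$f_min), log(config$f_max),
               length.out = config$n_frequencies))
  z <- .coleImpedance(pars$r0, pars$rinf, pars$fc, pars$alpha, f)
  s <- config$noise_sd_fraction
  r <- Re(z) * (1 + s * rnorm(length(f)))
  x <- -Im(z) * (1 + s * rnorm(length(f)))
  ImpedanceSpectrum(f, r, x, meta = meta)
}

#' Generate one synthetic subject
#'
#' Samples demographics around the packaged per-cell targets (age uniform
#' within the decade, weight and height truncated-normal) and per-muscle
#' Cole parameters from the calibrated cell distributions; renders one noisy
#' spectrum per muscle (two for gastrocnemius, with correlated left/right
#' parameters).  Deterministic for a fixed \code{seed}.
#'
#' @param gender \code{"men"} or \code{"women"}.
#' @param ageDecade one of \code{"20s" ... "60s"}.
#' @param config a \code{\link{biaGeneratorConfig}}.
#' @param seed integer seed for this subject, or NULL to draw from the
#'   current RNG stream (used by \code{\link{generateCohort}}, which seeds
#'   one stream for the whole cohort so that subjects are independent).
#' @param subjectId identifier string.
#' @param muscles muscles to record (default all eight).
#' @param calibration table from \code{\link{calibrateGenerator}}.
#' @param demographics table from \code{\link{loadDemographics}}.
#' @param renderSpectra render noisy spectra (set \code{FALSE} for fast
#'   parameter-level simulation).
#' @return list with \code{recordings} (data.frame of per-recording
#'   metadata), \code{values} (8 x recordings matrix of derived parameters,
#'   mc in nF), \code{truth} (sampled Cole parameters per recording) and
#'   \code{spectra} (named list, or NULL).
#' @export
generateSubject <- function(gender, ageDecade, config = biaGeneratorConfig(),
                            seed = config$seed, subjectId = "S001",
                            muscles = biaMuscles(),
                            calibration = calibrateGenerator(
                              truncation = config$truncation),
                            demographics = loadDemographics(),
                            renderSpectra = TRUE) {
  gender <- match.arg(gender, .BIA_GENDERS)
  ageDecade <- match.arg(ageDecade, .DECADES)
  muscles <- vapply(muscles, match.arg, "", choices = .BIA_MUSCLES)
  if (!is.null(seed)) set.seed(seed)

  demo <- demographics[demographics$gender == gender &
                         demographics$decade == ageDecade, ]
  stopifnot(nrow(demo) == 1L)
  age <- .decadeStart[[ageDecade]] + sample.int(10L, 1L) - 1L
  weight <- .rtruncnorm(1, demo$weight_mean, demo$weight_sd,
                        0.5 * demo$weight_mean)
  height <- .rtruncnorm(1, demo$height_mean, demo$height_sd,
                        0.75 * demo$height_mean)
  scale <- if (ageDecade %in% c("50s", "60s")) config$age_effect else 1

  recs <- list(); vals <- list(); truth <- list(); spectra <- list()
  for (mus in muscles) {
    cell <- calibration[calibration$muscle == mus &
                          calibration$gender == gender, ]
    stopifnot(nrow(cell) == 1L)
    bilateral <- mus == "gastrocnemius"
    sides <- if (bilateral) c("left", "right") else "unspecified"
    draws <- .sampleCell(cell, nSides = length(sides),
                         rho = if (bilateral) config$gastroc_correlation else 0,
                         scale = scale)
    for (k in seq_along(sides)) {
      p <- draws[[k]]
      id <- paste(subjectId, mus, sides[k], sep = "_")
      cp <- ColeParameters(r0 = p$r0, rinf = p$rinf, fc = p$fc,
                           alpha = p$alpha)
      recs[[id]] <- data.frame(
        recording_id = id, subject_id = subjectId, gender = gender,
        age = age, age_decade = ageDecade, weight_kg = weight,
        height_m = height, bmi = bmi(weight, height), muscle = mus,
        side = sides[k], stringsAsFactors = FALSE)
      vals[[id]] <- parameterVector(deriveParameters(cp), mcUnit = "nF")
      truth[[id]] <- data.frame(recording_id = id, r0 = p$r0, rinf = p$rinf,
                                fc = p$fc, alpha = p$alpha,
                                stringsAsFactors = FALSE)
      if (renderSpectra)
        spectra[[id]] <- .renderSpectrum(p, config, meta = list(
          subject_id = subjectId, muscle = mus, side = sides[k],
          gender = gender, age = age))
    }
  }
  list(recordings = do.call(rbind, c(recs, list(make.row.names = FALSE))),
       values = do.call(cbind, vals),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       spectra = if (renderSpectra) spectra else NULL)
}

#' Generate a calibrated synthetic cohort
#'
#' Assembles \code{n_per_cell} subjects per gender and decade (default:
#' the 50-subject reference design) into a \code{\linkS4class{BiaCohort}}.
#' The assay holds the derived parameters computed from each recording's
#' true sampled Cole state; rendered spectra (when requested) and the truth
#' table are attached to \code{metadata()} for round-trip validation via
#' \code{\link{fitCohort}}.  Deterministic for a fixed config seed: each
#' subject draws from an independent seed derived from it, so changing only
#' the seed changes the data but no calibration constant.
#'
#' @param config a \code{\link{biaGeneratorConfig}}.
#' @param muscles muscles to record (default all eight).
#' @param genders genders to include (default both).
#' @param renderSpectra render noisy spectra per recording (default TRUE;
#'   FALSE gives fast parameter-level cohorts for simulation studies).
#' @param reference normative table used for calibration.
#' @param calibration precomputed \code{\link{calibrateGenerator}} table
#'   (pass it when generating many cohorts to avoid re-solving the cells).
#' @return a \code{\linkS4class{BiaCohort}}.
#' @examples
#' cfg <- biaGeneratorConfig(seed = 7)
#' cohort <- generateCohort(cfg, muscles = "biceps", renderSpectra = FALSE)
#' cohort
#' @export
generateCohort <- function(config = biaGeneratorConfig(),
                           muscles = biaMuscles(),
                           genders = c("men", "women"),
                           renderSpectra = TRUE,
                           reference = loadReference(),
                           calibration = calibrateGenerator(
                             reference, truncation = config$truncation)) {
  stopifnot(inherits(config, "BiaGeneratorConfig"))
  demographics <- loadDemographics()
  recs <- list(); vals <- list(); truth <- list(); spectra <- list()
  set.seed(config$seed)
  k <- 0L
  for (gender in genders) {
    prefix <- if (gender == "men") "M" else "W"
    idx <- 0L
    for (decade in .DECADES) {
      for (j in seq_len(config$n_per_cell)) {
        k <- k + 1L; idx <- idx + 1L
        subjectId <- sprintf("%s%03d", prefix, idx)
        subj <- generateSubject(
          gender, decade, config, seed = NULL, subjectId = subjectId,
          muscles = muscles, calibration = calibration,
          demographics = demographics, renderSpectra = renderSpectra)
        recs[[k]] <- subj$recordings
        vals[[k]] <- subj$values
        truth[[k]] <- subj$truth
        if (renderSpectra) spectra <- c(spectra, subj$spectra)
      }
    }
  }
  .makeCohort(
    values = do.call(cbind, vals),
    recordings = do.call(rbind, recs),
    meta = list(config = config, calibration = calibration,
                truth = do.call(rbind, truth),
                spectra = if (renderSpectra) spectra else NULL))
}

#' Refit a cohort from its rendered spectra
#'
#' Runs \code{\link{fitCole}} + \code{\link{deriveParameters}} on every
#' rendered spectrum and returns a cohort whose assay holds the
#' fitted-derived values (the measurement pipeline's view of the synthetic
#' data), for comparison against the generator truth.
#'
#' @param cohort a \code{\linkS4class{BiaCohort}} with rendered spectra.
#' @param ... passed to \code{\link{fitCole}}.
#' @return a \code{\linkS4class{BiaCohort}} with assay from fits and a
#'   \code{fits} diagnostics data.frame in \code{metadata()}.
#' @export
fitCohort <- function(cohort, ...) {
  spectra <- cohortSpectra(cohort)
  if (is.null(spectra))
    stop("cohort has no rendered spectra (generate with renderSpectra = TRUE)")
  ids <- colData(cohort)$recording_id
  stopifnot(all(ids %in% names(spectra)))
  fits <- lapply(spectra[ids], fitCole, ...)
  vals <- vapply(fits, function(f)
    parameterVector(deriveParameters(coleParameters(f)), mcUnit = "nF"),
    numeric(8))
  rownames(vals) <- .BIA_PARAMETERS
  colnames(vals) <- ids
  diagn <- data.frame(
    recording_id = ids,
    rmse = vapply(fits, function(f) fitDiagnostics(f)@rmse, 0),
    arc_coverage = vapply(fits, function(f) fitDiagnostics(f)@arcCoverage, 0),
    converged = vapply(fits, function(f) fitDiagnostics(f)@converged, TRUE),
    stringsAsFactors = FALSE)
  meta <- metadata(cohort)
  meta$fits <- diagn
  .makeCohort(values = vals, recordings = as.data.frame(colData(cohort)),
              meta = meta)
}
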