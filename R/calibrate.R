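## Calibration: invert the printed normative means into Cole-model sampling
## distributions, one cell per muscle x gender.
##
## Targets per cell: the sampled Re, Ri and fc distributions must have means
## equal to the printed means (Re and Ri are sampled directly and rinf is
## derived through the parallel-circuit identity, which makes the plug-in
## means exact by construction and avoids the upward Jensen bias that
## sampling rinf would impose on Ri); alpha is solved so the model reactance
## at 50 kHz at the cell means equals the printed Xc mean.

#' Solve the dispersion exponent for one cell
#'
#' 1-D root solve for \eqn{\alpha} such that the Cole model with the given
#' \code{(r0, rinf, fc)} reproduces the target reactance at the readout
#' frequency.  The model reactance at fixed frequency increases from 0 (as
#' \eqn{\alpha \to 0}) to its semicircle value at \eqn{\alpha = 1}; a target
#' above the \eqn{\alpha = 1} value is geometrically infeasible.
#'
#' @param r0,rinf,fc Cole state (ohm, ohm, kHz).
#' @param xcTarget target reactance magnitude at \code{frequency}, ohm.
#' @param frequency readout frequency, kHz (default 50).
#' @return alpha in (0, 1].
#' @export
solveCellAlpha <- function(r0, rinf, fc, xcTarget, frequency = 50) {
  xcAt <- function(alpha)
    -Im(.coleImpedance(r0, rinf, fc, alpha, frequency))
  atOne <- xcAt(1)
  if (xcTarget > atOne + 1e-12)
    stop(sprintf(
      "calibration infeasible: target Xc %.3g ohm exceeds the alpha = 1 value %.3g ohm",
      xcTarget, atOne))
  if (xcTarget >= atOne) return(1)
  if (xcTarget <= 0)
    stop("calibration infeasible: target Xc must be positive")
  uniroot(function(a) xcAt(a) - xcTarget, c(1e-4, 1), tol = 1e-12)$root
}

#' Calibrate the cohort generator against the normative table
#'
#' For each muscle x gender cell, builds the sampling distribution of the
#' Cole parameters: truncated-normal distributions for Re, Ri and fc whose
#' truncated means equal the printed means exactly (the underlying location
#' is adjusted by a root solve, since plain truncation at
#' \code{truncation * mean} would inflate the mean of high-variance cells),
#' SDs taken from the printed SDs, and a fixed per-cell alpha from
#' \code{\link{solveCellAlpha}}.  Cells whose printed fc SD is not smaller
#' than the fc mean (a pathology of two cells in the source table) have the
#' fc SD capped at the mean, and are flagged.
#'
#' @param reference table from \code{\link{loadReference}}.
#' @param truncation lower truncation bound for sampled parameters as a
#'   fraction of the cell mean (default 0.1).
#' @return data.frame with one row per cell: means, SDs, truncation bounds
#'   and mean-corrected locations (\code{*_mu}) for \code{re}, \code{ri},
#'   \code{fc}; derived \code{rinf_mean}; solved \code{alpha}; the
#'   \code{xc_target}; and \code{fc_sd_capped}.
#' @export
calibrateGenerator <- function(reference = loadReference(), truncation = 0.1) {
  cells <- expand.grid(muscle = .BIA_MUSCLES, gender = .BIA_GENDERS,
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    mus <- cells$muscle[i]; gen <- cells$gender[i]
    get <- function(p) referenceLookup(reference, mus, gen, p)
    re <- get("re"); ri <- get("ri"); fc <- get("fc"); xc <- get("xc")
    fcSd <- fc$sd
    capped <- fcSd >= fc$mean
    if (capped) fcSd <- fc$mean
    spec <- function(mean, sd) {
      lower <- truncation * mean
      c(mean = mean, sd = sd, lower = lower,
        mu = .truncnormMatchMean(mean, sd, lower))
    }
    reS <- spec(re$mean, re$sd)
    riS <- spec(ri$mean, ri$sd)
    fcS <- spec(fc$mean, fcSd)
    rinfMean <- rinfFrom(re$mean, ri$mean)
    alpha <- tryCatch(
      solveCellAlpha(re$mean, rinfMean, fc$mean, xc$mean),
      error = function(e)
        stop(sprintf("cell (%s, %s): %s", mus, gen, conditionMessage(e))))
    data.frame(
      muscle = mus, gender = gen,
      re_mean = reS[["mean"]], re_sd = reS[["sd"]],
      re_lower = reS[["lower"]], re_mu = reS[["mu"]],
      ri_mean = riS[["mean"]], ri_sd = riS[["sd"]],
      ri_lower = riS[["lower"]], ri_mu = riS[["mu"]],
      fc_mean = fcS[["mean"]], fc_sd = fcS[["sd"]],
      fc_lower = fcS[["lower"]], fc_mu = fcS[["mu"]],
      fc_sd_capped = capped,
      rinf_mean = rinfMean, xc_target = xc$mean, alpha = alpha,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
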