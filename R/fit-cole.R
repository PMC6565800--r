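## Fitting the Cole model to a measured spectrum: algebraic circle fit in the
## complex plane for a deterministic initializer, then Levenberg-Marquardt
## refinement of (r0, rinf, fc, alpha) on the stacked complex residuals.

#' Algebraic least-squares circle fit
#'
#' Kasa-style fit: minimises the algebraic residual
#' \eqn{x^2 + y^2 + Dx + Ey + F} over all points, which is a linear
#' least-squares problem and exact for points lying on a circle.  Used as the
#' deterministic initializer for \code{\link{fitCole}}.
#'
#' @param r,x numeric vectors: point coordinates in the impedance plane
#'   (resistance, reactance), at least 3 non-collinear points.
#' @return list with \code{centerR}, \code{centerX}, \code{radius}.
#' @examples
#' fitCircle(c(0, 2, 1), c(0, 0, 1))   # center (1, 0), radius 1
#' @export
fitCircle <- function(r, x) {
  if (length(r) != length(x) || length(r) < 3)
    stop("need at least 3 (r, x) points")
  A <- cbind(r, x, 1)
  b <- -(r^2 + x^2)
  qrA <- qr(A)
  if (qrA$rank < 3)
    stop("degenerate geometry: points are collinear (or coincident)")
  coef <- qr.coef(qrA, b)
  cr <- -coef[[1]] / 2
  cx <- -coef[[2]] / 2
  rad2 <- cr^2 + cx^2 - coef[[3]]
  if (!is.finite(rad2) || rad2 <= 0)
    stop("degenerate geometry: no real circle through the points")
  list(centerR = cr, centerX = cx, radius = sqrt(rad2))
}

## Cole arc geometry for the positive-reactance convention: the chord lies on
## the real axis between rinf and r0, the centre sits below it at depression
## angle phi = (1 - alpha) * pi / 2, and the data span a central angle of at
## most alpha * pi.
.arcCenter <- function(r0, rinf, alpha) {
  phi <- (1 - alpha) * pi / 2
  half <- (r0 - rinf) / 2
  list(cr = (r0 + rinf) / 2, cx = -half * tan(phi),
       radius = half / cos(phi), phi = phi)
}

.coleInit <- function(spec) {
  circ <- fitCircle(spec@resistance, spec@reactance)
  h2 <- circ$radius^2 - circ$centerX^2
  if (h2 <= 0)
    stop("degenerate geometry: fitted circle does not intersect the real axis")
  h <- sqrt(h2)
  r0 <- circ$centerR + h
  rinf <- circ$centerR - h
  if (rinf <= 0) rinf <- min(spec@resistance) * 0.5
  if (rinf >= r0) stop("degenerate geometry: fitted rinf >= r0")
  ## depression angle below the real axis -> alpha
  phi <- atan2(max(-circ$centerX, 0), h)
  alpha <- min(max(1 - 2 * phi / pi, 0.05), 1)
  fc <- spec@frequency[which.max(spec@reactance)]
  list(r0 = r0, rinf = rinf, fc = fc, alpha = alpha)
}

#' Fit the Cole model to an impedance spectrum
#'
#' Initialises \code{(r0, rinf, alpha)} from the real-axis intercepts and
#' depression angle of an algebraic circle fit, \code{fc} from the frequency
#' of maximal measured reactance, then refines all four parameters by
#' Levenberg-Marquardt least squares on the stacked complex residuals
#' (resistance and reactance weighted equally per frequency; set
#' \code{proportionalWeights = TRUE} to weight residuals by 1/|Z|).  The
#' refinement works on an unconstrained transform (logs of \code{rinf},
#' \code{r0 - rinf} and \code{fc}; logit of \code{alpha}) so every iterate is
#' a valid parameter set.  The procedure is fully deterministic.
#'
#' @param spectrum an \code{\linkS4class{ImpedanceSpectrum}}.
#' @param proportionalWeights logical; weight complex residuals by the
#'   reciprocal model impedance magnitude (default \code{FALSE}: equal
#'   weights, no weighting is implied by standard practice).
#' @param fixAlpha logical; constrain the dispersion exponent to 1
#'   (undepressed semicircle) instead of fitting it.
#' @param maxIterations Levenberg-Marquardt iteration cap.
#' @return a \code{\linkS4class{ColeFit}}; non-convergence is flagged in the
#'   diagnostics (parameters are then the best iterate found).
#' @examples
#' p <- ColeParameters(r0 = 114, rinf = 63, fc = 42.3, alpha = 0.8)
#' f <- exp(seq(log(4), log(1000), length.out = 64))
#' m <- evaluateCole(p, f)
#' fitCole(ImpedanceSpectrum(f, m$resistance, m$reactance))
#' @export
fitCole <- function(spectrum, proportionalWeights = FALSE, fixAlpha = FALSE,
                    maxIterations = 200L) {
  stopifnot(is(spectrum, "ImpedanceSpectrum"))
  validObject(spectrum)
  init <- .coleInit(spectrum)
  if (fixAlpha) init$alpha <- 1
  f <- spectrum@frequency
  zObs <- complex(real = spectrum@resistance, imaginary = -spectrum@reactance)

  unpack <- function(par) {
    rinf <- exp(par[[1]])
    r0 <- rinf + exp(par[[2]])
    fc <- exp(par[[3]])
    alpha <- if (fixAlpha) 1 else stats::plogis(par[[4]])
    list(r0 = r0, rinf = rinf, fc = fc, alpha = alpha)
  }
  resid <- function(par) {
    p <- unpack(par)
    zm <- .coleImpedance(p$r0, p$rinf, p$fc, p$alpha, f)
    w <- if (proportionalWeights) 1 / Mod(zm) else 1
    c(w * (Re(zm) - Re(zObs)), w * (Im(zm) - Im(zObs)))
  }
  a0 <- min(max(init$alpha, 0.02), 0.995)
  par0 <- c(log(init$rinf), log(init$r0 - init$rinf), log(init$fc),
            if (fixAlpha) NULL else stats::qlogis(a0))
  fit <- minpack.lm::nls.lm(
    par = par0, fn = resid,
    control = minpack.lm::nls.lm.control(
      maxiter = maxIterations, ftol = 1e-14, ptol = 1e-14, gtol = 0))
  p <- unpack(fit$par)
  if (p$rinf >= p$r0)
    stop("degenerate geometry: fitted rinf >= r0")
  params <- ColeParameters(r0 = p$r0, rinf = p$rinf, fc = p$fc,
                           alpha = min(p$alpha, 1))
  zm <- .coleImpedance(p$r0, p$rinf, p$fc, p$alpha, f)
  rmse <- sqrt(mean(Mod(zm - zObs)^2))
  converged <- fit$info %in% 1:4
  diag <- FitDiagnostics(
    rmse = rmse,
    arcCoverage = .arcCoverage(params, range(f)),
    converged = isTRUE(converged),
    nPointsUsed = length(f))
  ColeFit(parameters = params, diagnostics = diag)
}

## fraction of the model arc's central angle (alpha * pi) spanned between the
## lowest and highest measured frequency
.arcCoverage <- function(params, frange) {
  cen <- .arcCenter(params@r0, params@rinf, params@alpha)
  ang <- function(f) {
    z <- .coleImpedance(params@r0, params@rinf, params@fc, params@alpha, f)
    atan2(-Im(z) - cen$cx, Re(z) - cen$cr)
  }
  span <- abs(ang(frange[1]) - ang(frange[2]))
  min(max(span / (params@alpha * pi), 0), 1)
}

#' Quality control for a fitted recording
#'
#' Mirrors the visual plausibility screen applied to each recording during
#' acquisition: the fitted arc must explain the data (RMSE below a fraction
#' of the arc width \code{r0 - rinf}), the sweep must cover a substantial
#' part of the arc, and the centre frequency must fall inside the swept
#' range (otherwise the apex was extrapolated, not measured).
#'
#' @param spectrum the measured \code{\linkS4class{ImpedanceSpectrum}}.
#' @param fit the corresponding \code{\linkS4class{ColeFit}}.
#' @param rmseFraction maximum RMSE as a fraction of \code{r0 - rinf}
#'   (default 0.05).
#' @param minArcCoverage minimum arc coverage (default 0.5).
#' @return list with \code{accept} (logical) and \code{reasons}
#'   (character vector, empty when accepted).
#' @export
qualityCheck <- function(spectrum, fit, rmseFraction = 0.05,
                         minArcCoverage = 0.5) {
  stopifnot(is(spectrum, "ImpedanceSpectrum"), is(fit, "ColeFit"))
  p <- fit@parameters
  d <- fit@diagnostics
  reasons <- character()
  if (d@rmse > rmseFraction * (p@r0 - p@rinf))
    reasons <- c(reasons, "rmse_exceeds_threshold")
  if (d@arcCoverage < minArcCoverage)
    reasons <- c(reasons, "insufficient_arc_coverage")
  fr <- range(spectrum@frequency)
  if (p@fc < fr[1] || p@fc > fr[2])
    reasons <- c(reasons, "fc_outside_sweep")
  if (!d@converged)
    reasons <- c(reasons, "fit_not_converged")
  list(accept = length(reasons) == 0L, reasons = reasons)
}
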