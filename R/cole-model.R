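## Closed-form layer: the Cole model and the four derivations used to report
## muscle parameters.  Pure computation, no I/O, no randomness.

#' Evaluate the Cole impedance model
#'
#' Computes model resistance (real part) and reactance magnitude (negated
#' imaginary part) at the requested frequencies for
#' \eqn{Z(f) = R_\infty + (R_0 - R_\infty)/(1 + (j f/f_c)^\alpha)}.
#' The reactance of a passive tissue is capacitive (negative imaginary part);
#' following the usual mfBIA table convention it is returned as a positive
#' magnitude.
#'
#' @param params a \code{\linkS4class{ColeParameters}} object.
#' @param frequency numeric vector of frequencies in kHz, all \code{> 0}.
#' @return data.frame with columns \code{frequency}, \code{resistance},
#'   \code{reactance} (ohm).
#' @examples
#' p <- ColeParameters(r0 = 114, rinf = 63, fc = 42.3, alpha = 1)
#' evaluateCole(p, c(4, 42.3, 50, 1000))
#' @export
evaluateCole <- function(params, frequency) {
  stopifnot(is(params, "ColeParameters"))
  validObject(params)
  if (!is.numeric(frequency) || length(frequency) == 0 ||
      any(!is.finite(frequency)) || any(frequency <= 0))
    stop("frequency must be a vector of positive finite values (kHz)")
  z <- .coleImpedance(params@r0, params@rinf, params@fc, params@alpha, frequency)
  data.frame(frequency = frequency, resistance = Re(z), reactance = -Im(z))
}

## complex impedance; f in kHz (only the ratio f/fc enters)
.coleImpedance <- function(r0, rinf, fc, alpha, f) {
  rinf + (r0 - rinf) / (1 + (1i * f / fc)^alpha)
}

#' Intracellular resistance from Re and Rinf
#'
#' \eqn{R_i = R_e R_\infty / (R_e - R_\infty)}: the resistance of the
#' intracellular branch of the parallel two-branch tissue circuit, given the
#' extracellular resistance (zero-frequency limit) and the
#' infinite-frequency resistance of the parallel combination.
#'
#' @param re extracellular resistance, ohm, \code{> rinf}.
#' @param rinf infinite-frequency resistance, ohm, \code{> 0}.
#' @return intracellular resistance, ohm.
#' @seealso \code{\link{rinfFrom}} for the algebraic inverse.
#' @export
riFrom <- function(re, rinf) {
  if (any(!is.finite(re)) || any(!is.finite(rinf)) || any(rinf <= 0))
    stop("re and rinf must be finite with rinf > 0")
  if (any(rinf >= re))
    stop("degenerate geometry: need rinf < re (Ri is unbounded otherwise)")
  re * rinf / (re - rinf)
}

#' Infinite-frequency resistance from Re and Ri
#'
#' Algebraic inverse of \code{\link{riFrom}}: the parallel combination
#' \eqn{R_\infty = R_e R_i / (R_e + R_i)}, always \code{< re}.  Used by the
#' cohort calibrator to translate printed (Re, Ri) pairs into Cole-model
#' state.
#'
#' @param re extracellular resistance, ohm, \code{> 0}.
#' @param ri intracellular resistance, ohm, \code{> 0}.
#' @return infinite-frequency resistance, ohm.
#' @export
rinfFrom <- function(re, ri) {
  if (any(!is.finite(re)) || any(!is.finite(ri)) || any(re <= 0) || any(ri <= 0))
    stop("re and ri must be finite and positive")
  re * ri / (re + ri)
}

#' Membrane capacitance from fc, Re and Ri
#'
#' Inverts the centre-frequency relation
#' \eqn{f_c = 1/(2\pi M_c (R_e + R_i))} to
#' \eqn{M_c = 1/(2\pi f_c (R_e + R_i))}.  \code{fc} is supplied in kHz (the
#' unit used throughout the package) and converted to Hz internally, so the
#' result is in farad.
#'
#' @param fc centre frequency, kHz, \code{> 0}.
#' @param re,ri resistances, ohm, \code{> 0}.
#' @return membrane capacitance, farad.
#' @export
mcFrom <- function(fc, re, ri) {
  if (any(!is.finite(fc)) || any(!is.finite(re)) || any(!is.finite(ri)) ||
      any(fc <= 0) || any(re <= 0) || any(ri <= 0))
    stop("fc, re and ri must be finite and positive")
  1 / (2 * pi * (fc * 1000) * (re + ri))
}

#' Impedance magnitude from resistance and reactance
#'
#' \eqn{Z = \sqrt{R^2 + X_c^2}}.
#'
#' @param r resistance, ohm, \code{>= 0}.
#' @param xc reactance magnitude, ohm, \code{>= 0}.
#' @return impedance magnitude, ohm.
#' @export
impedanceMagnitude <- function(r, xc) {
  if (any(!is.finite(r)) || any(!is.finite(xc)) || any(r < 0) || any(xc < 0))
    stop("r and xc must be finite and non-negative")
  sqrt(r^2 + xc^2)
}

#' Phase angle from resistance and reactance
#'
#' \eqn{PA = \arctan(X_c / R)} in degrees, in \code{[0, 90)}.
#'
#' @param r resistance, ohm, \code{> 0}.
#' @param xc reactance magnitude, ohm, \code{>= 0}.
#' @return phase angle, degrees.
#' @export
phaseAngle <- function(r, xc) {
  if (any(!is.finite(r)) || any(!is.finite(xc)) || any(r <= 0) || any(xc < 0))
    stop("need r > 0 and xc >= 0")
  atan(xc / r) * 180 / pi
}

#' Derive the eight reported parameters from fitted Cole state
#'
#' Evaluates the fitted model at 50 kHz for R and Xc (model evaluation rather
#' than raw-sample interpolation: the readout is then noise-robust), forms
#' Z and the phase angle from the closed forms, and derives Re (= R0),
#' Ri and Mc from the Cole state.
#'
#' @param params a \code{\linkS4class{ColeParameters}} object.
#' @param readoutFrequency detailed-analysis frequency in kHz (default 50).
#' @return a \code{\linkS4class{DerivedParameters}} object.
#' @examples
#' p <- ColeParameters(r0 = 2, rinf = 1, fc = 50, alpha = 1)
#' parameterVector(deriveParameters(p))
#' @export
deriveParameters <- function(params, readoutFrequency = 50) {
  stopifnot(is(params, "ColeParameters"))
  at50 <- evaluateCole(params, readoutFrequency)
  r <- at50$resistance
  xc <- at50$reactance
  re <- params@r0
  ri <- riFrom(params@r0, params@rinf)
  DerivedParameters(
    z = impedanceMagnitude(r, xc), r = r, xc = xc,
    pa = phaseAngle(r, xc), fc = params@fc,
    re = re, ri = ri, mc = mcFrom(params@fc, re, ri))
}
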