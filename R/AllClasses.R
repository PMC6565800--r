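#' @include AllGenerics.R
NULL

## Central S4 classes.  All quantities are in the units used throughout the
## package: resistances/reactances in ohm, frequencies in kHz, phase angle in
## degrees, membrane capacitance in farad (SI) unless a reporting unit is
## requested explicitly.

#' Cole model parameters
#'
#' State of the single-dispersion Cole impedance model
#' \eqn{Z(f) = R_\infty + (R_0 - R_\infty)/(1 + (j f/f_c)^\alpha)}.
#' \code{r0} is the zero-frequency resistance (identified with the
#' extracellular resistance Re), \code{rinf} the infinite-frequency
#' resistance, \code{fc} the centre frequency (kHz, apex of the arc) and
#' \code{alpha} the dispersion exponent controlling the depression of the
#' arc (\code{alpha = 1} gives an undepressed semicircle).
#'
#' @slot r0 numeric(1), ohm; zero-frequency resistance, \code{> rinf}.
#' @slot rinf numeric(1), ohm; infinite-frequency resistance, \code{> 0}.
#' @slot fc numeric(1), kHz; centre frequency, \code{> 0}.
#' @slot alpha numeric(1), dimensionless in \code{(0, 1]}.
#'
#' @param r0,rinf,fc,alpha see slots.
#' @param object a \code{ColeParameters} object.
#' @return \code{ColeParameters()} returns a validated object; the accessors
#'   return the corresponding slot.
#' @examples
#' p <- ColeParameters(r0 = 114, rinf = 63, fc = 42.3, alpha = 0.8)
#' r0(p); centerFrequency(p)
#' @aliases r0 rinf centerFrequency dispersionAlpha
#' @export ColeParameters
#' @exportClass ColeParameters
ColeParameters <- setClass("ColeParameters",
  representation(r0 = "numeric", rinf = "numeric",
                 fc = "numeric", alpha = "numeric"),
  prototype(alpha = 1))

setValidity("ColeParameters", function(object) {
  v <- c(object@r0, object@rinf, object@fc, object@alpha)
  if (length(object@r0) != 1L || length(object@rinf) != 1L ||
      length(object@fc) != 1L || length(object@alpha) != 1L)
    return("all slots must be scalar")
  if (!all(is.finite(v)))
    return("all parameters must be finite")
  if (!(object@rinf > 0 && object@rinf < object@r0))
    return("need 0 < rinf < r0 (arc must have positive width)")
  if (object@fc <= 0)
    return("fc must be > 0 kHz")
  if (!(object@alpha > 0 && object@alpha <= 1))
    return("alpha must lie in (0, 1]")
  TRUE
})

#' @rdname ColeParameters-class
setMethod("initialize", "ColeParameters", function(.Object, ...) {
  .Object <- callNextMethod(.Object, ...)
  validObject(.Object)
  .Object
})

#' One multi-frequency bioimpedance recording
#'
#' A frequency sweep over one muscle: per-frequency resistance and reactance
#' (reactance stored as a positive-sign magnitude, i.e. the negated imaginary
#' part of the impedance) plus free-form recording metadata (subject id,
#' muscle, side, gender, age, ...).
#'
#' The constructor sorts rows by frequency and rejects duplicated
#' frequencies.  At least 8 points are required (identifiability floor for
#' the four-parameter Cole fit); frequencies must lie in (0, 1e4] kHz and
#' resistance must be strictly positive.  Small negative reactance values are
#' tolerated (measurement noise near the ends of the sweep).
#'
#' @slot frequency numeric, kHz, strictly increasing.
#' @slot resistance numeric, ohm, \code{> 0}.
#' @slot reactance numeric, ohm (magnitude convention).
#' @slot meta list of recording metadata.
#'
#' @param frequency,resistance,reactance,meta see slots.
#' @param object an \code{ImpedanceSpectrum}.
#' @aliases frequencies resistance reactance spectrumMeta
#' @export ImpedanceSpectrum
#' @exportClass ImpedanceSpectrum
ImpedanceSpectrum <- function(frequency, resistance, reactance, meta = list()) {
  o <- order(frequency)
  new("ImpedanceSpectrum",
      frequency = as.numeric(frequency[o]),
      resistance = as.numeric(resistance[o]),
      reactance = as.numeric(reactance[o]),
      meta = meta)
}

setClass("ImpedanceSpectrum",
  representation(frequency = "numeric", resistance = "numeric",
                 reactance = "numeric", meta = "list"))

setValidity("ImpedanceSpectrum", function(object) {
  n <- length(object@frequency)
  if (n < 8L)
    return("a spectrum needs at least 8 frequency points")
  if (length(object@resistance) != n || length(object@reactance) != n)
    return("frequency, resistance and reactance must have equal length")
  if (!all(is.finite(object@frequency)) || !all(is.finite(object@resistance)) ||
      !all(is.finite(object@reactance)))
    return("all values must be finite")
  if (any(object@frequency <= 0) || any(object@frequency > 1e4))
    return("frequencies must lie in (0, 1e4] kHz")
  if (any(diff(object@frequency) <= 0))
    return("frequencies must be strictly increasing (no duplicates)")
  if (any(object@resistance <= 0))
    return("resistance must be strictly positive")
  TRUE
})

#' Cole-fit diagnostics
#'
#' @slot rmse numeric(1), ohm; root-mean-square residual distance in the
#'   complex impedance plane.
#' @slot arcCoverage numeric(1) in \code{[0, 1]}; fraction of the full model
#'   arc (central angle \eqn{\alpha\pi}) spanned by the data.
#' @slot converged logical(1).
#' @slot nPointsUsed integer(1).
#' @export FitDiagnostics
#' @exportClass FitDiagnostics
FitDiagnostics <- setClass("FitDiagnostics",
  representation(rmse = "numeric", arcCoverage = "numeric",
                 converged = "logical", nPointsUsed = "integer"))

setValidity("FitDiagnostics", function(object) {
  if (object@rmse < 0) return("rmse must be >= 0")
  if (object@arcCoverage < 0 || object@arcCoverage > 1)
    return("arcCoverage must lie in [0, 1]")
  TRUE
})

#' Result of a Cole-model fit
#'
#' Bundles the fitted \code{\linkS4class{ColeParameters}} with
#' \code{\linkS4class{FitDiagnostics}}.
#'
#' @slot parameters fitted \code{ColeParameters}.
#' @slot diagnostics \code{FitDiagnostics}.
#' @param object a \code{ColeFit}.
#' @aliases coleParameters fitDiagnostics
#' @export ColeFit
#' @exportClass ColeFit
ColeFit <- setClass("ColeFit",
  representation(parameters = "ColeParameters",
                 diagnostics = "FitDiagnostics"))

#' The eight reported muscle parameters
#'
#' Derived quantities for one recording: impedance magnitude \code{z},
#' resistance \code{r} and reactance \code{xc} at 50 kHz, phase angle
#' \code{pa} at 50 kHz (degrees), centre frequency \code{fc} (kHz),
#' extracellular resistance \code{re} (= R0), intracellular resistance
#' \code{ri} and membrane capacitance \code{mc} (stored in farad; see
#' \code{\link{parameterVector}} for the nanofarad reporting convention).
#'
#' @slot z,r,xc,pa,fc,re,ri,mc numeric(1); see description.
#' @param object a \code{DerivedParameters}.
#' @export DerivedParameters
#' @exportClass DerivedParameters
DerivedParameters <- setClass("DerivedParameters",
  representation(z = "numeric", r = "numeric", xc = "numeric", pa = "numeric",
                 fc = "numeric", re = "numeric", ri = "numeric",
                 mc = "numeric"))

setValidity("DerivedParameters", function(object) {
  v <- c(object@z, object@r, object@xc, object@pa, object@fc,
         object@re, object@ri, object@mc)
  if (length(v) != 8L || !all(is.finite(v)))
    return("all eight fields must be finite scalars")
  if (any(v <= 0))
    return("all derived parameters must be strictly positive")
  if (object@z < object@r || object@z < object@xc)
    return("impedance magnitude must dominate its components")
  if (object@pa <= 0 || object@pa >= 90)
    return("phase angle must lie in (0, 90) degrees")
  TRUE
})

## ---- accessors ----

#' @rdname ColeParameters-class
setMethod("r0", "ColeParameters", function(object) object@r0)
#' @rdname ColeParameters-class
setMethod("rinf", "ColeParameters", function(object) object@rinf)
#' @rdname ColeParameters-class
setMethod("centerFrequency", "ColeParameters", function(object) object@fc)
#' @rdname ColeParameters-class
setMethod("dispersionAlpha", "ColeParameters", function(object) object@alpha)

#' @rdname ImpedanceSpectrum-class
setMethod("frequencies", "ImpedanceSpectrum", function(object) object@frequency)
#' @rdname ImpedanceSpectrum-class
setMethod("resistance", "ImpedanceSpectrum", function(object) object@resistance)
#' @rdname ImpedanceSpectrum-class
setMethod("reactance", "ImpedanceSpectrum", function(object) object@reactance)
#' @rdname ImpedanceSpectrum-class
setMethod("spectrumMeta", "ImpedanceSpectrum", function(object) object@meta)

#' @rdname ColeFit-class
setMethod("coleParameters", "ColeFit", function(object) object@parameters)
#' @rdname ColeFit-class
setMethod("fitDiagnostics", "ColeFit", function(object) object@diagnostics)

#' @rdname parameterVector
setMethod("parameterVector", "DerivedParameters", function(object, mcUnit = c("nF", "F")) {
  mcUnit <- match.arg(mcUnit)
  mc <- if (mcUnit == "nF") object@mc * 1e9 else object@mc
  c(z = object@z, r = object@r, xc = object@xc, pa = object@pa,
    fc = object@fc, re = object@re, ri = object@ri, mc = mc)
})

## ---- show methods ----

setMethod("show", "ColeParameters", function(object) {
  cat(sprintf(
    "ColeParameters: R0 = %.2f ohm, Rinf = %.2f ohm, fc = %.2f kHz, alpha = %.3f\n",
    object@r0, object@rinf, object@fc, object@alpha))
})

setMethod("show", "ImpedanceSpectrum", function(object) {
  m <- object@meta
  lab <- paste(
    Filter(nzchar, c(m$subject_id, m$muscle, m$side, m$gender)), collapse = " / ")
  cat(sprintf("ImpedanceSpectrum: %d points, %.3g-%.4g kHz%s\n",
              length(object@frequency), min(object@frequency),
              max(object@frequency),
              if (nzchar(lab)) paste0(" [", lab, "]") else ""))
})

setMethod("show", "ColeFit", function(object) {
  show(object@parameters)
  d <- object@diagnostics
  cat(sprintf("  fit: rmse = %.4g ohm, arc coverage = %.2f, converged = %s (n = %d)\n",
              d@rmse, d@arcCoverage, d@converged, d@nPointsUsed))
})

setMethod("show", "DerivedParameters", function(object) {
  v <- parameterVector(object)
  cat("DerivedParameters (50 kHz readout, fc in kHz, Mc in nF):\n")
  print(round(v, 3))
})
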