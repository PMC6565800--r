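#' @rdname ColeParameters-class
#' @export
setGeneric("r0", function(object) standardGeneric("r0"))

#' @rdname ColeParameters-class
#' @export
setGeneric("rinf", function(object) standardGeneric("rinf"))

#' @rdname ColeParameters-class
#' @export
setGeneric("centerFrequency", function(object) standardGeneric("centerFrequency"))

#' @rdname ColeParameters-class
#' @export
setGeneric("dispersionAlpha", function(object) standardGeneric("dispersionAlpha"))

#' @rdname ImpedanceSpectrum-class
#' @export
setGeneric("frequencies", function(object) standardGeneric("frequencies"))

#' @rdname ImpedanceSpectrum-class
#' @export
setGeneric("resistance", function(object) standardGeneric("resistance"))

#' @rdname ImpedanceSpectrum-class
#' @export
setGeneric("reactance", function(object) standardGeneric("reactance"))

#' @rdname ImpedanceSpectrum-class
#' @export
setGeneric("spectrumMeta", function(object) standardGeneric("spectrumMeta"))

#' @rdname ColeFit-class
#' @export
setGeneric("coleParameters", function(object) standardGeneric("coleParameters"))

#' @rdname ColeFit-class
#' @export
setGeneric("fitDiagnostics", function(object) standardGeneric("fitDiagnostics"))

#' Flatten derived parameters to a named vector
#'
#' @param object a \code{\linkS4class{DerivedParameters}} object.
#' @param mcUnit unit for the membrane-capacitance element: \code{"nF"}
#'   (reporting convention, numerically comparable with the packaged normative
#'   table) or \code{"F"} (SI value actually produced by the defining formula).
#' @return named numeric vector with elements
#'   \code{z, r, xc, pa, fc, re, ri, mc}.
#' @export
setGeneric("parameterVector", function(object, mcUnit = c("nF", "F"))
  standardGeneric("parameterVector"))
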