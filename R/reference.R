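## Normative reference ranges: 8 muscles x 2 genders x 8 parameters packaged
## as a TSV resource, plus the comparison layer built on top of it (percent
## changes with the men's mean as baseline, z-scores for new recordings).

.BIA_MUSCLES <- c("biceps", "triceps", "abductor_pollicis_brevis", "trapezius",
                  "rectus_femoris", "vastus_lateralis", "gastrocnemius",
                  "tibialis_anterior")
.BIA_PARAMETERS <- c("z", "r", "xc", "pa", "fc", "re", "ri", "mc")
.BIA_GENDERS <- c("men", "women")

#' Muscles, parameters and genders covered by the normative table
#'
#' @return character vector of canonical identifiers.
#' @export
biaMuscles <- function() .BIA_MUSCLES

#' @rdname biaMuscles
#' @export
biaParameters <- function() .BIA_PARAMETERS

#' Load the packaged normative reference table
#'
#' Normative mean and SD for each of the eight parameters in each muscle and
#' gender cell (n = 25 healthy adults aged 20--69 per cell; Z, R, Xc, Ri, Re
#' in ohm, fc in kHz, PA in degrees).  The membrane-capacitance rows carry
#' the unit label \code{pF} exactly as printed in the source table even
#' though the defining formula applied to the same table's fc/Re/Ri values
#' yields tens of nanofarad; the label is therefore treated as ambiguous and
#' Mc values are only used in unit-free comparisons (percent changes,
#' z-scores).  See the package vignette.
#'
#' @return data.frame with columns \code{muscle}, \code{gender},
#'   \code{parameter}, \code{mean}, \code{sd}, \code{n}, \code{unit}
#'   (128 rows).
#' @examples
#' ref <- loadReference()
#' referenceLookup(ref, "biceps", "men", "z")
#' @export
loadReference <- function() {
  path <- system.file("extdata", "reference_norms.tsv", package = "muscleBIA",
                      mustWork = TRUE)
  ref <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(nrow(ref) == 128L,
            identical(sort(unique(ref$muscle)), sort(.BIA_MUSCLES)),
            all(ref$parameter %in% .BIA_PARAMETERS),
            all(ref$gender %in% .BIA_GENDERS),
            all(ref$sd > 0), all(ref$n == 25L))
  ref
}

#' Look up one normative cell
#'
#' @param reference table from \code{\link{loadReference}}.
#' @param muscle,gender,parameter canonical identifiers
#'   (see \code{\link{biaMuscles}}).
#' @return one-row data.frame (mean, sd, n, unit).
#' @export
referenceLookup <- function(reference, muscle, gender, parameter) {
  muscle <- match.arg(muscle, .BIA_MUSCLES)
  gender <- match.arg(gender, .BIA_GENDERS)
  parameter <- match.arg(parameter, .BIA_PARAMETERS)
  row <- reference[reference$muscle == muscle & reference$gender == gender &
                     reference$parameter == parameter, , drop = FALSE]
  if (nrow(row) != 1L)
    stop(sprintf("no reference entry for (%s, %s, %s)", muscle, gender, parameter))
  row
}

#' Percent change with the men's mean as baseline
#'
#' \code{100 * (womenMean - menMean) / menMean}, rounded half away from zero
#' to an integer, matching the printed style of the normative contrast table.
#'
#' @param menMean baseline group mean, must be \code{> 0}.
#' @param womenMean comparison group mean.
#' @return signed integer percent.
#' @examples
#' percentChange(86.4, 133.0)  # +54
#' @export
percentChange <- function(menMean, womenMean) {
  if (any(!is.finite(menMean)) || any(menMean <= 0))
    stop("baseline mean must be finite and > 0")
  roundHalfAwayFromZero(100 * (womenMean - menMean) / menMean)
}

#' Load the printed gender-contrast table
#'
#' The women-versus-men contrast rows as printed (direction, integer percent
#' with the men's mean as baseline, significance band).  Stored metadata:
#' the significance bands cannot be recomputed without subject-level data.
#'
#' @return data.frame with columns \code{muscle}, \code{parameter},
#'   \code{direction} (\code{increase}/\code{decrease}/\code{NS}),
#'   \code{percent} (\code{NA} when not printed), \code{p_band}.
#' @export
loadPrintedContrasts <- function() {
  path <- system.file("extdata", "printed_gender_contrasts.tsv",
                      package = "muscleBIA", mustWork = TRUE)
  pc <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(nrow(pc) == 64L)
  pc
}

#' Recompute the gender-contrast percent table from the packaged means
#'
#' For every (muscle, parameter) cell, recomputes the women-versus-men
#' percent change from the packaged normative means and pairs it with the
#' printed value.  A handful of printed cells differ by one percent point
#' from the mean-derived recomputation (the printed percentages were
#' evidently computed from unrounded subject-level data before rounding);
#' those cells are flagged rather than hidden.
#'
#' @param reference table from \code{\link{loadReference}}.
#' @param printed table from \code{\link{loadPrintedContrasts}}.
#' @return data.frame with one row per muscle x parameter: recomputed signed
#'   percent, printed signed percent (\code{NA} for cells printed NS without
#'   a percent), printed band, and \code{flagged} where the two integers
#'   disagree.
#' @export
genderContrastTable <- function(reference = loadReference(),
                                printed = loadPrintedContrasts()) {
  men <- reference[reference$gender == "men", ]
  women <- reference[reference$gender == "women", ]
  key <- function(d) paste(d$muscle, d$parameter)
  women <- women[match(key(men), key(women)), ]
  out <- data.frame(
    muscle = men$muscle, parameter = men$parameter,
    men_mean = men$mean, women_mean = women$mean,
    recomputed_percent = percentChange(men$mean, women$mean),
    stringsAsFactors = FALSE)
  m <- match(key(out), key(printed))
  sgn <- ifelse(printed$direction[m] == "decrease", -1, 1)
  out$printed_percent <- sgn * printed$percent[m]
  out$printed_band <- printed$p_band[m]
  out$significant <- printed$p_band[m] != "NS"
  out$flagged <- !is.na(out$printed_percent) &
    out$recomputed_percent != out$printed_percent
  out
}

#' z-scores of a recording against the normative table
#'
#' Standardises each of the eight derived parameters against the normative
#' mean and SD of the matching muscle/gender cell:
#' \eqn{z = (x - \mu)/\sigma}.  Membrane capacitance is compared on the
#' printed table's numeric scale (the package's nanofarad reporting values,
#' which are of the same magnitude as the printed numbers; the printed unit
#' label is ambiguous, but the z-score is unit-free given that convention).
#'
#' @param derived a \code{\linkS4class{DerivedParameters}} object.
#' @param muscle,gender canonical identifiers.
#' @param reference table from \code{\link{loadReference}}.
#' @param flagThreshold absolute z beyond which a parameter is flagged
#'   (default 2).
#' @return data.frame with one row per parameter: value (reporting units),
#'   reference mean/sd, z, and an outlier flag.
#' @examples
#' p <- ColeParameters(r0 = 114, rinf = 63, fc = 42.3, alpha = 0.7)
#' zscoreAgainstReference(deriveParameters(p), "biceps", "men")
#' @export
zscoreAgainstReference <- function(derived, muscle, gender,
                                   reference = loadReference(),
                                   flagThreshold = 2) {
  stopifnot(is(derived, "DerivedParameters"))
  muscle <- match.arg(muscle, .BIA_MUSCLES)
  gender <- match.arg(gender, .BIA_GENDERS)
  v <- parameterVector(derived, mcUnit = "nF")
  cell <- reference[reference$muscle == muscle & reference$gender == gender, ]
  if (nrow(cell) != 8L)
    stop(sprintf("incomplete reference cell for (%s, %s)", muscle, gender))
  m <- match(names(v), cell$parameter)
  if (anyNA(m)) stop("reference cell is missing parameters")
  z <- (v - cell$mean[m]) / cell$sd[m]
  data.frame(parameter = names(v), value = unname(v),
             ref_mean = cell$mean[m], ref_sd = cell$sd[m], unit = cell$unit[m],
             z = unname(z), outlier = unname(abs(z) > flagThreshold),
             stringsAsFactors = FALSE)
}
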