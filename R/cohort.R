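## Cohort container: a SummarizedExperiment whose assay holds the eight
## derived parameters (rows, reporting units: ohm / kHz / degrees / nF) for
## every recording (columns), with per-recording metadata in colData.

#' Cohort of muscle recordings
#'
#' Extends \code{SummarizedExperiment}: one column per recording, rows fixed
#' to the eight derived parameters (\code{z, r, xc, pa, fc, re, ri, mc}; mc
#' in nF reporting units).  Required \code{colData} columns:
#' \code{recording_id}, \code{subject_id}, \code{gender}, \code{age},
#' \code{age_decade}, \code{weight_kg}, \code{height_m}, \code{bmi},
#' \code{muscle}, \code{side}.  Synthetic cohorts additionally carry, in
#' \code{metadata()}: the generator config, the calibration table, a
#' \code{truth} data.frame with the per-recording sampled Cole parameters,
#' and (optionally) the rendered \code{spectra}.
#'
#' @param object a \code{BiaCohort}.
#' @aliases cohortTruth cohortSpectra
#' @export BiaCohort
#' @exportClass BiaCohort
BiaCohort <- setClass("BiaCohort", contains = "SummarizedExperiment")

.COHORT_COLS <- c("recording_id", "subject_id", "gender", "age", "age_decade",
                  "weight_kg", "height_m", "bmi", "muscle", "side")

setValidity("BiaCohort", function(object) {
  if (!identical(rownames(object), .BIA_PARAMETERS))
    return(sprintf("assay rows must be exactly: %s",
                   paste(.BIA_PARAMETERS, collapse = ", ")))
  missing <- setdiff(.COHORT_COLS, colnames(colData(object)))
  if (length(missing))
    return(paste("missing colData columns:", paste(missing, collapse = ", ")))
  cd <- colData(object)
  if (any(cd$age < 20 | cd$age > 69))
    return("ages must lie within [20, 69]")
  if (any(abs(cd$bmi - cd$weight_kg / cd$height_m^2) > 1e-9))
    return("bmi must equal weight/height^2")
  bad <- tapply(seq_len(ncol(object)),
                paste(cd$subject_id, cd$muscle),
                function(i) {
                  mus <- cd$muscle[i[1]]
                  n <- length(i)
                  (mus == "gastrocnemius" && n > 2) ||
                    (mus != "gastrocnemius" && n > 1)
                })
  if (any(unlist(bad)))
    return("only gastrocnemius may be recorded twice (left/right) per subject")
  TRUE
})

## assemble a BiaCohort from a per-recording data.frame and value matrix
.makeCohort <- function(values, recordings, meta = list()) {
  stopifnot(identical(rownames(values), .BIA_PARAMETERS))
  se <- SummarizedExperiment(
    assays = list(value = values),
    colData = DataFrame(recordings, row.names = recordings$recording_id))
  out <- BiaCohort(se)
  metadata(out) <- meta
  out
}

#' True (sampled) Cole parameters of a synthetic cohort
#'
#' @param cohort a synthetic \code{\linkS4class{BiaCohort}}.
#' @return data.frame with one row per recording (\code{recording_id},
#'   \code{r0}, \code{rinf}, \code{fc}, \code{alpha}), or \code{NULL} for
#'   cohorts not produced by the generator.
#' @export
cohortTruth <- function(cohort) metadata(cohort)$truth

#' Rendered spectra of a synthetic cohort
#'
#' @param cohort a synthetic \code{\linkS4class{BiaCohort}}.
#' @return named list of \code{\linkS4class{ImpedanceSpectrum}} objects
#'   (names are recording ids), or \code{NULL} when spectra were not
#'   rendered.
#' @export
cohortSpectra <- function(cohort) metadata(cohort)$spectra

setMethod("show", "BiaCohort", function(object) {
  cd <- colData(object)
  cat(sprintf("BiaCohort: %d recordings, %d subjects (%d men / %d women), %d muscle(s)\n",
              ncol(object), length(unique(cd$subject_id)),
              length(unique(cd$subject_id[cd$gender == "men"])),
              length(unique(cd$subject_id[cd$gender == "women"])),
              length(unique(cd$muscle))))
  cat(sprintf("  spectra attached: %s; generator truth attached: %s\n",
              !is.null(cohortSpectra(object)), !is.null(cohortTruth(object))))
})
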