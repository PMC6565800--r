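## File formats.  Spectrum CSV (one recording per file): optional comment
## lines `#key=value`, then the fixed header
## `frequency_khz,resistance_ohm,reactance_ohm`, comma-separated,
## dot-decimal, UTF-8.  Cohort manifest: TSV with one row per recording.

.SPECTRUM_HEADER <- "frequency_khz,resistance_ohm,reactance_ohm"
.MANIFEST_COLS <- c("subject_id", "gender", "age", "weight_kg", "height_m",
                    "muscle", "side", "spectrum_file")

#' Read one spectrum CSV
#'
#' Parses and validates a single-recording spectrum file.  Leading
#' \code{#key=value} lines become metadata; rows are returned sorted by
#' frequency; malformed headers, non-numeric cells and duplicated
#' frequencies raise errors naming the offending line.
#'
#' @param path file path.
#' @return an \code{\linkS4class{ImpedanceSpectrum}}.
#' @export
readSpectrum <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  isComment <- grepl("^#", lines)
  meta <- list()
  for (cl in lines[isComment]) {
    kv <- sub("^#", "", cl)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  body <- which(!isComment & nzchar(trimws(lines)))
  if (!length(body)) stop(path, ": empty spectrum file")
  if (trimws(lines[body[1]]) != .SPECTRUM_HEADER)
    stop(sprintf("%s: line %d: expected header '%s'",
                 path, body[1], .SPECTRUM_HEADER))
  dataLines <- body[-1]
  parts <- strsplit(lines[dataLines], ",", fixed = TRUE)
  n <- lengths(parts)
  if (any(n != 3L))
    stop(sprintf("%s: line %d: expected 3 comma-separated fields",
                 path, dataLines[which(n != 3L)[1]]))
  m <- suppressWarnings(
    matrix(as.numeric(unlist(parts)), ncol = 3, byrow = TRUE))
  if (anyNA(m)) {
    badRow <- which(apply(m, 1, anyNA))[1]
    stop(sprintf("%s: line %d: non-numeric value", path, dataLines[badRow]))
  }
  dup <- which(duplicated(m[, 1]))
  if (length(dup))
    stop(sprintf("%s: line %d: duplicated frequency %g kHz",
                 path, dataLines[dup[1]], m[dup[1], 1]))
  if (!is.null(meta$age)) meta$age <- as.numeric(meta$age)
  ImpedanceSpectrum(m[, 1], m[, 2], m[, 3], meta = meta)
}

#' Write one spectrum CSV
#'
#' Inverse of \code{\link{readSpectrum}} (metadata as \code{#key=value}
#' comment lines, rows in frequency order, full double precision).
#'
#' @param spectrum an \code{\linkS4class{ImpedanceSpectrum}}.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
writeSpectrum <- function(spectrum, path) {
  stopifnot(is(spectrum, "ImpedanceSpectrum"))
  meta <- spectrumMeta(spectrum)
  header <- vapply(names(meta), function(k)
    sprintf("#%s=%s", k, as.character(meta[[k]])), "")
  rows <- sprintf("%s,%s,%s",
                  format(frequencies(spectrum), digits = 15, trim = TRUE),
                  format(resistance(spectrum), digits = 15, trim = TRUE),
                  format(reactance(spectrum), digits = 15, trim = TRUE))
  writeLines(c(header, .SPECTRUM_HEADER, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' @param path TSV with columns \code{subject_id}, \code{gender},
#'   \code{age}, \code{weight_kg}, \code{height_m}, \code{muscle},
#'   \code{side}, \code{spectrum_file} (paths relative to the manifest).
#' @return data.frame.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  man <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(.MANIFEST_COLS, colnames(man))
  if (length(missing))
    stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  man$spectrum_file <- file.path(dirname(path), man$spectrum_file)
  man
}

#' Write a synthetic cohort to disk
#'
#' Materialises a generated cohort as the file layout the pipeline consumes:
#' one spectrum CSV per recording, a cohort manifest TSV, and a provenance
#' JSON (config echo, calibration constants, per-recording true parameters)
#' for oracle tests.
#'
#' @param cohort a \code{\linkS4class{BiaCohort}} with rendered spectra.
#' @param dir output directory (created if needed).
#' @return path of the manifest file, invisibly.
#' @export
writeCohortFiles <- function(cohort, dir) {
  spectra <- cohortSpectra(cohort)
  if (is.null(spectra)) stop("cohort has no rendered spectra")
  dir.create(file.path(dir, "spectra"), recursive = TRUE, showWarnings = FALSE)
  cd <- as.data.frame(colData(cohort))
  files <- file.path("spectra", paste0(cd$recording_id, ".csv"))
  for (i in seq_len(nrow(cd)))
    writeSpectrum(spectra[[cd$recording_id[i]]], file.path(dir, files[i]))
  man <- cbind(cd[, c("subject_id", "gender", "age", "weight_kg", "height_m",
                      "muscle", "side")],
               spectrum_file = files)
  manPath <- file.path(dir, "manifest.tsv")
  write.table(man, manPath, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- metadata(cohort)$config
  prov <- list(config = unclass(cfg),
               calibration = metadata(cohort)$calibration,
               truth = cohortTruth(cohort))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manPath)
}
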