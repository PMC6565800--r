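## End-to-end pipeline over a file-based cohort: read -> fit -> QC -> derive
## -> z-scores -> gender and pooled-age contrasts, with per-recording fault
## isolation and deterministic report output.

#' Run the full analysis pipeline on a cohort manifest
#'
#' For each manifest row: read the spectrum, fit the Cole model, apply
#' \code{\link{qualityCheck}}, derive the eight parameters and z-score them
#' against the normative table.  Per-recording failures (unreadable or
#' degenerate spectra) are recorded in the report and do not abort the run.
#' Muscle-level gender contrasts (Mann-Whitney, men baseline) are computed
#' for every muscle x parameter with data from both genders, and pooled-age
#' contrasts (20s+30s vs 50s+60s) per gender where all four decades are
#' present.  Output is deterministic: no randomness, no timestamps.
#'
#' @param manifestPath cohort manifest TSV (see \code{\link{readManifest}}).
#' @param outDir output directory, created if needed.
#' @param reference normative table (default \code{\link{loadReference}()}).
#' @param alpha significance threshold in (0,1), default 0.05.
#' @param formats report formats to write, subset of
#'   \code{c("tsv", "json")}.
#' @return (invisibly) the report list: \code{recordings} (derived values,
#'   QC), \code{zscores}, \code{contrasts}, \code{errors}.
#' @export
runPipeline <- function(manifestPath, outDir, reference = loadReference(),
                        alpha = 0.05, formats = c("tsv", "json")) {
  stopifnot(alpha > 0, alpha < 1)
  formats <- match.arg(formats, several.ok = TRUE)
  man <- readManifest(manifestPath)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  recRows <- list(); zRows <- list(); errors <- list()
  values <- list(); keep <- list()
  for (i in seq_len(nrow(man))) {
    row <- man[i, ]
    rid <- paste(row$subject_id, row$muscle, row$side, sep = "_")
    res <- tryCatch({
      spec <- readSpectrum(row$spectrum_file)
      fit <- fitCole(spec)
      qc <- qualityCheck(spec, fit)
      derived <- deriveParameters(coleParameters(fit))
      v <- parameterVector(derived, mcUnit = "nF")
      zs <- zscoreAgainstReference(derived, row$muscle, row$gender,
                                   reference = reference)
      d <- fitDiagnostics(fit)
      list(rec = data.frame(
             recording_id = rid, row[, .MANIFEST_COLS[1:7]],
             as.list(v), rmse = d@rmse, arc_coverage = d@arcCoverage,
             qc_accept = qc$accept,
             qc_reasons = paste(qc$reasons, collapse = ";"),
             stringsAsFactors = FALSE),
           z = data.frame(recording_id = rid, zs, stringsAsFactors = FALSE),
           v = v)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[rid]] <- data.frame(recording_id = rid,
                                  spectrum_file = row$spectrum_file,
                                  error = conditionMessage(res),
                                  stringsAsFactors = FALSE)
    } else {
      recRows[[rid]] <- res$rec
      zRows[[rid]] <- res$z
      values[[rid]] <- res$v
      keep[[rid]] <- i
    }
  }
  bindRows <- function(lst) if (length(lst))
    do.call(rbind, c(lst, list(make.row.names = FALSE))) else NULL
  recTab <- bindRows(recRows)
  zTab <- bindRows(zRows)
  errTab <- bindRows(errors)

  contrasts <- NULL
  if (length(values)) {
    okMan <- man[unlist(keep), ]
    okMan$recording_id <- names(values)
    okMan$age_decade <- paste0(10 * (okMan$age %/% 10), "s")
    okMan$bmi <- bmi(okMan$weight_kg, okMan$height_m)
    cohort <- .makeCohort(do.call(cbind, values),
                          okMan[, c(.COHORT_COLS)])
    contrasts <- .allContrasts(cohort, alpha = alpha)
  }

  report <- list(recordings = recTab, zscores = zTab,
                 contrasts = contrasts,
                 errors = errTab,
                 n_input = nrow(man), n_fitted = length(values),
                 significance_threshold = alpha)
  if ("tsv" %in% formats) {
    wr <- function(d, f) if (!is.null(d))
      write.table(d, file.path(outDir, f), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    wr(recTab, "recordings.tsv")
    wr(zTab, "zscores.tsv")
    wr(contrasts, "contrasts.tsv")
    wr(errTab, "errors.tsv")
  }
  if ("json" %in% formats)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  invisible(report)
}

## every muscle x parameter gender contrast, plus pooled-age contrasts per
## gender where the design is complete
.allContrasts <- function(cohort, alpha = 0.05) {
  cd <- colData(cohort)
  rows <- list()
  for (mus in intersect(.BIA_MUSCLES, unique(cd$muscle))) {
    both <- all(c("men", "women") %in% cd$gender[cd$muscle == mus])
    for (par in .BIA_PARAMETERS) {
      if (both)
        rows[[length(rows) + 1L]] <-
          genderContrast(cohort, mus, par, alpha = alpha)
      for (gen in intersect(.BIA_GENDERS, unique(cd$gender))) {
        full <- all(c("20s", "30s", "50s", "60s") %in%
                      cd$age_decade[cd$muscle == mus & cd$gender == gen])
        if (full)
          rows[[length(rows) + 1L]] <- cbind(
            ageContrast(cohort, mus, par, gen, alpha = alpha), gender = gen)
      }
    }
  }
  if (!length(rows)) return(NULL)
  base <- do.call(rbind, lapply(rows, function(r) {
    if (!"gender" %in% names(r)) r$gender <- NA_character_
    r
  }))
  base
}

#' Structural validation of a pipeline report
#'
#' Checks a report (as returned by \code{\link{runPipeline}} or re-read from
#' \code{report.json}) against the shipped report schema
#' (\code{inst/schema/report-schema.json}): required top-level fields,
#' required per-table columns, and value ranges for p-values.
#'
#' @param report list (parsed report).
#' @return TRUE invisibly; stops with a message when invalid.
#' @export
validateReport <- function(report) {
  schema <- jsonlite::read_json(
    system.file("schema", "report-schema.json", package = "muscleBIA",
                mustWork = TRUE))
  req <- unlist(schema$required)
  missing <- setdiff(req, names(report))
  if (length(missing))
    stop("report is missing fields: ", paste(missing, collapse = ", "))
  recCols <- unlist(schema$properties$recordings$items$required)
  if (!is.null(report$recordings) && length(report$recordings)) {
    have <- if (is.data.frame(report$recordings)) colnames(report$recordings)
            else names(report$recordings[[1]])
    if (length(setdiff(recCols, have)))
      stop("recordings table is missing columns: ",
           paste(setdiff(recCols, have), collapse = ", "))
  }
  ct <- report$contrasts
  if (!is.null(ct) && length(ct)) {
    p <- if (is.data.frame(ct)) ct$p_value
         else vapply(ct, function(r) r$p_value, 0)
    if (any(p < 0 | p > 1)) stop("contrast p-values outside [0, 1]")
  }
  invisible(TRUE)
}
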