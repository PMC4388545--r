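#' Fit every trace CSV in a directory
#'
#' Loads each `*.csv` in `dir` as an RPE trace, centres it, fits the sine
#' model and collects one row per eye. A trace that fails to load or fit
#' is logged to stderr and skipped; the batch continues.
#'
#' @param dir directory of trace CSVs.
#' @param options a list from [fitOptions()].
#' @return data frame of [fitAsRow()] rows, ordered by file name, with an
#'   attribute `failures` naming the skipped files.
#' @export
runTraceBatch <- function(dir, options = fitOptions()) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) stop("no trace CSV files found in ", dir)
  rows <- list()
  failures <- character()
  for (f in files) {
    res <- tryCatch(
      fitAsRow(fitSine(centerCoordinates(loadTrace(f)), options)),
      error = function(e) {
        message("trace failed [", basename(f), "]: ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) failures <- c(failures, basename(f))
    else rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) stop("all traces failed in ", dir)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}

#' Read a cohort table from CSV or XLSX with column mapping
#'
#' Column names in the wild vary, so ingestion goes through a mapping
#' from canonical names (`amplitude_rater1`, `amplitude_rater2`,
#' `amplitude_mean`, `amplitude_rater1_repeat`, `ovality_ratio`,
#' `axis_class`, `spherical_equivalent`, `axial_length`, `body_height`,
#' `eye_id`) to the file's actual headers. The mapping can be given as a
#' named list/vector or as a YAML file with one `canonical: actual` pair
#' per line. Unmapped canonical columns are taken verbatim when a header
#' of the same name exists, otherwise left absent.
#'
#' @param path CSV or XLSX file.
#' @param columnMap named character vector/list or path to a YAML file.
#' @param sheet sheet index or name for XLSX input (default first).
#' @return data frame with canonical column names.
#' @export
readCohort <- function(path, columnMap = NULL, sheet = 1) {
  ext <- tolower(sub(".*\\.", "", path))
  df <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX requires the readxl package")
    as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (is.character(columnMap) && length(columnMap) == 1L &&
      file.exists(columnMap)) {
    columnMap <- yaml::read_yaml(columnMap)
  }
  canonical <- c("eye_id", "amplitude", "amplitude_rater1",
                 "amplitude_rater1_repeat", "amplitude_rater2",
                 "amplitude_mean", "ovality_ratio", "axis_class",
                 "spherical_equivalent", "axial_length", "body_height")
  out <- list()
  for (cn in canonical) {
    src <- if (!is.null(columnMap) && cn %in% names(columnMap))
      columnMap[[cn]] else cn
    if (src %in% names(df)) out[[cn]] <- df[[src]]
  }
  if (!length(out)) stop("no recognised cohort columns in ", path)
  as.data.frame(out, stringsAsFactors = FALSE)
}

.amplitudeForAnalysis <- function(table) {
  # the analysed amplitude is the mean of the two raters when available
  if (all(c("amplitude_rater1", "amplitude_rater2") %in% names(table)))
    (table$amplitude_rater1 + table$amplitude_rater2) / 2
  else if ("amplitude_mean" %in% names(table)) table$amplitude_mean
  else if ("amplitude" %in% names(table)) table$amplitude
  else stop("cohort table has no amplitude column")
}

.pairCorr <- function(amp, covar) {
  keep <- is.finite(amp) & is.finite(covar)
  dropped <- sum(!keep)
  if (dropped) message("dropped ", dropped, " incomplete rows")
  if (sum(keep) < 3L) return(list(rho = NA_real_, pValue = NA_real_,
                                  n = sum(keep)))
  spearmanCorr(amp[keep], covar[keep])
}

#' Run the full cohort analysis
#'
#' Reproduces the validation analysis on a per-eye cohort table: summary
#' statistics for each measurement column; intra-rater ICC (rater 1 vs
#' their repeat) and inter-rater ICC (rater 1 vs rater 2), both as
#' two-way absolute-agreement single measures; Spearman correlations of
#' the two-rater mean amplitude against ovality ratio, spherical
#' equivalent, axial length and body height; the amplitude-ovality
#' correlation within the vertical-axis and horizontal-axis subgroups;
#' and, when a `r_squared` column is present, the fraction of fits
#' passing the R^2 > 0.90 gate. Rows with missing cells are dropped per
#' analysis (listwise), with a logged count.
#'
#' @param table cohort data frame with canonical columns (see
#'   [readCohort()]).
#' @return list of class `rpewaveReport`: `table1`, `iccIntra`,
#'   `iccInter`, `correlations`, `subgroup`, `quality`, `n`.
#' @export
runCohortAnalysis <- function(table) {
  stopifnot(is.data.frame(table))
  if (nrow(table) < 3L) stop("need at least 3 usable cohort rows")
  amp <- .amplitudeForAnalysis(table)
  table1 <- list()
  table1$amplitude <- summaryStats(amp)
  for (cn in c("ovality_ratio", "spherical_equivalent", "axial_length",
               "body_height")) {
    if (cn %in% names(table)) table1[[cn]] <- summaryStats(table[[cn]])
  }
  iccIntra <- iccInter <- NULL
  if (all(c("amplitude_rater1", "amplitude_rater1_repeat") %in% names(table))) {
    m <- cbind(table$amplitude_rater1, table$amplitude_rater1_repeat)
    iccIntra <- iccAbsoluteAgreement(m[stats::complete.cases(m), ])
  }
  if (all(c("amplitude_rater1", "amplitude_rater2") %in% names(table))) {
    m <- cbind(table$amplitude_rater1, table$amplitude_rater2)
    iccInter <- iccAbsoluteAgreement(m[stats::complete.cases(m), ])
  }
  correlations <- list()
  for (cn in c("ovality_ratio", "spherical_equivalent", "axial_length",
               "body_height")) {
    if (cn %in% names(table))
      correlations[[cn]] <- .pairCorr(amp, table[[cn]])
  }
  subgroup <- list()
  if (all(c("ovality_ratio", "axis_class") %in% names(table))) {
    for (cls in c("vertical", "horizontal")) {
      sel <- table$axis_class == cls
      if (sum(sel, na.rm = TRUE) >= 3) {
        subgroup[[cls]] <- .pairCorr(amp[sel], table$ovality_ratio[sel])
      }
    }
  }
  quality <- if ("r_squared" %in% names(table)) {
    mean(table$r_squared > 0.90, na.rm = TRUE)
  } else NA_real_
  structure(list(table1 = table1, iccIntra = iccIntra, iccInter = iccInter,
                 correlations = correlations, subgroup = subgroup,
                 quality = quality, n = nrow(table)),
            class = "rpewaveReport")
}

#' @export
print.rpewaveReport <- function(x, ...) {
  cat(sprintf("Cohort analysis report (n = %d eyes)\n", x$n))
  cat("Summary (mean +/- SD, range):\n")
  for (cn in names(x$table1)) {
    s <- x$table1[[cn]]
    cat(sprintf("  %-22s %6.2f +/- %5.2f  (%.2f ~ %.2f)  n=%d\n",
                cn, s$mean, s$sd, s$min, s$max, s$n))
  }
  for (nm in c("iccIntra", "iccInter")) {
    if (!is.null(x[[nm]])) {
      i <- x[[nm]]
      cat(sprintf("  %-22s %0.3f (95%% CI %0.3f-%0.3f), p = %.3g\n",
                  paste0(sub("icc", "ICC ", nm), " (A,1)"),
                  i$icc, i$ciLower, i$ciUpper, i$pValue))
    }
  }
  if (length(x$correlations)) {
    cat("Spearman correlations with amplitude:\n")
    for (cn in names(x$correlations)) {
      ct <- x$correlations[[cn]]
      cat(sprintf("  %-22s R = %+0.2f, p = %.3g, n = %d\n",
                  cn, ct$rho, ct$pValue, ct$n))
    }
  }
  if (length(x$subgroup)) {
    cat("Amplitude-ovality correlation by disc axis:\n")
    for (cn in names(x$subgroup)) {
      ct <- x$subgroup[[cn]]
      cat(sprintf("  %-22s R = %+0.2f, p = %.3g, n = %d\n",
                  cn, ct$rho, ct$pValue, ct$n))
    }
  }
  if (is.finite(x$quality))
    cat(sprintf("  fits with R^2 > 0.90:  %.1f%%\n", 100 * x$quality))
  invisible(x)
}

#' Serialise an analysis report to JSON
#'
#' @param report a report from [runCohortAnalysis()].
#' @param path output path; `NULL` returns the JSON string.
#' @return `path` (or the JSON string), invisibly.
#' @export
writeReportJSON <- function(report, path = NULL) {
  payload <- unclass(report)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(json, path)
  invisible(path)
}
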