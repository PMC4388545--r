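#' Construct an RPE trace from coordinate vectors
#'
#' @param x,y numeric pixel coordinates (x along the unrolled scan,
#'   y image row). Rows are sorted by `x`.
#' @param scanWidth total columns of the source B-scan; defaults to
#'   `floor(max(x)) + 1` so a full-width trace is accepted as-is.
#' @param eyeId identifier carried through the pipeline.
#' @return an [RPETrace-class] object.
#' @examples
#' tr <- rpeTrace(x = 0:1023, y = 100 + 20 * sin(2 * pi * (0:1023) / 1024))
#' tr
#' @export
rpeTrace <- function(x, y, scanWidth = floor(max(x)) + 1, eyeId = "eye") {
  ord <- order(x)
  new("RPETrace", x = as.numeric(x[ord]), y = as.numeric(y[ord]),
      scanWidth = as.numeric(scanWidth), eyeId = as.character(eyeId))
}

#' Read an RPE trace from a two-column CSV file
#'
#' Expects a comma-separated file with numeric columns x and y, an
#' optional single header row, UTF-8, decimal point. Rows are sorted by x;
#' duplicate x values are a validation error naming the offending value.
#'
#' @param path path to the CSV file.
#' @param scanWidth scan width in pixels; `NULL` derives it from the data.
#' @param eyeId identifier; defaults to the file name without extension.
#' @return an [RPETrace-class] object.
#' @export
loadTrace <- function(path, scanWidth = NULL,
                      eyeId = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*[-+0-9.]", first)
  df <- tryCatch(
    utils::read.csv(path, header = has_header,
                    colClasses = c("numeric", "numeric")),
    error = function(e) stop("failed to parse trace CSV '", path, "': ",
                             conditionMessage(e), call. = FALSE),
    warning = function(w) stop("failed to parse trace CSV '", path, "': ",
                               conditionMessage(w), call. = FALSE))
  if (ncol(df) != 2L) stop("trace CSV must have exactly two columns")
  if (anyNA(df)) stop("non-numeric rows in trace CSV '", path, "'")
  rpeTrace(df[[1]], df[[2]],
           scanWidth = if (is.null(scanWidth)) floor(max(df[[1]])) + 1
                       else scanWidth,
           eyeId = eyeId)
}

#' Write an RPE trace to CSV
#'
#' Uses full precision (up to 17 significant digits) so that
#' `loadTrace(saveTrace(tr))` round-trips bit-identically.
#'
#' @param trace an [RPETrace-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
saveTrace <- function(trace, path) {
  stopifnot(is(trace, "RPETrace"))
  df <- data.frame(x = trace@x, y = trace@y)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("x,y", con)
  writeLines(paste(format(df$x, digits = 17, trim = TRUE, scientific = FALSE),
                   format(df$y, digits = 17, trim = TRUE, scientific = FALSE),
                   sep = ","), con)
  invisible(path)
}

#' @rdname centerCoordinates
#' @export
setMethod("centerCoordinates", "RPETrace", function(trace) {
  u <- trace@x - (min(trace@x) + max(trace@x)) / 2
  v <- trace@y - mean(trace@y)
  new("CenteredTrace", u = u, v = v, scanWidth = trace@scanWidth,
      eyeId = trace@eyeId)
})

#' Coordinates of a trace as a data frame
#'
#' @param x an [RPETrace-class] or [CenteredTrace-class] object.
#' @param row.names,optional,... passed for interface compatibility; unused.
#' @return a two-column data frame (`x`,`y` or `u`,`v`).
#' @export
as.data.frame.RPETrace <- function(x, row.names = NULL, optional = FALSE,
                                   ...) {
  data.frame(x = x@x, y = x@y)
}

#' @rdname as.data.frame.RPETrace
#' @export
as.data.frame.CenteredTrace <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(u = x@u, v = x@v)
}
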