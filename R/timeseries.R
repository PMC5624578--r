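#' Uniformly sampled time series
#'
#' Light container for a uniformly indexed sample sequence with a nominal
#' sampling period.  For beat-to-beat R-R interval series the values are in
#' milliseconds and the sampling period is the mean heart period in seconds,
#' so that beat-domain spectra map onto a frequency axis in Hz.
#'
#' @param values numeric vector of samples (signal units); all finite,
#'   length at least 2.
#' @param dt sampling period in seconds (positive).
#' @param label free-text label carried through fits and reports.
#' @return an object of class `ar_ts`: a list with elements `values`, `dt`
#'   and `label`.
#' @seealso [read_rr_series()] to build one from a file.
#' @examples
#' x <- ar_ts(sin(1:100), dt = 1)
#' x
#' @export
ar_ts <- function(values, dt = 1, label = "") {
  values <- as.numeric(values)
  if (length(values) < 2L) .stopf("a time series needs at least 2 samples")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values))[1L]
    .stopf("non-finite value at sample %d", bad)
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    .stopf("'dt' must be a positive sampling period in seconds")
  structure(list(values = values, dt = as.numeric(dt),
                 label = as.character(label)[1L]),
            class = "ar_ts")
}

#' @export
print.ar_ts <- function(x, ...) {
  cat(sprintf("Time series%s: %d samples, dt = %g s (Nyquist %.3g Hz)\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$values), x$dt, 1 / (2 * x$dt)))
  cat(sprintf("  mean %.4g, sd %.4g\n", mean(x$values), sd(x$values)))
  invisible(x)
}

#' @export
length.ar_ts <- function(x) length(x$values)

#' @export
as.numeric.ar_ts <- function(x, ...) x$values

# accept an ar_ts or a bare numeric vector (with an explicit dt)
.as_ar_ts <- function(x, dt = 1, label = "") {
  if (inherits(x, "ar_ts")) x else ar_ts(x, dt = dt, label = label)
}

#' Read a beat-to-beat R-R interval series from a text file
#'
#' Accepts either a plain column of numbers (one R-R interval per line, with
#' an optional single header line) or a CSV file with a column named `rr`.
#' Values are converted to milliseconds; the sampling period attached to the
#' returned series is the mean R-R interval in seconds, which is the
#' conventional frequency-axis calibration for beat-domain HRV spectra.
#'
#' @param path file to read.
#' @param units units of the stored values: `"ms"` (default) or `"s"`.
#' @param label optional label; defaults to the file name.
#' @return an [ar_ts()] with values in ms.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(as.character(round(rnorm(120, 1000, 40))), f)
#' rr <- read_rr_series(f)
#' rr$dt   # close to 1 s
#' @export
read_rr_series <- function(path, units = c("ms", "s"), label = basename(path)) {
  units <- match.arg(units)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) .stopf("empty R-R file: %s", path)

  if (grepl(",", lines[1L], fixed = TRUE)) {
    tab <- read.csv(path, stringsAsFactors = FALSE)
    if (!"rr" %in% names(tab))
      .stopf("CSV file %s has no column named 'rr'", path)
    vals <- tab$rr
    if (!is.numeric(vals)) .stopf("column 'rr' of %s is not numeric", path)
    line_of <- function(i) i + 1L   # header line
  } else {
    vals <- suppressWarnings(as.numeric(lines))
    first_data <- 1L
    if (is.na(vals[1L]) && length(lines) > 1L) {
      first_data <- 2L               # tolerate one header line
      vals <- vals[-1L]
      lines <- lines[-1L]
    }
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1L]
      .stopf("non-numeric R-R value '%s' at line %d of %s",
             lines[bad], bad + first_data - 1L, path)
    }
    line_of <- function(i) i + first_data - 1L
  }

  if (anyNA(vals)) .stopf("missing R-R values in %s", path)
  if (any(vals <= 0)) {
    bad <- which(vals <= 0)[1L]
    .stopf("nonpositive R-R interval (%g) at line %d of %s",
           vals[bad], line_of(bad), path)
  }
  if (units == "s") vals <- vals * 1000
  ar_ts(vals, dt = mean(vals) / 1000, label = label)
}
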