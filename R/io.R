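# Shared CSV reading with structural validation: exact header, rectangular
# rows, informative line numbers.
.read_validated_csv <- function(file, header_cols) {
  lines <- readLines(file)
  if (length(lines) == 0) stop("no data: file is empty: ", file)
  hdr <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (!identical(trimws(hdr), header_cols))
    stop(sprintf("header mismatch in %s: expected '%s', found '%s'",
                 file, paste(header_cols, collapse = ","), lines[1]))
  if (length(lines) == 1) stop("no data rows in ", file)
  nf <- lengths(strsplit(lines[-1], ",", fixed = TRUE))
  bad <- which(nf != length(header_cols))
  if (length(bad))
    stop(sprintf("ragged row in %s at line %d (%d fields, expected %d)",
                 file, bad[1] + 1, nf[bad[1]], length(header_cols)))
  utils::read.csv(file, colClasses = "numeric")
}

#' Read / write intensity traces as CSV
#'
#' Format: header `time_s,counts`, one row per bin; `time_s` is the bin
#' start time.  A JSON sidecar (same path with extension `.json`) records
#' the simulation configuration when one is supplied.  Counts round-trip
#' losslessly as integers.
#'
#' @param trace an [intensity_trace()].
#' @param file CSV path.
#' @param sidecar optional list (e.g. config and species parameters) written
#'   alongside as JSON.
#' @return `write_trace_csv` returns `file` invisibly; `read_trace_csv`
#'   returns an [intensity_trace()].
#' @export
write_trace_csv <- function(trace, file, sidecar = NULL) {
  stopifnot(inherits(trace, "intensity_trace"))
  n <- length(trace$counts)
  df <- data.frame(
    time_s = format((seq_len(n) - 1) * trace$bin_width, digits = 17,
                    scientific = TRUE, trim = TRUE),
    counts = as.integer(trace$counts))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  if (!is.null(sidecar)) {
    jsonlite::write_json(sidecar, sub("\\.csv$", ".json", file),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}

#' @rdname write_trace_csv
#' @param label label for the trace read back (default: file name).
#' @export
read_trace_csv <- function(file, label = basename(file)) {
  df <- .read_validated_csv(file, c("time_s", "counts"))
  if (nrow(df) < 2) stop("trace needs at least 2 bins: ", file)
  bw <- stats::median(diff(df$time_s))
  if (bw <= 0) stop("time_s must be strictly increasing in ", file)
  intensity_trace(df$counts, bin_width = bw, label = label)
}

#' Read / write correlation curves as CSV
#'
#' Format: header `lag_s,g,sem` (sem column `NA` when absent); values are
#' written with 17 significant digits so that `g` round-trips to full double
#' precision.
#'
#' @param curve a [correlation_curve()].
#' @param file CSV path.
#' @return `write_curve_csv` returns `file` invisibly; `read_curve_csv`
#'   returns a [correlation_curve()].
#' @export
write_curve_csv <- function(curve, file) {
  stopifnot(inherits(curve, "correlation_curve"))
  fmt <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  df <- data.frame(lag_s = fmt(curve$lags), g = fmt(curve$g),
                   sem = if (is.null(curve$sem)) NA else fmt(curve$sem))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(file) {
  df <- .read_validated_csv(file, c("lag_s", "g", "sem"))
  sem <- if (all(is.na(df$sem))) NULL else df$sem
  correlation_curve(df$lag_s, df$g, sem = sem)
}

#' Bundled pooled BEEC 22q11.2 study counts
#'
#' Carrier counts pooled over the four published bladder
#' exstrophy-epispadias complex (BEEC) cohorts: 11 microduplication carriers
#' among 422 cases and 1 among 1,219 controls, reconstructed from the
#' printed pooled frequencies (2.61% and 0.08%).  The per-study carrier
#' narration in the source reports does not reconcile exactly with the
#' pooled frequency; the pooled reading is used as authoritative.
#'
#' @return data.frame in the [pool_counts()] layout.
#' @export
read_study_table <- function() {
  f <- system.file("extdata", "beec_22q11_studies.csv", package = "fcscnv",
                   mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Bundled 22q11.2 duplication calls
#'
#' The three array-CGH duplication calls (hg19) with their inheritance, as
#' a [duplication_calls()] data.frame.
#'
#' @return A [duplication_calls()] data.frame.
#' @export
read_duplication_table <- function() {
  f <- system.file("extdata", "duplications_22q11.tsv", package = "fcscnv",
                   mustWork = TRUE)
  df <- utils::read.delim(f, stringsAsFactors = FALSE)
  duplication_calls(df$patient, df$region, df$inheritance)
}
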