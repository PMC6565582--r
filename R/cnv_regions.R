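#' 1-based inclusive genomic interval
#'
#' Coordinate container for duplication calls as printed in array-CGH
#' reports: 1-based, inclusive at both ends, on a named assembly.
#'
#' @param chrom chromosome name, e.g. `"chr22"`.
#' @param start,end 1-based inclusive positions, `1 <= start <= end`.
#' @param assembly assembly tag (default `"hg19"`).
#' @return Object of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, assembly = "hg19") {
  if (!grepl("^chr[0-9XYM]+$", chrom))
    stop("malformed chromosome name: ", chrom)
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end)) stop("non-numeric coordinates")
  if (start < 1) stop("start must be >= 1 (1-based coordinates)")
  if (end < start) stop(sprintf("end (%s) before start (%s)",
                                format(end, big.mark = ","),
                                format(start, big.mark = ",")))
  structure(list(chrom = chrom, start = start, end = end,
                 assembly = assembly),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(format_region(x), sprintf("[%s, %.2f Mb]\n", x$assembly, length_mb(x)))
  invisible(x)
}

#' Parse a region string into a genomic interval
#'
#' Accepts `chrom:start-end` with optional thousands-separator commas and
#' either a hyphen or an en/em dash between the coordinates.  A doubled
#' chromosome token (`"chr22: chr22:..."`, an occasional report typo) is
#' tolerated with a warning.
#'
#' @param text region string, e.g. `"chr22:18,938,160–21,505,425"`.
#' @param assembly assembly tag (default `"hg19"`).
#' @return A [genomic_interval()].
#' @export
parse_region <- function(text, assembly = "hg19") {
  s <- trimws(text)
  dup <- "^(chr[0-9XYM]+)\\s*:\\s*(chr[0-9XYM]+)\\s*:"
  if (grepl(dup, s)) {
    m <- regmatches(s, regexec(dup, s))[[1]]
    if (m[2] != m[3])
      stop("conflicting chromosome tokens in region string: ", text)
    warning("repeated chromosome token normalized in: ", text)
    s <- sub("^chr[0-9XYM]+\\s*:\\s*", "", s)
  }
  pat <- "^(chr[0-9XYM]+)\\s*:\\s*([0-9,]+)\\s*[-–—]\\s*([0-9,]+)$"
  m <- regmatches(s, regexec(pat, s))[[1]]
  if (length(m) == 0) stop("cannot parse region string: ", text)
  genomic_interval(m[2],
                   as.numeric(gsub(",", "", m[3])),
                   as.numeric(gsub(",", "", m[4])),
                   assembly = assembly)
}

#' Format a genomic interval back into a region string
#'
#' @param interval a [genomic_interval()].
#' @param big_mark thousands separator (default `","`).
#' @return character region string; round-trips through [parse_region()].
#' @export
format_region <- function(interval, big_mark = ",") {
  stopifnot(inherits(interval, "genomic_interval"))
  sprintf("%s:%s-%s", interval$chrom,
          format(interval$start, big.mark = big_mark, scientific = FALSE),
          format(interval$end, big.mark = big_mark, scientific = FALSE))
}

#' Interval length
#'
#' 1-based inclusive length: `end - start + 1` base pairs; `length_mb`
#' divides by 1e6 and rounds half-up to `decimals` decimals (the convention
#' of printed duplication sizes).
#'
#' @param interval a [genomic_interval()].
#' @param decimals decimals for the Mb value (default 2).
#' @return base pairs (`length_bp`) or megabases (`length_mb`).
#' @export
length_bp <- function(interval) {
  stopifnot(inherits(interval, "genomic_interval"))
  interval$end - interval$start + 1
}

#' @rdname length_bp
#' @export
length_mb <- function(interval, decimals = 2) {
  x <- length_bp(interval) / 1e6 * 10^decimals
  # round half away from zero, not banker's rounding
  floor(x + 0.5) / 10^decimals
}

#' Intersect genomic intervals
#'
#' Common region of a list of intervals on one chromosome:
#' `(max start, min end)` when they all overlap, else `NULL`.  Associative
#' and order-independent.
#'
#' @param intervals list of [genomic_interval()]s on the same chromosome and
#'   assembly.
#' @return A [genomic_interval()], or `NULL` when the intersection is empty.
#' @export
intersect_intervals <- function(intervals) {
  if (inherits(intervals, "genomic_interval")) intervals <- list(intervals)
  if (length(intervals) == 0) stop("no intervals to intersect")
  stopifnot(all(vapply(intervals, inherits, logical(1), "genomic_interval")))
  chroms <- vapply(intervals, `[[`, character(1), "chrom")
  if (length(unique(chroms)) > 1)
    stop("cannot intersect intervals on different chromosomes: ",
         paste(unique(chroms), collapse = ", "))
  assemblies <- vapply(intervals, `[[`, character(1), "assembly")
  if (length(unique(assemblies)) > 1)
    stop("cannot intersect intervals on different assemblies")
  s <- max(vapply(intervals, `[[`, numeric(1), "start"))
  e <- min(vapply(intervals, `[[`, numeric(1), "end"))
  if (s > e) return(NULL)
  genomic_interval(chroms[1], s, e, assembly = assemblies[1])
}

#' Duplication call table
#'
#' @param patient character labels.
#' @param region region strings (parsed via [parse_region()]) or a list of
#'   [genomic_interval()]s.
#' @param inheritance one of `"maternal"`, `"paternal"`, `"de novo"`,
#'   `"unknown"` per call.
#' @param assembly assembly tag for parsed strings.
#' @return data.frame of class `duplication_calls` with columns `patient`,
#'   `chrom`, `start`, `end`, `assembly`, `inheritance`.
#' @export
duplication_calls <- function(patient, region, inheritance, assembly = "hg19") {
  allowed <- c("maternal", "paternal", "de novo", "unknown")
  if (!all(inheritance %in% allowed))
    stop("inheritance must be one of: ", paste(allowed, collapse = ", "))
  ivs <- if (is.character(region)) lapply(region, parse_region, assembly = assembly)
         else region
  stopifnot(all(vapply(ivs, inherits, logical(1), "genomic_interval")),
            length(patient) == length(ivs),
            length(inheritance) == length(ivs))
  out <- data.frame(patient = as.character(patient),
                    chrom = vapply(ivs, `[[`, character(1), "chrom"),
                    start = vapply(ivs, `[[`, numeric(1), "start"),
                    end = vapply(ivs, `[[`, numeric(1), "end"),
                    assembly = vapply(ivs, `[[`, character(1), "assembly"),
                    inheritance = as.character(inheritance))
  class(out) <- c("duplication_calls", "data.frame")
  out
}

#' Convert duplication calls to / from BED
#'
#' BED convention: 0-based half-open (`start_bed = start - 1`,
#' `end_bed = end`), tab-separated, with the patient label as the name
#' column.  `from_bed` validates every line and reports malformed lines with
#' their line numbers; `#`-prefixed comment lines are skipped.
#'
#' @param calls a [duplication_calls()] data.frame.
#' @param file path of the BED file.
#' @param assembly assembly tag to stamp on calls read back.
#' @return `to_bed` returns `file` invisibly; `from_bed` returns a
#'   [duplication_calls()] data.frame (inheritance `"unknown"`, which BED
#'   does not carry).
#' @export
to_bed <- function(calls, file) {
  stopifnot(inherits(calls, "duplication_calls"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# BED (0-based, half-open), assembly %s",
                     paste(unique(calls$assembly), collapse = "/")), con)
  if (nrow(calls) > 0) {
    writeLines(sprintf("%s\t%d\t%d\t%s", calls$chrom,
                       as.integer(calls$start - 1), as.integer(calls$end),
                       gsub("\\s+", "_", calls$patient)), con)
  }
  invisible(file)
}

#' @rdname to_bed
#' @export
from_bed <- function(file, assembly = "hg19") {
  lines <- readLines(file)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    return(duplication_calls(character(0), list(), character(0),
                             assembly = assembly))
  }
  recs <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    ln <- idx[j]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("BED line %d: expected at least 3 tab-separated fields", ln))
    s0 <- suppressWarnings(as.numeric(f[2]))
    e0 <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s0) || is.na(e0))
      stop(sprintf("BED line %d: non-numeric coordinates", ln))
    if (e0 <= s0)
      stop(sprintf("BED line %d: end must exceed start (half-open)", ln))
    recs[[j]] <- list(chrom = f[1], start = s0 + 1, end = e0,
                      name = if (length(f) >= 4) f[4] else sprintf("region_%d", j))
  }
  duplication_calls(
    patient = vapply(recs, `[[`, character(1), "name"),
    region = lapply(recs, function(r)
      genomic_interval(r$chrom, r$start, r$end, assembly = assembly)),
    inheritance = rep("unknown", length(recs)),
    assembly = assembly)
}
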