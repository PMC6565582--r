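#' Binned photon-count time series
#'
#' Container for one measurement segment: fluorescence intensity I(t) as
#' photon counts per bin.
#'
#' @param counts non-negative integer counts, length >= 2.
#' @param bin_width bin width in seconds (> 0).
#' @param label free-text label.
#' @return Object of class `intensity_trace` with fields `counts`,
#'   `bin_width`, `label`.
#' @export
intensity_trace <- function(counts, bin_width, label = "") {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (length(counts) < 2) stop("trace needs at least 2 bins")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(counts = as.numeric(counts), bin_width = bin_width,
                 label = as.character(label)),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("intensity trace '%s': %d bins x %.3g s (%.4g s total), mean %.4g counts/bin\n",
              x$label, length(x$counts), x$bin_width,
              length(x$counts) * x$bin_width, mean(x$counts)))
  invisible(x)
}

#' Temporal autocorrelation curve G(tau)
#'
#' @param lags lag times in seconds, strictly ascending, positive.
#' @param g values of the normalized autocorrelation G(tau) (baseline 1).
#' @param sem optional per-lag standard error.
#' @param n_segments number of measurement segments behind the curve.
#' @return Object of class `correlation_curve`.
#' @export
correlation_curve <- function(lags, g, sem = NULL, n_segments = 1L) {
  if (length(lags) != length(g)) stop("lags and g lengths differ")
  if (any(lags <= 0)) stop("all lags must be positive")
  if (length(lags) > 1 && any(diff(lags) <= 0))
    stop("lags must be strictly ascending")
  if (!is.null(sem)) {
    if (length(sem) == 1) sem <- rep(sem, length(lags))
    if (length(sem) != length(lags)) stop("sem length mismatch")
    if (any(sem < 0)) stop("sem must be non-negative")
  }
  structure(list(lags = as.numeric(lags), g = as.numeric(g),
                 sem = if (is.null(sem)) NULL else as.numeric(sem),
                 n_segments = as.integer(n_segments)),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("correlation curve: %d lags in [%.3g, %.3g] s, G range [%.4g, %.4g], %d segment(s)\n",
              length(x$lags), min(x$lags), max(x$lags), min(x$g), max(x$g),
              x$n_segments))
  invisible(x)
}

#' @export
as.data.frame.correlation_curve <- function(x, ...) {
  data.frame(lag_s = x$lags, g = x$g,
             sem = if (is.null(x$sem)) NA_real_ else x$sem)
}

# shared guard for both estimators
.check_correlatable <- function(trace) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (mean(trace$counts) <= 0)
    stop("trace mean is zero: G(tau) is undefined (division by zero)")
}

#' Direct (brute-force) normalized autocorrelation
#'
#' Computes `G(tau) = 1 + <dI(t) dI(t+tau)> / <I>^2` on a linear lag grid,
#' one lag per bin.  With `normalization = "symmetric"` (default) the means
#' are recomputed over the two overlapping windows at each lag, equivalent to
#' `G = <I1*I2> / (<I1><I2>)`, which suppresses drift bias.  The
#' `"plain"` variant uses the single global mean of the whole trace and is
#' the literal textbook estimator; it is retained as the reference oracle.
#'
#' @param trace an [intensity_trace()].
#' @param max_lag_bins largest lag, in bins (`< length/2`).
#' @param normalization `"symmetric"` or `"plain"`.
#' @return A [correlation_curve()].
#' @export
#' @examples
#' tr <- intensity_trace(c(1, 3, 1, 3), bin_width = 1)
#' autocorrelate_direct(tr, 1, normalization = "plain")$g       # 0.75
#' autocorrelate_direct(tr, 1, normalization = "symmetric")$g   # 27/35
autocorrelate_direct <- function(trace, max_lag_bins,
                                 normalization = c("symmetric", "plain")) {
  normalization <- match.arg(normalization)
  .check_correlatable(trace)
  I <- trace$counts
  n <- length(I)
  if (max_lag_bins < 1 || max_lag_bins >= n / 2)
    stop("max_lag_bins must be in [1, length/2)")
  g <- numeric(max_lag_bins)
  mu <- mean(I)
  for (k in seq_len(max_lag_bins)) {
    I1 <- I[seq_len(n - k)]
    I2 <- I[(k + 1):n]
    g[k] <- if (normalization == "symmetric") {
      mean(I1 * I2) / (mean(I1) * mean(I2))
    } else {
      1 + mean((I1 - mu) * (I2 - mu)) / mu^2
    }
  }
  correlation_curve(lags = seq_len(max_lag_bins) * trace$bin_width, g = g)
}

#' Multi-tau normalized autocorrelation
#'
#' Hardware-correlator style estimator on a quasi-logarithmic lag grid:
#' `channels_per_level` linear lags at the original bin width (level 0), then
#' for every further level the counts are re-binned by pairwise summation
#' (bin width doubling) and the upper half of the channels
#' (`channels_per_level/2 + 1` ... `channels_per_level`) is evaluated, so
#' consecutive levels extend the grid without overlap.  Each lag uses the
#' symmetric normalization `G = <I1*I2>/(<I1><I2>)` on the re-binned counts.
#' Lags are reported at the window start time, `k * level_bin_width`.
#'
#' @param trace an [intensity_trace()].
#' @param channels_per_level linear channels in level 0 (even, default 16).
#' @param n_levels number of levels; default: as many as the trace supports
#'   (each level needs at least `2 * channels_per_level` re-binned bins).
#' @return A [correlation_curve()].
#' @export
autocorrelate_multitau <- function(trace, channels_per_level = 16,
                                   n_levels = NULL) {
  .check_correlatable(trace)
  if (channels_per_level < 2 || channels_per_level %% 2 != 0)
    stop("channels_per_level must be an even number >= 2")
  I <- trace$counts
  max_levels <- floor(log2(length(I) / (2 * channels_per_level))) + 1
  if (max_levels < 1) stop("trace too short for the requested channel layout")
  if (is.null(n_levels)) n_levels <- max_levels
  if (n_levels > max_levels)
    stop(sprintf("trace supports at most %d levels", max_levels))
  width <- trace$bin_width
  lags <- numeric(0)
  g <- numeric(0)
  for (lev in seq_len(n_levels) - 1L) {
    if (lev > 0) {                       # pairwise re-binning
      m <- length(I) %/% 2L
      I <- I[seq(1, 2 * m, by = 2)] + I[seq(2, 2 * m, by = 2)]
      width <- width * 2
    }
    ks <- if (lev == 0) seq_len(channels_per_level)
          else (channels_per_level / 2 + 1):channels_per_level
    n <- length(I)
    for (k in ks) {
      I1 <- I[seq_len(n - k)]
      I2 <- I[(k + 1):n]
      lags <- c(lags, k * width)
      g <- c(g, sum(I1 * I2) * (n - k) / (sum(I1) * sum(I2)))
    }
  }
  correlation_curve(lags = lags, g = g)
}

#' Average a segmented measurement series
#'
#' Per-lag mean and standard error of the mean over consecutive measurement
#' segments sharing one lag grid (the instrument's "array of consecutive
#' measurements").  The SEM reflects segment-to-segment scatter, not photon
#' statistics.
#'
#' @param curves list of [correlation_curve()]s on identical lag grids.
#' @return A [correlation_curve()] with `sem` populated and `n_segments` set.
#' @export
average_series <- function(curves) {
  if (length(curves) == 0) stop("no curves to average")
  stopifnot(all(vapply(curves, inherits, logical(1), "correlation_curve")))
  lags <- curves[[1]]$lags
  for (cv in curves[-1]) {
    if (length(cv$lags) != length(lags) ||
        any(abs(cv$lags - lags) > 1e-12 * pmax(lags, 1e-300)))
      stop("curves do not share a common lag grid")
  }
  G <- vapply(curves, function(cv) cv$g, numeric(length(lags)))
  G <- matrix(G, nrow = length(lags))
  m <- rowMeans(G)
  sem <- if (ncol(G) > 1) apply(G, 1, stats::sd) / sqrt(ncol(G))
         else rep(0, length(lags))
  correlation_curve(lags = lags, g = m, sem = sem, n_segments = ncol(G))
}

#' Normalize a curve to unit amplitude at a reference lag
#'
#' Rescales the fluctuation part so that `G_n(tau_ref) = 1`:
#' `G_n(tau) = (G(tau) - 1) / (G(tau_ref) - 1)`, interpolating `G(tau_ref)`
#' linearly when the reference lag falls between grid points.  Used to
#' compare decay shapes across concentrations regardless of amplitude.
#'
#' @param curve a [correlation_curve()].
#' @param tau_ref reference lag in seconds (default 10 us).
#' @return A [correlation_curve()] whose `g` holds the normalized shape
#'   `G_n` (note: baseline 0, amplitude 1 at `tau_ref`).
#' @export
normalize_amplitude <- function(curve, tau_ref = 1e-5) {
  stopifnot(inherits(curve, "correlation_curve"))
  if (tau_ref < min(curve$lags) || tau_ref > max(curve$lags))
    stop("tau_ref outside the lag range of the curve")
  g_ref <- stats::approx(curve$lags, curve$g, xout = tau_ref)$y
  if (g_ref <= 1)
    stop("G(tau_ref) <= 1: no amplitude to normalize by")
  amp <- g_ref - 1
  correlation_curve(lags = curve$lags, g = (curve$g - 1) / amp,
                    sem = if (is.null(curve$sem)) NULL else curve$sem / amp,
                    n_segments = curve$n_segments)
}
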