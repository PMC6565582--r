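# Model evaluation on raw parameter vectors (taus may be unordered during
# optimization; ys may be provisional).  Kept separate from evaluate_model()
# so the optimizer never trips over constructor invariants.
.eval_G <- function(tau, N, taus, ys, trip_T, tau_T, r) {
  s <- rep(0, length(tau))
  for (i in seq_along(taus)) {
    x <- tau / taus[i]
    s <- s + ys[i] / ((1 + x) * sqrt(1 + r * x))
  }
  t_term <- if (trip_T > 0) 1 + trip_T / (1 - trip_T) * exp(-tau / tau_T) else 1
  1 + s * t_term / N
}

# Starting-point candidates for the diffusion times, spread around the lag
# where the fluctuation amplitude has decayed to half.
.start_taus <- function(lags, g, k) {
  amp <- g[1] - 1
  half_idx <- which(g - 1 <= amp / 2)
  tau_half <- if (length(half_idx)) lags[half_idx[1]] else stats::median(lags)
  tau_half <- min(max(tau_half, min(lags)), max(lags))
  if (k == 1) {
    lapply(c(1/3, 1, 3), function(f) tau_half * f)
  } else if (k == 2) {
    list(tau_half * c(1/3, 3), tau_half * c(1/10, 10),
         tau_half * c(1/30, 30), tau_half * c(1, 100))
  } else {
    list(tau_half * c(1/10, 1, 10), tau_half * c(1/30, 1, 30),
         tau_half * c(1/100, 1, 100))
  }
}

#' Fit the multi-component diffusion + triplet model to a correlation curve
#'
#' Weighted least squares (Levenberg-Marquardt with box bounds, multi-start
#' initialization) of the free 3D diffusion model with triplet contribution.
#' Free parameters: `N`, the `n_components` diffusion times `tau_D_i`, the
#' relative amplitudes `y_2 ... y_k` (`y_1 = 1 - sum` by construction), and,
#' unless fixed, the triplet fraction `T` and relaxation time `tau_T`.
#' Bounds: `N > 0`, `tau_D > 0`, `0 <= T < 0.5`, `1 us <= tau_T <= 20 us`
#' (kept below the fastest diffusion time so triplet and diffusion decays
#' cannot trade places).  The observation-volume geometry
#' \eqn{(w_{xy}/w_z)^2} is fixed from the calibration, never floated.
#'
#' Weights default to `1/sem^2` when the curve carries per-lag standard
#' errors (all positive), else uniform.
#'
#' @param curve a [correlation_curve()] with at least 5 points per free
#'   parameter.
#' @param n_components number of diffusive components to fit (1-3).
#' @param calibration an [calibrate()] result (supplies `geometry_ratio`).
#' @param fix_triplet `NULL` to float `T` and `tau_T`; a named vector such as
#'   `c(T = 0.15, tau_T = 3e-6)` to fix them; `c(T = 0)` drops the triplet
#'   term entirely.
#' @param weights optional per-lag weights overriding the default.
#' @return Object of class `fcs_fit`: fields `model` (an [fcs_model()]),
#'   `stderr` (named, per free parameter), `reduced_chi2`, `n_components`,
#'   `converged`, `ssr`, `nobs`, `n_free`.
#' @export
fit_curve <- function(curve, n_components = 1, calibration = calibrate(),
                      fix_triplet = NULL, weights = NULL) {
  stopifnot(inherits(curve, "correlation_curve"),
            inherits(calibration, "fcs_calibration"))
  k <- as.integer(n_components)
  if (k < 1 || k > 3) stop("n_components must be 1, 2 or 3")
  lags <- curve$lags
  g <- curve$g
  r <- calibration$geometry_ratio

  amp <- max(g) - 1
  if (amp < 1e-6)
    stop("degenerate (flat) curve: no fluctuation amplitude to fit")

  triplet_free <- is.null(fix_triplet)
  fix_T <- if (triplet_free) NA_real_ else unname(fix_triplet["T"])
  if (!triplet_free && is.na(fix_T))
    stop("fix_triplet must carry a T element (use c(T = 0) to disable)")
  fix_tau_T <- if (triplet_free) NA_real_ else {
    v <- unname(fix_triplet["tau_T"])
    if (is.na(v)) 3e-6 else v
  }
  n_free <- 1L + k + (k - 1L) + if (triplet_free) 2L else 0L
  if (length(lags) < 5 * n_free)
    stop("curve must have at least 5 points per free parameter")

  w <- if (!is.null(weights)) {
    if (length(weights) != length(lags)) stop("weights length mismatch")
    weights
  } else if (!is.null(curve$sem) && all(curve$sem > 0)) {
    1 / curve$sem^2
  } else rep(1, length(lags))
  sqrtw <- sqrt(w)

  # parameter vector: log10(N), log10(tau_1..k), y_2..k, [T, log10(tau_T)]
  p_names <- c("lN", paste0("ltau", seq_len(k)),
               if (k >= 2) paste0("y", 2:k),
               if (triplet_free) c("T", "ltauT"))
  lower <- c(-5, rep(log10(min(lags)) - 1, k), rep(0, k - 1),
             if (triplet_free) c(0, log10(1e-6)))
  upper <- c(6, rep(log10(max(lags)) + 1, k), rep(1, k - 1),
             if (triplet_free) c(0.499, log10(2e-5)))

  unpack <- function(p) {
    N <- 10^p[1]
    taus <- 10^p[2:(k + 1)]
    ys <- if (k == 1) 1 else {
      yfree <- p[(k + 2):(2 * k)]
      c(1 - sum(yfree), yfree)
    }
    if (triplet_free) {
      trip_T <- p[2 * k + 1]
      tau_T <- 10^p[2 * k + 2]
    } else {
      trip_T <- fix_T
      tau_T <- fix_tau_T
    }
    list(N = N, taus = taus, ys = ys, trip_T = trip_T, tau_T = tau_T)
  }
  resid_fn <- function(p) {
    u <- unpack(p)
    pen <- max(0, -min(u$ys))            # y_1 driven negative (k = 3 only)
    ys <- pmax(u$ys, 0)
    res <- (.eval_G(lags, u$N, u$taus, ys, u$trip_T, u$tau_T, r) - g) * sqrtw
    c(res, 100 * pen)
  }

  N0 <- max(1 / amp, 1e-4)
  best <- NULL
  for (taus0 in .start_taus(lags, g, k)) {
    p0 <- c(log10(N0), log10(pmin(pmax(taus0, 10^lower[2]), 10^upper[2])),
            if (k >= 2) rep(1 / k, k - 1),
            if (triplet_free) c(0.1, log10(3e-6)))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = stats::setNames(p0, p_names), lower = lower,
                         upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr_raw) {
      best <- list(fit = fit, ssr_raw = ssr)
    }
  }
  if (is.null(best)) stop("model fit failed from every starting point")
  fit <- best$fit
  converged <- fit$info %in% 1:3
  if (!converged)
    warning(sprintf("fit did not converge cleanly (nls.lm info = %d)", fit$info))

  p <- fit$par
  u <- unpack(p)

  # per-parameter standard errors from the covariance at the solution,
  # delta method for the log10-scaled parameters; when a parameter sits at
  # a bound the information matrix can be singular, so fall back to an SVD
  # pseudo-inverse rather than dropping all uncertainties
  se_p <- tryCatch({
    sm <- summary(fit)
    sm$coefficients[, "Std. Error"]
  }, error = function(e) {
    s2 <- fit$deviance / (length(fit$fvec) - length(p))
    sv <- svd(fit$hessian)
    pos <- sv$d > max(sv$d) * 1e-12
    cv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    sqrt(pmax(diag(cv), 0) * s2)
  })
  names(se_p) <- p_names
  ln10 <- log(10)
  stderr <- c(N = unname(u$N * ln10 * se_p["lN"]))
  ord <- order(u$taus)
  taus <- u$taus[ord]
  ys <- pmax(u$ys, 0)[ord]
  ys <- ys / sum(ys)
  se_tau <- (u$taus * ln10 * se_p[paste0("ltau", seq_len(k))])[ord]
  names(se_tau) <- paste0("tau_D", seq_len(k))
  stderr <- c(stderr, se_tau)
  if (k >= 2) {
    se_y <- se_p[paste0("y", 2:k)]
    names(se_y) <- paste0("y", 2:k)
    stderr <- c(stderr, se_y)
  }
  if (triplet_free) {
    stderr <- c(stderr, T = unname(se_p["T"]),
                tau_T = unname(u$tau_T * ln10 * se_p["ltauT"]))
  }
  # guard exact ties after sorting (degenerate over-parameterized fits)
  while (any(diff(taus) <= 0)) {
    i <- which(diff(taus) <= 0)[1]
    taus[i + 1] <- taus[i] * (1 + 1e-9)
  }

  n_res <- length(lags)
  ssr <- sum((fit$fvec[seq_len(n_res)])^2)
  model <- fcs_model(N = u$N, tau_D = taus, y = ys,
                     triplet = if (is.na(u$trip_T)) 0 else u$trip_T,
                     tau_T = u$tau_T, geometry_ratio = r)
  structure(list(model = model, stderr = stderr,
                 reduced_chi2 = ssr / (n_res - n_free),
                 n_components = k, converged = converged, ssr = ssr,
                 nobs = n_res, n_free = n_free),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("FCS fit: %d component(s), %s, reduced chi^2 = %.4g\n",
              x$n_components,
              if (x$converged) "converged" else "NOT converged",
              x$reduced_chi2))
  print(x$model)
  cat("stderr:\n")
  print(signif(x$stderr, 3))
  invisible(x)
}

#' Smoothed inverse-variance weights for curve fitting
#'
#' Per-lag standard errors estimated from a handful of segments are
#' themselves noisy; weighting by their raw inverse squares lets lags whose
#' scatter was small by chance dominate the fit.  This helper regularizes
#' them by a loess fit of `log(sem)` against `log(lag)` and returns
#' `1/smoothed_sem^2`.
#'
#' @param curve a [correlation_curve()] with a positive `sem` field.
#' @param span loess span (default 0.75).
#' @return numeric weight vector, one per lag.
#' @export
smoothed_weights <- function(curve, span = 0.75) {
  stopifnot(inherits(curve, "correlation_curve"))
  if (is.null(curve$sem)) stop("curve carries no per-lag standard errors")
  ok <- is.finite(curve$sem) & curve$sem > 0
  if (sum(ok) < 5)
    stop("curve must carry positive per-lag standard errors")
  df <- data.frame(ls = log(curve$sem[ok]), ll = log(curve$lags[ok]))
  fit <- stats::loess(ls ~ ll, data = df, span = span, degree = 2)
  pred <- stats::predict(fit, newdata = data.frame(ll = log(curve$lags)))
  # loess does not extrapolate: pad the window ends with the nearest value
  if (anyNA(pred)) {
    idx <- which(!is.na(pred))
    pred[seq_len(idx[1] - 1)] <- pred[idx[1]]
    last <- idx[length(idx)]
    if (last < length(pred)) pred[(last + 1):length(pred)] <- pred[last]
  }
  1 / exp(pred)^2
}

#' Restrict a correlation curve to a lag window
#'
#' @param curve a [correlation_curve()].
#' @param min_lag,max_lag window bounds in seconds.
#' @return the windowed [correlation_curve()].
#' @export
window_curve <- function(curve, min_lag = -Inf, max_lag = Inf) {
  stopifnot(inherits(curve, "correlation_curve"))
  keep <- curve$lags >= min_lag & curve$lags <= max_lag
  if (sum(keep) < 2) stop("lag window leaves fewer than 2 points")
  correlation_curve(curve$lags[keep], curve$g[keep],
                    sem = if (is.null(curve$sem)) NULL else curve$sem[keep],
                    n_segments = curve$n_segments)
}

#' Select the minimal number of diffusive components
#'
#' Fits models with 1, 2, ... `max_components` components in order and keeps
#' the simplest one: a model with `i + 1` components replaces the
#' `i`-component model only when the weighted-SSR F-test improvement is
#' significant at `alpha`.  This operationalizes the convention of always
#' using the model with the lowest number of components that describes the
#' curve.
#'
#' @inheritParams fit_curve
#' @param max_components largest component count to consider (default 3).
#' @param alpha significance level of the nested-model F-test (default 0.05).
#' @return The selected `fcs_fit`, with attribute `"selection"`: a data.frame
#'   of component counts, SSRs and F-test p-values.
#' @export
select_model <- function(curve, calibration = calibrate(), max_components = 3,
                         alpha = 0.05, fix_triplet = NULL, weights = NULL) {
  cur_fit <- fit_curve(curve, 1, calibration, fix_triplet, weights)
  sel <- data.frame(n_components = 1L, ssr = cur_fit$ssr, p_vs_previous = NA)
  if (max_components > 1) {
    for (i in seq_len(max_components - 1)) {
      nxt <- tryCatch(
        fit_curve(curve, i + 1, calibration, fix_triplet, weights),
        error = function(e) NULL)
      if (is.null(nxt)) break
      df1 <- nxt$n_free - cur_fit$n_free
      df2 <- nxt$nobs - nxt$n_free
      Fstat <- ((cur_fit$ssr - nxt$ssr) / df1) / (nxt$ssr / df2)
      pval <- if (!is.finite(Fstat) || Fstat <= 0) 1
              else stats::pf(Fstat, df1, df2, lower.tail = FALSE)
      sel <- rbind(sel, data.frame(n_components = i + 1L, ssr = nxt$ssr,
                                   p_vs_previous = pval))
      if (pval < alpha) cur_fit <- nxt else break
    }
  }
  attr(cur_fit, "selection") <- sel
  cur_fit
}
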