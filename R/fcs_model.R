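#' Multi-component free 3D diffusion + triplet correlation model
#'
#' Constructs the parameter set of the standard FCS model function
#' \deqn{G(\tau) = 1 + \frac{1}{N}\sum_i y_i
#'   \left(1+\frac{\tau}{\tau_{Di}}\right)^{-1}
#'   \left(1+\left(\frac{w_{xy}}{w_z}\right)^2\frac{\tau}{\tau_{Di}}\right)^{-1/2}
#'   \left(1 + \frac{T}{1-T}e^{-\tau/\tau_T}\right)}
#' where `N` is the mean number of molecules in the effective observation
#' volume, each diffusive component `i` has diffusion time `tau_D[i]` and
#' relative amplitude `y[i]` (summing to 1), `T` is the equilibrium triplet
#' fraction with relaxation time `tau_T`, and `geometry_ratio` is
#' \eqn{(w_{xy}/w_z)^2}, the reciprocal of the structure parameter
#' \eqn{S^2 = (w_z/w_{xy})^2}.
#'
#' @param N mean number of molecules in the observation volume (> 0).
#' @param tau_D diffusion time(s) in seconds, strictly increasing.
#' @param y relative amplitudes, same length as `tau_D`, summing to 1.
#'   Defaults to equal weights.
#' @param triplet equilibrium triplet fraction `T` in `[0, 1)`.
#' @param tau_T triplet relaxation time in seconds (> 0; irrelevant when
#'   `triplet = 0`).
#' @param geometry_ratio \eqn{(w_{xy}/w_z)^2} in `(0, 1)`; `1/S2`.
#' @return An object of class `fcs_model`.
#' @seealso [evaluate_model()], [fit_curve()], [calibrate()]
#' @export
#' @examples
#' m <- fcs_model(N = 4, tau_D = 220e-6, geometry_ratio = 1/7)
#' evaluate_model(m, 0)   # 1 + 1/N = 1.25
fcs_model <- function(N, tau_D, y = NULL, triplet = 0, tau_T = 3e-6,
                      geometry_ratio = 1/7) {
  if (is.null(y)) y <- rep(1 / length(tau_D), length(tau_D))
  m <- structure(
    list(N = as.numeric(N), tau_D = as.numeric(tau_D), y = as.numeric(y),
         triplet = as.numeric(triplet), tau_T = as.numeric(tau_T),
         geometry_ratio = as.numeric(geometry_ratio)),
    class = "fcs_model")
  validate_fcs_model(m)
  m
}

#' @rdname fcs_model
#' @param model an `fcs_model` object.
#' @export
validate_fcs_model <- function(model) {
  stopifnot(inherits(model, "fcs_model"))
  with(model, {
    if (!is.finite(N) || N <= 0) stop("N must be a positive number")
    if (length(tau_D) < 1 || any(tau_D <= 0)) stop("tau_D must be positive")
    if (length(tau_D) > 1 && any(diff(tau_D) <= 0))
      stop("tau_D must be strictly increasing")
    if (length(y) != length(tau_D)) stop("y and tau_D lengths differ")
    if (abs(sum(y) - 1) > 1e-9) stop("component amplitudes y must sum to 1")
    if (triplet < 0 || triplet >= 1) stop("triplet fraction must be in [0, 1)")
    if (triplet > 0 && tau_T <= 0) stop("tau_T must be positive when triplet > 0")
    if (geometry_ratio <= 0 || geometry_ratio >= 1)
      stop("geometry_ratio (w_xy/w_z)^2 must lie in (0, 1)")
  })
  invisible(model)
}

#' Evaluate the FCS model function at given lag times
#'
#' @param model an [fcs_model()].
#' @param tau lag times in seconds (>= 0), vectorized.
#' @return Numeric vector of G values (baseline 1).
#' @export
evaluate_model <- function(model, tau) {
  validate_fcs_model(model)
  if (any(tau < 0)) stop("lag times must be non-negative")
  r <- model$geometry_ratio
  diff_sum <- rep(0, length(tau))
  for (i in seq_along(model$tau_D)) {
    x <- tau / model$tau_D[i]
    diff_sum <- diff_sum + model$y[i] / ((1 + x) * sqrt(1 + r * x))
  }
  trip <- if (model$triplet > 0) {
    1 + model$triplet / (1 - model$triplet) * exp(-tau / model$tau_T)
  } else 1
  1 + diff_sum * trip / model$N
}

#' @export
print.fcs_model <- function(x, ...) {
  cat("FCS model: N =", signif(x$N, 4), "\n")
  comp <- data.frame(tau_D_s = x$tau_D, y = x$y)
  print(comp, row.names = FALSE)
  if (x$triplet > 0)
    cat("triplet: T =", signif(x$triplet, 3),
        " tau_T =", signif(x$tau_T, 3), "s\n")
  cat("geometry ratio (w_xy/w_z)^2 =", signif(x$geometry_ratio, 4), "\n")
  invisible(x)
}

#' Calibrate observation-volume geometry from a diffusion standard
#'
#' Converts the measured diffusion time of a standard with known diffusion
#' coefficient (rhodamine 6G by default) and the structure parameter
#' \eqn{S^2 = (w_z/w_{xy})^2} into the Gaussian beam radii and the effective
#' observation volume \eqn{V_{eff} = \pi^{3/2} w_{xy}^2 w_z}.
#'
#' @param tau_D_ref diffusion time of the standard, seconds (default 27 us,
#'   the Rh6G value of the calibrated instrument).
#' @param D_ref diffusion coefficient of the standard, um^2/s (default 414,
#'   the 25 C literature value for Rh6G in water).
#' @param S2 structure parameter \eqn{(w_z/w_{xy})^2} (> 1; default 7).
#' @return Object of class `fcs_calibration` with fields `w_xy`, `w_z` (um),
#'   `S2`, `geometry_ratio` (= 1/S2) and `V_eff_L` (litres).
#' @export
#' @examples
#' cal <- calibrate()           # w_xy ~ 0.211 um, V_eff ~ 1.39e-16 L
#' concentration_from_N(1, cal) # ~ 12 nmol/L
calibrate <- function(tau_D_ref = 27e-6, D_ref = 414, S2 = 7) {
  if (tau_D_ref <= 0 || D_ref <= 0) stop("tau_D_ref and D_ref must be positive")
  if (S2 <= 1) stop("structure parameter S2 must exceed 1")
  w_xy <- sqrt(4 * D_ref * tau_D_ref)        # um
  w_z <- w_xy * sqrt(S2)                     # um
  v_um3 <- pi^(3/2) * w_xy^2 * w_z           # um^3
  structure(
    list(tau_D_ref = tau_D_ref, D_ref = D_ref, S2 = S2,
         geometry_ratio = 1 / S2, w_xy = w_xy, w_z = w_z,
         V_eff_L = v_um3 * 1e-15),
    class = "fcs_calibration")
}

#' @export
print.fcs_calibration <- function(x, ...) {
  cat(sprintf("FCS calibration: w_xy = %.4f um, w_z = %.4f um (S2 = %.3g)\n",
              x$w_xy, x$w_z, x$S2))
  cat(sprintf("  V_eff = %.4g L  (tau_D_ref = %.3g s, D_ref = %.3g um^2/s)\n",
              x$V_eff_L, x$tau_D_ref, x$D_ref))
  invisible(x)
}

# Avogadro constant, 1/mol (2019 SI exact value)
.N_AVOGADRO <- 6.02214076e23

#' Convert a fitted molecule number to a molar concentration
#'
#' `C = N / (N_A * V_eff)`, reported in nmol/L.
#'
#' @param N mean number of molecules in the observation volume (> 0).
#' @param calibration an [calibrate()] result supplying `V_eff_L`.
#' @return concentration in nmol/L.
#' @export
concentration_from_N <- function(N, calibration) {
  stopifnot(inherits(calibration, "fcs_calibration"))
  if (any(N <= 0)) stop("N must be positive")
  N / (.N_AVOGADRO * calibration$V_eff_L) * 1e9
}

#' Diffusion time / diffusion coefficient conversion
#'
#' `tau_D = w_xy^2 / (4 D)`; the two functions are exact inverses.
#'
#' @param D diffusion coefficient, um^2/s.
#' @param tau_D diffusion time, seconds.
#' @param w_xy radial e^-2 beam radius, um.
#' @return seconds (`diffusion_time`) or um^2/s (`diffusion_coefficient`).
#' @export
diffusion_time <- function(D, w_xy) {
  if (any(D <= 0) || any(w_xy <= 0)) stop("inputs must be positive")
  w_xy^2 / (4 * D)
}

#' @rdname diffusion_time
#' @export
diffusion_coefficient <- function(tau_D, w_xy) {
  if (any(tau_D <= 0) || any(w_xy <= 0)) stop("inputs must be positive")
  w_xy^2 / (4 * tau_D)
}
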