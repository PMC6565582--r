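#' Emitter species for trace simulation
#'
#' @param D diffusion coefficient, um^2/s (> 0).
#' @param brightness molecular brightness at the beam center, counts/s per
#'   molecule (>= 0).  Default 10,000 counts/s, a realistic single-molecule
#'   count rate for a bright fluorescent protein under live-cell excitation.
#' @param triplet equilibrium dark-state (triplet) fraction `T` in `[0, 1)`;
#'   0 disables blinking (the default).
#' @param tau_T triplet relaxation time, seconds (> 0 when `triplet > 0`;
#'   default 3 us).
#' @return Object of class `emitter_species`.
#' @export
emitter_species <- function(D, brightness = 1e4, triplet = 0, tau_T = 3e-6) {
  if (D <= 0) stop("diffusion coefficient D must be positive")
  if (brightness < 0) stop("brightness must be non-negative")
  if (triplet < 0 || triplet >= 1) stop("triplet fraction must be in [0, 1)")
  if (triplet > 0 && tau_T <= 0) stop("tau_T must be positive when triplet > 0")
  structure(list(D = D, brightness = brightness, triplet = triplet,
                 tau_T = tau_T),
            class = "emitter_species")
}

#' Gaussian detection volume
#'
#' @param w_xy radial e^-2 beam radius, um.
#' @param w_z axial e^-2 beam radius, um (`w_z > w_xy`).
#' @return Object of class `detection_volume`.
#' @export
detection_volume <- function(w_xy, w_z) {
  if (w_xy <= 0 || w_z <= w_xy)
    stop("need 0 < w_xy < w_z")
  structure(list(w_xy = w_xy, w_z = w_z), class = "detection_volume")
}

#' Simulation configuration
#'
#' Defines the recording geometry and schedule: consecutive fixed-length
#' measurement segments (emulating an instrument array of consecutive
#' measurements), binned photon counting, a periodic cubic box, and a single
#' seed from which all randomness flows.
#'
#' @param bin_width photon-count bin width, seconds.
#' @param segment_duration duration of one measurement segment, seconds
#'   (>= 100 bins).
#' @param n_segments number of consecutive segments (>= 1).
#' @param box_edge edge of the periodic cubic simulation box, um
#'   (must be >= 10 * w_z of the detection volume used).
#' @param n_molecules number of molecules per species.  Alternatively give
#'   `concentration_nM` and the count is derived as
#'   `round(C * N_A * box_edge^3)`.
#' @param concentration_nM molar concentration, nmol/L (used when
#'   `n_molecules` is missing).
#' @param background_rate uncorrelated background, counts/s (default 0).
#' @param seed integer seed; every random draw in [simulate_trace()] derives
#'   from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(bin_width, segment_duration, n_segments, box_edge,
                       n_molecules = NULL, concentration_nM = NULL,
                       background_rate = 0, seed = 1L) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (segment_duration < 100 * bin_width)
    stop("segment_duration must be at least 100 bins")
  if (n_segments < 1) stop("need at least one segment")
  if (box_edge <= 0) stop("box_edge must be positive")
  if (is.null(n_molecules)) {
    if (is.null(concentration_nM))
      stop("give either n_molecules or concentration_nM")
    box_L <- box_edge^3 * 1e-15                       # um^3 -> litres
    n_molecules <- round(concentration_nM * 1e-9 * .N_AVOGADRO * box_L)
    if (n_molecules < 1)
      stop("concentration too low: fewer than one molecule in the box")
  }
  if (background_rate < 0) stop("background_rate must be non-negative")
  structure(list(bin_width = bin_width, segment_duration = segment_duration,
                 n_segments = as.integer(n_segments), box_edge = box_edge,
                 n_molecules = as.integer(n_molecules),
                 background_rate = background_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# Exact discretization of the two-state (bright/dark) continuous-time Markov
# chain: per-step switching probabilities
#   p(bright -> dark) = T * (1 - exp(-dt/tau_T))
#   p(dark -> bright) = (1 - T) * (1 - exp(-dt/tau_T))
# giving stationary dark fraction exactly T and relaxation time exactly tau_T.
# Simulated via alternating geometric dwell times; returns the state series
# plus the final state so trajectories can continue across segments.
.telegraph_run <- function(n_steps, triplet, tau_T, dt, init_bright) {
  if (triplet == 0) {
    return(list(bright = rep(TRUE, n_steps), final_bright = TRUE))
  }
  q <- 1 - exp(-dt / tau_T)
  p_bd <- triplet * q          # leave bright
  p_db <- (1 - triplet) * q    # leave dark
  mean_pair <- 1 / p_bd + 1 / p_db     # expected steps per bright+dark pair
  cur <- init_bright
  total <- 0
  states_acc <- list()
  dwells_acc <- list()
  i <- 1L
  while (total < n_steps) {
    k <- max(16L, ceiling((n_steps - total) / mean_pair * 1.3))
    d1 <- stats::rgeom(k, if (cur) p_bd else p_db) + 1
    d2 <- stats::rgeom(k, if (cur) p_db else p_bd) + 1
    dwells_acc[[i]] <- as.vector(rbind(d1, d2))   # interleave dwell pairs
    states_acc[[i]] <- rep(c(cur, !cur), k)
    total <- total + sum(d1) + sum(d2)
    i <- i + 1L                                   # batch ends back in `cur`
  }
  bright <- rep(unlist(states_acc), unlist(dwells_acc))[seq_len(n_steps)]
  list(bright = bright, final_bright = bright[n_steps])
}

#' Two-state triplet blinking (random telegraph) series
#'
#' Simulates the bright/dark state of a single emitter as the exact
#' discretization of a two-state Markov chain with rate-to-dark
#' `k_d = T/tau_T` and rate-to-bright `k_b = (1-T)/tau_T`, started from the
#' stationary distribution.  The stationary dark fraction is `T` and the
#' autocorrelation of the series decays with time constant
#' `1/(k_d + k_b) = tau_T`.
#'
#' @param triplet dark-state fraction `T` in `[0, 1)`.
#' @param tau_T relaxation time, seconds (> 0 when `triplet > 0`).
#' @param n_steps number of steps.
#' @param dt step length, seconds; must satisfy `dt <= tau_T/5` when
#'   `triplet > 0`.
#' @param seed integer seed.
#' @return Logical vector of length `n_steps`; `TRUE` = bright.
#' @export
triplet_telegraph <- function(triplet, tau_T, n_steps, dt, seed = 1L) {
  if (triplet < 0 || triplet >= 1) stop("triplet fraction must be in [0, 1)")
  if (triplet > 0) {
    if (tau_T <= 0) stop("tau_T must be positive when triplet > 0")
    if (dt > tau_T / 5)
      stop("dt must not exceed tau_T/5 when triplet > 0")
  }
  if (n_steps < 1) stop("n_steps must be >= 1")
  set.seed(seed)
  init <- if (triplet > 0) stats::runif(1) > triplet else TRUE
  .telegraph_run(n_steps, triplet, tau_T, dt, init)$bright
}

#' Simulate binned photon-count traces from diffusing emitters
#'
#' Brownian-dynamics stand-in for a confocal FCS recording: each molecule
#' performs per-axis Gaussian displacement steps of variance `2 D dt` in a
#' periodic cubic box; the expected count in a bin is
#' `sum over molecules of brightness * dt * exp(-2(x^2+y^2)/w_xy^2 - 2 z^2/w_z^2)`
#' (coordinates relative to the box center, minimum image) times the
#' bright-state indicator, plus `background_rate * dt`; realized counts are
#' Poisson draws.  Segments are contiguous slices of one long trajectory,
#' emulating consecutive instrument measurements, and the whole simulation is
#' reproducible from `config$seed` alone.
#'
#' The trajectory time step equals the bin width unless resolution demands
#' finer stepping: 4 substeps per bin when the fastest diffusion time spans
#' fewer than 10 bins, and enough substeps that the telegraph step obeys
#' `dt <= tau_T/5` for any blinking species.
#'
#' @param species a single [emitter_species()] or a list of them.
#' @param volume a [detection_volume()].
#' @param config a [sim_config()].
#' @return List of [intensity_trace()] objects, one per segment.
#' @export
simulate_trace <- function(species, volume, config) {
  if (inherits(species, "emitter_species")) species <- list(species)
  if (length(species) < 1) stop("need at least one species")
  stopifnot(all(vapply(species, inherits, logical(1), "emitter_species")),
            inherits(volume, "detection_volume"),
            inherits(config, "sim_config"))
  if (config$box_edge < 10 * volume$w_z)
    stop("box_edge must be at least 10 * w_z to keep boundary artifacts negligible")

  bw <- config$bin_width
  tau_Ds <- vapply(species, function(s) diffusion_time(s$D, volume$w_xy),
                   numeric(1))
  if (min(tau_Ds) < 5 * bw)
    warning("bin_width resolves the fastest diffusion time with < 5 bins; expect discretization bias")
  sub <- 1L
  if (min(tau_Ds) < 10 * bw) sub <- 4L
  for (s in species) {
    if (s$triplet > 0) sub <- max(sub, as.integer(ceiling(bw / (s$tau_T / 5))))
  }
  dt <- bw / sub
  n_bins <- round(config$segment_duration / bw)
  L <- config$box_edge

  set.seed(config$seed)
  lambda <- matrix(0, n_bins, config$n_segments)
  for (sp in species) {
    sim_species_lambda(lambda, config$n_molecules, sub, dt,
                       sd_step = sqrt(2 * sp$D * dt), L = L,
                       w_xy = volume$w_xy, w_z = volume$w_z,
                       brightness = sp$brightness,
                       triplet = sp$triplet, tau_T = sp$tau_T)
  }
  lambda <- lambda + config$background_rate * bw
  lapply(seq_len(config$n_segments), function(s) {
    intensity_trace(stats::rpois(n_bins, lambda[, s]), bw,
                    label = sprintf("segment_%02d", s))
  })
}

#' Generate a noisy analytic correlation curve
#'
#' Cheap generator for fitter tests: evaluates an [fcs_model()] on a lag grid
#' and adds i.i.d. Gaussian noise of the stated standard deviation; the
#' curve's `sem` field records that standard deviation.
#'
#' @param model an [fcs_model()].
#' @param lags ascending positive lag grid, seconds.
#' @param noise_sd per-lag noise standard deviation (scalar or vector, >= 0).
#' @param seed integer seed.
#' @return A [correlation_curve()].
#' @export
synth_curve <- function(model, lags, noise_sd = 0, seed = 1L) {
  if (any(lags <= 0)) stop("lags must be positive")
  if (length(lags) > 1 && any(diff(lags) <= 0)) stop("lags must be ascending")
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative")
  sd_vec <- rep_len(as.numeric(noise_sd), length(lags))
  g0 <- evaluate_model(model, lags)
  set.seed(seed)
  noise <- if (all(sd_vec == 0)) 0 else stats::rnorm(length(lags), 0, sd_vec)
  correlation_curve(lags = lags, g = g0 + noise, sem = sd_vec)
}

#' Logarithmic lag grid
#'
#' @param from,to grid limits in seconds.
#' @param points_per_decade grid density (default 16).
#' @return Ascending numeric vector of lags.
#' @export
log_lag_grid <- function(from = 1e-6, to = 1, points_per_decade = 16) {
  if (from <= 0 || to <= from) stop("need 0 < from < to")
  n <- ceiling(log10(to / from) * points_per_decade)
  10^seq(log10(from), log10(to), length.out = n + 1)
}
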