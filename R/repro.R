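#' Simulate-correlate-fit recovery of a single-component diffusion time
#'
#' Full pipeline experiment: Brownian photon-count traces of one species with
#' diffusion time `tau_D_target` are simulated as consecutive segments,
#' multi-tau correlated per segment, averaged, and fitted with a
#' one-component model (triplet term floated).  Repeated over independent
#' seeds; per-seed sub-seeds derive from `base_seed` as
#' `base_seed * 1000 + replicate`.
#'
#' Default scale: ten 1-second segments of 2-microsecond bins, 200 molecules
#' in a 6 um periodic box, brightness 10,000 counts/s, geometry from the
#' rhodamine 6G calibration.  The fit uses loess-smoothed inverse-variance
#' weights (see [smoothed_weights()]) and a lag window up to 20 ms -- two
#' orders of magnitude below the segment length, where the finite-segment
#' mean-subtraction bias of the correlator is negligible.
#'
#' @param tau_D_target generating diffusion time, seconds (default 220 us).
#' @param n_seeds number of replicate simulations (default 5).
#' @param base_seed integer master seed.
#' @param calibration an [calibrate()] result fixing the geometry.
#' @param n_molecules molecules in the box.
#' @param segment_duration,n_segments,bin_width recording schedule, seconds.
#' @param box_edge periodic box edge, um.
#' @param brightness counts/s per molecule at beam center.
#' @param n_levels multi-tau levels (default 12: lags 2 us to ~66 ms).
#' @param fit_max_lag upper lag bound of the fit window, seconds.
#' @return data.frame with one row per seed: `seed`, `tau_D_us`, `N_fit`,
#'   `converged`.
#' @export
recover_tauD_pipeline <- function(tau_D_target = 220e-6, n_seeds = 5,
                                  base_seed = 1, calibration = calibrate(),
                                  n_molecules = 200, segment_duration = 1,
                                  n_segments = 10, bin_width = 2e-6,
                                  box_edge = 6, brightness = 1e4,
                                  n_levels = 12, fit_max_lag = 0.02) {
  vol <- detection_volume(calibration$w_xy, calibration$w_z)
  sp <- emitter_species(D = diffusion_coefficient(tau_D_target,
                                                  calibration$w_xy),
                        brightness = brightness)
  out <- lapply(seq_len(n_seeds), function(i) {
    cfg <- sim_config(bin_width = bin_width,
                      segment_duration = segment_duration,
                      n_segments = n_segments, box_edge = box_edge,
                      n_molecules = n_molecules,
                      seed = base_seed * 1000 + i)
    traces <- simulate_trace(sp, vol, cfg)
    curves <- lapply(traces, autocorrelate_multitau, n_levels = n_levels)
    avg <- window_curve(average_series(curves), max_lag = fit_max_lag)
    fit <- fit_curve(avg, n_components = 1, calibration = calibration,
                     weights = smoothed_weights(avg))
    data.frame(seed = cfg$seed, tau_D_us = fit$model$tau_D[1] * 1e6,
               N_fit = fit$model$N, converged = fit$converged)
  })
  do.call(rbind, out)
}

#' Two-component recovery on noisy analytic curves
#'
#' Generates noisy model curves with two diffusive components (defaults: the
#' cytoplasmic two-component parameters at the highest measured
#' concentration -- fast 340 us, slow 27 ms, slow fraction 0.32, N = 3,
#' structure parameter 7), then fits a two-component model (triplet off) and
#' collects the recovered parameters over independent seeds.
#'
#' @param n_seeds number of replicate curves (default 20).
#' @param base_seed integer master seed; per-replicate seeds are
#'   `base_seed * 1000 + replicate`.
#' @param tau_fast,tau_slow generating diffusion times, seconds.
#' @param y_slow generating slow-component amplitude fraction.
#' @param N generating molecule number.
#' @param noise_sd Gaussian noise standard deviation per lag (default 0.005).
#' @param lags lag grid, seconds (default 16 points per decade, 1 us - 1 s).
#' @param calibration an [calibrate()] result fixing the geometry.
#' @return data.frame with one row per seed: `seed`, `tau_fast_us`,
#'   `tau_slow_ms`, `y_slow`, `N_fit`, `converged`.
#' @export
recover_two_component <- function(n_seeds = 20, base_seed = 1,
                                  tau_fast = 340e-6, tau_slow = 27e-3,
                                  y_slow = 0.32, N = 3, noise_sd = 0.005,
                                  lags = log_lag_grid(1e-6, 1, 16),
                                  calibration = calibrate()) {
  model <- fcs_model(N = N, tau_D = c(tau_fast, tau_slow),
                     y = c(1 - y_slow, y_slow), triplet = 0,
                     geometry_ratio = calibration$geometry_ratio)
  out <- lapply(seq_len(n_seeds), function(i) {
    cv <- synth_curve(model, lags, noise_sd = noise_sd,
                      seed = base_seed * 1000 + i)
    fit <- fit_curve(cv, n_components = 2, calibration = calibration,
                     fix_triplet = c(T = 0))
    data.frame(seed = base_seed * 1000 + i,
               tau_fast_us = fit$model$tau_D[1] * 1e6,
               tau_slow_ms = fit$model$tau_D[2] * 1e3,
               y_slow = fit$model$y[2], N_fit = fit$model$N,
               converged = fit$converged)
  })
  do.call(rbind, out)
}

#' End-to-end reproduction pipeline
#'
#' Runs every stage on the bundled inputs and synthetic data: the
#' simulate-correlate-fit recovery of the single-component diffusion time,
#' the two-component analytic-curve recovery, the pooled 22q11.2 enrichment
#' statistics, the duplication-interval measurements and their intersection,
#' and the calibration-based concentration conversion.  Writes one
#' JSON-compatible report carrying every headline quantity together with the
#' seeds used; the report is a pure function of `seed` and the arguments.
#'
#' @param seed master integer seed.
#' @param out_dir directory for `repro_report.json` (`NULL`: no file).
#' @param sim_reps seeds for the pipeline recovery (default 5).
#' @param curve_reps seeds for the analytic-curve recovery (default 20).
#' @param sim_args optional named list overriding
#'   [recover_tauD_pipeline()] arguments (e.g. smaller scale for smoke runs).
#' @return The report as a nested list, invisibly when written to disk.
#' @export
run_repro <- function(seed = 1, out_dir = NULL, sim_reps = 5,
                      curve_reps = 20, sim_args = list()) {
  cal <- calibrate()

  sim <- do.call(recover_tauD_pipeline,
                 c(list(n_seeds = sim_reps, base_seed = seed,
                        calibration = cal), sim_args))
  two <- recover_two_component(n_seeds = curve_reps, base_seed = seed,
                               calibration = cal)

  enr <- enrichment_analysis(read_study_table())

  calls <- read_duplication_table()
  ivs <- lapply(seq_len(nrow(calls)), function(i)
    genomic_interval(calls$chrom[i], calls$start[i], calls$end[i],
                     calls$assembly[i]))
  core <- intersect_intervals(ivs)

  report <- list(
    seed = seed,
    calibration = list(w_xy_um = cal$w_xy, w_z_um = cal$w_z, S2 = cal$S2,
                       V_eff_L = cal$V_eff_L,
                       nM_per_molecule = concentration_from_N(1, cal)),
    pipeline_tauD = list(
      median_tau_D_us = stats::median(sim$tau_D_us),
      median_N = stats::median(sim$N_fit),
      seeds = sim$seed, per_seed_tau_D_us = sim$tau_D_us),
    two_component = list(
      median_tau_fast_us = stats::median(two$tau_fast_us),
      median_tau_slow_ms = stats::median(two$tau_slow_ms),
      median_y_slow = stats::median(two$y_slow),
      seeds = two$seed),
    enrichment = list(
      case_freq_pct = enr$case_freq_pct,
      control_freq_pct = enr$control_freq_pct,
      odds_ratio = enr$odds_ratio, ci_low = enr$ci_low,
      ci_high = enr$ci_high, p_fisher = enr$p_fisher),
    duplications = list(
      lengths_mb = stats::setNames(
        vapply(ivs, length_mb, numeric(1)), calls$patient),
      shared_region = if (is.null(core)) NULL else format_region(core)))

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "repro_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report
}
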