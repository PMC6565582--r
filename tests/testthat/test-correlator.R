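test_that("constant and white-noise traces have no correlation", {
  tr <- intensity_trace(rep(5, 200), 1e-5)
  expect_true(all(autocorrelate_direct(tr, 20)$g == 1))
  expect_true(all(autocorrelate_direct(tr, 20, "plain")$g == 1))
  expect_true(all(abs(autocorrelate_multitau(tr)$g - 1) < 1e-12))

  # i.i.d. Poisson counts: G(tau > 0) = 1 within sampling error
  set.seed(8)
  trp <- intensity_trace(stats::rpois(1e6, 4), 1e-5)
  expect_true(all(abs(autocorrelate_direct(trp, 5)$g - 1) < 0.005))
})

test_that("the 4-bin hand example reproduces both normalizations", {
  tr <- intensity_trace(c(1, 3, 1, 3), 1)
  # plain (global mean): G = 1 + (-1)/2^2 = 0.75
  expect_equal(autocorrelate_direct(tr, 1, "plain")$g, 0.75)
  # symmetric (window means 5/3 and 7/3): G = 3 / (5/3 * 7/3) = 27/35
  expect_equal(autocorrelate_direct(tr, 1, "symmetric")$g, 27 / 35)
})

test_that("multi-tau agrees with the direct oracle at shared lags", {
  set.seed(21)
  for (i in 1:50) {
    tr <- random_poisson_trace(1e4)
    mt <- autocorrelate_multitau(tr, channels_per_level = 16)
    dr <- autocorrelate_direct(tr, 16)
    expect_lt(max(abs(mt$g[1:16] - dr$g)), 1e-10)
    expect_equal(mt$lags[1:16], dr$lags)
  }
})

test_that("multi-tau lag grid is quasi-logarithmic and ascending", {
  tr <- random_poisson_trace(2^14)
  mt <- autocorrelate_multitau(tr, channels_per_level = 16, n_levels = 6)
  expect_equal(length(mt$lags), 16 + 5 * 8)
  expect_true(all(diff(mt$lags) > 0))
  # level-0 lags linear at bin width; later levels double the spacing
  expect_equal(mt$lags[1:16], (1:16) * tr$bin_width)
  expect_equal(mt$lags[17:24], (9:16) * 2 * tr$bin_width)
  expect_error(autocorrelate_multitau(tr, n_levels = 20), "at most")
  expect_error(autocorrelate_multitau(intensity_trace(rep(0, 100), 1), 8),
               "mean is zero")
})

test_that("correlator recovers the model curve from simulated traces", {
  # single species in a small box; compare against the known generating
  # model at three durations: the error must decrease monotonically, the
  # amplitude must match 1 + 1/N_eff, and G -> 1 at lags >> tau_D
  vol <- detection_volume(0.2, 0.5)
  box <- 5
  n_mol <- 200
  D <- 100                                    # tau_D = 1e-4 s
  tau_D <- diffusion_time(D, vol$w_xy)
  N_eff <- n_mol * (pi^1.5 * vol$w_xy^2 * vol$w_z) / box^3
  truth <- fcs_model(N = N_eff, tau_D = tau_D,
                     geometry_ratio = (vol$w_xy / vol$w_z)^2)
  sp <- emitter_species(D = D, brightness = 2e4)
  err <- vapply(c(0.2, 0.8, 3.2), function(dur) {
    cfg <- sim_config(1e-5, dur, 1, box, n_molecules = n_mol, seed = 77)
    cv <- autocorrelate_multitau(simulate_trace(sp, vol, cfg)[[1]],
                                 n_levels = 9)
    keep <- cv$lags <= 10 * tau_D
    sqrt(mean((cv$g[keep] - evaluate_model(truth, cv$lags[keep]))^2))
  }, numeric(1))
  expect_true(all(diff(err) < 0))

  # finer bins (tau_D = 20 bins) keep the first-lag binning bias small
  cfg <- sim_config(5e-6, 3.2, 1, box, n_molecules = n_mol, seed = 78)
  cv <- autocorrelate_multitau(simulate_trace(sp, vol, cfg)[[1]])
  # amplitude 1 + 1/N_eff at the smallest lag; the per-seed amplitude
  # scatters ~10-15%, so average over seeds before comparing
  g1 <- vapply(1:5, function(i) {
    cfg_i <- sim_config(5e-6, 1.6, 1, box, n_molecules = n_mol, seed = 70 + i)
    autocorrelate_multitau(simulate_trace(sp, vol, cfg_i)[[1]])$g[1]
  }, numeric(1))
  expect_equal(mean(g1), 1 + 1 / N_eff, tolerance = 0.08)
  # decay to baseline: beyond 250 tau_D the generating model itself is
  # within 0.005 of 1 at this amplitude; the averaged estimate must be too
  far <- cv$lags >= 250 * tau_D
  expect_true(sum(far) >= 8)
  expect_lt(abs(mean(cv$g[far] - 1)), 0.01)
})

test_that("segment averaging yields per-lag means and SEMs", {
  lags <- (1:10) * 1e-5
  c1 <- correlation_curve(lags, rep(1.2, 10))
  c2 <- correlation_curve(lags, rep(1.4, 10))
  avg <- average_series(list(c1, c2))
  expect_equal(avg$g, rep(1.3, 10))
  expect_equal(avg$sem, rep(0.1, 10))
  expect_equal(avg$n_segments, 2L)

  # identical curves: sem exactly zero
  avg10 <- average_series(rep(list(c1), 10))
  expect_equal(avg10$g, c1$g)
  expect_true(all(avg10$sem == 0))

  # Gaussian noise: sem ~ sd/sqrt(n)
  cal <- test_cal()
  m <- fcs_model(N = 2, tau_D = 340e-6, geometry_ratio = cal$geometry_ratio)
  grid <- log_lag_grid(1e-6, 0.1, 8)
  curves <- lapply(1:10, function(i) synth_curve(m, grid, 0.01, seed = 400 + i))
  avg_n <- average_series(curves)
  expect_equal(mean(avg_n$sem), 0.01 / sqrt(10), tolerance = 0.15)

  expect_error(average_series(list(c1, correlation_curve(lags * 2, c1$g))),
               "common lag grid")
  expect_error(average_series(list()), "no curves")
})

test_that("amplitude normalization rescales to G_n(tau_ref) = 1", {
  cal <- test_cal()
  grid <- log_lag_grid(1e-6, 0.1, 16)
  m2 <- fcs_model(N = 2, tau_D = 340e-6, geometry_ratio = cal$geometry_ratio)
  m10 <- fcs_model(N = 10, tau_D = 340e-6, geometry_ratio = cal$geometry_ratio)
  n2 <- normalize_amplitude(synth_curve(m2, grid, 0), tau_ref = 1e-5)
  n10 <- normalize_amplitude(synth_curve(m10, grid, 0), tau_ref = 1e-5)
  # N only scales the amplitude: normalized shapes are identical
  expect_lt(max(abs(n2$g - n10$g)), 1e-12)
  # exactly 1 at the reference lag (interpolated)
  at_ref <- stats::approx(n2$lags, n2$g, xout = 1e-5)$y
  expect_equal(at_ref, 1, tolerance = 1e-12)

  flat <- correlation_curve(grid, rep(1, length(grid)))
  expect_error(normalize_amplitude(flat), "no amplitude")
  expect_error(normalize_amplitude(n2, tau_ref = 10), "outside")
})
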