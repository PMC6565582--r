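test_that("telegraph process matches its stationary distribution and relaxation", {
  # no dark rate: always bright
  expect_true(all(triplet_telegraph(0, 5e-6, 1e4, 1e-6, seed = 1)))

  # stationary dark fraction of the 2-state Markov chain at long run length
  s <- triplet_telegraph(0.2, 5e-6, 1e7, 5e-7, seed = 1)
  expect_equal(mean(!s), 0.2, tolerance = 0.025)  # 0.200 +/- 0.005 absolute
  expect_lt(abs(mean(!s) - 0.2), 0.005)

  # autocorrelation decays with time constant tau_T (closed form e^{-t/tau_T})
  dt <- 2.5e-7                                    # tau_T / 20
  s2 <- triplet_telegraph(0.25, 5e-6, 2e6, dt, seed = 2)
  rho <- stats::acf(as.numeric(s2), lag.max = 40, plot = FALSE,
                    demean = TRUE)$acf[-1]
  ks <- seq_along(rho)
  tau_hat <- -dt / stats::coef(stats::lm(log(rho[rho > 0.05]) ~ 0 +
                                           ks[rho > 0.05]))[[1]]
  expect_equal(tau_hat, 5e-6, tolerance = 0.1)

  expect_error(triplet_telegraph(1, 5e-6, 10, 1e-7), "\\[0, 1\\)")
  expect_error(triplet_telegraph(0.2, -1, 10, 1e-7), "positive")
  expect_error(triplet_telegraph(0.2, 5e-6, 10, 2e-6), "tau_T/5")
})

test_that("simulated traces are reproducible and Poisson-dispersed", {
  vol <- detection_volume(0.2, 0.5)
  sp <- emitter_species(D = 100, brightness = 2e4)
  cfg <- sim_config(1e-5, 0.02, 2, 5, n_molecules = 100, seed = 99)
  tr1 <- simulate_trace(sp, vol, cfg)
  tr2 <- simulate_trace(sp, vol, cfg)
  # bit-identical under identical seed/config
  expect_identical(tr1[[1]]$counts, tr2[[1]]$counts)
  expect_identical(tr1[[2]]$counts, tr2[[2]]$counts)
  # different seed differs
  cfg2 <- sim_config(1e-5, 0.02, 2, 5, n_molecules = 100, seed = 100)
  expect_false(identical(simulate_trace(sp, vol, cfg2)[[1]]$counts,
                         tr1[[1]]$counts))

  # super-Poissonian marginal: variance/mean >= 1, probed where number
  # fluctuations contribute measurably above shot noise (bright emitters)
  spb <- emitter_species(D = 100, brightness = 1e5)
  trb <- simulate_trace(spb, vol,
                        sim_config(1e-5, 0.05, 2, 5, n_molecules = 100,
                                   seed = 123))
  counts <- unlist(lapply(trb, `[[`, "counts"))
  expect_gte(stats::var(counts) / mean(counts), 1)

  # dark emitters yield an all-zero trace
  sp0 <- emitter_species(D = 100, brightness = 0)
  tr0 <- simulate_trace(sp0, vol, cfg)
  expect_true(all(unlist(lapply(tr0, `[[`, "counts")) == 0))
})

test_that("mean count rate matches the spatially averaged Gaussian profile", {
  # expected rate = n * brightness * (pi/2)^(3/2) w_xy^2 w_z / box^3
  vol <- detection_volume(0.2, 0.5)
  n_mol <- 300
  brightness <- 1e4
  box <- 5
  expected <- n_mol * brightness *
    (pi / 2)^1.5 * vol$w_xy^2 * vol$w_z / box^3
  rates <- vapply(1:3, function(i) {
    cfg <- sim_config(1e-5, 1, 1, box, n_molecules = n_mol, seed = 300 + i)
    tr <- simulate_trace(emitter_species(D = 100, brightness = brightness),
                         vol, cfg)[[1]]
    mean(tr$counts) / tr$bin_width
  }, numeric(1))
  expect_equal(mean(rates), expected, tolerance = 0.05)

  # uncorrelated background adds its own rate
  cfgb <- sim_config(1e-5, 0.05, 1, box, n_molecules = 1,
                     background_rate = 5e4, seed = 7)
  trb <- simulate_trace(emitter_species(D = 100, brightness = 0), vol, cfgb)[[1]]
  expect_equal(mean(trb$counts) / trb$bin_width, 5e4, tolerance = 0.05)
})

test_that("simulation guards reject unphysical configurations", {
  vol <- detection_volume(0.2, 0.5)
  sp <- emitter_species(D = 100)
  expect_error(simulate_trace(sp, vol,
                              sim_config(1e-5, 0.01, 1, 4, n_molecules = 5)),
               "10 \\* w_z")
  # bins too coarse for the diffusion time warn but do not fail
  fast <- emitter_species(D = 1e4)   # tau_D = 1 us at w_xy = 0.2
  expect_warning(simulate_trace(fast, vol,
                                sim_config(1e-5, 0.01, 1, 5, n_molecules = 2)),
                 "discretization")
  expect_error(sim_config(1e-5, 0.0005, 1, 5, n_molecules = 5), "100 bins")
  expect_error(sim_config(1e-5, 0.01, 1, 5), "n_molecules or concentration")
  # molecule count derived from concentration: C * N_A * box^3
  cfg <- sim_config(1e-5, 0.01, 1, 5, concentration_nM = 100)
  expect_equal(cfg$n_molecules,
               round(100e-9 * 6.02214076e23 * 125e-15))
})

test_that("synthetic curves reproduce the model plus calibrated noise", {
  cal <- test_cal()
  m <- fcs_model(N = 2, tau_D = 340e-6, geometry_ratio = cal$geometry_ratio)
  lags <- log_lag_grid(1e-6, 0.1, 16)

  # zero noise: exactly the model
  cv0 <- synth_curve(m, lags, noise_sd = 0, seed = 1)
  expect_identical(cv0$g, evaluate_model(m, lags))

  # amplitude near 1 + 1/N at lags far below tau_D
  expect_equal(cv0$g[1], 1.5, tolerance = 0.005)

  # Monte-Carlo check of the noise model at a few lags
  draws <- vapply(1:200, function(i)
    synth_curve(m, lags[c(1, 30, 60)], noise_sd = 0.01, seed = i)$g,
    numeric(3))
  sds <- apply(draws, 1, stats::sd)
  expect_true(all(abs(sds - 0.01) < 0.002))

  expect_error(synth_curve(m, c(2e-6, 1e-6), 0), "ascending")
  expect_error(synth_curve(m, lags, -0.1), "non-negative")
})
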