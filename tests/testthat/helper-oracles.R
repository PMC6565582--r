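# Independent oracles and small fixture builders shared across tests.

# Two-sided Fisher p by explicit enumeration over all tables with the
# observed margins, point probabilities from binomial coefficients.
fisher_enum_oracle <- function(a, b, c, d) {
  n1 <- a + b
  n2 <- c + d
  m <- a + c
  n <- n1 + n2
  xs <- max(0, m - n2):min(n1, m)
  logp <- lchoose(n1, xs) + lchoose(n2, m - xs) - lchoose(n, m)
  p <- exp(logp)
  p_obs <- exp(lchoose(n1, a) + lchoose(n2, m - a) - lchoose(n, m))
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# random 2x2 table with all cells >= min_cell
random_table2x2 <- function(max_n = 200, min_cell = 0) {
  cells <- min_cell + stats::rpois(4, stats::runif(4, 1, max_n / 4))
  table2x2(cells[1], cells[2], cells[3], cells[4])
}

# random Poisson trace for correlator equivalence checks
random_poisson_trace <- function(n = 1e4, lambda = NULL, bin_width = 1e-5) {
  if (is.null(lambda)) lambda <- stats::runif(1, 0.5, 20)
  intensity_trace(stats::rpois(n, lambda), bin_width)
}

# default small calibration used throughout fitting tests
test_cal <- function() calibrate(tau_D_ref = 27e-6, D_ref = 414, S2 = 7)
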