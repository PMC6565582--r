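pooled <- pool_counts(read_study_table())

test_that("pooling the published cohorts reproduces the printed frequencies", {
  expect_equal(pooled$table$a, 11)
  expect_equal(pooled$table$b, 411)
  expect_equal(pooled$table$c, 1)
  expect_equal(pooled$table$d, 1218)
  expect_equal(pooled$case_freq_pct, 2.61)
  expect_equal(pooled$control_freq_pct, 0.08)

  # identity on a single study; doubling studies doubles cells, keeps freqs
  one <- data.frame(label = "s", n_cases = 10, case_carriers = 2,
                    n_controls = 100, control_carriers = 1)
  p1 <- pool_counts(one)
  expect_equal(unlist(p1$table[c("a", "b", "c", "d")]),
               c(a = 2, b = 8, c = 1, d = 99))
  p2 <- pool_counts(rbind(one, one))
  expect_equal(p2$table$a, 4)
  expect_equal(p2$case_freq_pct, p1$case_freq_pct)

  expect_error(pool_counts(data.frame()), "non-empty")
  bad <- one; bad$case_carriers <- 11
  expect_error(pool_counts(bad), "exceed")
})

test_that("count_from_percent reconstructs printed carrier counts", {
  expect_equal(count_from_percent(2.61, 422), 11L)
  expect_equal(count_from_percent(0.08, 1219), 1L)
  expect_warning(count_from_percent(2.5, 422), "not close to an integer")
})

test_that("odds ratio matches the printed value and algebraic identities", {
  expect_equal(round(odds_ratio(pooled$table), 1), 32.6)
  expect_equal(odds_ratio(table2x2(10, 10, 10, 10)), 1)

  set.seed(31)
  for (i in 1:20) {
    tb <- random_table2x2(min_cell = 1)
    # swapping the arms inverts the odds ratio
    swapped <- table2x2(tb$c, tb$d, tb$a, tb$b)
    expect_equal(odds_ratio(swapped), 1 / odds_ratio(tb), tolerance = 1e-12)
    # uniform scaling leaves the OR unchanged
    scaled <- table2x2(tb$a * 3, tb$b * 3, tb$c * 3, tb$d * 3)
    expect_equal(odds_ratio(scaled), odds_ratio(tb), tolerance = 1e-12)
  }
  # Haldane-Anscombe keeps zero-cell tables finite
  expect_true(is.finite(odds_ratio(table2x2(5, 5, 0, 10))))
})

test_that("Woolf interval reproduces the printed CI and its structure", {
  ci <- woolf_ci(pooled$table, 0.95)
  expect_equal(round(ci, 1), c(4.2, 253.3))

  set.seed(32)
  for (i in 1:20) {
    tb <- random_table2x2(min_cell = 1)
    or <- odds_ratio(tb)
    ci_i <- woolf_ci(tb)
    # log-symmetry about ln OR
    expect_equal(log(ci_i[2]) - log(or), log(or) - log(ci_i[1]),
                 tolerance = 1e-12)
    # point estimate inside the interval
    expect_true(ci_i[1] <= or && or <= ci_i[2])
    # scaling all cells up narrows the interval
    big <- table2x2(tb$a * 4, tb$b * 4, tb$c * 4, tb$d * 4)
    ci_big <- woolf_ci(big)
    expect_lt(ci_big[2] / ci_big[1], ci_i[2] / ci_i[1])
  }
  # degenerate level: both bounds collapse onto the OR
  ci0 <- woolf_ci(pooled$table, 0)
  expect_equal(ci0[1], odds_ratio(pooled$table), tolerance = 1e-12)
  expect_equal(ci0[2], odds_ratio(pooled$table), tolerance = 1e-12)
})

test_that("Fisher exact test equals the enumeration oracle", {
  # identical arm proportions: p = 1
  expect_equal(fisher_exact(table2x2(5, 45, 5, 45)), 1)

  set.seed(33)
  for (i in 1:40) {
    tb <- random_table2x2(max_n = 200)
    p <- fisher_exact(tb)
    expect_gte(p, 0); expect_lte(p, 1)
    expect_equal(p, fisher_enum_oracle(tb$a, tb$b, tb$c, tb$d),
                 tolerance = 1e-12)
    # cross-check against the stock implementation
    ft <- stats::fisher.test(matrix(c(tb$a, tb$c, tb$b, tb$d), 2))$p.value
    expect_equal(p, ft, tolerance = 1e-8)
  }
  # pooled table: strongly significant (printed value is of order 1e-3 or less)
  expect_lt(fisher_exact(pooled$table), 0.005)
})

test_that("two-proportion chi-square behaves like its large-sample theory", {
  expect_equal(two_proportion_test(5, 50, 10, 100), 1)
  # under equal true proportions with ample expected counts, the asymptotic
  # chi-square p agrees with the exact test within a factor of 2 outside the
  # deep tail (where the normal approximation is known to degrade)
  set.seed(34)
  checked <- 0
  while (checked < 20) {
    p0 <- stats::runif(1, 0.2, 0.8)
    n1 <- sample(50:200, 1); n2 <- sample(50:200, 1)
    a <- stats::rbinom(1, n1, p0); cc <- stats::rbinom(1, n2, p0)
    if (min(a, n1 - a, cc, n2 - cc) < 8) next
    p_f <- fisher_exact(table2x2(a, n1 - a, cc, n2 - cc))
    if (p_f < 0.01) next
    p_chi <- two_proportion_test(a, n1, cc, n2)
    expect_lt(abs(log(p_chi / p_f)), log(2) + 1e-9)
    checked <- checked + 1
  }
  # doubling all counts strengthens the evidence for unequal proportions
  expect_lt(two_proportion_test(20, 100, 10, 100),
            two_proportion_test(10, 50, 5, 50))
  expect_error(two_proportion_test(5, 4, 1, 10), "invalid")
})

test_that("the pooled analysis bundle reports consistent pieces", {
  enr <- enrichment_analysis(read_study_table())
  expect_equal(round(enr$odds_ratio, 1), 32.6)
  expect_equal(round(c(enr$ci_low, enr$ci_high), 1), c(4.2, 253.3))
  expect_equal(enr$case_freq_pct, 2.61)
  expect_true(enr$ci_low <= enr$odds_ratio && enr$odds_ratio <= enr$ci_high)
  expect_lt(enr$p_fisher, 0.005)
})
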