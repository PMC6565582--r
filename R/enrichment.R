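#' 2x2 carrier table for case-control enrichment
#'
#' @param a case carriers, @param b case non-carriers,
#' @param c control carriers, @param d control non-carriers.
#' @return Object of class `table2x2`.
#' @export
table2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  if (a + b == 0 || c + d == 0) stop("both arms must contain observations")
  structure(as.list(cells), class = "table2x2")
}

#' @export
print.table2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("cases", "controls"),
                              c("carrier", "non-carrier")))
  print(m)
  invisible(x)
}

#' Pool study-level carrier counts into a 2x2 table
#'
#' Cell-wise sums across studies, with carrier frequencies per arm reported
#' as percentages rounded to 2 decimals.
#'
#' @param studies data.frame with columns `label`, `n_cases`,
#'   `case_carriers`, `n_controls`, `control_carriers`.
#' @return List with `table` (a [table2x2()]), `case_freq_pct` and
#'   `control_freq_pct`.
#' @export
#' @examples
#' studies <- read_study_table()   # bundled pooled BEEC cohort counts
#' pool_counts(studies)            # 2.61% in cases vs 0.08% in controls
pool_counts <- function(studies) {
  req <- c("label", "n_cases", "case_carriers", "n_controls", "control_carriers")
  if (!is.data.frame(studies) || nrow(studies) == 0)
    stop("studies must be a non-empty data.frame")
  missing_cols <- setdiff(req, names(studies))
  if (length(missing_cols))
    stop("missing study columns: ", paste(missing_cols, collapse = ", "))
  if (any(studies$case_carriers > studies$n_cases) ||
      any(studies$control_carriers > studies$n_controls))
    stop("carrier counts exceed arm totals")
  n_cases <- sum(studies$n_cases)
  a <- sum(studies$case_carriers)
  n_controls <- sum(studies$n_controls)
  cc <- sum(studies$control_carriers)
  list(table = table2x2(a, n_cases - a, cc, n_controls - cc),
       case_freq_pct = round(100 * a / n_cases, 2),
       control_freq_pct = round(100 * cc / n_controls, 2))
}

#' Reconstruct a carrier count from a printed percentage
#'
#' Rounds `percent * total / 100` to the nearest integer, warning when the
#' implied count is ambiguous, i.e. `percent * total / 100` falls more than
#' 0.25 away from any integer and therefore does not cleanly identify a
#' count.
#'
#' @param percent carrier frequency in percent.
#' @param total arm size.
#' @return integer count.
#' @export
count_from_percent <- function(percent, total) {
  x <- percent * total / 100
  n <- round(x)
  if (abs(n - x) > 0.25)
    warning(sprintf("percent*total/100 = %.2f is not close to an integer; using %d",
                    x, n))
  as.integer(n)
}

.haldane <- function(tab) {
  cells <- c(tab$a, tab$b, tab$c, tab$d)
  if (any(cells == 0)) cells <- cells + 0.5    # Haldane-Anscombe correction
  stats::setNames(as.list(cells), c("a", "b", "c", "d"))
}

#' Odds ratio of a 2x2 table
#'
#' `(a*d)/(b*c)`, with the Haldane-Anscombe +0.5 correction applied to every
#' cell whenever any cell is zero.
#'
#' @param tab a [table2x2()].
#' @return numeric odds ratio.
#' @export
odds_ratio <- function(tab) {
  stopifnot(inherits(tab, "table2x2"))
  h <- .haldane(tab)
  (h$a * h$d) / (h$b * h$c)
}

#' Woolf (log-normal) confidence interval for an odds ratio
#'
#' `exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` with `z` the standard
#' normal quantile at `(1 + level)/2`; the same zero-cell correction as
#' [odds_ratio()].
#'
#' @param tab a [table2x2()].
#' @param level confidence level (default 0.95).
#' @return numeric vector `c(low, high)`.
#' @export
woolf_ci <- function(tab, level = 0.95) {
  stopifnot(inherits(tab, "table2x2"))
  if (level < 0 || level >= 1) stop("level must be in [0, 1)")
  h <- .haldane(tab)
  lor <- log((h$a * h$d) / (h$b * h$c))
  se <- sqrt(1 / h$a + 1 / h$b + 1 / h$c + 1 / h$d)
  z <- stats::qnorm((1 + level) / 2)
  exp(lor + c(-1, 1) * z * se)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional hypergeometric test: with margins fixed, the two-sided p-value
#' sums the probabilities of all tables whose point probability does not
#' exceed that of the observed table (up to a 1e-7 relative tolerance against
#' floating-point ties).
#'
#' @param tab a [table2x2()].
#' @return p-value in `[0, 1]`.
#' @export
fisher_exact <- function(tab) {
  stopifnot(inherits(tab, "table2x2"))
  n1 <- tab$a + tab$b          # cases
  n2 <- tab$c + tab$d          # controls
  m <- tab$a + tab$c           # carriers
  support <- max(0, m - n2):min(n1, m)
  probs <- stats::dhyper(support, n1, n2, m)
  p_obs <- stats::dhyper(tab$a, n1, n2, m)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Chi-square test for two proportions
#'
#' Pearson chi-square on the implied 2x2 table, 1 degree of freedom, without
#' continuity correction.
#'
#' @param x1,n1 successes and total in arm 1.
#' @param x2,n2 successes and total in arm 2.
#' @return p-value.
#' @export
two_proportion_test <- function(x1, n1, x2, n2) {
  if (x1 > n1 || x2 > n2 || n1 <= 0 || n2 <= 0) stop("invalid counts")
  if (x1 / n1 == x2 / n2) return(1)    # statistic exactly 0
  suppressWarnings(
    stats::prop.test(c(x1, x2), c(n1, n2), correct = FALSE)$p.value)
}

#' Pooled enrichment analysis of a study table
#'
#' Pools the studies, then reports carrier frequencies, odds ratio, Woolf
#' confidence interval and Fisher exact p-value.
#'
#' @param studies study data.frame as in [pool_counts()].
#' @param ci_level confidence level (default 0.95).
#' @return List of class `enrichment_result` with fields `table`,
#'   `case_freq_pct`, `control_freq_pct`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `ci_level`, `p_fisher`, `methods`.
#' @export
enrichment_analysis <- function(studies, ci_level = 0.95) {
  pooled <- pool_counts(studies)
  or <- odds_ratio(pooled$table)
  ci <- woolf_ci(pooled$table, ci_level)
  structure(
    list(table = pooled$table,
         case_freq_pct = pooled$case_freq_pct,
         control_freq_pct = pooled$control_freq_pct,
         odds_ratio = or, ci_low = ci[1], ci_high = ci[2],
         ci_level = ci_level, p_fisher = fisher_exact(pooled$table),
         methods = c(or = "cross-product (Haldane-Anscombe on zero cells)",
                     ci = "Woolf log-normal", test = "Fisher exact, two-sided")),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("carrier frequency: %.2f%% cases vs %.2f%% controls\n",
              x$case_freq_pct, x$control_freq_pct))
  cat(sprintf("OR = %.1f; %d%% CI = %.1f-%.1f; Fisher p = %.2g\n",
              x$odds_ratio, round(100 * x$ci_level), x$ci_low, x$ci_high,
              x$p_fisher))
  invisible(x)
}
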