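#' Relative risk as observed-to-expected lift
#'
#' The multimorbidity-literature definition of relative risk for a condition
#' pair: `RR_ij = N * N_ij / (N_i * N_j)`, the ratio of the observed
#' co-occurrence count to the count expected under independence.
#'
#' @param N Cohort size.
#' @param N_i,N_j Marginal counts of the two conditions.
#' @param N_ij Co-occurrence count.
#' @return The lift; `NA` (degenerate) when a margin is zero.
#' @examples
#' relative_risk(100, 10, 20, 5)  # 2.5
#' @export
relative_risk <- function(N, N_i, N_j, N_ij) {
  # numeric coercion: N_i * N_j overflows 32-bit integers in large cohorts
  ifelse(N_i > 0 & N_j > 0,
         as.numeric(N) * N_ij / (as.numeric(N_i) * N_j), NA_real_)
}

#' Log-scale standard error of the lift (delta method)
#' @inheritParams relative_risk
#' @return SE of `log(RR)`; `NA` when undefined (`N_ij` = 0 or a boundary
#'   table with non-positive delta-method variance).
#' @export
rr_log_se <- function(N, N_i, N_j, N_ij) {
  v <- 1 / N_ij - 1 / N_i - 1 / N_j + 1 / N
  ifelse(N_ij > 0 & v > 0, sqrt(v), NA_real_)
}

#' Confidence interval for a pairwise relative risk
#'
#' Log-normal (Katz-style) interval `exp(log(est) +/- z * SE)`. Two
#' variants are available because the classical Katz interval targets the
#' conditional risk ratio rather than the lift:
#' \describe{
#'   \item{`"lift-delta"`}{(default) centres on the lift
#'     `N N_ij / (N_i N_j)` with delta-method SE
#'     `sqrt(1/N_ij - 1/N_i - 1/N_j + 1/N)`, so the point estimate and the
#'     interval share one estimand.}
#'   \item{`"katz-2x2"`}{the textbook Katz interval: centres on the
#'     conditional risk ratio `[a/(a+b)] / [c/(c+d)]` with SE
#'     `sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`, where `a = N_ij`,
#'     `b = N_i - N_ij`, `c = N_j - N_ij`, `d = N - N_i - N_j + N_ij`.}
#' }
#'
#' @inheritParams relative_risk
#' @param level Coverage level (default 0.99).
#' @param method `"lift-delta"` or `"katz-2x2"`.
#' @return Named vector `c(low, high)`; both `NA` when the interval is
#'   undefined (`N_ij` = 0 or an empty conditioning margin).
#' @export
rr_confidence_interval <- function(N, N_i, N_j, N_ij, level = 0.99,
                                   method = c("lift-delta", "katz-2x2")) {
  method <- match.arg(method)
  stopifnot(level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "lift-delta") {
    est <- relative_risk(N, N_i, N_j, N_ij)
    se <- rr_log_se(N, N_i, N_j, N_ij)
  } else {
    a <- N_ij; b <- N_i - N_ij; c_ <- N_j - N_ij
    d <- N - N_i - N_j + N_ij
    ok <- a > 0 & c_ > 0 & (a + b) > 0 & (c_ + d) > 0
    est <- ifelse(ok, (a / (a + b)) / (c_ / (c_ + d)), NA_real_)
    se <- ifelse(ok, sqrt(1 / a - 1 / (a + b) + 1 / c_ - 1 / (c_ + d)),
                 NA_real_)
  }
  c(low = exp(log(est) - z * se), high = exp(log(est) + z * se))
}

#' Fisher's exact test for a pair table
#'
#' Two-sided p-value at fixed margins: the sum of hypergeometric
#' probabilities of all tables no more probable than the observed one.
#'
#' @inheritParams relative_risk
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(N, N_i, N_j, N_ij) {
  a <- N_ij; b <- N_i - N_ij; c_ <- N_j - N_ij
  d <- N - N_i - N_j + N_ij
  stats::fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE))$p.value
}

#' Is a relative-risk estimate significant?
#' @param p_value Fisher two-sided p-value(s).
#' @param alpha Significance level (default 0.01, matching the 99% interval
#'   convention).
#' @return Logical flag(s).
#' @export
rr_significance <- function(p_value, alpha = 0.01) {
  !is.na(p_value) & p_value < alpha
}

#' Relative-risk estimates for all condition pairs
#'
#' @param tables Pair-count data frame from [pairwise_counts()].
#' @param level CI coverage level (default 0.99).
#' @param alpha Fisher significance level (default 0.01).
#' @param method CI method, see [rr_confidence_interval()].
#' @return The input pair table with columns `rr`, `ci_low`, `ci_high`,
#'   `p_value`, `significant`, `degenerate` appended. `degenerate` marks
#'   pairs whose estimate or interval is undefined (zero margin or
#'   `N_ij` = 0); such pairs are never flagged significant by the interval
#'   but keep their exact Fisher p-value.
#' @export
rr_estimates <- function(tables, level = 0.99, alpha = 0.01,
                         method = c("lift-delta", "katz-2x2")) {
  method <- match.arg(method)
  n <- nrow(tables)
  out <- tables
  out$rr <- relative_risk(tables$N, tables$N_i, tables$N_j, tables$N_ij)
  ci <- t(mapply(function(N, Ni, Nj, Nij)
    rr_confidence_interval(N, Ni, Nj, Nij, level = level, method = method),
    tables$N, tables$N_i, tables$N_j, tables$N_ij))
  out$ci_low <- ci[, 1L]
  out$ci_high <- ci[, 2L]
  out$p_value <- vapply(seq_len(n), function(k)
    fisher_exact(tables$N[k], tables$N_i[k], tables$N_j[k], tables$N_ij[k]),
    numeric(1L))
  out$degenerate <- is.na(out$rr) | is.na(out$ci_low)
  out$significant <- rr_significance(out$p_value, alpha) & !out$degenerate
  attr(out, "ci_level") <- level
  attr(out, "alpha") <- alpha
  attr(out, "ci_method") <- method
  out
}

#' Compare one pair's relative risk between two groups
#'
#' Two-sided normal test on the log-lift difference,
#' `z = (log RR_A - log RR_B) / sqrt(SE_A^2 + SE_B^2)` with the delta-method
#' SEs on the log scale.
#'
#' @param tableA,tableB One-row pair tables (list or data frame row with
#'   `N`, `N_i`, `N_j`, `N_ij`) from the two groups.
#' @return Two-sided p-value; `NA` when either estimate is degenerate.
#' @export
compare_rr_between_groups <- function(tableA, tableB) {
  rrA <- relative_risk(tableA$N, tableA$N_i, tableA$N_j, tableA$N_ij)
  rrB <- relative_risk(tableB$N, tableB$N_i, tableB$N_j, tableB$N_ij)
  seA <- rr_log_se(tableA$N, tableA$N_i, tableA$N_j, tableA$N_ij)
  seB <- rr_log_se(tableB$N, tableB$N_i, tableB$N_j, tableB$N_ij)
  if (anyNA(c(rrA, rrB, seA, seB)) || rrA <= 0 || rrB <= 0) {
    return(NA_real_)
  }
  z <- (log(rrA) - log(rrB)) / sqrt(seA^2 + seB^2)
  2 * stats::pnorm(-abs(z))
}
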