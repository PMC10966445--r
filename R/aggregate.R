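#' Average ABC association of each condition, with uncertainty
#'
#' For every posterior draw, the mean ABC of a condition over its `P - 1`
#' partners is computed, giving a full posterior distribution of the average
#' association; it is summarised by its median, interquartile range and 99%
#' equal-tailed credible interval. Unlike the relative-risk convention, no
#' significance masking is applied: the shrinkage prior already pulls
#' unsupported pairs towards 1.
#'
#' @param fit An `abc_fit`.
#' @param conditions Conditions to summarise (default: all in the fit).
#' @return Data frame with one row per condition: `median`, `q25`, `q75`,
#'   `ci_low`, `ci_high` (99%).
#' @export
average_association_abc <- function(fit, conditions = NULL) {
  if (is.null(conditions)) conditions <- fit$conditions
  if (length(fit$conditions) < 2L) stop("need at least 2 conditions")
  out <- lapply(conditions, function(cond) {
    k <- which(fit$pairs$cond_i == cond | fit$pairs$cond_j == cond)
    if (!length(k)) stop("condition not in fit: ", cond)
    per_draw <- rowMeans(fit$abc_draws[, k, drop = FALSE])
    q <- stats::quantile(per_draw, c(0.25, 0.5, 0.75), names = FALSE)
    ci <- equal_tailed_ci(per_draw, level = 0.99)
    data.frame(condition = cond, median = q[2L], q25 = q[1L], q75 = q[3L],
               ci_low = ci[["low"]], ci_high = ci[["high"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Average relative-risk association of each condition
#'
#' Arithmetic mean of a condition's pairwise relative risks over its
#' `P - 1` partners, where non-significant and degenerate pairs contribute
#' the independence value 1.
#'
#' @param estimates Data frame from [rr_estimates()].
#' @param conditions Conditions to summarise (default: all present).
#' @return Data frame with `condition` and `average_rr`.
#' @export
average_association_rr <- function(estimates, conditions = NULL) {
  if (is.null(conditions)) {
    conditions <- unique(c(estimates$cond_i, estimates$cond_j))
  }
  val <- ifelse(estimates$significant & !estimates$degenerate,
                estimates$rr, 1)
  data.frame(
    condition = conditions,
    average_rr = vapply(conditions, function(cond) {
      k <- estimates$cond_i == cond | estimates$cond_j == cond
      if (!any(k)) stop("condition not in estimates: ", cond)
      mean(val[k])
    }, numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Nonparametric bootstrap CI for relative-risk average associations
#'
#' Resamples patients with replacement, recomputes all pairwise relative
#' risks and their Fisher significance in each replicate, and averages with
#' the non-significant-pairs-contribute-1 convention; returns percentile
#' intervals of the replicate averages.
#'
#' @param cohort An `abc_cohort`.
#' @param conditions Conditions to summarise (default: all).
#' @param B Number of bootstrap replicates (>= 100).
#' @param level Percentile interval mass (default 0.99).
#' @param alpha Fisher significance level inside each replicate.
#' @param seed Seed; fixed seed gives identical intervals.
#' @return Data frame with `condition`, `average_rr` (observed-cohort
#'   value), `boot_low`, `boot_high`.
#' @export
bootstrap_rr_average <- function(cohort, conditions = NULL, B = 200L,
                                 level = 0.99, alpha = 0.01, seed = 1L) {
  stopifnot(B >= 100L)
  if (is.null(conditions)) conditions <- condition_names(cohort)
  N <- n_patients(cohort)
  reps <- with_seed(seed, {
    sapply(seq_len(B), function(b) {
      idx <- sample.int(N, N, replace = TRUE)
      coh_b <- suppressMessages(
        cohort(cohort$presence[idx, , drop = FALSE]))
      est <- rr_estimates(pairwise_counts(coh_b), alpha = alpha)
      average_association_rr(est, conditions)$average_rr
    })
  })
  if (is.null(dim(reps))) reps <- matrix(reps, nrow = 1L)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  obs <- average_association_rr(
    rr_estimates(pairwise_counts(cohort), alpha = alpha), conditions)
  data.frame(
    condition = conditions,
    average_rr = obs$average_rr,
    boot_low = apply(reps, 1L, stats::quantile, probs[1L], names = FALSE),
    boot_high = apply(reps, 1L, stats::quantile, probs[2L], names = FALSE),
    row.names = NULL, stringsAsFactors = FALSE)
}
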