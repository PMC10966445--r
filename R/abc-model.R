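#' Association Beyond Chance from model parameters
#'
#' ABC is the model-space analogue of the observed-to-expected lift: with
#' independent-factor rates `f_i`, `f_j` and a (signed) shared-mechanism
#' co-occurrence excess `f_ij`, `ABC = 1 + f_ij / (f_i * f_j)`. ABC = 1 means
#' the two conditions co-occur only by chance; values above 1 indicate common
#' mechanisms promoting co-occurrence, values below 1 negative association.
#'
#' @param f_i,f_j Independent-factor rates in (0, 1).
#' @param f_ij Shared co-occurrence excess (may be negative).
#' @return The ABC value `1 + f_ij / (f_i * f_j)`.
#' @examples
#' abc_from_params(0.1, 0.1, 0.01)  # 2: as much co-occurrence from shared
#'                                  # mechanisms as by chance
#' @export
abc_from_params <- function(f_i, f_j, f_ij) {
  if (any(f_i <= 0 | f_i >= 1) || any(f_j <= 0 | f_j >= 1)) {
    stop("f_i and f_j must lie strictly in (0, 1)")
  }
  1 + f_ij / (f_i * f_j)
}

#' Feasible range of the joint-occurrence probability
#'
#' Frechet bounds for `p11 = P(both conditions)` given marginals:
#' `max(0, f_i + f_j - 1) <= p11 <= min(f_i, f_j)`.
#'
#' @param f_i,f_j Marginal probabilities.
#' @return List with vectors `lo` and `hi`.
#' @export
p11_bounds <- function(f_i, f_j) {
  list(lo = pmax(0, f_i + f_j - 1), hi = pmin(f_i, f_j))
}

#' Sampler and prior settings for the ABC model
#'
#' Defaults follow the reference analysis: 4 chains by 5,000 retained draws
#' (20,000 total) after 1,000 warmup iterations per chain. The prior on each
#' pair's association is centred on ABC = 1 (no association); its scale is
#' either fixed via `sigma_abc` or given a half-normal hyperprior of scale
#' `sigma_abc_scale`. Independent-factor rates get a
#' `Beta(mu * kappa, (1 - mu) * kappa)` prior with weak hyperpriors on `mu`
#' (uniform) and `kappa` (half-normal, scale `kappa_scale`).
#'
#' @param chains Number of MCMC chains.
#' @param draws Retained draws per chain.
#' @param warmup Warmup (burn-in) iterations per chain.
#' @param adapt JAGS adaptation iterations per chain.
#' @param seed Integer seed; chain seeds are derived from it.
#' @param sigma_abc Fixed prior scale for the association parameter, or
#'   `NULL` (default) to place a half-normal hyperprior on it.
#' @param sigma_abc_scale Scale of the half-normal hyperprior on the
#'   association prior scale (default 0.5).
#' @param kappa_scale Scale of the half-normal hyperprior on the Beta
#'   concentration `kappa` (default 10).
#' @param rhat_threshold Split-R-hat above which [fit_abc()] warns.
#' @return An object of class `abc_model_spec`.
#' @export
abc_model_spec <- function(chains = 4L, draws = 5000L, warmup = 1000L,
                           adapt = 500L, seed = 1L, sigma_abc = NULL,
                           sigma_abc_scale = 0.5, kappa_scale = 10,
                           rhat_threshold = 1.05) {
  stopifnot(chains >= 1, draws >= 1, warmup >= 0,
            is.null(sigma_abc) || sigma_abc > 0,
            sigma_abc_scale > 0, kappa_scale > 0)
  structure(list(chains = as.integer(chains), draws = as.integer(draws),
                 warmup = as.integer(warmup), adapt = as.integer(adapt),
                 seed = as.integer(seed), sigma_abc = sigma_abc,
                 sigma_abc_scale = sigma_abc_scale,
                 kappa_scale = kappa_scale,
                 rhat_threshold = rhat_threshold),
            class = "abc_model_spec")
}

#' Joint composite log-likelihood of the ABC model
#'
#' Each pair contributes a multinomial likelihood over its four 2x2 cells
#' with `p11 = f_i * f_j * ABC_ij`, `p10 = f_i - p11`, `p01 = f_j - p11`,
#' `p00 = 1 - f_i - f_j + p11`; one `f_i` per condition is shared across all
#' of its pairs. Because each patient is reused across pairs, the product
#' over pairs is a composite likelihood. Returns `-Inf` outside the
#' feasibility bounds of any pair.
#'
#' @param f Vector of independent-factor rates, one per condition.
#' @param abc Vector of ABC values, one per row of `tables`.
#' @param tables Pair-count data frame from [pairwise_counts()].
#' @return Scalar composite log-likelihood.
#' @export
abc_log_likelihood <- function(f, abc, tables) {
  stopifnot(length(abc) == nrow(tables))
  ll <- 0
  for (k in seq_len(nrow(tables))) {
    fi <- f[tables$i[k]]; fj <- f[tables$j[k]]
    p11 <- fi * fj * abc[k]
    b <- p11_bounds(fi, fj)
    if (p11 < b$lo || p11 > b$hi) return(-Inf)
    p <- c(p11, fi - p11, fj - p11, 1 - fi - fj + p11)
    x <- c(tables$N_ij[k],
           tables$N_i[k] - tables$N_ij[k],
           tables$N_j[k] - tables$N_ij[k],
           tables$N[k] - tables$N_i[k] - tables$N_j[k] + tables$N_ij[k])
    if (any(p <= 0 & x > 0)) return(-Inf)
    ll <- ll + stats::dmultinom(x, prob = p, log = TRUE)
  }
  ll
}

# JAGS code for the joint model. The association parameter u[k] is an
# unconstrained variable mapped by an offset scaled-logistic onto the
# feasible p11 interval; u = 0 maps exactly to p11 = f_i f_j (ABC = 1), so
# the Normal(0, sigma) prior is centred on no-association for every pair,
# and for low-prevalence pairs u is approximately log ABC. The tiny eps
# margin keeps all four cell probabilities strictly positive.
abc_jags_code <- function(fixed_sigma) {
  paste0("
model {
  mu ~ dunif(0, 1)
  kappa ~ dnorm(0, kappa_prec) T(0.001,)
", if (fixed_sigma) "" else
"  sigma ~ dnorm(0, sigma_prec) T(1e-4,)
  tau <- 1 / (sigma * sigma)
", "
  for (i in 1:P) {
    f[i] ~ dbeta(mu * kappa + 0.001, (1 - mu) * kappa + 0.001)
  }
  for (k in 1:K) {
    u[k] ~ dnorm(0, tau)
    lo[k] <- max(0, f[pi[k]] + f[pj[k]] - 1)
    hi[k] <- min(f[pi[k]], f[pj[k]])
    m[k] <- f[pi[k]] * f[pj[k]]
    off[k] <- logit((m[k] - lo[k]) / (hi[k] - lo[k]))
    p11[k] <- lo[k] + (hi[k] - lo[k]) *
              (1e-9 + (1 - 2e-9) * ilogit(u[k] + off[k]))
    ABC[k] <- p11[k] / m[k]
    p[k, 1] <- p11[k]
    p[k, 2] <- f[pi[k]] - p11[k]
    p[k, 3] <- f[pj[k]] - p11[k]
    p[k, 4] <- 1 - f[pi[k]] - f[pj[k]] + p11[k]
    x[k, 1:4] ~ dmulti(p[k, 1:4], N)
  }
}")
}

#' Fit the ABC joint model by MCMC
#'
#' Builds the joint model over all condition pairs of a cohort — one shared
#' independent-factor rate `f_i` per condition, one association parameter
#' per pair with a shrinkage prior centred on ABC = 1 — and samples its
#' posterior with JAGS. Conditions with zero prevalence are dropped from the
#' model (their rate is unidentifiable) with a message.
#'
#' @param cohort An `abc_cohort`, or a pair-count data frame from
#'   [pairwise_counts()].
#' @param spec An [abc_model_spec()].
#' @return An object of class `abc_fit` with elements:
#'   \describe{
#'     \item{`f_draws`}{matrix of posterior draws of `f_i` (draws x P).}
#'     \item{`abc_draws`}{matrix of posterior draws of `ABC_ij`
#'       (draws x pairs), columns named `"A|B"`.}
#'     \item{`pairs`}{pair index table with condition names.}
#'     \item{`summaries`}{per-pair data frame: `mode` (HPDI midpoint),
#'       `ci_low`, `ci_high` (99% equal-tailed), `significant`.}
#'     \item{`diagnostics`}{list with per-parameter split `rhat`,
#'       effective sample sizes `ess`, and `n_draws`.}
#'   }
#' @export
fit_abc <- function(cohort, spec = abc_model_spec()) {
  if (inherits(cohort, "abc_cohort")) {
    prev <- colSums(cohort$presence)
    if (any(prev == 0L)) {
      drop <- colnames(cohort$presence)[prev == 0L]
      message("dropping zero-prevalence conditions from the model: ",
              paste(drop, collapse = ", "))
      cohort <- suppressMessages(
        cohort(cohort$presence[, prev > 0L, drop = FALSE],
               strata = cohort$strata))
    }
    tables <- pairwise_counts(cohort)
    conditions <- condition_names(cohort)
  } else {
    tables <- cohort
    conditions <- unique(c(tables$cond_i, tables$cond_j))
  }
  if (length(unique(tables$N)) != 1L) {
    stop("inconsistent cohort size N across pair tables")
  }
  N <- tables$N[1L]
  P <- length(conditions)
  K <- nrow(tables)
  fixed_sigma <- !is.null(spec$sigma_abc)

  cells <- pair_cells(tables)
  dat <- list(P = P, K = K, N = N, pi = tables$i, pj = tables$j,
              x = cbind(cells$a, cells$b, cells$c, cells$d),
              kappa_prec = 1 / spec$kappa_scale^2)
  if (fixed_sigma) {
    dat$tau <- 1 / spec$sigma_abc^2
  } else {
    dat$sigma_prec <- 1 / spec$sigma_abc_scale^2
  }
  inits <- lapply(seq_len(spec$chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = spec$seed * 100L + ch))
  monitors <- c("f", "ABC", "mu", "kappa",
                if (!fixed_sigma) "sigma")
  jm <- rjags::jags.model(textConnection(abc_jags_code(fixed_sigma)),
                          data = dat, inits = inits,
                          n.chains = spec$chains, n.adapt = spec$adapt,
                          quiet = TRUE)
  if (spec$warmup > 0) stats::update(jm, spec$warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, monitors, n.iter = spec$draws,
                              progress.bar = "none")

  draws <- do.call(rbind, lapply(samp, as.matrix))
  f_draws <- draws[, sprintf("f[%d]", seq_len(P)), drop = FALSE]
  colnames(f_draws) <- conditions
  # coda drops the index on length-1 monitored vectors
  abc_cols <- if (K == 1L) "ABC" else sprintf("ABC[%d]", seq_len(K))
  abc_draws <- draws[, abc_cols, drop = FALSE]
  colnames(abc_draws) <- paste(tables$cond_i, tables$cond_j, sep = "|")

  summaries <- tables[c("i", "j", "cond_i", "cond_j",
                        "N", "N_i", "N_j", "N_ij")]
  summaries$mode <- apply(abc_draws, 2L, hpdi_mode)
  ci <- apply(abc_draws, 2L, equal_tailed_ci, level = 0.99)
  summaries$ci_low <- ci[1L, ]
  summaries$ci_high <- ci[2L, ]
  summaries$significant <- abc_significance(summaries$ci_low,
                                            summaries$ci_high)

  rhat <- tryCatch({
    if (spec$chains >= 2L) {
      coda::gelman.diag(samp, multivariate = FALSE,
                        autoburnin = FALSE)$psrf[, 1L]
    } else NULL
  }, error = function(e) NULL)
  ess <- coda::effectiveSize(samp)
  if (!is.null(rhat) && any(rhat > spec$rhat_threshold, na.rm = TRUE)) {
    warning(sprintf(
      "possible non-convergence: max split-Rhat %.3f (threshold %.2f)",
      max(rhat, na.rm = TRUE), spec$rhat_threshold))
  }
  structure(list(f_draws = f_draws, abc_draws = abc_draws,
                 pairs = tables, summaries = summaries,
                 conditions = conditions,
                 hyper_draws = draws[, intersect(colnames(draws),
                                                 c("mu", "kappa", "sigma")),
                                     drop = FALSE],
                 diagnostics = list(rhat = rhat, ess = ess,
                                    n_draws = nrow(draws)),
                 spec = spec),
            class = "abc_fit")
}

#' @export
print.abc_fit <- function(x, ...) {
  cat(sprintf("<abc_fit> %d conditions, %d pairs, %d posterior draws\n",
              length(x$conditions), nrow(x$pairs),
              x$diagnostics$n_draws))
  cat(sprintf("significant pairs (99%% CrI excludes 1): %d of %d\n",
              sum(x$summaries$significant), nrow(x$summaries)))
  if (!is.null(x$diagnostics$rhat)) {
    cat(sprintf("max split-Rhat: %.3f; min ESS: %.0f\n",
                max(x$diagnostics$rhat, na.rm = TRUE),
                min(x$diagnostics$ess)))
  }
  invisible(x)
}

#' Posterior draws for one pair
#' @param fit An `abc_fit`.
#' @param cond_i,cond_j Condition names (order-free).
#' @return Numeric vector of ABC posterior draws for that pair.
#' @export
abc_pair_draws <- function(fit, cond_i, cond_j) {
  key1 <- paste(cond_i, cond_j, sep = "|")
  key2 <- paste(cond_j, cond_i, sep = "|")
  hit <- intersect(c(key1, key2), colnames(fit$abc_draws))
  if (!length(hit)) stop("pair not in fit: ", key1)
  fit$abc_draws[, hit[1L]]
}

#' Write posterior draws and pair summaries to disk
#' @param fit An `abc_fit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Writes `abc_draws.csv` (columns `f[...]` and
#'   `ABC[...|...]`), `abc_summaries.csv` and `abc_diagnostics.json`.
#' @export
write_abc_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  draws <- cbind(fit$f_draws, fit$abc_draws)
  colnames(draws) <- c(sprintf("f[%s]", colnames(fit$f_draws)),
                       sprintf("ABC[%s]", colnames(fit$abc_draws)))
  utils::write.csv(draws, file.path(dir, "abc_draws.csv"),
                   row.names = FALSE)
  utils::write.csv(fit$summaries, file.path(dir, "abc_summaries.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(rhat = as.list(fit$diagnostics$rhat),
         ess = as.list(fit$diagnostics$ess),
         n_draws = fit$diagnostics$n_draws),
    file.path(dir, "abc_diagnostics.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
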