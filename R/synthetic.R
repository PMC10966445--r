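# Run code under a temporary RNG state so generators are reproducible
# without disturbing the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# P(Z1 > a, Z2 > b) for standard bivariate normal with correlation rho,
# by 1-D conditioning: integral over x > a of phi(x) * Phi((rho x - b)/s).
bvn_upper_orthant <- function(a, b, rho) {
  if (abs(rho) >= 1 - 1e-12) {
    if (rho > 0) return(1 - stats::pnorm(max(a, b)))
    return(max(0, stats::pnorm(-b) - stats::pnorm(a)))
  }
  s <- sqrt(1 - rho^2)
  stats::integrate(function(x)
    stats::dnorm(x) * stats::pnorm((rho * x - b) / s),
    lower = a, upper = Inf, rel.tol = 1e-10)$value
}

#' Define a ground-truth association structure for synthetic cohorts
#'
#' Two generative modes are available, reporting their implied truth through
#' one interface:
#' \describe{
#'   \item{`"trigger"`}{each patient acquires condition `i` from an
#'     independent trigger (`Bernoulli(g_i)`) or from a shared trigger of
#'     any of its associated pairs (`Bernoulli(s_ij)` sets both conditions).
#'     This mechanism story only produces lifts >= 1.}
#'   \item{`"copula"`}{a latent correlated Gaussian vector is thresholded at
#'     per-condition quantiles; negative latent correlations give lifts
#'     below 1 (negative associations).}
#' }
#' In both modes the per-pair parameter (`s_ij` or `rho_ij`) is calibrated
#' so the implied lift `P(i,j) / (pi_i * pi_j)` matches the requested target
#' while per-condition marginals stay at `prevalences`.
#'
#' @param P Number of conditions.
#' @param prevalence_range Range from which marginal prevalences are drawn
#'   log-uniformly when `prevalences` is not supplied (default emulates the
#'   heterogeneity of primary-care LTC panels, 0.1%-45%).
#' @param assoc Data frame with columns `i`, `j`, `lift`: the pairs carrying
#'   a planted association and their target lifts. Pairs not listed have
#'   lift 1. May be empty (the default).
#' @param mode `"trigger"` or `"copula"`.
#' @param prevalences Optional vector of target marginals (length `P`).
#' @param labels Optional condition names (default `C1..CP`).
#' @param seed Seed for the prevalence draw.
#' @return An object of class `abc_truth` with the generator parameters
#'   (`g` and `s`, or `rho` and thresholds) and the implied truth
#'   (see [implied_truth()]).
#' @export
generate_truth <- function(P, prevalence_range = c(0.001, 0.45),
                           assoc = NULL, mode = c("trigger", "copula"),
                           prevalences = NULL, labels = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(P >= 2)
  if (is.null(labels)) labels <- sprintf("C%d", seq_len(P))
  if (is.null(prevalences)) {
    stopifnot(length(prevalence_range) == 2L,
              all(prevalence_range > 0), all(prevalence_range < 1))
    prevalences <- with_seed(seed,
      exp(stats::runif(P, log(prevalence_range[1L]),
                       log(prevalence_range[2L]))))
  }
  stopifnot(length(prevalences) == P,
            all(prevalences > 0), all(prevalences < 1))
  if (is.null(assoc)) {
    assoc <- data.frame(i = integer(), j = integer(), lift = numeric())
  }
  stopifnot(all(c("i", "j", "lift") %in% names(assoc)))
  if (nrow(assoc)) {
    swap <- assoc$i > assoc$j
    tmp <- assoc$i[swap]; assoc$i[swap] <- assoc$j[swap]; assoc$j[swap] <- tmp
    stopifnot(all(assoc$i >= 1), all(assoc$j <= P), all(assoc$i < assoc$j),
              all(assoc$lift > 0), !anyDuplicated(assoc[c("i", "j")]))
  }
  pi_ <- prevalences

  # feasibility of each target joint probability (Frechet bounds)
  for (r in seq_len(nrow(assoc))) {
    p11 <- assoc$lift[r] * pi_[assoc$i[r]] * pi_[assoc$j[r]]
    b <- p11_bounds(pi_[assoc$i[r]], pi_[assoc$j[r]])
    if (p11 > b$hi + 1e-12 || p11 < b$lo - 1e-12) {
      stop(sprintf("infeasible target: lift %.3g for pair (%d,%d) %s",
                   assoc$lift[r], assoc$i[r], assoc$j[r],
                   "forces p11 outside the feasible interval"))
    }
  }

  truth <- list(mode = mode, P = P, labels = labels, pi = pi_,
                assoc = assoc, seed = seed)
  if (mode == "trigger") {
    if (any(assoc$lift < 1)) {
      stop("trigger mode cannot produce lifts below 1; use mode = \"copula\"")
    }
    s <- matrix(0, P, P)
    for (r in seq_len(nrow(assoc))) {
      i <- assoc$i[r]; j <- assoc$j[r]; L <- assoc$lift[r]
      # with marginal-preserving g, the implied lift depends only on s_ij:
      # lift = [pi_i + pi_j - 1 + (1-pi_i)(1-pi_j)/(1-s)] / (pi_i pi_j)
      denom <- L * pi_[i] * pi_[j] - pi_[i] - pi_[j] + 1
      if (denom <= 0) stop("infeasible trigger-mode target lift")
      s[i, j] <- s[j, i] <- 1 - (1 - pi_[i]) * (1 - pi_[j]) / denom
    }
    keep <- apply(s, 1L, function(r) prod(1 - r))
    if (any(keep < 1 - pi_ - 1e-12)) {
      stop("shared triggers alone exceed a target marginal; infeasible")
    }
    truth$s <- s
    truth$g <- 1 - (1 - pi_) / keep
  } else {
    thr <- stats::qnorm(1 - pi_)
    rho <- diag(P)
    for (r in seq_len(nrow(assoc))) {
      i <- assoc$i[r]; j <- assoc$j[r]; L <- assoc$lift[r]
      target <- L * pi_[i] * pi_[j]
      fr <- function(x) bvn_upper_orthant(thr[i], thr[j], x) - target
      rho[i, j] <- rho[j, i] <-
        stats::uniroot(fr, c(-0.99999, 0.99999), tol = 1e-9)$root
    }
    if (min(eigen(rho, symmetric = TRUE, only.values = TRUE)$values) <
        -1e-8) {
      stop("requested association pattern gives a non-positive-definite ",
           "latent correlation matrix")
    }
    truth$rho <- rho
    truth$thresholds <- thr
  }
  truth$implied <- implied_truth_(truth)
  class(truth) <- "abc_truth"
  truth
}

#' Build a trigger-mode truth directly from rates
#'
#' Low-level constructor: supply the independent trigger rates `g` and the
#' symmetric shared-trigger rate matrix `s` directly instead of calibrating
#' them to target lifts.
#'
#' @param g Vector of independent trigger rates in \[0, 1).
#' @param s Symmetric P x P matrix of shared trigger rates (zero diagonal).
#' @param labels Optional condition names.
#' @return An `abc_truth` (trigger mode) with its implied truth.
#' @export
trigger_truth <- function(g, s, labels = NULL) {
  P <- length(g)
  stopifnot(P >= 2, all(g >= 0), all(g < 1),
            is.matrix(s), all(dim(s) == P), isSymmetric(s),
            all(s >= 0), all(s < 1), all(diag(s) == 0))
  if (is.null(labels)) labels <- sprintf("C%d", seq_len(P))
  idx <- which(upper.tri(s) & s > 0, arr.ind = TRUE)
  truth <- structure(
    list(mode = "trigger", P = P, labels = labels, pi = NULL,
         assoc = data.frame(i = idx[, 1L], j = idx[, 2L],
                            lift = rep(NA_real_, nrow(idx))),
         g = g, s = s, seed = NA_integer_),
    class = "abc_truth")
  truth$implied <- implied_truth_(truth)
  truth$pi <- truth$implied$pi
  truth
}

#' Build a copula-mode truth directly from correlations
#'
#' @param prevalences Marginal prevalences in (0, 1).
#' @param rho Latent correlation matrix (positive semi-definite).
#' @param labels Optional condition names.
#' @return An `abc_truth` (copula mode) with its implied truth.
#' @export
copula_truth <- function(prevalences, rho, labels = NULL) {
  P <- length(prevalences)
  stopifnot(P >= 2, all(prevalences > 0), all(prevalences < 1),
            is.matrix(rho), all(dim(rho) == P), isSymmetric(rho),
            all(diag(rho) == 1))
  if (min(eigen(rho, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8) {
    stop("rho is not positive semi-definite")
  }
  if (is.null(labels)) labels <- sprintf("C%d", seq_len(P))
  idx <- which(upper.tri(rho) & rho != 0, arr.ind = TRUE)
  truth <- structure(
    list(mode = "copula", P = P, labels = labels, pi = prevalences,
         assoc = data.frame(i = idx[, 1L], j = idx[, 2L],
                            lift = rep(NA_real_, nrow(idx))),
         rho = rho, thresholds = stats::qnorm(1 - prevalences),
         seed = NA_integer_),
    class = "abc_truth")
  truth$implied <- implied_truth_(truth)
  truth
}

# internal: closed-form marginals, joints and lifts from generator params
implied_truth_ <- function(truth) {
  P <- truth$P
  joint <- matrix(NA_real_, P, P)
  if (truth$mode == "trigger") {
    g <- truth$g; s <- truth$s
    p_abs <- (1 - g) * apply(s, 1L, function(r) prod(1 - r))
    pi_ <- 1 - p_abs
    for (i in seq_len(P - 1L)) for (j in seq.int(i + 1L, P)) {
      others_i <- prod(1 - s[i, -c(i, j)])
      others_j <- prod(1 - s[j, -c(i, j)])
      both_abs <- (1 - g[i]) * (1 - g[j]) * (1 - s[i, j]) *
        others_i * others_j
      joint[i, j] <- joint[j, i] <- 1 - p_abs[i] - p_abs[j] + both_abs
    }
  } else {
    thr <- truth$thresholds
    pi_ <- 1 - stats::pnorm(thr)
    for (i in seq_len(P - 1L)) for (j in seq.int(i + 1L, P)) {
      joint[i, j] <- joint[j, i] <-
        bvn_upper_orthant(thr[i], thr[j], truth$rho[i, j])
    }
  }
  lift <- joint / outer(pi_, pi_)
  diag(lift) <- NA_real_
  list(pi = pi_, joint = joint, lift = lift)
}

#' Implied marginals and lifts of a generator truth
#'
#' Closed forms: in trigger mode, a condition is absent iff its independent
#' trigger and every shared trigger involving it are silent, giving
#' `P(i absent) = (1 - g_i) prod_k (1 - s_ik)` and the pair-absence product
#' form; joint presence follows by inclusion-exclusion. In copula mode the
#' joint is a bivariate-normal upper-orthant probability.
#'
#' @param truth An `abc_truth`.
#' @return List with `pi` (implied marginals), `joint` (P x P joint
#'   presence probabilities) and `lift` (P x P implied lifts).
#' @export
implied_truth <- function(truth) {
  stopifnot(inherits(truth, "abc_truth"))
  truth$implied
}

#' @export
print.abc_truth <- function(x, ...) {
  cat(sprintf("<abc_truth> mode=%s, %d conditions, %d planted pairs\n",
              x$mode, x$P, nrow(x$assoc)))
  cat("implied prevalences:",
      paste(sprintf("%.3g", x$implied$pi), collapse = " "), "\n")
  if (nrow(x$assoc)) {
    L <- x$implied$lift[cbind(x$assoc$i, x$assoc$j)]
    cat("planted lifts (target -> implied):",
        paste(sprintf("%.3g->%.4g", x$assoc$lift, L), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Simulate a binary cohort from a generator truth
#'
#' @param truth An `abc_truth` from [generate_truth()].
#' @param N Number of patients.
#' @param seed Seed; the same `(truth, N, seed)` always yields the same
#'   cohort.
#' @return An `abc_cohort`.
#' @export
generate_cohort <- function(truth, N, seed = 1L) {
  stopifnot(inherits(truth, "abc_truth"), N >= 1)
  P <- truth$P
  X <- with_seed(seed, {
    if (truth$mode == "trigger") {
      M <- matrix(stats::rbinom(N * P, 1L, rep(truth$g, each = N)), N, P)
      for (r in seq_len(nrow(truth$assoc))) {
        i <- truth$assoc$i[r]; j <- truth$assoc$j[r]
        sh <- stats::rbinom(N, 1L, truth$s[i, j])
        M[, i] <- pmax(M[, i], sh)
        M[, j] <- pmax(M[, j], sh)
      }
      M
    } else {
      Z <- matrix(stats::rnorm(N * P), N, P) %*% chol(truth$rho)
      matrix(as.integer(Z > rep(truth$thresholds, each = N)), N, P)
    }
  })
  colnames(X) <- truth$labels
  suppressMessages(cohort(X))
}

#' Write a generator truth as JSON
#' @param truth An `abc_truth`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- list(mode = truth$mode, P = truth$P, labels = truth$labels,
              target_prevalence = truth$pi, assoc = truth$assoc,
              implied = list(pi = truth$implied$pi,
                             lift = truth$implied$lift))
  if (truth$mode == "trigger") {
    out$g <- truth$g; out$s <- truth$s
  } else {
    out$rho <- truth$rho
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}
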