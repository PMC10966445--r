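# Small in-code fixtures shared across test files.

# 5-patient cohort: A on rows 1-3, B on rows 3-5 -> N_A = N_B = 3, N_AB = 1
fixture_ab <- function() {
  cohort(cbind(A = c(1L, 1L, 1L, 0L, 0L),
               B = c(0L, 0L, 1L, 1L, 1L)))
}

# random binary cohort with heterogeneous prevalences
fixture_random_cohort <- function(n, p, rng_seed, strata = NULL) {
  set.seed(rng_seed)
  prev <- runif(p, 0.05, 0.6)
  X <- sapply(prev, function(q) rbinom(n, 1L, q))
  colnames(X) <- sprintf("C%d", seq_len(p))
  suppressMessages(cohort(X, strata = strata))
}

# one-row pair table as a list (the shape compare_rr_between_groups takes)
pair_table <- function(N, N_i, N_j, N_ij) {
  list(N = N, N_i = N_i, N_j = N_j, N_ij = N_ij)
}

# single-pair pair-count data frame, for fitting the ABC model directly
# from counts (e.g. the rare-pair shrinkage fixture)
single_pair_tables <- function(N, N_i, N_j, N_ij,
                               labels = c("A", "B")) {
  data.frame(i = 1L, j = 2L, cond_i = labels[1L], cond_j = labels[2L],
             N = N, N_i = N_i, N_j = N_j, N_ij = N_ij,
             stringsAsFactors = FALSE)
}

# fast small-footprint sampler settings for unit tests
quick_spec <- function(seed = 1L, ...) {
  abc_model_spec(chains = 2L, draws = 1500L, warmup = 600L, adapt = 400L,
                 seed = seed, ...)
}

# minimal hand-built abc_fit carrying given ABC draws (for aggregation
# tests that need exact control over the posterior)
fake_abc_fit <- function(abc_draws, pairs) {
  conditions <- unique(c(pairs$cond_i, pairs$cond_j))
  colnames(abc_draws) <- paste(pairs$cond_i, pairs$cond_j, sep = "|")
  structure(list(abc_draws = abc_draws, pairs = pairs,
                 conditions = conditions),
            class = "abc_fit")
}
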