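# MCMC behaviour of the joint ABC fit. Sampler settings are kept small
# (2 chains x 1500 draws) so each fit runs in about a second; posterior
# tolerances below are set accordingly.

test_that("posterior recovers a planted association at N = 10,000", {
  truth <- generate_truth(2, prevalences = c(0.2, 0.2),
                          assoc = data.frame(i = 1, j = 2, lift = 2),
                          mode = "trigger")
  coh <- generate_cohort(truth, 10000, seed = 101)
  fit <- fit_abc(coh, quick_spec(seed = 5))
  expect_gt(fit$summaries$mode, 1.8)
  expect_lt(fit$summaries$mode, 2.2)
  expect_true(fit$summaries$significant)
})

test_that("identical seeds give identical draws", {
  coh <- fixture_random_cohort(2000, 3, rng_seed = 55)
  spec <- abc_model_spec(chains = 1L, draws = 300L, warmup = 200L,
                         adapt = 200L, seed = 9)
  f1 <- fit_abc(coh, spec)
  f2 <- fit_abc(coh, spec)
  expect_identical(f1$abc_draws, f2$abc_draws)
  expect_identical(f1$f_draws, f2$f_draws)
  f3 <- fit_abc(coh, abc_model_spec(chains = 1L, draws = 300L,
                                    warmup = 200L, adapt = 200L, seed = 10))
  expect_false(identical(f1$abc_draws, f3$abc_draws))
})

test_that("a rare pair is shrunk towards no-association", {
  # prevalences 0.005 at N = 10,000, two co-occurrences: the lift is 8 but
  # the evidence is two patients
  tab <- single_pair_tables(10000, 50, 50, 2)
  fit <- fit_abc(tab, abc_model_spec(chains = 4L, draws = 2500L,
                                     warmup = 1000L, adapt = 500L,
                                     seed = 2))
  rr <- relative_risk(10000, 50, 50, 2)
  expect_equal(rr, 8)
  expect_lte(fit$summaries$ci_low, 1)   # 99% CrI contains 1
  expect_gte(fit$summaries$ci_high, 1)
  expect_lt(fit$summaries$mode, rr)     # shrunk towards 1
})

test_that("widening the prior moves the mode towards the empirical lift", {
  tab <- single_pair_tables(2000, 160, 140, 22)  # lift ~ 1.96
  lift <- relative_risk(2000, 160, 140, 22)
  modes <- vapply(c(0.05, 0.5, 5), function(sig) {
    fit_abc(tab, quick_spec(seed = 3, sigma_abc = sig))$summaries$mode
  }, numeric(1))
  expect_true(all(diff(modes) > 0))             # monotone in sigma
  expect_true(all(diff(abs(modes - lift)) < 0)) # approaching the lift
  expect_lt(abs(modes[1] - 1), 0.1)             # narrow prior pins ABC at 1
})

test_that("well-populated pairs reach the empirical lift (wide prior)", {
  tab <- single_pair_tables(10000, 2000, 1500, 500)  # all cells >= 100
  fit <- fit_abc(tab, quick_spec(seed = 4, sigma_abc = 5))
  lift <- relative_risk(10000, 2000, 1500, 500)
  expect_lt(abs(fit$summaries$mode - lift) / lift, 0.05)
})

test_that("every retained draw respects the feasibility bounds", {
  coh <- fixture_random_cohort(500, 4, rng_seed = 77)
  fit <- fit_abc(coh, quick_spec(seed = 6))
  for (k in seq_len(nrow(fit$pairs))) {
    fi <- fit$f_draws[, fit$pairs$i[k]]
    fj <- fit$f_draws[, fit$pairs$j[k]]
    p11 <- fi * fj * fit$abc_draws[, k]
    expect_true(all(p11 >= pmax(0, fi + fj - 1) - 1e-12))
    expect_true(all(p11 <= pmin(fi, fj) + 1e-12))
  }
  expect_true(all(fit$f_draws > 0 & fit$f_draws < 1))
  expect_true(all(fit$abc_draws > 0))
})

test_that("inference is symmetric under condition relabelling", {
  truth <- generate_truth(2, prevalences = c(0.25, 0.15),
                          assoc = data.frame(i = 1, j = 2, lift = 1.8),
                          mode = "trigger")
  coh <- generate_cohort(truth, 8000, seed = 12)
  swapped <- cohort(coh$presence[, c(2, 1)])
  fit1 <- fit_abc(coh, quick_spec(seed = 7))
  fit2 <- fit_abc(swapped, quick_spec(seed = 7))
  expect_equal(fit1$summaries$mode, fit2$summaries$mode, tolerance = 0.03)
  expect_equal(fit1$summaries$significant, fit2$summaries$significant)
})

test_that("zero-prevalence conditions are dropped with a notice", {
  X <- cbind(A = rbinom(300, 1, 0.3), B = rbinom(300, 1, 0.2),
             C = 0L)
  coh <- suppressMessages(cohort(X))
  expect_message(fit <- fit_abc(coh, quick_spec(seed = 8)),
                 "zero-prevalence")
  expect_equal(fit$conditions, c("A", "B"))
  expect_equal(nrow(fit$pairs), 1L)
})

test_that("summaries and persisted draws are internally consistent", {
  coh <- fixture_random_cohort(1500, 3, rng_seed = 91)
  fit <- fit_abc(coh, quick_spec(seed = 11, sigma_abc = 0.5))
  s <- fit$summaries
  expect_true(all(s$ci_low <= s$mode & s$mode <= s$ci_high))
  expect_equal(s$mode, apply(fit$abc_draws, 2, hpdi_mode),
               ignore_attr = TRUE)
  expect_equal(s$significant, abc_significance(s$ci_low, s$ci_high))
  expect_equal(fit$diagnostics$n_draws,
               fit$spec$chains * fit$spec$draws)
  expect_false(is.null(fit$diagnostics$rhat))

  dir <- withr::local_tempdir()
  write_abc_fit(fit, dir)
  back <- read.csv(file.path(dir, "abc_draws.csv"), check.names = FALSE)
  expect_equal(nrow(back), fit$diagnostics$n_draws)
  expect_equal(unname(back[["ABC[C1|C2]"]]), unname(fit$abc_draws[, 1]))
})
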