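# multiabc

Robust estimation of pairwise associations between long-term conditions
(LTCs) from binary patient-by-condition cohort data, for multimorbidity
research: epidemiologists and health-data scientists who need association
networks and per-condition summaries that do not fall apart when condition
counts are low.

## What it computes

The standard association measure in this literature is the
observed-to-expected lift, usually called relative risk:

```
RR_ij = N * N_ij / (N_i * N_j)
```

where `N` is the cohort size, `N_i`, `N_j` the marginal condition counts
and `N_ij` the co-occurrence count. The lift is noisy and upward-biased
exactly where the interesting questions live — rare conditions and small
subgroups.

The package's core estimator, **Association Beyond Chance (ABC)**, is a
hierarchical Bayesian joint model. Each condition carries an
independent-factor rate `f_i`, each pair a shared-mechanism co-occurrence
excess `f_ij`, and

```
ABC_ij = 1 + f_ij / (f_i * f_j),        p11 = f_i * f_j * ABC_ij
```

so `ABC = 1` is independence, `ABC = 2` means shared mechanisms contribute
as much co-occurrence as chance, and `ABC < 1` is a negative association.
Each pair contributes a multinomial likelihood over its 2x2 cells with a
single `f_i` per condition shared across all of its pairs, and the prior
on every pair's association is centred on `ABC = 1`, so weakly supported
associations are shrunk towards no-association instead of being reported
as spuriously strong. The posterior is sampled by MCMC (JAGS); pairs are
summarised by the HPDI-midpoint mode and 99% equal-tailed credible
intervals, and a pair is significant when its CrI excludes 1.

Around the two estimators the package provides: Fisher's exact tests and
Katz-style 99% CIs for the lift, significance-filtered association
networks with Clauset-Newman-Moore community detection and
modularity/coverage/performance scores, per-condition average associations
with full uncertainty propagation (and a bootstrap for the RR variant),
posterior-overlap comparison of strata, and a synthetic cohort generator
with exactly known ground truth (trigger and Gaussian-copula modes).

## Worked example

Plant three known associations (lifts 0.5, 2 and 4) in a synthetic
6-condition cohort and recover them:

```r
library(multiabc)

truth <- generate_truth(
  6, prevalences = c(0.30, 0.25, 0.20, 0.15, 0.10, 0.08),
  assoc = data.frame(i = c(1, 3, 5), j = c(2, 4, 6),
                     lift = c(0.5, 2, 4)),
  mode = "copula")
coh <- generate_cohort(truth, N = 10000, seed = 42)
fit <- fit_abc(coh, abc_model_spec(chains = 4, draws = 1000,
                                   warmup = 500, seed = 1))
fit
#> <abc_fit> 6 conditions, 15 pairs, 4000 posterior draws
#> significant pairs (99% CrI excludes 1): 3 of 15
#> max split-Rhat: 1.004; min ESS: 1734

subset(fit$summaries, significant,
       select = c(cond_i, cond_j, N_ij, mode, ci_low, ci_high))
#>    cond_i cond_j N_ij      mode    ci_low   ci_high
#> 1      C1     C2  378 0.5102791 0.4509961 0.5712168
#> 10     C3     C4  633 2.0291265 1.8753124 2.1384871
#> 15     C5     C6  296 3.9762527 3.5398172 4.3727290
```

Exactly the three planted pairs are called significant, with modes close
to the true lifts 0.5, 2 and 4, and all twelve independent pairs
correctly retain `ABC = 1` in their intervals.

The caution property for sparse evidence — a pair with prevalences 0.5%
and only two co-occurring patients in 10,000:

```r
rare <- data.frame(i = 1L, j = 2L, cond_i = "A", cond_j = "B",
                   N = 10000L, N_i = 50L, N_j = 50L, N_ij = 2L)
fit_rare <- fit_abc(rare, abc_model_spec(chains = 4, draws = 2500,
                                         warmup = 1000, seed = 5))
relative_risk(10000, 50, 50, 2)
#> [1] 8
round(fit_rare$summaries[, c("mode", "ci_low", "ci_high", "significant")], 3)
#>    mode ci_low ci_high significant
#> 1 0.999   0.45   11.52           0
```

The lift claims an eight-fold association from two patients; ABC reports
a mode at 1 with a wide interval and no significance call.

Networks and cluster quality:

```r
net <- build_network(fit$summaries, fit$conditions, measure = "ABC")
partition_quality(net, detect_communities(net))
#> $modularity
#> [1] 0.6666667
#> $coverage
#> [1] 1
#> $performance
#> [1] 1
```

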