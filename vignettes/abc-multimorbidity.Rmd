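---
title: "Association Beyond Chance: robust pairwise association analysis for multimorbidity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Association Beyond Chance: robust pairwise association analysis for multimorbidity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multimorbidity research routinely asks whether two long-term conditions
(LTCs) co-occur more often than chance would predict. The standard measure
is the observed-to-expected lift, usually called relative risk in this
literature: for conditions $i$ and $j$ in a cohort of $N$ patients with
marginal counts $N_i$, $N_j$ and co-occurrence count $N_{ij}$,

$$RR_{ij} = \frac{N\,N_{ij}}{N_i\,N_j}.$$

The lift misbehaves exactly where multimorbidity questions are most
interesting: rare conditions and small subgroups. With a handful of
co-occurrences the estimate is dominated by noise, its log-normal
(Katz-style) interval relies on large-sample normality that does not hold,
and spurious extreme values propagate into everything built on top of the
pairwise estimates — association networks, cluster structure, per-condition
summary scores. The usual defence of excluding conditions below an ad hoc
prevalence threshold throws away the very signals of interest.

`multiabc` implements a Bayesian alternative, **Association Beyond Chance
(ABC)**, that keeps low-count pairs in the analysis but makes the estimator
honest about the evidence behind them, together with the lift baseline and
the downstream analytics needed to compare the two.

## The generative model

Each condition $i$ is assigned an *independent-factor rate*
$f_i \in (0,1)$: the probability that a patient acquires the condition
through mechanisms unrelated to any other condition in the panel. Each
unordered pair $(i,j)$ additionally carries a signed co-occurrence excess
$f_{ij}$ attributable to mechanisms shared by the two conditions (shared
risk factors, one condition promoting the other). The association measure
is defined in model space as

$$ABC_{ij} = 1 + \frac{f_{ij}}{f_i\,f_j},$$

so that $ABC = 1$ means the pair co-occurs exactly as often as its
independent factors predict, $ABC = 2$ means shared mechanisms contribute
as much co-occurrence as chance does, and $ABC < 1$ is a negative
association. On this scale ABC is directly comparable to the lift, and the
joint-occurrence probability of a pair is $p_{11} = f_i f_j \, ABC_{ij}$.

Each pair contributes a multinomial likelihood over its four 2x2 cells,

$$(p_{11},\; f_i - p_{11},\; f_j - p_{11},\; 1 - f_i - f_j + p_{11}),$$

subject to the Fréchet feasibility bounds
$\max(0, f_i + f_j - 1) \le p_{11} \le \min(f_i, f_j)$. Crucially, a single
$f_i$ per condition is shared across *all* pairs involving that condition,
so each pairwise association is estimated in the context of the whole
panel rather than in isolation. Because every patient appears in every
pair's table, the product over pairs is a *composite* likelihood rather
than an exact joint likelihood; no correction for this reuse is applied,
and the calibration consequences are measured empirically (see below).
`abc_log_likelihood()` exposes this density directly.

## Priors and parameterisation

The defining feature of the estimator is a prior on each pair's
association centred on *no association*:

* The pair parameter is an unconstrained variable
  $u_{ij} \sim \mathcal N(0, \sigma_{ABC})$ mapped by an offset scaled
  logistic onto the feasible $p_{11}$ interval, constructed so that
  $u = 0$ maps exactly to $p_{11} = f_i f_j$, i.e. $ABC = 1$, for every
  value of $(f_i, f_j)$. For low-prevalence pairs (where
  $f_i f_j \ll \min(f_i, f_j)$) $u$ is approximately $\log ABC$, so
  $\sigma_{ABC}$ reads as a prior scale on the log-association. The
  sampler therefore never proposes an infeasible state, and shrinkage
  towards independence is built in: a pair backed by two co-occurrences
  is pulled towards 1, a pair backed by hundreds is not.
* $\sigma_{ABC}$ either gets a half-normal hyperprior (scale 0.5 by
  default) or is fixed by the user (`sigma_abc` in `abc_model_spec()`);
  fixing it wide (e.g. 5) effectively removes the shrinkage and is the
  configuration in which the posterior mode should agree with the
  empirical lift for well-populated tables.
* $f_i \sim \mathrm{Beta}(\mu\kappa, (1-\mu)\kappa)$ with
  $\mu \sim \mathrm U(0,1)$ and $\kappa$ half-normal with scale 10 —
  weakly informative, letting the panel's prevalence profile inform
  individual rates without constraining them strongly.

A tiny relative margin ($10^{-9}$ of the feasible interval) keeps all four
cell probabilities strictly positive; its effect on estimates is far below
Monte Carlo error. Conditions with zero prevalence are dropped from the
model with a message — their $f_i$ is unidentifiable — rather than
silently imputed.

## Sampling and summaries

The posterior is sampled with JAGS (via `rjags`), 4 chains by 5,000
retained draws after 1,000 warmup iterations by default (20,000 draws
total). Chain seeds derive deterministically from the single `seed` field
of `abc_model_spec()`, so a fit is exactly reproducible. Split-$\hat R$
and effective sample sizes are computed with `coda` and a warning is
raised when $\hat R$ exceeds 1.05; with a single pair and very sparse
data the hierarchical scale mixes slowly and longer chains (or a fixed
`sigma_abc`) are advisable.

Per-pair summaries follow conventions chosen for skewed posteriors:

* **Point estimate**: the midpoint of the shortest interval containing 5%
  of the sorted draws (`hpdi_mode()`) — a robust sample-based mode. The 5%
  mass is a compromise between bias (large windows) and noise (small
  windows) at the default 20,000 draws and is configurable.
* **Interval**: the 99% equal-tailed credible interval, i.e. the 0.5th and
  99.5th percentiles of the draws (standard interpolation quantiles).
* **Significance**: a pair is called significant when its 99% CrI excludes
  1. There is no multiple-testing correction; the shrinkage prior plays
  that role by biasing weakly supported associations towards 1.

For subgroup comparisons (`compare_groups()`), two independent posteriors
are compared through $p = 2\min\{\Pr(A > B), \Pr(B > A)\}$ with ties split
evenly. $\Pr(A > B)$ is computed *exactly* over all pairs of draws via the
rank (Mann–Whitney) identity rather than by pairing shuffled draws: the
result is deterministic, needs no length matching, and estimates the same
overlap quantity. When the posteriors are data-dominated this behaves like
a two-sided z-test; when they are prior-dominated it is conservative,
which is the intended behaviour for sparse strata.

## The relative-risk baseline

`rr_estimates()` implements the comparison pipeline: the lift point
estimate, a 99% log-normal interval, Fisher's exact two-sided p-value
(hypergeometric enumeration at fixed margins, via `fisher.test`), and a
significance flag at $\alpha = 0.01$, matching the 99% interval
convention. Two interval variants are exposed because the classical Katz
interval targets the *conditional* risk ratio
$[a/(a+b)]/[c/(c+d)]$ while the multimorbidity literature's point estimate
is the lift. The default `"lift-delta"` centres the interval on the lift
with the delta-method standard error
$\sqrt{1/N_{ij} - 1/N_i - 1/N_j + 1/N}$ on the log scale, so point
estimate and interval share one estimand; `"katz-2x2"` gives the textbook
interval. Zero cells are never continuity-corrected: degenerate estimates
are flagged and excluded from interval-based significance (the exact
Fisher p-value is still reported), and degenerate pairs contribute the
independence value 1 to aggregate summaries.

## Networks, communities, aggregation

`build_network()` assembles the significant pairs of either measure into
an undirected graph: nodes are conditions (with prevalence attributes),
edges carry the association value as weight, a sign relative to 1, and a
log-scale display width. Community detection
(`detect_communities()`) runs Clauset–Newman–Moore greedy modularity
maximisation (igraph's implementation) on the unweighted significant-edge
graph, including negative edges by default (`positive_only` restricts to
positive ones). The returned partition is the cut of the merge tree with
maximal modularity; ties — e.g. the final zero-gain merge on a complete
graph — are broken towards the coarsest partition, making output
deterministic. Only the standard resolution (1) is supported, which is the
CNM objective itself. Partition quality is scored by modularity, coverage
(fraction of within-cluster edges) and performance (fraction of correctly
classified node pairs); all three are validated against independent
brute-force pair/edge loops in the test suite.

Per-condition *average associations* follow different conventions for the
two measures, by design. For ABC the average over a condition's $P-1$
partners is computed per posterior draw, yielding a full distribution
summarised by median, IQR and 99% CrI; no significance masking is applied
because shrinkage already pulls unsupported pairs to 1. For RR,
non-significant and degenerate pairs contribute exactly 1 to the average,
and a nonparametric patient-level bootstrap (`bootstrap_rr_average()`)
provides percentile intervals — which become very wide for rare
conditions, honestly reflecting how unstable the RR average is there.

## The synthetic-cohort generator

Because real primary-care datasets of this kind are not publicly
shareable, every claim the package makes is tested on synthetic cohorts
with known ground truth (`generate_truth()` / `generate_cohort()`). Two
mechanisms are provided behind one interface:

* **Trigger mode** mirrors the generative story behind ABC: each patient
  draws an independent trigger per condition and a shared trigger per
  associated pair, and a condition is present if any of its triggers
  fires. Marginals and pairwise lifts have closed forms; with
  marginal-preserving independent rates the implied lift of a pair
  depends only on its own shared rate, so calibration to a target lift is
  an exact inversion. This mechanism can only produce lifts $\ge 1$.
* **Copula mode** thresholds a correlated latent Gaussian vector at
  per-condition quantiles; pairwise joints are bivariate-normal orthant
  probabilities (computed by the 1-D conditioning integral with
  `integrate`, absolute latent correlations calibrated by `uniroot` at
  tolerance $10^{-9}$). This mode covers negative associations
  ($L < 1$), which the trigger story cannot express.

Default prevalences are drawn log-uniformly over 0.1%–45%, emulating the
heterogeneity of real LTC panels (from hypertension-like to
viral-hepatitis-like rarity). The generator reproduces marginal and joint
probabilities but deliberately not other features of real cohorts — age
structure, deprivation, survivorship, temporal ordering, coding noise — so
passing tests demonstrate statistical correctness of the estimators under
the stated model, not clinical validity on any particular dataset.

## What the tests establish, and at what scale

The suite (and `scripts/acceptance.R`, which recomputes the same
quantities from scratch) checks, among others:

* exact agreement of Fisher p-values with full hypergeometric enumeration
  over all 2x2 tables up to $N = 60$ (canonical margins; the symmetry
  completions are tested separately);
* agreement of generator closed forms with million-patient Monte Carlo
  within 3 standard errors;
* posterior recovery of planted lifts $\{0.5, 1, 2, 4\}$ on a 6-condition
  panel at $N = 10{,}000$ (modes within 15%, with reduced sampling of
  4 chains x 1,000 draws), and 99% CrI coverage of the implied truth
  $\ge 90\%$ across 50 replicate cohorts;
* the caution property: for a pair with prevalences 0.005 and two
  co-occurrences at $N = 10{,}000$ the lift reports 8 while the ABC 99%
  CrI retains 1 and the mode sits near 1;
* the large-data limit: with all cells $\ge 100$ and a wide prior
  ($\sigma_{ABC} = 5$) the mode is within 5% of the empirical lift;
* null calibration of subgroup comparison under the target cohort profile
  (unequal strata of 3,000 and 9,000 patients, prevalences down to 0.5%):
  strata generated from identical truths are flagged as different in well
  under 5% of pairs. In data-rich balanced strata the overlap test
  approaches its nominal level instead — the conservatism is a
  sparse-data property, which is exactly the regime the method targets.

Replicate counts and chain lengths in the tests are scaled-down choices
that keep the whole suite in the low minutes while leaving Monte Carlo
error well inside the asserted tolerances; the package defaults
(4 x 5,000 draws) are what an analysis of a real cohort should use.

## Known limitations

* The per-pair multinomial product is a composite likelihood; its
  empirical 99% coverage on replicate synthetic cohorts is excellent at
  the tested sizes, but no theoretical correction for patient reuse is
  applied.
* Sampling is Gibbs/slice-based (JAGS). The model's geometry is benign at
  panel sizes tested here (up to 40 conditions, 780 pairs); the
  hierarchical association scale can mix slowly when almost no pairs
  carry signal, which the $\hat R$ warning surfaces.
* No covariate adjustment (age, deprivation), no temporal ordering, no
  causal direction: associations are cross-sectional and symmetric.
* Community detection treats the significant-edge graph as unweighted;
  whether and how negative edges should enter clustering is exposed as an
  option rather than decided by the package.
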