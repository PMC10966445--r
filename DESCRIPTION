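Package: multiabc
Title: Bayesian Association-Beyond-Chance Analysis of Multimorbidity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation of pairwise associations between long-term conditions
    from binary patient-by-condition cohort data. Implements Association
    Beyond Chance (ABC), a hierarchical Bayesian joint model in which each
    condition has a single independent-factor rate shared across all of its
    pairs and each pair carries a shrinkage prior centred on independence, so
    that associations supported by little evidence are pulled towards the
    no-association value. The classical relative-risk (lift) baseline is
    provided with Katz-style log-normal confidence intervals and Fisher's
    exact test, together with downstream multimorbidity analytics:
    significance-filtered association networks with greedy modularity
    community detection and partition quality scores, per-condition average
    associations with full uncertainty propagation, subgroup comparison via
    posterior overlap, and a synthetic cohort generator with known
    ground-truth association structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    coda,
    igraph,
    jsonlite,
    rjags,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
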