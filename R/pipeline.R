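#' Simulate a cohort and write it with its ground truth
#'
#' @param truth An `abc_truth` from [generate_truth()].
#' @param N Number of patients.
#' @param dir Output directory (created if needed).
#' @param seed Cohort seed.
#' @return Invisibly, a list with the written `cohort` (CSV) and `truth`
#'   (JSON) paths.
#' @export
simulate_cohort_files <- function(truth, N, dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  coh <- generate_cohort(truth, N, seed = seed)
  cohort_path <- file.path(dir, "cohort.csv")
  truth_path <- file.path(dir, "truth.json")
  write_cohort(coh, cohort_path)
  write_truth(truth, truth_path)
  message(sprintf("simulated %d patients x %d conditions (seed %d) -> %s",
                  N, truth$P, seed, dir))
  invisible(list(cohort = cohort_path, truth = truth_path))
}

#' Run the full association analysis on one cohort
#'
#' Orchestrates the complete pipeline: pairwise counts, relative-risk
#' estimates (Katz-style 99% CIs + Fisher significance), the Bayesian ABC
#' fit, association networks for both measures with community detection and
#' partition quality, and per-condition average associations.
#'
#' @param cohort An `abc_cohort`.
#' @param spec An [abc_model_spec()] for the ABC fit.
#' @param level CI / CrI level (default 0.99).
#' @param alpha Fisher significance level (default 0.01).
#' @param ci_method Relative-risk CI method, see [rr_confidence_interval()].
#' @param positive_only Restrict community detection to positive edges.
#' @return A bundle: list with `tables`, `rr`, `fit`, `networks`,
#'   `partitions`, `quality`, `averages` and the effective `config`.
#' @export
analyze_cohort <- function(cohort, spec = abc_model_spec(), level = 0.99,
                           alpha = 0.01,
                           ci_method = c("lift-delta", "katz-2x2"),
                           positive_only = FALSE) {
  ci_method <- match.arg(ci_method)
  tables <- pairwise_counts(cohort)
  rr <- rr_estimates(tables, level = level, alpha = alpha,
                     method = ci_method)
  fit <- fit_abc(cohort, spec)
  prev <- stats::setNames(colMeans(cohort$presence),
                          condition_names(cohort))
  nets <- list(
    ABC = build_network(fit$summaries, fit$conditions, measure = "ABC",
                        prevalence = prev),
    RR = build_network(rr, condition_names(cohort), measure = "RR",
                       prevalence = prev))
  partitions <- lapply(nets, detect_communities,
                       positive_only = positive_only)
  quality <- lapply(names(nets), function(nm) {
    if (igraph::ecount(nets[[nm]]) == 0L) return(NULL)
    partition_quality(nets[[nm]], partitions[[nm]])
  })
  names(quality) <- names(nets)
  averages <- list(abc = average_association_abc(fit),
                   rr = average_association_rr(rr))
  list(tables = tables, rr = rr, fit = fit, networks = nets,
       partitions = partitions, quality = quality, averages = averages,
       config = list(level = level, alpha = alpha, ci_method = ci_method,
                     positive_only = positive_only,
                     spec = unclass(spec)))
}

#' Write an analysis bundle to a directory
#'
#' Emits every artifact of [analyze_cohort()]: pair tables, the
#' relative-risk table, ABC draws/summaries/diagnostics, GraphML networks
#' with cluster ids, the partition-quality report, average-association
#' tables, and the effective configuration (so the run is reproducible).
#'
#' @param bundle Result of [analyze_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$tables, file.path(dir, "pair_tables.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$rr, file.path(dir, "rr_estimates.csv"),
                   row.names = FALSE)
  write_abc_fit(bundle$fit, dir)
  for (nm in names(bundle$networks)) {
    export_graph(bundle$networks[[nm]],
                 file.path(dir, sprintf("network_%s.graphml", nm)),
                 partition = bundle$partitions[[nm]])
    export_graph(bundle$networks[[nm]],
                 file.path(dir, sprintf("edges_%s.csv", nm)),
                 format = "csv")
  }
  jsonlite::write_json(
    list(quality = bundle$quality,
         partitions = lapply(bundle$partitions, as.list)),
    file.path(dir, "network_report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(bundle$averages$abc,
                   file.path(dir, "average_abc.csv"), row.names = FALSE)
  utils::write.csv(bundle$averages$rr,
                   file.path(dir, "average_rr.csv"), row.names = FALSE)
  jsonlite::write_json(bundle$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Compare associations between two strata
#'
#' For each measure, restricts to the pairs found significant in both
#' strata (the reference procedure) and tests each for a between-stratum
#' difference: posterior overlap for ABC, a two-sided z-test on the
#' log-lift difference for relative risk.
#'
#' @param bundleA,bundleB Results of [analyze_cohort()] on two strata of
#'   the same condition panel (e.g. men and women).
#' @param threshold Difference-significance threshold (default 0.05; 0.01
#'   is also reported as `significant_diff_01`).
#' @return List of two data frames, `abc` and `rr`, one row per pair
#'   significant in both strata by that measure, with the two per-stratum
#'   values, the difference p-value and significance flags.
#' @export
compare_strata <- function(bundleA, bundleB, threshold = 0.05) {
  sA <- bundleA$fit$summaries; sB <- bundleB$fit$summaries
  keyA <- paste(sA$cond_i, sA$cond_j, sep = "|")
  keyB <- paste(sB$cond_i, sB$cond_j, sep = "|")
  shared <- intersect(keyA[sA$significant], keyB[sB$significant])
  abc <- do.call(rbind, lapply(shared, function(k) {
    ia <- match(k, keyA); ib <- match(k, keyB)
    cmp <- compare_groups(
      abc_pair_draws(bundleA$fit, sA$cond_i[ia], sA$cond_j[ia]),
      abc_pair_draws(bundleB$fit, sB$cond_i[ib], sB$cond_j[ib]))
    data.frame(cond_i = sA$cond_i[ia], cond_j = sA$cond_j[ia],
               mode_a = sA$mode[ia], mode_b = sB$mode[ib],
               p = cmp$p, stringsAsFactors = FALSE)
  }))
  if (is.null(abc)) {
    message("no pairs significant in both strata by ABC")
    abc <- data.frame(cond_i = character(), cond_j = character(),
                      mode_a = numeric(), mode_b = numeric(),
                      p = numeric())
  }
  abc$significant_diff <- abc$p < threshold
  abc$significant_diff_01 <- abc$p < 0.01

  rA <- bundleA$rr; rB <- bundleB$rr
  keyA <- paste(rA$cond_i, rA$cond_j, sep = "|")
  keyB <- paste(rB$cond_i, rB$cond_j, sep = "|")
  sharedr <- intersect(keyA[rA$significant], keyB[rB$significant])
  rr <- do.call(rbind, lapply(sharedr, function(k) {
    ia <- match(k, keyA); ib <- match(k, keyB)
    data.frame(cond_i = rA$cond_i[ia], cond_j = rA$cond_j[ia],
               rr_a = rA$rr[ia], rr_b = rB$rr[ib],
               p = compare_rr_between_groups(rA[ia, ], rB[ib, ]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rr)) {
    message("no pairs significant in both strata by RR")
    rr <- data.frame(cond_i = character(), cond_j = character(),
                     rr_a = numeric(), rr_b = numeric(), p = numeric())
  }
  rr$significant_diff <- !is.na(rr$p) & rr$p < threshold
  rr$significant_diff_01 <- !is.na(rr$p) & rr$p < 0.01
  list(abc = abc, rr = rr)
}

#' Analyse a cohort separately by stratum and compare
#'
#' Convenience wrapper: fits every stratum of a stratified cohort
#' independently with [analyze_cohort()] and compares each pair of strata
#' with [compare_strata()].
#'
#' @param cohort An `abc_cohort` with strata.
#' @param ... Passed to [analyze_cohort()].
#' @return List with `bundles` (one per stratum) and `comparisons` (one per
#'   stratum pair, named `"A.vs.B"`).
#' @export
analyze_strata <- function(cohort, ...) {
  if (is.null(cohort$strata)) stop("cohort has no strata")
  labs <- unique(cohort$strata)
  bundles <- lapply(labs, function(l) analyze_cohort(stratify(cohort, l), ...))
  names(bundles) <- labs
  comparisons <- list()
  if (length(labs) >= 2L) {
    for (a in seq_len(length(labs) - 1L)) for (b in seq.int(a + 1L, length(labs))) {
      comparisons[[paste(labs[a], labs[b], sep = ".vs.")]] <-
        compare_strata(bundles[[a]], bundles[[b]])
    }
  }
  list(bundles = bundles, comparisons = comparisons)
}
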