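test_that("networks contain exactly the significant pairs", {
  s <- random_summaries(5, p_edge = 0, rng_seed = 1)
  g0 <- build_network(s, sprintf("C%d", 1:5), measure = "ABC")
  expect_equal(igraph::vcount(g0), 5)
  expect_equal(igraph::ecount(g0), 0)

  s2 <- random_summaries(5, p_edge = 0.3, rng_seed = 2)
  g <- build_network(s2, sprintf("C%d", 1:5), measure = "ABC")
  expect_equal(igraph::ecount(g), sum(s2$significant))
  expect_true(all(igraph::E(g)$weight > 0))
  expect_equal(igraph::E(g)$sign,
               ifelse(igraph::E(g)$weight > 1, "positive", "negative"))
  expect_equal(igraph::E(g)$width, abs(log(igraph::E(g)$weight)))
})

test_that("network edges reproduce CrI-based calls from a real fit", {
  truth <- generate_truth(4, prevalences = c(0.3, 0.3, 0.2, 0.2),
                          assoc = data.frame(i = 1, j = 2, lift = 2),
                          mode = "trigger")
  coh <- generate_cohort(truth, 6000, seed = 19)
  fit <- fit_abc(coh, quick_spec(seed = 19))
  net <- build_network(fit$summaries, fit$conditions, measure = "ABC")
  el <- igraph::as_edgelist(net)
  keys <- paste(el[, 1], el[, 2], sep = "|")
  want <- with(fit$summaries,
               paste(cond_i, cond_j, sep = "|")[significant])
  expect_setequal(keys, want)
})

two_cliques <- function() {
  s <- data.frame(
    cond_i = c("A", "A", "B", "D", "D", "E"),
    cond_j = c("B", "C", "C", "E", "F", "F"),
    mode = 2, significant = TRUE, stringsAsFactors = FALSE)
  build_network(s, LETTERS[1:6], measure = "ABC")
}

test_that("greedy modularity recovers planted communities", {
  net <- two_cliques()
  memb <- detect_communities(net)
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[c("A", "B", "C")])), 1)
  expect_equal(length(unique(memb[c("D", "E", "F")])), 1)

  # exhaustive check: no partition of the 6 nodes beats the clique split
  adj <- network_adjacency(net)
  best <- max_modularity_exhaustive(adj)
  expect_equal(network_modularity(net, memb), best, tolerance = 1e-12)
})

test_that("complete graphs collapse to one community", {
  pairs <- t(combn(LETTERS[1:5], 2))
  s <- data.frame(cond_i = pairs[, 1], cond_j = pairs[, 2],
                  mode = 1.5, significant = TRUE, stringsAsFactors = FALSE)
  net <- build_network(s, LETTERS[1:5], measure = "ABC")
  expect_equal(length(unique(detect_communities(net))), 1)
})

test_that("isolated nodes and edgeless graphs get singleton clusters", {
  s <- data.frame(cond_i = "A", cond_j = "B", mode = 2,
                  significant = TRUE, stringsAsFactors = FALSE)
  net <- build_network(s, c("A", "B", "Z"), measure = "ABC")
  memb <- detect_communities(net)
  expect_equal(memb[["A"]], memb[["B"]])
  expect_false(memb[["Z"]] == memb[["A"]])

  empty <- build_network(random_summaries(4, 0, 1), sprintf("C%d", 1:4),
                         measure = "RR", value_col = "mode")
  expect_equal(sort(unname(detect_communities(empty))), 1:4)
  expect_error(network_modularity(empty, 1:4), "no edges")
})

test_that("community detection is deterministic", {
  s <- random_summaries(10, 0.35, rng_seed = 6)
  net <- build_network(s, sprintf("C%d", 1:10), measure = "ABC")
  expect_identical(detect_communities(net), detect_communities(net))
})

test_that("quality scores match hand counts on the two-clique fixture", {
  net <- two_cliques()
  memb <- setNames(c(1, 1, 1, 2, 2, 2), LETTERS[1:6])
  expect_equal(network_modularity(net, memb), 0.5)
  expect_equal(network_coverage(net, memb), 1.0)
  expect_equal(network_performance(net, memb), 1.0)  # (6 + 9) / 15

  one <- setNames(rep(1, 6), LETTERS[1:6])
  expect_equal(network_modularity(net, one), 0)
  singletons <- setNames(1:6, LETTERS[1:6])
  expect_equal(network_coverage(net, singletons), 0)
})

test_that("quality scores agree with brute-force loops on random graphs", {
  for (rng_seed in 1:8) {
    n <- sample(5:12, 1)
    s <- random_summaries(n, runif(1, 0.2, 0.6), rng_seed = rng_seed * 100)
    net <- build_network(s, sprintf("C%d", seq_len(n)), measure = "RR",
                         value_col = "mode")
    if (igraph::ecount(net) == 0) next
    memb <- detect_communities(net)
    adj <- network_adjacency(net)
    mo <- memb[rownames(adj)]
    expect_equal(network_modularity(net, memb),
                 oracle_modularity(adj, mo), tolerance = 1e-12)
    expect_equal(network_coverage(net, memb),
                 oracle_coverage(adj, mo), tolerance = 1e-12)
    expect_equal(network_performance(net, memb),
                 oracle_performance(adj, mo), tolerance = 1e-12)
    q <- partition_quality(net, memb)
    expect_gte(q$modularity, -0.5); expect_lte(q$modularity, 1)
    expect_gte(q$coverage, 0); expect_lte(q$coverage, 1)
    expect_gte(q$performance, 0); expect_lte(q$performance, 1)
  }
})

test_that("positive-only clustering drops negative edges", {
  s <- data.frame(cond_i = c("A", "C"), cond_j = c("B", "D"),
                  mode = c(2, 0.5), significant = TRUE,
                  stringsAsFactors = FALSE)
  net <- build_network(s, LETTERS[1:4], measure = "ABC")
  expect_equal(igraph::ecount(net), 2)
  memb <- detect_communities(net, positive_only = TRUE)
  expect_false(memb[["C"]] == memb[["D"]])
  expect_error(detect_communities(net, resolution = 2), "resolution")
})

test_that("GraphML export round-trips nodes, edges and attributes", {
  net <- two_cliques()
  memb <- detect_communities(net)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graph(net, path, partition = memb)
  back <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(back), 6)
  expect_setequal(igraph::V(back)$name, LETTERS[1:6])
  expect_equal(sort(igraph::E(back)$weight), sort(igraph::E(net)$weight))
  expect_equal(unname(igraph::V(back)$cluster[
    match(names(memb), igraph::V(back)$name)]), unname(memb),
    ignore_attr = TRUE)

  csv <- withr::local_tempfile(fileext = ".csv")
  export_graph(net, csv, format = "csv")
  el <- read.csv(csv)
  expect_equal(nrow(el), 6)
  expect_true(all(el$sign == ifelse(el$weight > 1, "positive", "negative")))
})
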