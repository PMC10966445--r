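#' Build an association network from pair summaries
#'
#' Nodes are conditions (with a prevalence attribute when supplied); edges
#' are the significant pairs, weighted by the association value, with a sign
#' attribute (`"positive"` for values above 1, `"negative"` below) and a
#' display width on the log scale, `abs(log(weight))`.
#'
#' @param summaries Per-pair data frame with columns `cond_i`, `cond_j`, a
#'   value column, and a logical `significant` column — either `rr`
#'   estimates from [rr_estimates()] or `abc_fit$summaries` (value column
#'   `mode`).
#' @param conditions Character vector of all conditions (nodes), so that
#'   conditions with no significant pair still appear as isolated nodes.
#' @param measure `"ABC"` or `"RR"`; also selects the default value column.
#' @param value_col Name of the association-value column (default `"mode"`
#'   for ABC, `"rr"` for RR).
#' @param prevalence Optional named vector of condition prevalences.
#' @return An `igraph` graph with graph attribute `measure`.
#' @export
build_network <- function(summaries, conditions, measure = c("ABC", "RR"),
                          value_col = NULL, prevalence = NULL) {
  measure <- match.arg(measure)
  if (is.null(value_col)) {
    value_col <- if (measure == "ABC") "mode" else "rr"
  }
  sig <- summaries[which(summaries$significant), , drop = FALSE]
  w <- sig[[value_col]]
  if (any(w <= 0, na.rm = TRUE) || anyNA(w)) {
    message("dropping ", sum(is.na(w) | w <= 0),
            " significant pair(s) with non-positive association value")
    keep <- !is.na(w) & w > 0
    sig <- sig[keep, , drop = FALSE]
    w <- w[keep]
  }
  edges <- data.frame(from = sig$cond_i, to = sig$cond_j,
                      weight = w,
                      sign = ifelse(w > 1, "positive", "negative"),
                      width = abs(log(w)),
                      stringsAsFactors = FALSE)
  vertices <- data.frame(name = conditions, stringsAsFactors = FALSE)
  if (!is.null(prevalence)) vertices$prevalence <- prevalence[conditions]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  g <- igraph::set_graph_attr(g, "measure", measure)
  g
}

#' Detect condition communities by greedy modularity maximisation
#'
#' Clauset-Newman-Moore greedy modularity maximisation (igraph's
#' `cluster_fast_greedy`) on the unweighted graph of significant edges.
#' Negative-association edges are included by default; set
#' `positive_only = TRUE` to restrict clustering to positive associations.
#' An edgeless graph yields singleton clusters. Output is deterministic:
#' the partition returned is the cut of the greedy merge tree with maximal
#' modularity, with ties broken towards the coarsest partition (fewest
#' clusters), so repeated runs on the same graph agree.
#'
#' @param net Network from [build_network()].
#' @param resolution Modularity resolution; only the standard value 1 is
#'   supported (the greedy CNM objective has no resolution knob).
#' @param positive_only Drop negative-association edges before clustering.
#' @return Named integer vector: cluster id per condition.
#' @export
detect_communities <- function(net, resolution = 1, positive_only = FALSE) {
  if (resolution != 1) {
    stop("only resolution = 1 (standard modularity) is supported")
  }
  g <- net
  if (positive_only && igraph::ecount(g) > 0) {
    g <- igraph::delete_edges(
      g, igraph::E(g)[igraph::E(g)$sign == "negative"])
  }
  gu <- igraph::delete_edge_attr(g, "weight")
  gu <- igraph::simplify(gu)
  if (igraph::ecount(gu) == 0L) {
    return(stats::setNames(seq_len(igraph::vcount(gu)),
                           igraph::V(gu)$name))
  }
  cl <- igraph::cluster_fast_greedy(gu)
  # cut the merge tree at maximal modularity; on ties (e.g. a final
  # zero-gain merge) prefer the coarsest partition
  n <- igraph::vcount(gu)
  n_min <- n - nrow(cl$merges)
  best <- NULL; best_q <- -Inf
  for (no in seq.int(n_min, n)) {
    memb <- igraph::cut_at(cl, no = no)
    q <- igraph::modularity(gu, memb)
    if (q > best_q + 1e-12) {   # strict improvement: coarser cut wins ties
      best_q <- q
      best <- memb
    }
  }
  stats::setNames(best, igraph::V(gu)$name)
}

#' Newman modularity of a partition
#'
#' `Q = sum_c [ e_c / m - (d_c / 2m)^2 ]` over clusters `c`, on the
#' unweighted graph of significant edges: within-cluster edge fraction minus
#' its expectation under the degree-preserving random-graph null.
#'
#' @param net Network from [build_network()].
#' @param partition Named cluster membership vector (as returned by
#'   [detect_communities()]).
#' @return Modularity in \[-0.5, 1\].
#' @export
network_modularity <- function(net, partition) {
  if (igraph::ecount(net) == 0L) stop("modularity undefined: no edges")
  gu <- igraph::simplify(igraph::delete_edge_attr(net, "weight"))
  igraph::modularity(gu, partition[igraph::V(gu)$name])
}

#' Coverage of a partition
#'
#' Fraction of edges that fall within clusters.
#'
#' @inheritParams network_modularity
#' @return Coverage in \[0, 1\].
#' @export
network_coverage <- function(net, partition) {
  m <- igraph::ecount(net)
  if (m == 0L) stop("coverage undefined: no edges")
  el <- igraph::as_edgelist(net)
  mean(partition[el[, 1L]] == partition[el[, 2L]])
}

#' Performance of a partition
#'
#' Fraction of all node pairs correctly classified by the partition:
#' within-cluster pairs joined by an edge plus between-cluster pairs not
#' joined by an edge, divided by `choose(P, 2)`.
#'
#' @inheritParams network_modularity
#' @return Performance in \[0, 1\].
#' @export
network_performance <- function(net, partition) {
  P <- igraph::vcount(net)
  stopifnot(P >= 2)
  memb <- partition[igraph::V(net)$name]
  el <- igraph::as_edgelist(igraph::simplify(net))
  within_edges <- sum(partition[el[, 1L]] == partition[el[, 2L]])
  same_cluster_pairs <- sum(choose(table(memb), 2))
  between_pairs <- choose(P, 2) - same_cluster_pairs
  between_nonedges <- between_pairs - (nrow(el) - within_edges)
  (within_edges + between_nonedges) / choose(P, 2)
}

#' All three partition quality scores
#' @inheritParams network_modularity
#' @return List with `modularity`, `coverage`, `performance`.
#' @export
partition_quality <- function(net, partition) {
  list(modularity = network_modularity(net, partition),
       coverage = network_coverage(net, partition),
       performance = network_performance(net, partition))
}

#' Export an association network
#'
#' Writes GraphML (nodes carry prevalence and cluster id; edges carry
#' weight and sign) and/or an edge-list CSV. GraphML round-trips losslessly
#' through `igraph::read_graph`.
#'
#' @param net Network from [build_network()].
#' @param path Output file path.
#' @param partition Optional membership vector stored as a `cluster` node
#'   attribute.
#' @param format `"graphml"` or `"csv"` (edge list).
#' @return `path`, invisibly.
#' @export
export_graph <- function(net, path, partition = NULL,
                         format = c("graphml", "csv")) {
  format <- match.arg(format)
  if (!is.null(partition)) {
    net <- igraph::set_vertex_attr(net, "cluster",
                                   value = as.integer(
                                     partition[igraph::V(net)$name]))
  }
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(net)
    utils::write.csv(
      data.frame(cond_i = el[, 1L], cond_j = el[, 2L],
                 weight = igraph::E(net)$weight,
                 sign = igraph::E(net)$sign,
                 stringsAsFactors = FALSE),
      path, row.names = FALSE)
  }
  invisible(path)
}
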