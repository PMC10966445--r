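# Independent brute-force oracles used across the suite. These deliberately
# take the slowest, most literal route so they share no code with the
# implementation they check.

# two-sided Fisher p by explicit hypergeometric enumeration at fixed margins
oracle_fisher <- function(N, N_i, N_j, N_ij) {
  lo <- max(0L, N_i + N_j - N)
  hi <- min(N_i, N_j)
  support <- lo:hi
  probs <- dhyper(support, N_i, N - N_i, N_j)
  p_obs <- probs[N_ij - lo + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])  # relative tie tolerance
}

# pairwise 2x2 counts by an O(N * P^2) double loop over patients
oracle_pair_counts <- function(X) {
  P <- ncol(X)
  out <- NULL
  for (i in seq_len(P - 1L)) for (j in seq.int(i + 1L, P)) {
    nij <- 0L
    for (r in seq_len(nrow(X))) {
      if (X[r, i] == 1L && X[r, j] == 1L) nij <- nij + 1L
    }
    out <- rbind(out, data.frame(i = i, j = j, N = nrow(X),
                                 N_i = sum(X[, i]), N_j = sum(X[, j]),
                                 N_ij = nij))
  }
  out
}

# partition quality by literal loops over an adjacency matrix
oracle_modularity <- function(adj, memb) {
  m <- sum(adj) / 2
  deg <- rowSums(adj)
  q <- 0
  for (i in seq_len(nrow(adj))) for (j in seq_len(nrow(adj))) {
    if (memb[i] == memb[j]) {
      q <- q + adj[i, j] / (2 * m) - unname(deg[i] * deg[j]) / (2 * m)^2
    }
  }
  q
}

oracle_coverage <- function(adj, memb) {
  within <- 0; total <- 0
  for (i in seq_len(nrow(adj) - 1L)) for (j in seq.int(i + 1L, nrow(adj))) {
    if (adj[i, j] == 1) {
      total <- total + 1
      if (memb[i] == memb[j]) within <- within + 1
    }
  }
  within / total
}

oracle_performance <- function(adj, memb) {
  good <- 0; total <- 0
  for (i in seq_len(nrow(adj) - 1L)) for (j in seq.int(i + 1L, nrow(adj))) {
    total <- total + 1
    same <- memb[i] == memb[j]
    if ((same && adj[i, j] == 1) || (!same && adj[i, j] == 0)) {
      good <- good + 1
    }
  }
  good / total
}

# HPDI-midpoint mode by scanning every window explicitly
oracle_hpdi_mode <- function(x, mass) {
  x <- sort(x)
  s <- length(x)
  w <- max(2L, ceiling(mass * s))
  best_width <- Inf; best_mid <- NA_real_
  for (start in seq_len(s - w + 1L)) {
    width <- x[start + w - 1L] - x[start]
    if (width < best_width) {
      best_width <- width
      best_mid <- (x[start] + x[start + w - 1L]) / 2
    }
  }
  best_mid
}

# best achievable modularity by exhaustive enumeration of all set
# partitions (feasible up to ~8 nodes; Bell(6) = 203)
max_modularity_exhaustive <- function(adj) {
  n <- nrow(adj)
  partitions <- list(rep(1L, 1L))
  for (node in 2:n) {
    partitions <- unlist(lapply(partitions, function(p) {
      k <- max(p)
      lapply(seq_len(k + 1L), function(cl) c(p, cl))
    }), recursive = FALSE)
  }
  max(vapply(partitions, function(p) oracle_modularity(adj, p), numeric(1)))
}

# turn an igraph network into a 0/1 adjacency matrix in vertex-name order
network_adjacency <- function(net) {
  adj <- as.matrix(igraph::as_adjacency_matrix(igraph::simplify(net)))
  adj[adj > 1] <- 1
  adj
}

# random undirected graph on n nodes as a fake significant-pair summary
random_summaries <- function(n, p_edge, rng_seed) {
  set.seed(rng_seed)
  pairs <- t(combn(n, 2))
  labels <- sprintf("C%d", seq_len(n))
  data.frame(cond_i = labels[pairs[, 1L]], cond_j = labels[pairs[, 2L]],
             mode = exp(rnorm(nrow(pairs), 0, 0.5)),
             significant = runif(nrow(pairs)) < p_edge,
             stringsAsFactors = FALSE)
}
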