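# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and igraph shortest-path routines).

# all-pairs shortest paths by Floyd-Warshall on a binary adjacency matrix
fw_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

adj_of <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  A[A > 0] <- 1
  A
}

# exhaustive census of induced connected 3- and 4-node subgraphs via
# isomorphism tests against reference patterns
brute_motifs <- function(g) {
  refs3 <- list(v3 = igraph::make_graph(c(1, 2, 2, 3), directed = FALSE),
                tri3 = igraph::make_full_graph(3))
  refs4 <- list(
    p4_path = igraph::make_graph(c(1, 2, 2, 3, 3, 4), directed = FALSE),
    p4_star = igraph::make_star(4, mode = "undirected"),
    p4_paw = igraph::make_graph(c(1, 2, 2, 3, 3, 1, 3, 4), directed = FALSE),
    p4_cycle = igraph::make_ring(4),
    p4_diamond = igraph::make_graph(c(1, 2, 2, 3, 3, 1, 1, 4, 3, 4),
                                    directed = FALSE),
    p4_k4 = igraph::make_full_graph(4))
  out <- setNames(rep(0L, 8),
                  c("v3", "tri3", "p4_path", "p4_star", "p4_paw",
                    "p4_cycle", "p4_k4", "p4_diamond"))
  n <- igraph::vcount(g)
  count_sets <- function(k, refs) {
    if (n < k) return()
    sets <- utils::combn(n, k)
    for (i in seq_len(ncol(sets))) {
      sub <- igraph::induced_subgraph(g, sets[, i])
      if (!igraph::is_connected(sub)) next
      for (nm in names(refs)) {
        if (igraph::isomorphic(sub, refs[[nm]])) {
          out[nm] <<- out[nm] + 1L
          break
        }
      }
    }
  }
  count_sets(3, refs3)
  count_sets(4, refs4)
  out
}

# transitivity by explicit triple enumeration
brute_transitivity <- function(g) {
  A <- adj_of(g)
  n <- nrow(A)
  if (n < 3) return(0)
  tri <- 0; triples <- 0
  cmb <- utils::combn(n, 3)
  for (i in seq_len(ncol(cmb))) {
    v <- cmb[, i]
    e <- A[v[1], v[2]] + A[v[1], v[3]] + A[v[2], v[3]]
    if (e == 3) tri <- tri + 1
  }
  deg <- rowSums(A)
  triples <- sum(choose(deg, 2))
  if (triples == 0) return(0)
  3 * tri / triples
}

# all set partitions of 1..n (Bell-number enumeration; fine for n <= 7)
all_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  sub <- all_partitions(n - 1L)
  out <- list()
  for (p in sub) {
    for (bi in seq_along(p)) {
      q <- p
      q[[bi]] <- c(q[[bi]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# maximum Newman-Girvan modularity by exhaustive partition search
brute_best_modularity <- function(g) {
  A <- adj_of(g)
  m <- sum(A) / 2
  deg <- rowSums(A)
  best <- -Inf
  for (p in all_partitions(nrow(A))) {
    q <- 0
    for (blk in p) {
      e_c <- sum(A[blk, blk, drop = FALSE]) / 2
      d_c <- sum(deg[blk])
      q <- q + e_c / m - (d_c / (2 * m))^2
    }
    best <- max(best, q)
  }
  best
}

# small connected random graph for oracle comparisons; built from a uniform
# spanning tree plus random extra edges, independently of the package's own
# null-model sampler
random_connected_test_graph <- function(n_max = 40, n_min = 4) {
  n <- sample(n_min:n_max, 1)
  g <- igraph::sample_tree(n)
  extra <- sample(0:round(0.6 * n), 1)
  if (extra > 0) {
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    free <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
    extra <- min(extra, nrow(free))
    pick <- free[sample.int(nrow(free), extra), , drop = FALSE]
    g <- igraph::add_edges(g, t(pick))
  }
  g
}

# a component without degree-2 vertices, as produced by the generator and
# reduced to the class a voxel skeleton can encode
random_embeddable_component <- function(size_range = c(6, 16)) {
  repeat {
    g <- generate_component(sample(size_range[1]:size_range[2], 1),
                            triangle_propensity = 0.4, chain_bias = 0.4)
    h <- smooth_network(g)
    if (igraph::vcount(h) >= 2 && max(igraph::degree(h)) <= 8) return(h)
  }
}

# synthetic feature instances with a controlled group separation (in SD units).
# Noise is truncated at +/- 2 SD so that a 5-SD shift yields groups that are
# separable by construction (the separable-case checks assert AUC = 1 exactly).
make_instances <- function(n_subj_per_class = 4, n_inst = 8, shift = 0,
                           n_feat = 3, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (cl in c("PD", "control")) {
    for (s in seq_len(n_subj_per_class)) {
      id <- paste0(cl, "_", s)
      X <- matrix(pmin(pmax(rnorm(n_inst * n_feat), -2), 2), n_inst, n_feat)
      if (cl == "PD") X[, 1] <- X[, 1] + shift
      df <- data.frame(subject_id = rep(id, n_inst), label = cl,
                       side = "left", size = 20)
      for (j in seq_len(n_feat)) df[[paste0("f", j, "_z")]] <- X[, j]
      rows[[length(rows) + 1L]] <- df
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "features") <- paste0("f", seq_len(n_feat), "_z")
  out
}
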