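#' Decompose a network into connected components
#'
#' Components are the unit of topological analysis: maximal connected
#' subgraphs, sorted by descending size with ties broken by the smallest
#' original node id.
#'
#' @param net A [mito_network()] or bare igraph.
#' @return List of igraph components; each carries a `min_node` graph
#'   attribute (smallest original node id) for reproducible ordering.
#' @export
extract_components <- function(net) {
  g <- if (inherits(net, "mito_network")) net$graph else net
  if (igraph::vcount(g) == 0) return(list())
  igraph::V(g)$orig_id <- seq_len(igraph::vcount(g))
  comps <- igraph::decompose(g)
  min_id <- vapply(comps, function(cc) min(igraph::V(cc)$orig_id), 1)
  sizes <- vapply(comps, igraph::vcount, numeric(1))
  ord <- order(-sizes, min_id)
  comps <- comps[ord]
  for (i in seq_along(comps))
    comps[[i]] <- igraph::set_graph_attr(comps[[i]], "min_node",
                                         min_id[ord][i])
  comps
}

#' Normalized node degrees within a component
#'
#' `k*_i = k_i / N`, the raw degree over the component size, making
#' degrees comparable across components of different sizes.
#'
#' @param component Connected igraph.
#' @return Numeric vector, one value per node, in (0, 1\].
#' @export
normalized_degree <- function(component) {
  igraph::degree(component) / igraph::vcount(component)
}

#' Link density of a component
#'
#' Fraction of active links over possible links,
#' `l_d = sum(a_ij) / (N (N - 1))` with binary `a_ij` over ordered pairs.
#'
#' @param component Connected igraph with at least 2 nodes.
#' @return Real in \[0, 1\]; `NA` for single-node components.
#' @export
link_density <- function(component) {
  n <- igraph::vcount(component)
  if (n < 2) return(NA_real_)
  2 * igraph::ecount(component) / (n * (n - 1))
}

#' Maximum degree of a component
#'
#' @param component Connected igraph with at least 2 nodes.
#' @return Integer; `NA` for single-node components.
#' @export
max_degree <- function(component) {
  if (igraph::vcount(component) < 2) return(NA_integer_)
  max(igraph::degree(component))
}

# topological (unweighted) all-pairs distances; weights deliberately ignored
.topo_dist <- function(component) {
  igraph::distances(component, weights = NA)
}

#' Average shortest path length (ASPL)
#'
#' Mean geodesic distance over all ordered node pairs, links unweighted.
#'
#' @param component Connected igraph with at least 2 nodes.
#' @return Real >= 1; `NA` for single-node components.
#' @export
aspl <- function(component) {
  n <- igraph::vcount(component)
  if (n < 2) return(NA_real_)
  dmat <- .topo_dist(component)
  if (any(!is.finite(dmat))) stop_invalid("component must be connected")
  mean(dmat[row(dmat) != col(dmat)])
}

#' Network diameter
#'
#' Greatest geodesic distance between any pair of nodes (unweighted).
#'
#' @param component Connected igraph with at least 2 nodes.
#' @return Integer count; `NA` for single-node components.
#' @export
net_diameter <- function(component) {
  n <- igraph::vcount(component)
  if (n < 2) return(NA_real_)
  dmat <- .topo_dist(component)
  if (any(!is.finite(dmat))) stop_invalid("component must be connected")
  max(dmat)
}

#' Network efficiency
#'
#' Harmonic mean of geodesic distances:
#' `E = mean(1 / d_ij)` over ordered pairs. Equals 1 iff complete.
#'
#' @param component Connected igraph with at least 2 nodes.
#' @return Real in (0, 1\]; `NA` for single-node components.
#' @export
efficiency <- function(component) {
  n <- igraph::vcount(component)
  if (n < 2) return(NA_real_)
  dmat <- .topo_dist(component)
  if (any(!is.finite(dmat))) stop_invalid("component must be connected")
  mean(1 / dmat[row(dmat) != col(dmat)])
}

#' Louvain modularity of a component
#'
#' Community structure detected by the Louvain algorithm; returns the
#' Newman-Girvan modularity Q of the detected partition. Seeded for
#' reproducibility (Louvain visits nodes in randomized order).
#'
#' @param component Connected igraph with at least 2 nodes.
#' @param seed Integer seed fixing the node-visit order.
#' @return List with `membership` (integer vector) and `Q` (real).
#' @export
modularity_louvain <- function(component, seed = 42L) {
  if (igraph::vcount(component) < 2)
    return(list(membership = rep(1L, igraph::vcount(component)), Q = NA_real_))
  local_seed(seed, {
    cl <- igraph::cluster_louvain(component, weights = NA)
    list(membership = igraph::membership(cl),
         Q = igraph::modularity(component, igraph::membership(cl)))
  })
}

#' Degree assortativity
#'
#' Pearson correlation between the degrees of the two endpoints of each
#' link. Undefined (returned as `NA`) when either endpoint-degree
#' sequence has zero variance, e.g. for regular graphs.
#'
#' @param component Connected igraph with at least 2 nodes.
#' @return Real in \[-1, 1\] or `NA` when undefined.
#' @export
assortativity_deg <- function(component) {
  el <- igraph::as_edgelist(component, names = FALSE)
  if (nrow(el) < 2) return(NA_real_)
  deg <- igraph::degree(component)
  # symmetrize: each link contributes both orientations
  x <- c(deg[el[, 1]], deg[el[, 2]])
  y <- c(deg[el[, 2]], deg[el[, 1]])
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Transitivity (global clustering coefficient)
#'
#' Density of triangles: `3 * triangles / connected triples`. Zero for
#' components with fewer than 3 nodes or no connected triples.
#'
#' @param component Connected igraph.
#' @return Real in \[0, 1\].
#' @export
transitivity_global <- function(component) {
  if (igraph::vcount(component) < 3) return(0)
  t <- igraph::transitivity(component, type = "global")
  if (is.nan(t)) 0 else t
}

#' Information content of a component
#'
#' Mesoscale-regularity measure: total bits lost when node pairs are
#' iteratively merged. At each of the `s - 1` steps the pair whose merge
#' is cheapest is merged (ties broken by the lowest node-id pair); the
#' cost of merging rows `i`, `j` of the adjacency matrix is
#' `log2(choose(n - 2, m))` bits, `m` being the number of other nodes on
#' which the two rows disagree (the bits needed to say which entries
#' must be corrected to reconstruct the original rows). The merged row
#' is the elementwise OR. Regular structures (e.g. complete graphs)
#' yield 0 bits.
#'
#' @param component Connected igraph with at least 2 nodes.
#' @return Non-negative real (bits); `NA` for single-node components.
#' @export
information_content <- function(component) {
  n <- igraph::vcount(component)
  if (n < 2) return(NA_real_)
  A <- as.matrix(igraph::as_adjacency_matrix(component))
  A[A > 0] <- 1
  total <- 0
  while (nrow(A) > 1) {
    k <- nrow(A)
    dvec <- rowSums(A)
    H <- outer(dvec, dvec, `+`) - 2 * (A %*% A) - 2 * A
    # m_ij = disagreements excluding columns i and j
    loss <- lchoose(k - 2, H) / log(2)
    diag(loss) <- Inf
    best <- min(loss)
    idx <- which(loss == best, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    total <- total + best
    merged <- pmin(A[i, ] + A[j, ], 1)
    A[i, ] <- merged; A[, i] <- merged
    A[i, i] <- 0
    A <- A[-j, -j, drop = FALSE]
  }
  total
}

#' Small worldness against a null ensemble
#'
#' `S-W = (T / mean(T_rand)) / (ASPL / mean(ASPL_rand))`, the classic
#' ratio-of-ratios of clustering and path length versus connected random
#' graphs with matched nodes and links.
#'
#' @param component Connected igraph with at least 2 nodes.
#' @param null A [build_null()] ensemble for this component.
#' @return Real; `NA` when the null mean transitivity is 0.
#' @export
small_worldness <- function(component, null) {
  check_null_match(component, null)
  t_r <- null_mean(null, "transitivity")
  a_r <- null_mean(null, "aspl")
  if (is.na(t_r) || t_r == 0) return(NA_real_)
  (transitivity_global(component) / t_r) / (aspl(component) / a_r)
}

#' Per-component metric table
#'
#' Computes the full metric battery for every component of one or more
#' networks. Size-1 components appear with size only (pairwise metrics
#' `NA`); transitivity of size-2 components is 0.
#'
#' @param networks A `synthetic_cohort`, a list of [mito_network()]s, or
#'   a single one.
#' @param louvain_seed Seed for the Louvain runs.
#' @return data.frame with one row per component: provenance columns,
#'   `size`, `links`, and each metric (including `diameter_over_n`, the
#'   raw diameter/size ratio).
#' @export
metrics_table <- function(networks, louvain_seed = 42L) {
  nets <- as_network_list(networks)
  rows <- list()
  for (net in nets) {
    comps <- extract_components(net)
    for (ci in seq_along(comps)) {
      cc <- comps[[ci]]
      n <- igraph::vcount(cc)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = net$subject_id, side = net$side,
        network_id = net$network_id,
        component_id = paste0(net$network_id, "_c", ci),
        size = n, links = igraph::ecount(cc),
        link_density = link_density(cc),
        max_degree = if (n < 2) NA_integer_ else max_degree(cc),
        aspl = if (n < 2) NA_real_ else aspl(cc),
        diameter = if (n < 2) NA_real_ else net_diameter(cc),
        diameter_over_n = if (n < 2) NA_real_ else net_diameter(cc) / n,
        efficiency = if (n < 2) NA_real_ else efficiency(cc),
        modularity = if (n < 2) NA_real_ else modularity_louvain(cc, louvain_seed)$Q,
        assortativity = if (n < 2) NA_real_ else assortativity_deg(cc),
        transitivity = transitivity_global(cc),
        information_content = if (n < 2) NA_real_ else information_content(cc))
    }
  }
  do.call(rbind, rows)
}

as_network_list <- function(networks) {
  if (inherits(networks, "synthetic_cohort"))
    return(unlist(lapply(networks$subjects, `[[`, "networks"),
                  recursive = FALSE))
  if (inherits(networks, "mito_network")) return(list(networks))
  if (igraph::is_igraph(networks)) return(list(mito_network(networks)))
  networks
}

#' Pool per-component metric values across networks
#'
#' Applies an optional inclusive size filter, then returns the pooled
#' per-component values of one metric column (the global-MIN view of a
#' subject or group).
#'
#' @param tbl A [metrics_table()]-style data.frame.
#' @param metric Column name to pool.
#' @param size_filter Optional `c(min, max)` inclusive bounds on
#'   component size.
#' @param drop_na Drop undefined values (default TRUE).
#' @return Numeric vector (possibly empty).
#' @export
global_metric_distribution <- function(tbl, metric, size_filter = NULL,
                                       drop_na = TRUE) {
  if (!metric %in% names(tbl)) stop_invalid("unknown metric '%s'", metric)
  if (!is.null(size_filter)) {
    if (length(size_filter) != 2 || size_filter[1] > size_filter[2])
      stop_invalid("size_filter must be c(min, max) with min <= max")
    tbl <- tbl[tbl$size >= size_filter[1] & tbl$size <= size_filter[2], ]
  }
  v <- tbl[[metric]]
  if (drop_na) v <- v[!is.na(v)]
  v
}
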