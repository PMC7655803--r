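#' Sample a connected random graph with fixed nodes and links
#'
#' Uniform draw from Erdos-Renyi G(n, l) conditioned on connectivity,
#' by rejection sampling. If no connected draw appears within
#' `max_rejects` attempts (very sparse large graphs), falls back to a
#' uniform spanning tree plus random extra links — a constructive sampler
#' that is connected by design but not exactly uniform; the result is
#' then flagged with attribute `biased = TRUE` and a warning is issued.
#'
#' @param n Nodes, at least 2.
#' @param l Links, between `n - 1` and `n (n - 1) / 2`.
#' @param max_rejects Rejection cap before the constructive fallback.
#' @return Connected igraph with exactly `n` nodes and `l` links.
#' @export
random_connected_graph <- function(n, l, max_rejects = 1e4) {
  if (n < 2) stop_invalid("n must be >= 2")
  if (l < n - 1 || l > n * (n - 1) / 2)
    stop_invalid("l must lie in [n-1, n(n-1)/2]")
  for (i in seq_len(max_rejects)) {
    g <- igraph::sample_gnm(n, l)
    if (igraph::is_connected(g)) return(g)
  }
  warning("rejection cap reached; using biased spanning-tree fallback")
  g <- igraph::sample_tree(n)
  extra <- l - (n - 1)
  if (extra > 0) {
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    free <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
    pick <- free[sample.int(nrow(free), extra), , drop = FALSE]
    g <- igraph::add_edges(g, t(pick))
  }
  attr(g, "biased") <- TRUE
  g
}

.null_metrics <- c("link_density", "max_degree", "aspl", "diameter",
                   "efficiency", "modularity", "assortativity",
                   "transitivity", "information_content")

#' Build the null ensemble for one component
#'
#' Generates `n_random` connected random graphs with the component's
#' exact node and link counts and caches the metric battery and motif
#' census of every member, plus per-metric mean/SD summaries used for
#' Z-score normalization.
#'
#' @param component Connected igraph with at least 2 nodes.
#' @param n_random Ensemble size.
#' @param seed Integer seed; the ensemble is reproducible given
#'   (component, seed).
#' @param keep_graphs Store the member graphs (default TRUE).
#' @return Object of class `null_ensemble`: `n`, `l`, `graphs`,
#'   `metrics` (matrix members x metrics), `motif_census` (members x
#'   classes), `summaries` (metric, mu, sigma), `seed`.
#' @export
build_null <- function(component, n_random = 100, seed = 1L,
                       keep_graphs = TRUE) {
  n <- igraph::vcount(component)
  l <- igraph::ecount(component)
  if (n < 2) stop_invalid("component size must be >= 2")
  local_seed(seed, {
    graphs <- replicate(n_random, random_connected_graph(n, l),
                        simplify = FALSE)
    met <- t(vapply(graphs, function(g) c(
      link_density = link_density(g),
      max_degree = as.numeric(max_degree(g)),
      aspl = aspl(g),
      diameter = net_diameter(g),
      efficiency = efficiency(g),
      modularity = modularity_louvain(g)$Q,
      assortativity = assortativity_deg(g),
      transitivity = transitivity_global(g),
      information_content = information_content(g)),
      numeric(length(.null_metrics))))
    census <- t(vapply(graphs, motif_census,
                       integer(length(.motif_classes))))
    summaries <- data.frame(
      metric = colnames(met),
      mu = colMeans(met, na.rm = TRUE),
      sigma = apply(met, 2, sd, na.rm = TRUE),
      row.names = NULL)
    structure(list(n = n, l = l,
                   graphs = if (keep_graphs) graphs else NULL,
                   metrics = met, motif_census = census,
                   summaries = summaries, seed = seed),
              class = "null_ensemble")
  })
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble: %d graphs, n=%d l=%d, seed %d>\n",
              nrow(x$metrics), x$n, x$l, x$seed))
  invisible(x)
}

check_null_match <- function(component, null) {
  stopifnot(inherits(null, "null_ensemble"))
  if (igraph::vcount(component) != null$n ||
      igraph::ecount(component) != null$l)
    stop_invalid("null ensemble does not match component (n=%d l=%d vs n=%d l=%d)",
                 null$n, null$l,
                 igraph::vcount(component), igraph::ecount(component))
  invisible(TRUE)
}

null_mean <- function(null, metric) {
  null$summaries$mu[match(metric, null$summaries$metric)]
}

#' Z-score of a metric against a null summary
#'
#' `z = (M - mu) / sigma`; when `sigma = 0` the record is flagged
#' undefined (`z = NA`) rather than infinite, and is excluded from
#' downstream histograms and tests.
#'
#' @param M Observed metric value.
#' @param mu,sigma Null mean and standard deviation.
#' @param metric Optional metric name carried in the record.
#' @param component_id Optional component id carried in the record.
#' @return One-row data.frame: `component_id`, `metric`, `M`, `mu`,
#'   `sigma`, `z`, `undefined`.
#' @export
zscore <- function(M, mu, sigma, metric = NA_character_,
                   component_id = NA_character_) {
  undef <- is.na(M) || is.na(sigma) || sigma == 0
  data.frame(component_id = component_id, metric = metric,
             M = M, mu = mu, sigma = sigma,
             z = if (undef) NA_real_ else (M - mu) / sigma,
             undefined = undef)
}

#' Z-scores of a component's metric battery
#'
#' @param component Connected igraph with at least 2 nodes.
#' @param null Matching [build_null()] ensemble.
#' @param component_id Id carried into the records.
#' @param louvain_seed Seed for the component's own Louvain run.
#' @return Long-format data.frame of [zscore()] records, one per metric.
#' @export
component_zscores <- function(component, null,
                              component_id = NA_character_,
                              louvain_seed = 42L) {
  check_null_match(component, null)
  obs <- c(link_density = link_density(component),
           max_degree = as.numeric(max_degree(component)),
           aspl = aspl(component),
           diameter = net_diameter(component),
           efficiency = efficiency(component),
           modularity = modularity_louvain(component, louvain_seed)$Q,
           assortativity = assortativity_deg(component),
           transitivity = transitivity_global(component),
           information_content = information_content(component))
  rows <- lapply(names(obs), function(mname) {
    s <- null$summaries[null$summaries$metric == mname, ]
    zscore(obs[[mname]], s$mu, s$sigma, metric = mname,
           component_id = component_id)
  })
  do.call(rbind, rows)
}

#' Z-score probability histogram
#'
#' Per-bin fraction `m / n`, where `m` is the number of components whose
#' Z-score falls in the bin and `n` the number of components with a
#' defined Z-score. With bins covering the full range the fractions sum
#' to 1.
#'
#' @param records data.frame of [zscore()] records (one metric).
#' @param bin_edges Strictly increasing numeric vector; defaults to
#'   width-0.5 bins on \[-5, 5\] with open outer bins.
#' @return data.frame `lower`, `upper`, `count`, `probability`; the
#'   number of dropped undefined records in attribute `n_undefined`.
#' @export
zscore_probability <- function(records, bin_edges = NULL) {
  if (nrow(records) == 0) stop_invalid("no records supplied")
  if (is.null(bin_edges)) bin_edges <- c(-Inf, seq(-5, 5, by = 0.5), Inf)
  if (any(diff(bin_edges) <= 0))
    stop_invalid("bin edges must be strictly increasing")
  z <- records$z[!records$undefined]
  n_undef <- sum(records$undefined)
  if (!length(z)) stop_invalid("all records are undefined")
  counts <- table(cut(z, bin_edges, right = FALSE, include.lowest = TRUE))
  out <- data.frame(lower = head(bin_edges, -1), upper = tail(bin_edges, -1),
                    count = as.integer(counts),
                    probability = as.integer(counts) / length(z))
  attr(out, "n_undefined") <- n_undef
  out
}
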