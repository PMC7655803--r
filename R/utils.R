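#' @importFrom stats sd cor rbinom runif rnorm quantile median coef vcov
#'   pnorm qnorm setNames ks.test cor.test predict nls.control
#' @importFrom utils combn head tail write.table read.table
NULL

# Run `code` under a local RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

# Canonical undirected graph from an edge matrix (2 columns of node ids 1..n).
graph_from_edges <- function(edges, n, weights = NULL) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  if (!is.null(weights)) igraph::E(g)$weight <- weights
  g
}
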