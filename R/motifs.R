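.motif_classes <- c("v3", "tri3", "p4_path", "p4_star", "p4_paw",
                    "p4_cycle", "p4_k4", "p4_diamond")

#' Induced 3-/4-node motif census
#'
#' Counts induced connected subgraphs on all node triples and quadruples,
#' classified up to isomorphism: `v3` (2-edge path, the partially
#' connected triad), `tri3` (triangle), and the six connected 4-node
#' classes `p4_path` (U-shape), `p4_star`, `p4_paw` (triangle plus
#' pendant), `p4_cycle`, `p4_diamond`, `p4_k4`. Enumeration is
#' exhaustive; disconnected subsets are not counted (their number is
#' implied by the binomial totals).
#'
#' On 4 nodes the sorted degree sequence of the induced subgraph
#' identifies the isomorphism class, so the census reduces to vectorized
#' edge lookups.
#'
#' @param component igraph (any graph; counts are 0 below the motif size).
#' @return Named integer vector over the eight classes.
#' @export
motif_census <- function(component) {
  n <- igraph::vcount(component)
  out <- setNames(integer(length(.motif_classes)), .motif_classes)
  if (n < 3) return(out)
  A <- as.matrix(igraph::as_adjacency_matrix(component))
  A[A > 0] <- 1L
  tri <- combn(n, 3)
  e3 <- A[cbind(tri[1, ], tri[2, ])] + A[cbind(tri[1, ], tri[3, ])] +
    A[cbind(tri[2, ], tri[3, ])]
  out["v3"] <- sum(e3 == 2L)
  out["tri3"] <- sum(e3 == 3L)
  if (n < 4) return(out)
  q <- combn(n, 4)
  e <- list(
    A[cbind(q[1, ], q[2, ])], A[cbind(q[1, ], q[3, ])],
    A[cbind(q[1, ], q[4, ])], A[cbind(q[2, ], q[3, ])],
    A[cbind(q[2, ], q[4, ])], A[cbind(q[3, ], q[4, ])])
  etot <- Reduce(`+`, e)
  # per-quadruple degrees of the four nodes
  d1 <- e[[1]] + e[[2]] + e[[3]]
  d2 <- e[[1]] + e[[4]] + e[[5]]
  d3 <- e[[2]] + e[[4]] + e[[6]]
  d4 <- e[[3]] + e[[5]] + e[[6]]
  dmax <- pmax(d1, d2, d3, d4)
  dmin <- pmin(d1, d2, d3, d4)
  # e=3: tree (path or star) unless a triangle + isolate (dmin 0)
  out["p4_path"]  <- sum(etot == 3L & dmax == 2L & dmin >= 1L)
  out["p4_star"]  <- sum(etot == 3L & dmax == 3L)
  # e=4 on 4 nodes is always connected: cycle or paw
  out["p4_cycle"] <- sum(etot == 4L & dmax == 2L)
  out["p4_paw"]   <- sum(etot == 4L & dmax == 3L)
  out["p4_diamond"] <- sum(etot == 5L)
  out["p4_k4"]    <- sum(etot == 6L)
  out
}

#' Z-scores of a motif census against a null ensemble
#'
#' Applies the Z-score normalization to each motif class using the
#' censuses of the ensemble members; classes whose null SD is zero are
#' flagged undefined (`NA`).
#'
#' @param counts Census from [motif_census()].
#' @param null A [build_null()] ensemble built for the same component
#'   (matching node and link counts).
#' @param component Optional: the component itself, to assert that the
#'   ensemble matches its node and link counts.
#' @return data.frame with `metric`, `M`, `mu`, `sigma`, `z`, `undefined`.
#' @export
motif_zscores <- function(counts, null, component = NULL) {
  stopifnot(inherits(null, "null_ensemble"))
  if (!is.null(component)) check_null_match(component, null)
  census <- null$motif_census
  rows <- lapply(.motif_classes, function(cl) {
    mu <- mean(census[, cl]); sig <- sd(census[, cl])
    zscore(counts[[cl]], mu, sig, metric = paste0(cl, "_z"))
  })
  do.call(rbind, rows)
}
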