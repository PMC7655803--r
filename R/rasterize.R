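#' Suppress degree-2 vertices of a weighted network
#'
#' Skeleton tracing cannot represent degree-2 vertices: a voxel with two
#' neighbours is, by the branch-point rule, part of a link interior. This
#' helper reduces a network to its homeomorphic core, the class of graphs
#' a voxel skeleton can encode: each degree-2 vertex with links
#' `(u,n,w1)` and `(n,v,w2)` is replaced by a link `(u,v,w1+w2-1)` (the
#' shared voxel counted once); self-loops created this way are dropped
#' and parallel links collapsed by summing weights, exactly as
#' [skeleton_to_network()] does.
#'
#' @param g igraph with edge attribute `weight`.
#' @return igraph with no degree-2 vertices.
#' @export
smooth_network <- function(g) {
  if (is.null(igraph::E(g)$weight)) igraph::E(g)$weight <- 2L
  repeat {
    # collapse parallels / drop loops first
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                          edge.attr.comb = list(weight = "sum"))
    deg <- igraph::degree(g)
    v2 <- which(deg == 2)
    if (!length(v2)) return(g)
    v <- v2[1]
    inc <- igraph::incident(g, v)
    nbs <- setdiff(unique(unlist(igraph::ends(g, inc, names = FALSE))), v)
    w <- sum(igraph::E(g)$weight[as.integer(inc)]) - 1L
    g <- igraph::delete_vertices(g, v)
    if (length(nbs) == 2) {
      # vertex ids shift after deletion
      nbs2 <- nbs - (nbs > v)
      g <- igraph::add_edges(g, nbs2, weight = w)
    } # length(nbs) == 1 means both links went to the same vertex: self-loop
  }
}

.corner_offsets <- rbind(c(1, 1), c(-1, 1), c(1, -1), c(-1, -1))

# voxel path for one edge; returns matrix of (x,y,z) rows incl both node voxels
.edge_path <- function(xu, xv, off_u, off_v, h, dz, z0) {
  au <- off_u[1]; bu <- off_u[2]; av <- off_v[1]; bv <- off_v[2]
  d <- sign((xv + av) - (xu + au))
  zs <- seq(z0 + dz, h - dz, by = dz)
  p <- rbind(c(xu, 0, z0), cbind(xu + au, bu, zs), c(xu + au, 2 * bu, h))
  if (bu == bv) {
    p <- rbind(p, cbind(seq(xu + au + d, xv + av - d, by = d), 3 * bu, h))
  } else {
    xc <- min(xu, xv) + 4
    p <- rbind(p,
               cbind(seq(xu + au + d, xc - d, by = d), 3 * bu, h),
               cbind(xc, seq(2 * bu, 2 * bv, by = -bu), h),
               cbind(seq(xc + d, xv + av - d, by = d), 3 * bv, h))
  }
  p <- rbind(p, c(xv + av, 2 * bv, h), cbind(xv + av, bv, rev(zs)),
             c(xv, 0, z0))
  unname(p)
}

#' Rasterize a component into a 3D voxel skeleton
#'
#' Embeds a connected graph in a voxel grid so that
#' [skeleton_to_network()] recovers it exactly: nodes become voxels with
#' as many 26-neighbours as their graph degree, links become chains of
#' degree-2 voxels routed through private slabs of the volume. The voxel
#' count of each routed path (including both node voxels) is recorded as
#' the expected link weight.
#'
#' Degree-2 vertices cannot be represented (their voxel would be
#' indistinguishable from a link interior); reduce the graph with
#' [smooth_network()] first. Vertices of degree above 8 exhaust the
#' collision-free attachment slots and raise an embedding error.
#'
#' @param component Connected igraph (no degree-2 vertices).
#' @param link_length Voxel length of the single link when the component
#'   is one edge (the only case with a free length choice).
#' @param max_retries Shuffled-order retries for slab slot assignment.
#' @return List of class `rasterized_component`: `skeleton` (a
#'   [voxel_skeleton()]), `node_coords` (row per vertex, 1-based), and
#'   `expected_edges` (`node_i`, `node_j`, `weight`).
#' @export
rasterize_to_skeleton <- function(component, link_length = 5,
                                  max_retries = 20) {
  g <- component
  n <- igraph::vcount(g)
  if (n == 1) {
    vol <- array(1L, c(1, 1, 1))
    return(structure(list(skeleton = voxel_skeleton(vol),
                          node_coords = cbind(1, 1, 1),
                          expected_edges = data.frame(node_i = integer(0),
                                                      node_j = integer(0),
                                                      weight = integer(0))),
                     class = "rasterized_component"))
  }
  if (!igraph::is_connected(g)) stop_invalid("component must be connected")
  if (n == 2) {
    if (link_length < 2) stop_invalid("link_length must be >= 2")
    vol <- array(0L, c(link_length, 1, 1))
    vol[, 1, 1] <- 1L
    return(structure(list(skeleton = voxel_skeleton(vol),
                          node_coords = rbind(c(1, 1, 1),
                                              c(link_length, 1, 1)),
                          expected_edges = data.frame(node_i = 1L, node_j = 2L,
                                                      weight = as.integer(link_length))),
                     class = "rasterized_component"))
  }
  deg <- igraph::degree(g)
  if (any(deg == 2))
    stop_invalid(paste("cannot embed a degree-2 vertex (indistinguishable",
                       "from a link interior); apply smooth_network() first"))
  if (any(deg > 8))
    stop_invalid("cannot embed vertices of degree > 8")
  el <- igraph::as_edgelist(g, names = FALSE)
  m <- nrow(el)
  xs <- 8 * (seq_len(n) - 1)
  z0 <- 0
  for (try in seq_len(max_retries)) {
    ord <- if (try == 1) seq_len(m) else sample.int(m)
    up_used <- integer(n); down_used <- integer(n)
    assign_dir <- integer(m); slot_u <- integer(m); slot_v <- integer(m)
    ok <- TRUE
    up_count <- 0L; down_count <- 0L
    slab <- integer(m)
    for (e in ord) {
      u <- el[e, 1]; v <- el[e, 2]
      if (up_used[u] < 4 && up_used[v] < 4) {
        assign_dir[e] <- 1L
        up_used[u] <- up_used[u] + 1L; slot_u[e] <- up_used[u]
        up_used[v] <- up_used[v] + 1L; slot_v[e] <- up_used[v]
        up_count <- up_count + 1L; slab[e] <- z0 + 1 + 2 * up_count
      } else if (down_used[u] < 4 && down_used[v] < 4) {
        assign_dir[e] <- -1L
        down_used[u] <- down_used[u] + 1L; slot_u[e] <- down_used[u]
        down_used[v] <- down_used[v] + 1L; slot_v[e] <- down_used[v]
        down_count <- down_count + 1L; slab[e] <- z0 - 1 - 2 * down_count
      } else { ok <- FALSE; break }
    }
    if (ok) break
    if (try == max_retries)
      stop_invalid("embedding failure: could not assign attachment slots")
  }
  paths <- vector("list", m)
  for (e in seq_len(m)) {
    u <- el[e, 1]; v <- el[e, 2]
    paths[[e]] <- .edge_path(xs[u], xs[v], .corner_offsets[slot_u[e], ],
                             .corner_offsets[slot_v[e], ],
                             slab[e], assign_dir[e], z0)
  }
  allv <- do.call(rbind, paths)
  shift <- apply(allv, 2, min) - 1L
  allv <- sweep(allv, 2, shift)
  dims <- apply(allv, 2, max)
  vol <- array(0L, dims)
  vol[allv] <- 1L
  node_coords <- cbind(xs, 0, z0)
  node_coords <- sweep(node_coords, 2, shift)
  # embedding sanity: every node voxel must have exactly `degree` neighbours,
  # every other voxel exactly 2
  pv <- pad_volume(vol)
  offs <- lin_offsets26(dim(pv))
  fg <- which(pv == 1L)
  vdeg <- rowSums(matrix(pv[outer(fg, offs, `+`)] == 1L, nrow = length(fg)))
  node_lin <- (node_coords[, 1] + 1) +
    (node_coords[, 2] + 1 - 1) * dim(pv)[1] +
    (node_coords[, 3] + 1 - 1) * dim(pv)[1] * dim(pv)[2]
  names(vdeg) <- fg
  if (!all(vdeg[as.character(node_lin)] == deg) ||
      !all(vdeg[!fg %in% node_lin] == 2))
    stop_invalid("embedding failure: voxel collision detected")
  expected <- data.frame(node_i = el[, 1], node_j = el[, 2],
                         weight = vapply(paths, nrow, 1L))
  structure(list(skeleton = voxel_skeleton(vol), node_coords = node_coords,
                 expected_edges = expected),
            class = "rasterized_component")
}
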