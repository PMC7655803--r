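#' A voxel skeleton
#'
#' One-voxel-thick binary 3D volume plus voxel spacing metadata.
#'
#' @param volume 3D array containing only 0/1.
#' @param voxel_spacing Positive length-3 numeric (micrometres per voxel).
#' @return Object of class `voxel_skeleton`.
#' @export
voxel_skeleton <- function(volume, voxel_spacing = c(1, 1, 1)) {
  if (length(dim(volume)) != 3L) stop_invalid("volume must be a 3D array")
  if (!all(volume %in% c(0, 1))) stop_invalid("volume must be binary {0,1}")
  if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0))
    stop_invalid("voxel_spacing must be 3 positive reals")
  structure(list(volume = volume, voxel_spacing = voxel_spacing),
            class = "voxel_skeleton")
}

# ---- 26-neighbourhood machinery --------------------------------------------

# 26 neighbour offsets (rows), excluding the origin
.offsets26 <- local({
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  o[rowSums(abs(o)) > 0, , drop = FALSE]
})

# linear-index offsets of the 26 neighbours in a padded array
lin_offsets26 <- function(d) {
  .offsets26[, 1] + .offsets26[, 2] * d[1] + .offsets26[, 3] * d[1] * d[2]
}

pad_volume <- function(vol) {
  d <- dim(vol)
  out <- array(0L, d + 2L)
  out[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- vol
  out
}

# ---- 3D thinning ------------------------------------------------------------

# Precomputed structures on the 3x3x3 cube (27 cells, center = 14).
.cube <- local({
  coords <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  n <- nrow(coords)
  cheb <- as.matrix(stats::dist(coords, method = "maximum"))
  manh <- as.matrix(stats::dist(coords, method = "manhattan"))
  adj26 <- cheb == 1
  adj6 <- manh == 1
  center <- which(rowSums(abs(coords)) == 0)
  n18 <- which(rowSums(abs(coords)) <= 2 & rowSums(abs(coords)) > 0)
  list(coords = coords, adj26 = adj26, adj6 = adj6,
       center = center, n18 = n18)
})

# count connected components of `cells` (indices into the 27-cube) under `adj`
.cube_ncomp <- function(cells, adj) {
  if (!length(cells)) return(0L)
  seen <- logical(length(cells))
  ncomp <- 0L
  idx <- seq_along(cells)
  sub <- adj[cells, cells, drop = FALSE]
  while (any(!seen)) {
    ncomp <- ncomp + 1L
    stack <- idx[!seen][1]
    seen[stack] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      nb <- idx[sub[v, ] & !seen]
      seen[nb] <- TRUE
      stack <- c(stack, nb)
    }
  }
  ncomp
}

# Bertrand's simple-point test on a 27-bit neighbourhood (center foreground):
# (a) foreground 26-neighbours form exactly one 26-component;
# (b) background cells of N18 that are 6-adjacent to the center form exactly
#     one 6-component within the 18-neighbourhood background.
.is_simple <- function(nbhd) {
  fg <- which(nbhd == 1)
  fg <- fg[fg != .cube$center]
  if (.cube_ncomp(fg, .cube$adj26) != 1L) return(FALSE)
  bg18 <- intersect(.cube$n18, which(nbhd == 0))
  if (!length(bg18)) return(FALSE)
  # restrict to the 6-component(s) of bg18 that touch the center by 6-adjacency
  sub <- .cube$adj6[bg18, bg18, drop = FALSE]
  touch <- .cube$adj6[bg18, .cube$center]
  if (!any(touch)) return(FALSE)
  # count 6-components of bg18; each must be checked for center adjacency
  seen <- logical(length(bg18))
  ncomp_touch <- 0L
  idx <- seq_along(bg18)
  while (any(!seen)) {
    stack <- idx[!seen][1]
    comp <- stack
    seen[stack] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      nb <- idx[sub[v, ] & !seen]
      seen[nb] <- TRUE
      comp <- c(comp, nb); stack <- c(stack, nb)
    }
    if (any(touch[comp])) ncomp_touch <- ncomp_touch + 1L
  }
  ncomp_touch == 1L
}

#' Thin a binary 3D mask to a one-voxel skeleton
#'
#' Sequential topology-preserving thinning: border voxels that are simple
#' points (removal changes neither the number of foreground 26-components
#' nor of background 6-components locally) and not curve endpoints are
#' deleted in directional sub-iterations until stability. Connected
#' components of the mask are preserved.
#'
#' @param mask 3D array of 0/1 (any non-zero treated as foreground after
#'   validation that values are binary).
#' @param voxel_spacing Passed through to the result.
#' @return A [voxel_skeleton()].
#' @export
skeletonize_mask <- function(mask, voxel_spacing = c(1, 1, 1)) {
  if (length(dim(mask)) != 3L) stop_invalid("mask must be a 3D array")
  if (!all(mask %in% c(0, 1))) stop_invalid("mask must be binary {0,1}")
  vol <- pad_volume(mask)
  d <- dim(vol)
  offs <- lin_offsets26(d)
  # 6-neighbour linear offsets, one per deletion direction
  off6 <- c(-1, 1, -d[1], d[1], -d[1] * d[2], d[1] * d[2])
  nb_idx <- function(i) i + offs
  repeat {
    deleted <- 0L
    for (dir in off6) {
      fg <- which(vol == 1L)
      if (!length(fg)) break
      border <- fg[vol[fg + dir] == 0L]
      for (i in border) {
        if (vol[i] == 0L) next
        nb <- vol[nb_idx(i)]
        if (sum(nb) <= 1L) next  # endpoint or isolated: keep
        nbhd <- integer(27); nbhd[.cube$center] <- 1L
        nbhd[-.cube$center] <- nb
        if (.is_simple(nbhd)) {
          vol[i] <- 0L
          deleted <- deleted + 1L
        }
      }
    }
    if (deleted == 0L) break
  }
  dm <- dim(mask)
  out <- vol[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1), drop = FALSE]
  voxel_skeleton(array(out, dm), voxel_spacing)
}

# ---- skeleton -> network ----------------------------------------------------

#' Convert a voxel skeleton into a weighted MIN
#'
#' Nodes are skeleton voxels whose 26-neighbour count differs from 2
#' (branch points and endpoints); links are traced through chains of
#' degree-2 voxels. The link weight `A_ij` is the voxel count of the
#' traced path including both terminal node voxels, so every link has
#' weight at least 2 and `A_ij > 0` iff a link exists. Parallel voxel
#' paths between the same node pair are collapsed (weights summed);
#' paths returning to their origin node are dropped. With `thr > 0`,
#' terminal branches shorter than `thr` voxels are pruned before node
#' detection.
#'
#' @param skel A [voxel_skeleton()] or bare binary 3D array.
#' @param thr Minimum terminal-branch length; 0 (the default) keeps
#'   everything.
#' @param subject_id,side,network_id Provenance recorded on the result.
#' @return A [mito_network()] with node voxel coordinates.
#' @export
skeleton_to_network <- function(skel, thr = 0, subject_id = NA_character_,
                                side = NA_character_,
                                network_id = NA_character_) {
  if (!inherits(skel, "voxel_skeleton")) skel <- voxel_skeleton(skel)
  vol <- pad_volume(skel$volume)
  d <- dim(vol)
  offs <- lin_offsets26(d)
  deg_of <- function(v, i) {
    m <- outer(i, offs, `+`)
    rowSums(matrix(v[m] == 1L, nrow = length(i)))
  }
  if (thr > 0) vol <- prune_short_branches(vol, offs, thr)
  fg <- which(vol == 1L)
  if (!length(fg)) {
    return(mito_network(igraph::make_empty_graph(0, directed = FALSE),
                        subject_id, side, network_id,
                        node_coords = matrix(numeric(0), 0, 3)))
  }
  deg <- deg_of(vol, fg)
  is_node <- deg != 2L
  # pure degree-2 cycles have no node voxel: promote the smallest voxel
  lab <- integer(length(fg)); lab[is_node] <- seq_len(sum(is_node))
  fgpos <- new.env(hash = TRUE, size = length(fg))
  for (j in seq_along(fg)) assign(as.character(fg[j]), j, envir = fgpos)
  getpos <- function(i) get(as.character(i), envir = fgpos)
  neighbors_of <- function(i) {
    cand <- i + offs
    cand[vol[cand] == 1L]
  }
  # mark voxels in degree-2 chains reachable from nodes; leftovers are cycles
  repeat {
    node_ids <- which(is_node)
    visited <- is_node
    for (np in node_ids) {
      stack <- np
      while (length(stack)) {
        v <- stack[length(stack)]; stack <- stack[-length(stack)]
        for (nb in neighbors_of(fg[v])) {
          p <- getpos(nb)
          if (!visited[p]) { visited[p] <- TRUE; stack <- c(stack, p) }
        }
      }
    }
    if (all(visited)) break
    # promote the smallest unvisited voxel of each leftover cycle
    is_node[which(!visited)[1]] <- TRUE
  }
  node_pos <- which(is_node)
  node_id <- integer(length(fg))
  node_id[node_pos] <- seq_along(node_pos)
  # trace links
  edges <- list(); weights <- integer(0)
  seen_interior <- logical(length(fg))
  direct <- new.env(hash = TRUE)
  for (np in node_pos) {
    for (nb in neighbors_of(fg[np])) {
      p <- getpos(nb)
      if (is_node[p]) {
        key <- paste(sort(c(np, p)), collapse = "-")
        if (!exists(key, envir = direct)) {
          assign(key, TRUE, envir = direct)
          edges[[length(edges) + 1L]] <- c(node_id[np], node_id[p])
          weights <- c(weights, 2L)
        }
        next
      }
      if (seen_interior[p]) next
      # walk the degree-2 chain
      chain <- p
      prev <- fg[np]; cur <- nb
      repeat {
        nbs <- neighbors_of(cur)
        nxt <- nbs[nbs != prev]
        if (length(nxt) != 1L)
          stop_invalid("non-thin skeleton: ambiguous tracing at voxel %d", cur)
        prev <- cur; cur <- nxt
        pc <- getpos(cur)
        if (is_node[pc]) break
        chain <- c(chain, pc)
      }
      seen_interior[chain] <- TRUE
      end <- getpos(cur)
      if (end == np) next  # self-loop: dropped
      edges[[length(edges) + 1L]] <- c(node_id[np], node_id[end])
      weights <- c(weights, length(chain) + 2L)
    }
  }
  n_nodes <- length(node_pos)
  if (length(edges)) {
    em <- do.call(rbind, edges)
    em <- t(apply(em, 1, sort))
    key <- paste(em[, 1], em[, 2])
    # interior-bearing links are traced once (visited marking blocks the
    # reverse walk) and direct links are deduped above, so duplicate pairs
    # are genuine parallel voxel paths: collapse by summing voxel counts
    agg <- tapply(weights, key, sum)
    pairs <- do.call(rbind, strsplit(names(agg), " "))
    em2 <- cbind(as.integer(pairs[, 1]), as.integer(pairs[, 2]))
    g <- graph_from_edges(em2, n_nodes, weights = as.integer(agg))
  } else {
    g <- igraph::make_empty_graph(n_nodes, directed = FALSE)
  }
  coords <- arrayInd(fg[node_pos], d) - 1L  # un-pad
  mito_network(g, subject_id, side, network_id, node_coords = coords)
}

# prune terminal branches shorter than thr voxels (endpoint to first node)
prune_short_branches <- function(vol, offs, thr) {
  repeat {
    fg <- which(vol == 1L)
    if (!length(fg)) return(vol)
    nbmat <- outer(fg, offs, `+`)
    deg <- rowSums(matrix(vol[nbmat] == 1L, nrow = length(fg)))
    ends <- fg[deg == 1L]
    removed_any <- FALSE
    for (e in ends) {
      if (vol[e] == 0L) next
      chain <- e; prev <- NA_integer_; cur <- e
      repeat {
        nbs <- cur + offs; nbs <- nbs[vol[nbs] == 1L]
        nxt <- if (is.na(prev)) nbs else nbs[nbs != prev]
        if (length(nxt) != 1L) break  # reached a node (or isolated)
        prev <- cur; cur <- nxt
        nbs2 <- cur + offs; nbs2 <- nbs2[vol[nbs2] == 1L]
        if (length(nbs2) != 2L) break  # cur is a node voxel: stop before it
        chain <- c(chain, cur)
      }
      if (length(chain) < thr) { vol[chain] <- 0L; removed_any <- TRUE }
    }
    if (!removed_any) return(vol)
  }
}

#' Load a TIFF stack as a binary volume
#'
#' @param path Path to a (multi-page) TIFF; any value > 0 maps to 1.
#' @return 3D 0/1 array, slices along the third dimension (Z order).
#' @export
load_mask_stack <- function(path) {
  slices <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  dims <- lapply(slices, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop_invalid("TIFF slices have inconsistent shapes")
  d2 <- dims[[1]]
  vol <- array(0L, c(d2[1], d2[2], length(slices)))
  for (z in seq_along(slices)) vol[, , z] <- (slices[[z]] > 0) * 1L
  vol
}

#' Write a binary volume as a multi-page TIFF
#'
#' @param volume 3D 0/1 array.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mask_stack <- function(volume, path) {
  slices <- lapply(seq_len(dim(volume)[3]),
                   function(z) volume[, , z] * 1.0)
  tiff::writeTIFF(slices, path)
  invisible(path)
}
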