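#' Specify a synthetic MIN cohort
#'
#' A cohort spec fixes the study conditions for the synthetic generator:
#' two subject groups whose mitochondrial components differ in their
#' size-distribution slope `k` (the base of the decay `P(s) ~ k^s`), their
#' triangle-closure propensity, and their chain bias (path-like wiring that
#' inflates ASPL and diameter, and depresses efficiency).
#'
#' @param n_group_a,n_group_b Number of subjects per group. Group "a" is
#'   labelled `PD`, group "b" `control`.
#' @param components_per_subject Connected components generated per subject
#'   (split evenly between a left and a right network).
#' @param size_slope_a,size_slope_b Base `k` of the component-size law
#'   `p(s) ~ k^s`, strictly inside (0, 1). Larger `k` means heavier tails,
#'   i.e. more large components.
#' @param min_size,max_size Inclusive truncation bounds of the size support.
#' @param triangle_propensity_a,triangle_propensity_b Probability in \[0, 1\]
#'   that an extra link closes an open triad rather than joining a random
#'   non-adjacent pair.
#' @param chain_bias_a,chain_bias_b Wiring bias in \[0, 1\]: 0 gives a random
#'   spanning tree, 1 a path.
#' @param extra_link_rate Expected extra links per node beyond the spanning
#'   tree (binomially sampled).
#' @param subject_sd Between-subject SD added to the group chain bias; also
#'   drives the synthetic UPDRS score so that severity couples to wiring.
#' @param seed Integer seed making the cohort a pure function of the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_group_a = 4, n_group_b = 4,
                        components_per_subject = 200,
                        size_slope_a = 0.75, size_slope_b = 0.65,
                        min_size = 2, max_size = 28,
                        triangle_propensity_a = 0.6, triangle_propensity_b = 0.3,
                        chain_bias_a = 0.8, chain_bias_b = 0.4,
                        extra_link_rate = 0.15,
                        subject_sd = 0.05,
                        seed = 1L) {
  counts <- c(n_group_a = n_group_a, n_group_b = n_group_b,
              components_per_subject = components_per_subject,
              min_size = min_size, max_size = max_size)
  if (any(counts < 1) || any(counts != round(counts)))
    stop_invalid("all counts must be positive integers")
  for (k in c(size_slope_a, size_slope_b))
    if (!(k > 0 && k < 1)) stop_invalid("size slopes must lie strictly in (0,1)")
  for (p in c(triangle_propensity_a, triangle_propensity_b,
              chain_bias_a, chain_bias_b))
    if (p < 0 || p > 1) stop_invalid("propensities and biases must lie in [0,1]")
  if (min_size < 2) stop_invalid("min_size must be >= 2")
  if (min_size > max_size) stop_invalid("min_size must be <= max_size")
  structure(list(
    n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
    components_per_subject = as.integer(components_per_subject),
    size_slope_a = size_slope_a, size_slope_b = size_slope_b,
    min_size = as.integer(min_size), max_size = as.integer(max_size),
    triangle_propensity_a = triangle_propensity_a,
    triangle_propensity_b = triangle_propensity_b,
    chain_bias_a = chain_bias_a, chain_bias_b = chain_bias_b,
    extra_link_rate = extra_link_rate, subject_sd = subject_sd,
    seed = as.integer(seed)), class = "cohort_spec")
}

#' Sample component sizes from the truncated decay law
#'
#' Draws sizes from the discrete distribution `p(s) proportional to k^s`
#' on the inclusive support `min_size:max_size` (a truncated geometric
#' family; its cumulative tail decays as `k^s`).
#'
#' @param slope_k Base of the decay, strictly in (0, 1).
#' @param n Number of draws.
#' @param min_size,max_size Inclusive support bounds.
#' @return Integer vector of `n` sizes.
#' @export
sample_component_sizes <- function(slope_k, n, min_size = 2, max_size = 28) {
  if (!(slope_k > 0 && slope_k < 1))
    stop_invalid("slope_k must lie strictly in (0,1)")
  if (n < 1) stop_invalid("n must be >= 1")
  if (min_size > max_size) stop_invalid("min_size must be <= max_size")
  support <- min_size:max_size
  if (length(support) == 1L) return(rep(as.integer(support), n))
  # normalize in a numerically safe way (k^s underflows for huge s)
  logw <- support * log(slope_k)
  w <- exp(logw - max(logw))
  sample(support, n, replace = TRUE, prob = w)
}

#' Generate one connected component
#'
#' Builds a connected graph on `size` nodes: a spanning structure that
#' interpolates between a random tree (`chain_bias = 0`) and a path
#' (`chain_bias = 1`), plus `n_extra` links each closing a random open
#' triad with probability `triangle_propensity`, else joining a uniform
#' random non-adjacent pair. Link weights are uniform integers in
#' \[2, 20\] (voxel-count stand-ins; topology metrics ignore them).
#'
#' @param size Number of nodes, at least 2.
#' @param triangle_propensity,chain_bias Wiring knobs in \[0, 1\].
#' @param n_extra Number of extra links beyond the spanning tree
#'   (default binomial with mean `extra_link_rate * size`).
#' @param extra_link_rate Mean extra links per node when `n_extra` is NULL.
#' @return An igraph object with integer edge weights.
#' @export
generate_component <- function(size, triangle_propensity = 0.5,
                               chain_bias = 0.5, n_extra = NULL,
                               extra_link_rate = 0.15) {
  if (size < 2) stop_invalid("component size must be >= 2")
  size <- as.integer(size)
  if (is.null(n_extra)) n_extra <- rbinom(1L, size, min(1, extra_link_rate))
  ord <- sample.int(size)
  parent <- integer(size - 1L)
  for (i in 2:size) {
    parent[i - 1L] <- if (i == 2L || runif(1) < chain_bias) ord[i - 1L]
                      else ord[sample.int(i - 1L, 1L)]
  }
  edges <- cbind(parent, ord[2:size])
  adj <- matrix(FALSE, size, size)
  adj[edges] <- TRUE; adj[edges[, 2:1, drop = FALSE]] <- TRUE
  for (e in seq_len(n_extra)) {
    added <- FALSE
    if (runif(1) < triangle_propensity) {
      # open triads through a random center node
      deg <- rowSums(adj)
      centers <- which(deg >= 2)
      if (length(centers)) {
        ctr <- centers[sample.int(length(centers), 1L)]
        nb <- which(adj[ctr, ])
        open <- which(!adj[nb, nb] & upper.tri(matrix(0, length(nb), length(nb))),
                      arr.ind = TRUE)
        if (nrow(open)) {
          pick <- open[sample.int(nrow(open), 1L), ]
          i <- nb[pick[1L]]; j <- nb[pick[2L]]
          adj[i, j] <- adj[j, i] <- TRUE
          edges <- rbind(edges, c(i, j)); added <- TRUE
        }
      }
    }
    if (!added) {
      free <- which(!adj & upper.tri(adj), arr.ind = TRUE)
      free <- free[free[, 1] != free[, 2], , drop = FALSE]
      if (nrow(free) == 0L) break
      pick <- free[sample.int(nrow(free), 1L), ]
      adj[pick[1L], pick[2L]] <- adj[pick[2L], pick[1L]] <- TRUE
      edges <- rbind(edges, pick)
    }
  }
  w <- sample(2:20, nrow(edges), replace = TRUE)
  graph_from_edges(edges, size, weights = w)
}

#' Generate a full synthetic cohort
#'
#' Deterministic in `spec$seed`. Each subject receives a group label
#' (`PD` for group a, `control` for group b), a subject-level wiring
#' jitter, a synthetic UPDRS score coupled to that jitter (PD only), and
#' `components_per_subject` components split into a left-side and a
#' right-side network (disjoint unions of components).
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: list of subject records
#'   (`subject_id`, `group`, `updrs`, `networks` of class `mito_network`)
#'   plus the provenance spec.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  local_seed(spec$seed, {
    subjects <- list()
    groups <- c(rep("a", spec$n_group_a), rep("b", spec$n_group_b))
    for (si in seq_along(groups)) {
      grp <- groups[si]
      label <- if (grp == "a") "PD" else "control"
      id <- sprintf("S%02d", si)
      slope <- if (grp == "a") spec$size_slope_a else spec$size_slope_b
      tri   <- if (grp == "a") spec$triangle_propensity_a else spec$triangle_propensity_b
      chain <- if (grp == "a") spec$chain_bias_a else spec$chain_bias_b
      jitter <- rnorm(1, 0, spec$subject_sd)
      chain_s <- min(1, max(0, chain + jitter))
      updrs <- if (label == "PD") round(30 + 150 * jitter + rnorm(1, 0, 2), 1)
               else NA_real_
      sizes <- sample_component_sizes(slope, spec$components_per_subject,
                                      spec$min_size, spec$max_size)
      comps <- lapply(sizes, generate_component,
                      triangle_propensity = tri, chain_bias = chain_s,
                      extra_link_rate = spec$extra_link_rate)
      half <- ceiling(length(comps) / 2)
      right_idx <- if (half < length(comps)) seq.int(half + 1, length(comps))
                   else integer(0)
      sides <- list(left = comps[seq_len(half)], right = comps[right_idx])
      sides <- sides[vapply(sides, length, 1L) > 0]
      networks <- lapply(names(sides), function(sd_name) {
        g <- Reduce(igraph::disjoint_union, sides[[sd_name]])
        mito_network(g, subject_id = id, side = sd_name,
                     network_id = paste0(id, "_", sd_name))
      })
      subjects[[si]] <- list(subject_id = id, group = label,
                             updrs = updrs, networks = networks)
    }
    structure(list(subjects = subjects, provenance = spec),
              class = "synthetic_cohort")
  })
}

#' A mitochondria interaction network (MIN)
#'
#' Thin container binding a weighted undirected igraph to its provenance:
#' subject, body side and network id; optionally per-node voxel coordinates.
#'
#' @param graph igraph object; edge attribute `weight` holds voxel counts.
#' @param subject_id,side,network_id Provenance strings (`side` one of
#'   `"left"`, `"right"`, `NA`).
#' @param node_coords Optional matrix of voxel coordinates (one row per node).
#' @return Object of class `mito_network`.
#' @export
mito_network <- function(graph, subject_id = NA_character_,
                         side = NA_character_, network_id = NA_character_,
                         node_coords = NULL) {
  stopifnot(igraph::is_igraph(graph))
  structure(list(graph = graph, subject_id = subject_id, side = side,
                 network_id = network_id, node_coords = node_coords),
            class = "mito_network")
}

#' @export
print.mito_network <- function(x, ...) {
  cat(sprintf("<mito_network %s subject=%s side=%s: %d nodes, %d links>\n",
              x$network_id, x$subject_id, x$side,
              as.integer(igraph::vcount(x$graph)),
              as.integer(igraph::ecount(x$graph))))
  invisible(x)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d subjects, %d components/subject, seed %d>\n",
              length(x$subjects), x$provenance$components_per_subject,
              x$provenance$seed))
  invisible(x)
}

#' Write a cohort to disk as edge lists plus a manifest
#'
#' One TSV per network (`node_i`, `node_j`, `weight`) and a manifest TSV
#' with columns `subject_id`, `group`, `side`, `updrs`, `network_path`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (subj in cohort$subjects) {
    for (net in subj$networks) {
      path <- file.path(dir, paste0(net$network_id, ".tsv"))
      el <- igraph::as_edgelist(net$graph, names = FALSE)
      df <- data.frame(node_i = el[, 1], node_j = el[, 2],
                       weight = igraph::E(net$graph)$weight %||%
                         rep(1L, nrow(el)))
      write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subj$subject_id, group = subj$group, side = net$side,
        updrs = subj$updrs, network_path = basename(path))
    }
  }
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.tsv` and network TSVs.
#' @return A `synthetic_cohort`-shaped list (no provenance spec).
#' @export
read_cohort <- function(dir) {
  manifest <- read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                         header = TRUE, stringsAsFactors = FALSE)
  subjects <- lapply(split(manifest, manifest$subject_id), function(m) {
    networks <- lapply(seq_len(nrow(m)), function(i) {
      df <- read.table(file.path(dir, m$network_path[i]), sep = "\t",
                       header = TRUE)
      n <- max(df$node_i, df$node_j)
      g <- graph_from_edges(cbind(df$node_i, df$node_j), n, weights = df$weight)
      mito_network(g, subject_id = m$subject_id[i], side = m$side[i],
                   network_id = sub("\\.tsv$", "", m$network_path[i]))
    })
    list(subject_id = m$subject_id[1], group = m$group[1],
         updrs = m$updrs[1], networks = networks)
  })
  names(subjects) <- NULL
  structure(list(subjects = subjects, provenance = NULL),
            class = "synthetic_cohort")
}
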