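p4 <- igraph::make_graph(c(1, 2, 2, 3, 3, 4), directed = FALSE)

test_that("hand-enumerated path and complete-graph values are reproduced", {
  expect_equal(aspl(p4), 10 / 6)
  expect_equal(net_diameter(p4), 3)
  expect_equal(efficiency(p4), (3 * 1 + 2 * 0.5 + 1 / 3) / 6)
  expect_equal(link_density(p4), 0.5)
  expect_equal(max_degree(p4), 2)
  for (n in c(3, 5, 8)) {
    kn <- igraph::make_full_graph(n)
    expect_equal(aspl(kn), 1)
    expect_equal(net_diameter(kn), 1)
    expect_equal(efficiency(kn), 1)
    expect_equal(normalized_degree(kn), rep((n - 1) / n, n))
  }
})

test_that("normalized degree satisfies the handshake identity", {
  set.seed(41)
  for (i in 1:20) {
    g <- random_connected_test_graph(30)
    expect_equal(sum(normalized_degree(g)),
                 2 * igraph::ecount(g) / igraph::vcount(g))
    expect_equal(link_density(g),
                 2 * igraph::ecount(g) /
                   (igraph::vcount(g) * (igraph::vcount(g) - 1)))
  }
})

test_that("distance metrics equal the Floyd-Warshall oracle", {
  set.seed(43)
  for (i in 1:30) {
    g <- random_connected_test_graph(40)
    D <- fw_distances(adj_of(g))
    off <- D[row(D) != col(D)]
    expect_equal(aspl(g), mean(off))
    expect_equal(net_diameter(g), max(off))
    expect_equal(efficiency(g), mean(1 / off))
    expect_equal(max_degree(g), max(rowSums(adj_of(g))))
  }
})

test_that("metric inequalities hold and edges never lengthen paths", {
  set.seed(47)
  for (i in 1:25) {
    g <- random_connected_test_graph(30)
    expect_gte(efficiency(g), 1 / aspl(g) - 1e-12)
    expect_gte(net_diameter(g), aspl(g))
    A <- adj_of(g)
    free <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
    if (nrow(free)) {
      pick <- free[sample.int(nrow(free), 1), ]
      g2 <- igraph::add_edges(g, pick)
      expect_lte(aspl(g2), aspl(g))
      expect_lte(net_diameter(g2), net_diameter(g))
    }
  }
})

test_that("Louvain modularity matches exhaustive partition search", {
  two_tri <- igraph::make_graph(c(1, 2, 2, 3, 3, 1, 4, 5, 5, 6, 6, 4, 1, 4),
                                directed = FALSE)
  res <- modularity_louvain(two_tri)
  expect_equal(res$Q, 5 / 14)
  expect_equal(length(unique(res$membership)), 2)
  expect_equal(brute_best_modularity(two_tri), 5 / 14)

  k6 <- igraph::make_full_graph(6)
  expect_equal(modularity_louvain(k6)$Q, 0)

  star <- igraph::make_star(6, mode = "undirected")
  expect_equal(modularity_louvain(star)$Q, brute_best_modularity(star),
               tolerance = 1e-12)
  # deterministic under a fixed seed
  expect_identical(modularity_louvain(two_tri, seed = 7L),
                   modularity_louvain(two_tri, seed = 7L))
})

test_that("assortativity matches igraph and flags regular graphs undefined", {
  expect_equal(assortativity_deg(igraph::make_star(4, mode = "undirected")), -1)
  expect_true(is.na(assortativity_deg(igraph::make_ring(5))))
  set.seed(53)
  for (i in 1:20) {
    g <- random_connected_test_graph(25)
    mine <- assortativity_deg(g)
    ref <- igraph::assortativity_degree(g)
    if (is.na(mine)) expect_true(is.nan(ref) || is.na(ref))
    else expect_equal(mine, ref)
  }
})

test_that("transitivity matches brute-force triple enumeration", {
  paw <- igraph::make_graph(c(1, 2, 2, 3, 3, 1, 3, 4), directed = FALSE)
  expect_equal(transitivity_global(paw), 0.6)
  expect_equal(transitivity_global(igraph::make_full_graph(3)), 1)
  expect_equal(transitivity_global(igraph::make_full_graph(4)), 1)
  expect_equal(transitivity_global(igraph::make_star(4, mode = "undirected")), 0)
  set.seed(59)
  for (i in 1:15) {
    g <- random_connected_test_graph(20)
    expect_equal(transitivity_global(g), brute_transitivity(g))
  }
})

test_that("information content vanishes on complete graphs and grows with disorder", {
  for (n in c(4, 8, 12)) {
    expect_equal(information_content(igraph::make_full_graph(n)), 0)
  }
  # two nodes with identical neighbourhoods cost nothing to merge
  expect_equal(information_content(igraph::make_star(3, mode = "undirected")), 0)
  set.seed(61)
  er_ic <- replicate(20, {
    g <- random_connected_graph(12, sample(20:40, 1))
    information_content(g)
  })
  expect_gt(mean(er_ic), 0)
  expect_gte(min(er_ic), 0)
})

test_that("small worldness is 1 for complete graphs and 0 for trees", {
  k4 <- igraph::make_full_graph(4)
  nl <- build_null(k4, 20, seed = 5)
  expect_equal(small_worldness(k4, nl), 1)

  p5 <- igraph::make_graph(c(1, 2, 2, 3, 3, 4, 4, 5), directed = FALSE)
  nl5 <- build_null(p5, 50, seed = 5)
  tmean <- nl5$summaries$mu[nl5$summaries$metric == "transitivity"]
  if (tmean > 0) expect_equal(small_worldness(p5, nl5), 0)

  # lattice plus shortcut is small-world on average
  set.seed(67)
  g <- igraph::make_ring(12)
  chords <- cbind(1:12, (1:12 + 1) %% 12 + 1)  # (i, i+2) ring chords
  g <- igraph::add_edges(g, t(chords))
  g <- igraph::add_edges(g, c(1, 7))
  vals <- vapply(1:5, function(s) small_worldness(g, build_null(g, 30, seed = s)), 1)
  expect_gt(mean(vals), 1)

  expect_error(small_worldness(k4, nl5), "match")
})

test_that("metric pooling applies inclusive size filters", {
  tbl <- data.frame(size = c(10, 24, 30), efficiency = c(0.9, 0.8, 0.7))
  expect_equal(global_metric_distribution(tbl, "efficiency", c(24, 28)), 0.8)
  expect_equal(global_metric_distribution(tbl, "efficiency"), c(0.9, 0.8, 0.7))
  expect_error(global_metric_distribution(tbl, "efficiency", c(28, 24)),
               "size_filter")
  expect_error(global_metric_distribution(tbl, "nope"), "unknown")
})

test_that("component extraction matches flood-fill structure and ordering", {
  g <- igraph::disjoint_union(igraph::make_full_graph(3),
                              igraph::make_full_graph(3))
  comps <- extract_components(g)
  expect_equal(length(comps), 2)
  expect_equal(vapply(comps, igraph::vcount, numeric(1)), c(3, 3))
  expect_equal(extract_components(igraph::make_empty_graph(0, directed = FALSE)),
               list())
  # partition identical to igraph's membership on a random disconnected graph
  set.seed(71)
  h <- igraph::sample_gnp(50, 0.03)
  comps <- extract_components(h)
  memb <- igraph::components(h)$membership
  expect_equal(length(comps), max(memb))
  expect_equal(sum(vapply(comps, igraph::vcount, numeric(1))), 50)
  sizes <- vapply(comps, igraph::vcount, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})
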