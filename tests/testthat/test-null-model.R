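test_that("connected G(n,l) sampler matches exact enumeration on small cases", {
  set.seed(91)
  # n=3, l=2: the three labeled paths, each ~ 1/3
  draws <- replicate(3000, paste(sort(apply(
    igraph::as_edgelist(random_connected_graph(3, 2)), 1,
    function(e) paste(sort(e), collapse = "-"))), collapse = "|"))
  freq <- table(draws) / 3000
  expect_equal(length(freq), 3L)
  se <- sqrt(1 / 3 * 2 / 3 / 3000)
  expect_true(all(abs(freq - 1 / 3) <= 4 * se))

  # n=4, l=3: always a tree; all 16 labeled trees appear
  tree_draws <- replicate(4000, {
    g <- random_connected_graph(4, 3)
    paste(sort(apply(igraph::as_edgelist(g), 1,
                     function(e) paste(sort(e), collapse = "-"))),
          collapse = "|")
  })
  expect_equal(length(unique(tree_draws)), 16L)

  # n=5, l=10 is forced to K5
  g <- random_connected_graph(5, 10)
  expect_equal(igraph::ecount(g), 10)
  expect_equal(min(igraph::degree(g)), 4)

  expect_error(random_connected_graph(4, 2), "l must")
  expect_error(random_connected_graph(4, 7), "l must")
  expect_error(random_connected_graph(1, 0), "n must")
})

test_that("accepted draws are uniform over connected graphs at (4,4)", {
  set.seed(93)
  # enumerate connected labeled graphs with 4 nodes, 4 edges
  pairs <- utils::combn(4, 2)
  subsets <- utils::combn(6, 4)
  keys <- character(0)
  for (i in seq_len(ncol(subsets))) {
    el <- pairs[, subsets[, i], drop = FALSE]
    g <- igraph::graph_from_edgelist(t(el), directed = FALSE)
    if (igraph::vcount(g) == 4 && igraph::is_connected(g))
      keys <- c(keys, paste(sort(apply(el, 2, function(e)
        paste(sort(e), collapse = "-"))), collapse = "|"))
  }
  n_classes <- length(keys)
  draws <- replicate(4000, paste(sort(apply(
    igraph::as_edgelist(random_connected_graph(4, 4)), 1,
    function(e) paste(sort(e), collapse = "-"))), collapse = "|"))
  freq <- table(factor(draws, levels = keys)) / 4000
  p <- 1 / n_classes
  se <- sqrt(p * (1 - p) / 4000)
  expect_true(all(abs(freq - p) <= 4 * se))
})

test_that("ensembles hold exact (n, l) and connectivity for every member", {
  set.seed(97)
  for (i in 1:5) {
    g <- generate_component(sample(5:15, 1), 0.4, 0.4)
    nl <- build_null(g, 100, seed = i)
    expect_equal(length(nl$graphs), 100)
    for (memb in nl$graphs) {
      expect_equal(igraph::vcount(memb), nl$n)
      expect_equal(igraph::ecount(memb), nl$l)
      expect_true(igraph::is_connected(memb))
    }
  }
  expect_error(build_null(igraph::make_empty_graph(1, directed = FALSE)),
               "size")
})

test_that("null summaries are reproducible and stable in ensemble size", {
  g <- generate_component(10, 0.5, 0.5, n_extra = 3)
  a <- build_null(g, 60, seed = 5)
  b <- build_null(g, 60, seed = 5)
  expect_equal(a$summaries, b$summaries)
  big <- build_null(g, 120, seed = 6)
  for (mm in c("aspl", "efficiency", "transitivity")) {
    mu1 <- a$summaries$mu[a$summaries$metric == mm]
    mu2 <- big$summaries$mu[big$summaries$metric == mm]
    sg <- a$summaries$sigma[a$summaries$metric == mm]
    expect_lt(abs(mu1 - mu2), max(3 * sg / sqrt(60), 1e-9))
  }
  # K4 admits a single graph: all defined null SDs vanish (assortativity is
  # undefined on regular graphs and stays NA)
  nk <- build_null(igraph::make_full_graph(4), 30, seed = 1)
  expect_true(all(nk$summaries$sigma == 0, na.rm = TRUE))
  expect_true(is.na(nk$summaries$sigma[nk$summaries$metric == "assortativity"]))
})

test_that("Z-score records follow the normalization formula", {
  z <- zscore(5, 3, 1)
  expect_equal(z$z, 2)
  expect_false(z$undefined)
  expect_equal(zscore(3, 3, 1)$z, 0)
  z0 <- zscore(4, 4, 0)
  expect_true(z0$undefined)
  expect_true(is.na(z0$z))
})

test_that("Z-score probabilities are per-bin fractions that conserve mass", {
  recs <- do.call(rbind, lapply(c(rep(0.1, 3), rep(2.2, 9)), zscore,
                                mu = 0, sigma = 1))
  h <- zscore_probability(recs, bin_edges = c(-1, 1, 3))
  expect_equal(h$probability, c(3 / 12, 9 / 12))
  h1 <- zscore_probability(recs, bin_edges = c(-10, 10))
  expect_equal(h1$probability, 1)
  set.seed(101)
  recs2 <- do.call(rbind, lapply(rnorm(200), zscore, mu = 0, sigma = 1))
  h2 <- zscore_probability(recs2)
  expect_equal(sum(h2$probability), 1, tolerance = 1e-12)
  expect_error(zscore_probability(recs[0, ]), "records")
  expect_error(zscore_probability(recs, bin_edges = c(1, 1)), "increasing")
})

test_that("component Z-scores recompute and respect the matching contract", {
  set.seed(103)
  g <- generate_component(12, 0.5, 0.5, n_extra = 3)
  nl <- build_null(g, 50, seed = 11)
  zs <- component_zscores(g, nl, component_id = "c1")
  row <- zs[zs$metric == "efficiency", ]
  expect_equal(row$z, (efficiency(g) - row$mu) / row$sigma)
  other <- generate_component(13, 0.5, 0.5)
  expect_error(component_zscores(other, nl), "match")
})
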