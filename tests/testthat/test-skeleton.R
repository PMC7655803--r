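# build a volume from a matrix of voxel coordinates (rows, 1-based)
vol_from_coords <- function(coords, dims = apply(coords, 2, max)) {
  v <- array(0L, dims)
  v[coords] <- 1L
  v
}

test_that("a straight line extracts as one link with voxel-count weight", {
  v <- array(0L, c(5, 1, 1)); v[, 1, 1] <- 1L
  net <- skeleton_to_network(v)
  expect_equal(igraph::vcount(net$graph), 2)
  expect_equal(igraph::ecount(net$graph), 1)
  expect_equal(igraph::E(net$graph)$weight, 5L)
})

test_that("a corner-armed T extracts as 1 branch + 3 ends with weight-4 links", {
  # junction at the center, three 3-voxel arms leaving along corner
  # directions (pairwise non-adjacent first steps)
  ctr <- c(4, 4, 4)
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1))
  coords <- ctr
  for (d in 1:3) for (k in 1:3) coords <- rbind(coords, ctr + k * dirs[d, ])
  net <- skeleton_to_network(vol_from_coords(coords, c(7, 7, 7)))
  expect_equal(igraph::vcount(net$graph), 4)
  expect_equal(igraph::ecount(net$graph), 3)
  expect_equal(igraph::E(net$graph)$weight, rep(4L, 3))
  expect_equal(sort(igraph::degree(net$graph)), c(1, 1, 1, 3))
  # voxel conservation: interiors + nodes account for every skeleton voxel
  total <- sum(igraph::E(net$graph)$weight - 2) + igraph::vcount(net$graph)
  expect_equal(total, nrow(coords))
})

test_that("empty volumes and isolated voxels are handled", {
  empty <- array(0L, c(3, 3, 3))
  net <- skeleton_to_network(empty)
  expect_equal(igraph::vcount(net$graph), 0)
  one <- array(0L, c(3, 3, 3)); one[2, 2, 2] <- 1L
  net1 <- skeleton_to_network(one)
  expect_equal(igraph::vcount(net1$graph), 1)
  expect_equal(igraph::ecount(net1$graph), 0)
})

test_that("two adjacent branch voxels form a weight-2 link", {
  # two junctions side by side, each with two corner arms
  c1 <- c(5, 5, 5); c2 <- c(6, 5, 5)
  coords <- rbind(c1, c2)
  for (k in 1:2) coords <- rbind(coords,
                                 c1 + k * c(-1, 1, 1), c1 + k * c(-1, -1, -1),
                                 c2 + k * c(1, 1, -1), c2 + k * c(1, -1, 1))
  net <- skeleton_to_network(vol_from_coords(coords, c(9, 9, 9)))
  expect_equal(igraph::vcount(net$graph), 6)  # 2 junctions + 4 ends
  ws <- igraph::E(net$graph)$weight
  expect_true(2L %in% ws)
  expect_equal(sum(ws == 3L), 4)
})

test_that("thr prunes short terminal branches only", {
  # junction with two 4-voxel arms and one 1-voxel spur (corner directions)
  ctr <- c(5, 5, 5)
  coords <- ctr
  for (k in 1:4) coords <- rbind(coords, ctr + k * c(1, 1, 1),
                                 ctr + k * c(1, -1, -1))
  coords <- rbind(coords, ctr + c(-1, 1, -1))  # spur
  v <- vol_from_coords(coords, c(9, 9, 9))
  net0 <- skeleton_to_network(v, thr = 0)
  expect_equal(igraph::vcount(net0$graph), 4)  # junction + 2 arm ends + spur end
  expect_equal(sort(igraph::E(net0$graph)$weight), c(2L, 5L, 5L))
  net2 <- skeleton_to_network(v, thr = 2)
  expect_equal(igraph::vcount(net2$graph), 2)
  expect_equal(igraph::E(net2$graph)$weight, 9L)
})

test_that("thinning keeps already-thin structures and preserves components", {
  bar <- array(0L, c(1, 1, 7)); bar[1, 1, ] <- 1L
  sk <- skeletonize_mask(bar)
  expect_equal(sk$volume, bar)

  empty <- array(0L, c(4, 4, 4))
  expect_equal(sum(skeletonize_mask(empty)$volume), 0)

  cube <- array(1L, c(5, 5, 5))
  sk2 <- skeletonize_mask(cube)
  expect_gt(sum(sk2$volume), 0)
  net <- skeleton_to_network(sk2$volume)
  comps <- extract_components(net)
  expect_equal(length(comps), 1)

  # two disjoint bars stay two components
  two <- array(0L, c(9, 3, 3))
  two[1:3, 2, 2] <- 1L; two[7:9, 2, 2] <- 1L
  skt <- skeletonize_mask(two)
  expect_equal(length(extract_components(skeleton_to_network(skt$volume))), 2)

  expect_error(skeletonize_mask(array(2, c(2, 2, 2))), "binary")
})

test_that("TIFF stacks round-trip as binary volumes", {
  v <- array(0L, c(4, 4, 3))
  v[1, 1, 1] <- 1L; v[2, 3, 2] <- 1L; v[4, 4, 3] <- 1L
  path <- tempfile(fileext = ".tif")
  write_mask_stack(v, path)
  back <- load_mask_stack(path)
  expect_equal(dim(back), c(4, 4, 3))
  expect_equal(back, v)
})

test_that("rasterized components re-extract isomorphic with equal weights", {
  set.seed(31)
  for (i in 1:10) {
    h <- random_embeddable_component()
    r <- rasterize_to_skeleton(h)
    net <- skeleton_to_network(r$skeleton)
    expect_equal(igraph::vcount(net$graph), igraph::vcount(h))
    expect_equal(igraph::ecount(net$graph), igraph::ecount(h))
    expect_true(igraph::isomorphic(net$graph, h))
    expect_equal(sort(igraph::E(net$graph)$weight),
                 sort(r$expected_edges$weight))
    # voxel conservation under thr = 0
    total <- sum(igraph::E(net$graph)$weight - 2) + igraph::vcount(net$graph)
    expect_equal(total, sum(r$skeleton$volume))
  }
})

test_that("rasterizer special cases and contracts hold", {
  # single edge with requested length
  r <- rasterize_to_skeleton(igraph::make_graph(c(1, 2), directed = FALSE),
                             link_length = 5)
  expect_equal(sum(r$skeleton$volume), 5)
  expect_equal(dim(r$skeleton$volume)[1], 5)
  net <- skeleton_to_network(r$skeleton)
  expect_equal(igraph::E(net$graph)$weight, 5L)

  # star with 3 leaves: exactly one voxel with 3 skeleton neighbours
  star <- igraph::make_star(4, mode = "undirected")
  rs <- rasterize_to_skeleton(star)
  nets <- skeleton_to_network(rs$skeleton)
  expect_equal(sort(igraph::degree(nets$graph)), c(1, 1, 1, 3))

  # degree-2 vertices are rejected with guidance
  expect_error(rasterize_to_skeleton(igraph::make_ring(5)), "degree-2")
})

test_that("smooth_network reduces to the skeleton-representable class", {
  set.seed(33)
  for (i in 1:20) {
    g <- generate_component(sample(4:20, 1), runif(1), runif(1))
    h <- smooth_network(g)
    expect_true(all(igraph::degree(h) != 2))
    expect_true(igraph::is_connected(h))
  }
  # weight bookkeeping: a path a-b-c with weights w1, w2 merges to w1+w2-1
  p <- igraph::make_graph(c(1, 2, 2, 3), directed = FALSE)
  igraph::E(p)$weight <- c(4L, 7L)
  h <- smooth_network(p)
  expect_equal(igraph::ecount(h), 1)
  expect_equal(igraph::E(h)$weight, 10L)
})
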