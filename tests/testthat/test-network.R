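test_that("taxon and split angles follow the equal-angle assignment", {
  expect_equal(taxon_angles(1:4), c(0, 90, 180, 270))
  expect_equal(taxon_angles(1:6)[2], 60)
  # trivial split isolating the taxon at position 2 of 4
  expect_equal(split_angle(c(2L), 1:4), 90)
  expect_equal(split_angle(c(2L, 3L), 1:4), (90 + 180) / 2)
  # everything except taxon 1
  expect_equal(split_angle(2:4, 1:4), mean(c(90, 180, 270)))
  expect_error(split_angle(c(2L, 4L), 1:4), "not compatible")
})

test_that("outlines close and draw each split as two antiparallel edges", {
  # single split: degenerate two-edge polygon
  ss1 <- split_system(paste0("t", 1:4), list(c(3L, 4L)), 2.5, ordering = 1:4)
  ol1 <- build_outline(ss1)
  expect_identical(nrow(ol1$edges), 2L)
  expect_length(check_outline_properties(ol1, ss1), 0)
  # three unit trivial splits: hexagonal star outline
  ss3 <- split_system(paste0("t", 1:3),
                      all_circular_splits(1:3)$splits, rep(1, 3),
                      ordering = 1:3)
  ol3 <- build_outline(ss3)
  expect_identical(nrow(ol3$edges), 6L)
  expect_length(check_outline_properties(ol3, ss3), 0)
  # random circular systems
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    ss <- rand_system(n, n_internal = sample(0:(n * 2), 1))
    ss$ordering <- compute_circular_ordering(distances_from_splits(ss))
    ol <- build_outline(ss)
    expect_length(check_outline_properties(ol, ss), 0)
  }
  # incompatible split is rejected
  bad <- split_system(paste0("t", 1:4), list(c(2L, 4L)), 1, ordering = 1:4)
  expect_error(build_outline(bad), "not compatible")
})

test_that("compatible split systems build as trees and crossing pairs as parallelograms", {
  # a tree's splits: the network is that tree (one edge per split)
  ss <- split_system(paste0("t", 1:4),
                     list(c(2L), c(3L), c(4L), c(2L, 3L)),
                     c(1, 2, 3, 1.5), ordering = 1:4)
  net <- build_split_network(ss)
  expect_identical(nrow(net$edges), 4L)
  expect_identical(nrow(net$nodes), 5L)
  expect_length(check_network_properties(net, ss), 0)
  # two crossing splits: a single 4-gon with the taxa on its corners
  ss2 <- split_system(paste0("t", 1:4), list(c(2L, 3L), c(3L, 4L)),
                      c(1, 1), ordering = 1:4)
  net2 <- build_split_network(ss2)
  expect_identical(nrow(net2$nodes), 4L)
  expect_identical(nrow(net2$edges), 4L)
  expect_length(check_network_properties(net2, ss2), 0)
})

test_that("random circular networks satisfy the split-network properties", {
  set.seed(32)
  for (rep in 1:8) {
    n <- sample(5:10, 1)
    nint <- sample(0:(n * (n - 3) / 2), 1)
    ss <- rand_system(n, n_internal = nint)
    ss$ordering <- compute_circular_ordering(distances_from_splits(ss))
    net <- build_split_network(ss)
    expect_length(check_network_properties(net, ss), 0)
    expect_identical(count_edge_crossings(net), 0L)
  }
})

test_that("network geodesics equal split distances", {
  set.seed(33)
  ss <- rand_system(8, 6)
  ss$ordering <- compute_circular_ordering(distances_from_splits(ss))
  net <- build_split_network(ss)
  dm <- network_distances(net)
  dS <- distances_from_splits(ss)
  expect_equal(dm, dS, tolerance = 1e-12)
  expect_identical(network_distance(net, 3, 3), 0)
  expect_equal(network_distance(net, "t2", "t5"), dS["t2", "t5"])
  # tree-splits network: path length is the tree distance
  inst <- random_tree_instance(7, seed = 5)
  ss2 <- inst$splits
  ss2$ordering <- compute_circular_ordering(inst$d)
  net2 <- build_split_network(ss2)
  expect_equal(network_distances(net2), inst$d, tolerance = 1e-9)
})

test_that("plotting runs without error", {
  ss <- rand_system(6, 3)
  ss$ordering <- compute_circular_ordering(distances_from_splits(ss))
  net <- build_split_network(ss)
  ol <- build_outline(ss)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(net))
  expect_silent(plot(ol))
})
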