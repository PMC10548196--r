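test_that("split separation and canonical form follow the bipartition definition", {
  expect_true(split_separates(c(2L, 3L), 1, 2))
  expect_false(split_separates(c(2L, 3L), 2, 3))
  expect_false(split_separates(c(2L), 1, 3))
  expect_error(split_separates(c(2L), 2, 2), "distinct")
  # canonical part never contains taxon 1
  expect_identical(split_canonical(c(1L, 4L), 4), c(2L, 3L))
  expect_identical(split_canonical(c(3L, 2L), 4), c(2L, 3L))
  expect_error(split_canonical(1:4, 4), "proper")
  expect_error(split_system(c("a", "a"), list(), numeric()), "unique")
  expect_error(split_system(letters[1:3], list(2L, c(1L, 3L)), c(1, 1)),
               "duplicate")
})

test_that("split distance matches the weighted sum over separating splits", {
  ss0 <- split_system(letters[1:4], list(), numeric())
  expect_identical(split_distance(ss0, 1, 4), 0)
  ss1 <- split_system(letters[1:3], list(c(2L, 3L)), 1.5)
  expect_equal(split_distance(ss1, 1, 2), 1.5)
  expect_equal(split_distance(ss1, 2, 3), 0)
  # full circular system on 3 taxa at unit weight: every pair separated by 2
  acs <- all_circular_splits(1:3)
  ss3 <- split_system(letters[1:3], acs$splits, rep(1, 3))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(split_distance(ss3, i, j), 2)
  # brute-force double-loop oracle on random systems, n <= 7
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(4:7, 1)
    ss <- rand_system(n, n_internal = sample(0:4, 1))
    d <- distances_from_splits(ss)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      expect_equal(d[i, j], brute_split_distance(ss$splits, ss$weights, i, j))
  }
})

test_that("distance matrices from split systems satisfy the metric axioms", {
  set.seed(7)
  for (rep in 1:10) {
    ss <- rand_system(sample(3:9, 1), n_internal = sample(0:6, 1))
    d <- distances_from_splits(ss)
    expect_identical(d, t(d))
    expect_identical(unname(diag(d)), rep(0, nrow(d)))
    expect_true(all(d >= 0))
  }
  # star system: only trivial splits -> d(i,j) = w_i + w_j
  w <- c(0.5, 1, 2, 4)
  ss <- split_system(letters[1:4], lapply(1:4, identity), w)
  d <- distances_from_splits(ss)
  expect_equal(unname(d), outer(w, w, `+`) - diag(2 * w))
})

test_that("interval compatibility with an ordering means one contiguous block", {
  expect_true(is_compatible_with_ordering(c(2L, 3L), 1:4))
  expect_false(is_compatible_with_ordering(c(2L, 4L), 1:4))
  expect_true(is_compatible_with_ordering(c(2L, 3L), c(1L, 3L, 2L, 4L)))
})

test_that("the circular split system of an ordering has n(n-1)/2 compatible splits", {
  expect_length(all_circular_splits(1:2)$splits, 1)
  acs3 <- all_circular_splits(1:3)
  expect_length(acs3$splits, 3)
  expect_true(all(lengths(acs3$splits) %in% c(1L, 2L)))  # all trivial
  set.seed(1)
  for (n in c(6, 9)) {
    theta <- normalize_ordering(c(1L, sample(2:n)))
    acs <- all_circular_splits(theta)
    expect_length(acs$splits, n * (n - 1) / 2)
    keys <- vapply(acs$splits, paste, "", collapse = ",")
    expect_false(anyDuplicated(keys) > 0)
    expect_true(all(vapply(acs$splits, is_compatible_with_ordering, NA,
                           theta = theta)))
  }
  expect_error(all_circular_splits(1L), "at least two")
})

test_that("fit percentage follows its closed form and rejects zero input", {
  d <- matrix(c(0, 5, 5, 0), 2, 2)
  expect_equal(fit_percent(d, d), 100)
  expect_equal(fit_percent(d, 0 * d), 0)
  p <- matrix(c(0, 4, 4, 0), 2, 2)
  expect_equal(fit_percent(d, p), 100 * (1 - 1 / 25))
  expect_error(fit_percent(0 * d, d), "identically zero")
  # invariance under simultaneous relabeling
  set.seed(3)
  ss <- rand_system(6, 4)
  d6 <- distances_from_splits(ss)
  p6 <- perturb(d6, 0.1, seed = 1)
  pi6 <- sample(6)
  expect_equal(fit_percent(d6, p6), fit_percent(d6[pi6, pi6], p6[pi6, pi6]))
})

test_that("distance validation enforces symmetry, finiteness and non-negativity", {
  m <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_silent(validate_distances(m))
  expect_error(validate_distances(m - 2), "negative")
  m2 <- m; m2[1, 2] <- 2
  expect_error(validate_distances(m2), "asymmetric")
  m3 <- m; m3[1, 1] <- 1
  expect_error(validate_distances(m3), "diagonal")
  m4 <- m; m4[1, 2] <- m4[2, 1] <- Inf
  expect_error(validate_distances(m4), "finite")
  # triangle-inequality violations are allowed
  tv <- matrix(0, 3, 3); tv[1, 2] <- tv[2, 1] <- 10
  tv[1, 3] <- tv[3, 1] <- 1; tv[2, 3] <- tv[3, 2] <- 1
  expect_silent(validate_distances(tv))
})
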