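test_that("component distances average over active nodes only", {
  d <- matrix(0, 5, 5)
  d[lower.tri(d)] <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  d <- d + t(d)
  state <- circularnet:::new_agglomeration_state(d)
  # two singletons
  expect_equal(circularnet:::component_distance(state, 1, 2), d[1, 2])
  # singleton vs chain with ends 2 and 3 (chain 2-3)
  state$components <- list(1L, c(2L, 3L), 4L, 5L)
  expect_equal(circularnet:::component_distance(state, 1, 2),
               (d[1, 2] + d[1, 3]) / 2)
  # chain vs chain: 4-term average
  state$components <- list(c(1L, 4L), c(2L, 3L), 5L)
  expect_equal(circularnet:::component_distance(state, 1, 2),
               mean(d[c(1, 4), c(2, 3)]))
})

test_that("chain-end selection prefers the first end on ties and the closer end otherwise", {
  # symmetric configuration: both ends equivalent -> q1 (smaller label)
  d <- matrix(0, 4, 4)
  d[1, 2] <- d[2, 1] <- 1; d[1, 3] <- d[3, 1] <- 1
  d[2, 3] <- d[3, 2] <- 1; d[1, 4] <- d[4, 1] <- 2
  d[2, 4] <- d[4, 2] <- 2; d[3, 4] <- d[4, 3] <- 2
  state <- circularnet:::new_agglomeration_state(d)
  state$components <- list(1L, c(2L, 3L), 4L)
  expect_identical(circularnet:::select_node_in_chain(state, 1, 2), 2L)
  # d(q1,p) much smaller than d(q2,p), all else equal -> q1
  d2 <- d; d2[1, 3] <- d2[3, 1] <- 10
  state2 <- circularnet:::new_agglomeration_state(d2)
  state2$components <- list(1L, c(2L, 3L), 4L)
  expect_identical(circularnet:::select_node_in_chain(state2, 1, 2), 2L)
  # reversed: taxon 3 closer, criterion must pick it
  d3 <- d; d3[1, 2] <- d3[2, 1] <- 10
  state3 <- circularnet:::new_agglomeration_state(d3)
  state3$components <- list(1L, c(2L, 3L), 4L)
  expect_identical(circularnet:::select_node_in_chain(state3, 1, 2), 3L)
})

test_that("two-chain end selection agrees with exhaustive evaluation of the criterion", {
  set.seed(11)
  for (rep in 1:12) {
    n <- 8
    d <- matrix(0, n, n)
    d[lower.tri(d)] <- stats::runif(n * (n - 1) / 2, 1, 5)
    d <- d + t(d)
    state <- circularnet:::new_agglomeration_state(d)
    state$components <- list(c(1L, 5L, 2L), c(3L, 6L, 4L), 7L, 8L)
    sel <- circularnet:::select_nodes_two_chains(state, 1, 2)
    # independent recomputation over the four candidate pairs
    m <- length(state$components)
    act <- function(ci) circularnet:::comp_active(state$components[[ci]])
    others <- function(x) sum(vapply(3:4, function(s)
      mean(d[x, act(s)]), 0))
    best <- Inf; expected <- NULL
    for (p in sort(act(1))) for (q in sort(act(2))) {
      rp <- d[p, act(2)[1]] + d[p, act(2)[2]] + others(p)
      rq <- d[act(1)[1], q] + d[act(1)[2], q] + others(q)
      crit <- m * d[p, q] - rp - rq
      if (crit < best - 1e-12) { best <- crit; expected <- c(p, q) }
    }
    expect_identical(sel, expected)
  }
})

test_that("joins preserve chain structure and the reduction formulas", {
  # singleton-chain with all distances equal: reduced distance stays c
  cval <- 3.7
  d <- matrix(cval, 5, 5); diag(d) <- 0
  state <- circularnet:::new_agglomeration_state(d)
  state$components <- list(1L, c(2L, 3L), 4L, 5L)
  st2 <- circularnet:::join_and_reduce(state, 1, 2)
  newc <- st2$components[[1]]
  expect_length(newc, 3)
  qbar <- newc[3]
  expect_equal(st2$D[1, qbar], cval)
  expect_equal(st2$D[1, 4], cval)
  # chain-chain reduction is symmetric in the roles of P and Q
  set.seed(2)
  d6 <- matrix(0, 6, 6)
  d6[lower.tri(d6)] <- stats::runif(15, 1, 4)
  d6 <- d6 + t(d6)
  mk <- function(order_pq) {
    st <- circularnet:::new_agglomeration_state(d6)
    # swap which chain plays P and which plays Q
    st$components <- if (order_pq) list(c(1L, 2L), c(3L, 4L), 5L, 6L)
                     else list(c(3L, 4L), c(1L, 2L), 5L, 6L)
    circularnet:::join_and_reduce(st, 1, 2)
  }
  a <- mk(TRUE); b <- mk(FALSE)
  expect_equal(a$D, b$D)
  # hand-evaluated six-term average for the new end-to-end distance
  st <- circularnet:::new_agglomeration_state(d6)
  st$components <- list(c(1L, 2L), c(3L, 4L), 5L, 6L)
  sel <- circularnet:::select_nodes_two_chains(st, 1, 2)
  p <- sel[1]; q <- sel[2]
  pbar <- setdiff(c(1L, 2L), p); qbar <- setdiff(c(3L, 4L), q)
  st2 <- circularnet:::join_and_reduce(st, 1, 2)
  expect_equal(st2$D[pbar, qbar],
               (d6[pbar, p] + d6[pbar, q] + d6[pbar, qbar] +
                d6[p, q] + d6[p, qbar] + d6[q, qbar]) / 6)
})

test_that("the agglomeration always returns a Hamiltonian cycle after n - 1 joins", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(4:30, 1)
    d <- matrix(0, n, n)
    d[lower.tri(d)] <- stats::runif(n * (n - 1) / 2)
    d <- d + t(d)
    theta <- compute_circular_ordering(d)
    expect_identical(sort(as.integer(theta)), seq_len(n))
    expect_identical(attr(theta, "joins"), n - 1L)
    expect_identical(theta[1], 1L)
    expect_lt(theta[2], theta[n])
  }
  # trivial sizes
  expect_identical(as.integer(compute_circular_ordering(matrix(0, 1, 1))), 1L)
  d2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_identical(as.integer(compute_circular_ordering(d2)), 1:2)
})

test_that("orderings are consistent on circular metrics", {
  set.seed(5)
  for (rep in 1:15) {
    n <- sample(5:12, 1)
    ss <- rand_system(n, n_internal = sample(1:(2 * n), 1))
    d <- distances_from_splits(ss)
    theta <- compute_circular_ordering(d)
    expect_true(all(vapply(ss$splits, is_compatible_with_ordering, NA,
                           theta = theta)),
                label = sprintf("all generating splits are intervals (n=%d)", n))
  }
  # additive metrics are circular: a 5-taxon caterpillar
  tr <- ape::read.tree(text = "((a:1,b:2):1,(c:1.5,(d:1,e:1):0.5):1);")
  d <- ape::cophenetic.phylo(tr)
  o <- order(rownames(d))
  d <- d[o, o]
  theta <- compute_circular_ordering(d)
  # tree splits on sorted labels a..e
  tree_splits <- list(c(2L), c(3L), c(4L), c(5L), c(4L, 5L), c(3L, 4L, 5L))
  for (sp in tree_splits)
    expect_true(is_compatible_with_ordering(sp, theta))
})

test_that("relabeling taxa relabels the ordering", {
  # generic distances: all selection criteria have unique minimizers, so
  # the ordering must transform equivariantly (under exact ties only the
  # deterministic index-based tie-break, which is label-dependent, applies)
  set.seed(21)
  d <- matrix(0, 8, 8)
  d[lower.tri(d)] <- stats::runif(28, 1, 2)
  d <- d + t(d)
  theta <- compute_circular_ordering(d)
  pi8 <- sample(8)  # new labels: old taxon i becomes pi8[i]
  dperm <- d
  dperm[pi8, pi8] <- d
  theta2 <- compute_circular_ordering(unname(dperm))
  expect_identical(normalize_ordering(pi8[theta]), as.integer(theta2))
})
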