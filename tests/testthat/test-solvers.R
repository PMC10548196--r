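test_that("initial weights are the clipped exact inverse", {
  set.seed(40)
  n <- 8; m <- 28
  w <- stats::rexp(m) * stats::rbinom(m, 1, 0.5)
  d <- apply_A(w, n)
  expect_equal(initial_weights(d, n), w)          # no clipping needed
  expect_equal(initial_weights(rep(0, m), n), rep(0, m))
  # clipping: negative entries zeroed, others untouched
  d2 <- d + stats::rnorm(m, 0, 0.3)
  raw <- apply_Ainv(d2, n)
  iw <- initial_weights(d2, n)
  expect_true(all(iw >= 0))
  expect_equal(iw[raw >= 0], raw[raw >= 0])
  expect_true(all(iw[raw < 0] == 0))
})

test_that("truncated CGNR solves masked least squares against a dense reference", {
  set.seed(41)
  for (n in c(6, 8, 10)) {
    m <- n * (n - 1) / 2
    # consistent unconstrained system: exact solve
    w <- stats::rexp(m)
    d <- apply_A(w, n)
    sol <- cgnr_solve(rep(FALSE, m), d, rep(0, m), n, cap = 4 * m)
    expect_lt(max(abs(apply_A(sol, n) - d)), 1e-6)
    # all-but-one active: closed-form single coordinate
    d2 <- d + stats::rnorm(m, 0, 0.2)
    act <- rep(TRUE, m); free <- sample(m, 1); act[free] <- FALSE
    sol1 <- cgnr_solve(act, d2, rep(0, m), n, cap = 50)
    e <- rep(0, m); e[free] <- 1
    col <- apply_A(e, n)
    expect_equal(sol1[free], sum(col * d2) / sum(col^2), tolerance = 1e-8)
    expect_true(all(sol1[act] == 0))
    # random mask vs dense restricted least squares
    act2 <- stats::runif(m) < 0.4
    sol2 <- cgnr_solve(act2, d2, rep(0, m), n, cap = 4 * m)
    ref <- dense_restricted_ls(act2, d2, n)
    expect_lt(max(abs(sol2 - ref)), 1e-6)
  }
})

test_that("all three solvers reach the dense NNLS optimum on random problems", {
  set.seed(42)
  for (n in c(6, 8, 10)) {
    m <- n * (n - 1) / 2
    for (rep in 1:3) {
      w <- stats::rexp(m) * stats::rbinom(m, 1, 0.4)
      d <- pmax(apply_A(w, n) + stats::rnorm(m, 0, 0.3), 0)
      fref <- dense_nnls_objective(d, n)
      # a tight certificate: the default threshold scales with ||A^T d||^2,
      # which on small noisy problems tolerates objective gaps larger than
      # the agreement examined here
      opts <- nnls_options(delta_scale = 1e-12)
      for (meth in c("active_set", "gradient_projection", "apgd")) {
        res <- switch(meth,
                      active_set = solve_active_set(d, n, opts),
                      gradient_projection = solve_gradient_projection(d, n, opts),
                      apgd = solve_apgd(d, n, opts))
        expect_true(all(res$lambda >= 0), label = paste(meth, "feasible"))
        expect_lt(abs(res$objective - fref) / max(fref, 1e-12), 1e-4)
        if (res$converged) {
          # recompute the KKT certificate from scratch
          og <- objective_and_gradient(res$lambda, d, n)
          g <- projected_gradient(res$lambda, og$grad)
          expect_lt(sum(g^2), res$delta)
        }
      }
    }
  }
})

test_that("circular input is solved at initialization with zero iterations", {
  set.seed(43)
  for (n in c(6, 12)) {
    m <- n * (n - 1) / 2
    w <- stats::rexp(m) * stats::rbinom(m, 1, 0.6)
    d <- apply_A(w, n)
    for (f in list(solve_active_set, solve_gradient_projection, solve_apgd)) {
      res <- f(d, n)
      expect_true(res$converged)
      expect_identical(res$outer_iterations, 0L)
      expect_equal(res$lambda, w, tolerance = 1e-8)
    }
  }
})

test_that("momentum recurrence of the accelerated solver matches its closed form", {
  # theta0 = 1 gives theta1 = (sqrt(5) - 1) / 2
  theta0 <- 1
  theta1 <- (-theta0^2 + theta0 * sqrt(theta0^2 + 4)) / 2
  expect_equal(theta1, (sqrt(5) - 1) / 2)
  # the sequence stays in (0, 1) and decreases
  th <- theta1
  for (k in 1:20) {
    thn <- (-th^2 + th * sqrt(th^2 + 4)) / 2
    expect_lt(thn, th)
    expect_gt(thn, 0)
    th <- thn
  }
})

test_that("estimated split systems recover ground truth and prune zero weights", {
  set.seed(44)
  # tree distances: recovered splits are the tree splits with branch lengths
  inst <- random_tree_instance(8, seed = 2)
  theta <- compute_circular_ordering(inst$d)
  ss <- estimate_split_weights(inst$d, theta)
  truth <- inst$splits
  key <- function(s) vapply(s, paste, "", collapse = ",")
  expect_setequal(key(ss$splits), key(truth$splits))
  mi <- match(key(truth$splits), key(ss$splits))
  expect_equal(ss$weights[mi], truth$weights, tolerance = 1e-6)
  # zero distances: empty system
  d0 <- matrix(0, 4, 4)
  ss0 <- estimate_split_weights(d0, 1:4)
  expect_length(ss0$splits, 0)
})
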