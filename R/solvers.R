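# Constrained least-squares estimation of circular split weights.
#
# Given a circular ordering, the weights of all n(n-1)/2 compatible splits
# are chosen to minimize ||A lambda - d||^2 subject to lambda >= 0, with A
# the implicit circular design operator.  Three solvers are provided: an
# active-set method with truncated CGNR inner solves and multi-variable
# active-set growth; a gradient projection method with piecewise-quadratic
# line search over breakpoints plus conjugate-gradient refinement; and
# Nesterov-accelerated projected gradient descent with adaptive restart.
# All use the same initialization (clipped exact inverse) and the same
# convergence certificate: squared norm of the projected gradient below
# delta = delta_scale * ||A^T d||^2.

#' Solver options for split-weight estimation
#'
#' @param method one of `"active_set"` (default), `"gradient_projection"`,
#'   `"apgd"`.
#' @param delta_scale convergence threshold scale: the solver stops when the
#'   squared norm of the projected gradient drops below
#'   `delta_scale * ||A^T d||^2` (default `1e-8`).
#' @param rho fraction (0, 1) of the infeasible coordinates moved into the
#'   active set per active-set iteration (default 0.6).
#' @param cgnr_cap iteration bound of the inner CGNR solver; default
#'   `max(50, n)`, resolved when `n` is known.
#' @param cgnr_tol relative normal-equation residual at which CGNR stops
#'   before reaching the cap.
#' @param max_outer_iterations bound on outer iterations; when exceeded the
#'   best iterate is returned flagged `converged = FALSE`.
#' @param weight_prune_threshold splits with estimated weight at or below
#'   this value are dropped from the reported system; default
#'   `1e-8 * max(d)`, resolved at solve time.
#' @param theta0 initial momentum parameter of the accelerated solver.
#' @return List of options of class `nnls_options`.
#' @export
nnls_options <- function(method = c("active_set", "gradient_projection", "apgd"),
                         delta_scale = 1e-8, rho = 0.6,
                         cgnr_cap = NULL, cgnr_tol = 1e-10,
                         max_outer_iterations = 1000L,
                         weight_prune_threshold = NULL,
                         theta0 = 1.0) {
  method <- match.arg(method)
  stopifnot(delta_scale > 0, rho > 0, rho < 1,
            is.null(cgnr_cap) || cgnr_cap >= 1, max_outer_iterations >= 1)
  structure(list(method = method, delta_scale = delta_scale, rho = rho,
                 cgnr_cap = cgnr_cap, cgnr_tol = cgnr_tol,
                 max_outer_iterations = as.integer(max_outer_iterations),
                 weight_prune_threshold = weight_prune_threshold,
                 theta0 = theta0),
            class = "nnls_options")
}

#' Initial split weights
#'
#' The unconstrained exact solution `A^{-1} d` with negative entries
#' replaced by zero.  If `A^{-1} d` is already non-negative (in particular
#' whenever `d` is a circular metric for this ordering) the result is the
#' global optimum of the constrained problem and no iterations are needed.
#'
#' @param d numeric pair vector of distances (ordering-relative).
#' @param n number of taxa.
#' @return Non-negative pair vector of weights.
#' @export
initial_weights <- function(d, n) {
  pmax(apply_Ainv(d, n), 0)
}

#' Truncated CGNR on the masked normal equations
#'
#' Minimizes `||A lambda - d||` over the coordinates not in the active set
#' (those in the active set are pinned at zero), by conjugate gradients on
#' the normal equations.  The restricted matrix is never formed: columns are
#' removed by zero-masking the inputs of `A` and the outputs of `A^T`.  The
#' iteration stops at a relative normal-equation residual of `tol` or after
#' `cap` iterations, whichever comes first; non-convergence at the cap is
#' expected and handled by the outer solver.
#'
#' @param active logical pair vector: coordinates pinned at zero.
#' @param d pair vector of distances.
#' @param lambda_start feasible warm start (zero on the active set).
#' @param n number of taxa.
#' @param cap maximum number of CGNR iterations.
#' @param tol relative residual tolerance of the normal equations.
#' @return Pair vector minimizing the restricted least squares (possibly
#'   with negative entries off the active set).
#' @export
cgnr_solve <- function(active, d, lambda_start, n, cap = max(50L, n),
                       tol = 1e-10) {
  lam <- lambda_start
  lam[active] <- 0
  r <- d - apply_A(lam, n)
  z <- apply_At(r, n); z[active] <- 0
  zz <- sum(z^2)
  z0 <- apply_At(d, n); z0[active] <- 0
  thresh <- (tol * sqrt(sum(z0^2)))^2
  if (zz <= thresh) return(lam)
  p <- z
  for (it in seq_len(cap)) {
    w <- apply_A(p, n)                 # p is zero on the active set
    ww <- sum(w^2)
    if (ww == 0) break
    alpha <- zz / ww
    lam <- lam + alpha * p
    r <- r - alpha * w
    z <- apply_At(r, n); z[active] <- 0
    zz_new <- sum(z^2)
    if (zz_new <= thresh) break
    p <- z + (zz_new / zz) * p
    zz <- zz_new
  }
  lam[active] <- 0
  lam
}

# shared bookkeeping: build an NNLSResult
nnls_result <- function(lambda, d, n, delta, iterations, converged) {
  og <- objective_and_gradient(lambda, d, n)
  g <- projected_gradient(lambda, og$grad)
  structure(list(lambda = lambda,
                 projected_gradient_sq_norm = sum(g^2),
                 outer_iterations = iterations,
                 converged = converged,
                 delta = delta,
                 objective = og$f,
                 residual_norm = sqrt(2 * og$f)),
            class = "nnls_result")
}

#' @export
print.nnls_result <- function(x, ...) {
  cat(sprintf(
    "NNLS result: %s after %d iteration(s); ||g||^2 = %.3e (delta = %.3e), residual %.6g\n",
    if (x$converged) "converged" else "NOT converged",
    x$outer_iterations, x$projected_gradient_sq_norm, x$delta, x$residual_norm))
  invisible(x)
}

#' Active-set solver for non-negative split weights
#'
#' Active-set method with two departures from the textbook scheme: the
#' equality-constrained subproblems are solved by truncated CGNR (the inner
#' iteration is deliberately not run to convergence), and many variables may
#' enter the active set per iteration -- the infeasible coordinates are
#' sorted by `lambda * (lambda - lambda*)` and the smallest fraction `rho`
#' of them (at least one) is pinned.  Coordinates that hit zero within
#' 1e-12 during the feasibility step are also pinned.  A coordinate leaves
#' the active set when it has the most negative gradient there.  The
#' objective is non-increasing across accepted iterates.
#'
#' @param d pair vector of distances (ordering-relative).
#' @param n number of taxa.
#' @param options an [nnls_options()] list.
#' @return An `nnls_result`: non-negative `lambda`, projected-gradient
#'   certificate, iteration count and convergence flag.
#' @export
solve_active_set <- function(d, n, options = nnls_options()) {
  delta <- options$delta_scale * sum(apply_At(d, n)^2)
  cap <- if (is.null(options$cgnr_cap)) max(50L, n) else options$cgnr_cap
  lam <- initial_weights(d, n)
  og <- objective_and_gradient(lam, d, n)
  if (sum(projected_gradient(lam, og$grad)^2) < delta)
    return(nnls_result(lam, d, n, delta, 0L, TRUE))
  active <- lam == 0
  best <- lam; best_f <- og$f
  for (iter in seq_len(options$max_outer_iterations)) {
    lam_star <- cgnr_solve(active, d, lam, n, cap = cap, tol = options$cgnr_tol)
    neg <- !active & (lam_star < 0)
    if (any(neg)) {
      # step to the closest feasible point on the segment toward lam_star
      dir <- lam_star - lam
      block <- neg & (dir < 0)
      tstep <- min(1, lam[block] / (-dir[block]))
      lam <- pmax(lam + tstep * dir, 0)
      hit <- lam <= 1e-12
      # multi-variable growth: pin ceil(rho * #infeasible) coordinates with
      # the smallest lambda * (lambda - lambda*)
      score <- lam * (lam - lam_star)
      cand <- which(neg)
      k <- max(1L, ceiling(options$rho * length(cand)))
      grow <- cand[order(score[cand])][seq_len(min(k, length(cand)))]
      active <- active | hit
      active[grow] <- TRUE
      lam[active] <- 0
    } else {
      lam <- pmax(lam_star, 0)
      lam[active] <- 0
      og <- objective_and_gradient(lam, d, n)
      if (og$f <= best_f) { best <- lam; best_f <- og$f }
      g <- projected_gradient(lam, og$grad)
      if (sum(g^2) < delta) return(nnls_result(lam, d, n, delta, iter, TRUE))
      gact <- og$grad
      gact[!active] <- Inf
      if (any(active) && min(gact) < 0) {
        drop <- which.min(gact)          # release the most negative
        active[drop] <- FALSE
      }
      # otherwise: KKT holds on the active set but CGNR was truncated;
      # the next pass continues the inner iteration from the warm start
    }
  }
  nnls_result(best, d, n, delta, options$max_outer_iterations, FALSE)
}

# Piecewise-quadratic line search along the projected steepest-descent path:
# returns the first local minimizer t* of q(t) = f(pi(lambda + t p)).
# Breakpoints occur where a coordinate of the projected path hits zero;
# coincident breakpoints (within relative 1e-12) are merged.  At most
# `max_segments` segments are examined; if the search is still descending
# there, the current segment's unconstrained minimizer is returned (early
# termination, the refinement step makes up the difference).
projected_line_search <- function(lam, p, d, n, max_segments = 200L) {
  pinned <- lam == 0 & p < 0
  pfree <- p; pfree[pinned] <- 0
  brk <- ifelse(!pinned & p < 0 & lam > 0, lam / (-p), Inf)
  bp <- sort(unique(brk[is.finite(brk)]))
  if (length(bp) > 1L)
    bp <- bp[c(TRUE, diff(bp) > 1e-12 * bp[-1L])]
  t_lo <- 0
  x <- lam
  for (seg in seq_len(min(length(bp) + 1L, max_segments))) {
    if (all(pfree == 0)) return(t_lo)
    Ap <- apply_A(pfree, n)
    r <- apply_A(x, n) - d
    slope <- sum(r * Ap)
    curv <- sum(Ap^2)
    if (slope >= 0) return(t_lo)              # q increasing: local min here
    t_hi <- if (seg <= length(bp)) bp[seg] else Inf
    tstar <- t_lo + (-slope / curv)
    if (tstar <= t_hi || !is.finite(t_hi)) return(tstar)
    # advance to the breakpoint; pin the coordinates that hit zero there
    x <- pmax(lam + t_hi * p, 0)
    newly <- !pinned & p < 0 & brk <= t_hi * (1 + 1e-12)
    pinned <- pinned | newly
    pfree[newly] <- 0
    x[pinned] <- 0
    t_lo <- t_hi
  }
  t_lo
}

#' Gradient projection solver for non-negative split weights
#'
#' Each iteration takes the steepest-descent direction, finds the first
#' local minimum of the piecewise-quadratic objective along the projected
#' path (breakpoints where coordinates hit zero), then refines the free
#' coordinates with a few CGNR iterations and accepts the refined point via
#' a projected backtracking search with a sufficient-decrease check.
#'
#' @inheritParams solve_active_set
#' @export
solve_gradient_projection <- function(d, n, options = nnls_options()) {
  delta <- options$delta_scale * sum(apply_At(d, n)^2)
  cap <- if (is.null(options$cgnr_cap)) max(50L, n) else options$cgnr_cap
  lam <- initial_weights(d, n)
  best <- lam; best_f <- Inf
  for (iter in 0:options$max_outer_iterations) {
    og <- objective_and_gradient(lam, d, n)
    if (og$f <= best_f) { best <- lam; best_f <- og$f }
    g <- projected_gradient(lam, og$grad)
    if (sum(g^2) < delta) return(nnls_result(lam, d, n, delta, iter, TRUE))
    if (iter == options$max_outer_iterations) break
    p <- -og$grad
    tstar <- projected_line_search(lam, p, d, n)
    lamc <- pmax(lam + tstar * p, 0)
    fc <- objective_and_gradient(lamc, d, n)$f
    # conjugate-gradient refinement on the face identified by the search
    active <- lamc == 0
    lam_star <- cgnr_solve(active, d, lamc, n, cap = cap, tol = options$cgnr_tol)
    lam_next <- lamc
    t <- 1
    repeat {
      cand <- pmax(lamc + t * (lam_star - lamc), 0)
      fcand <- objective_and_gradient(cand, d, n)$f
      if (fcand <= fc) { lam_next <- cand; break }
      t <- t / 2
      if (t < 1e-8) break
    }
    lam <- lam_next
  }
  nnls_result(best, d, n, delta, options$max_outer_iterations, FALSE)
}

#' Accelerated projected gradient solver for non-negative split weights
#'
#' Nesterov-accelerated projected gradient descent with fixed step
#' `1 / ||A^T A||` (spectral norm over-estimated by power iteration) and the
#' momentum recurrences
#' \deqn{\theta_{k+1} = (-\theta_k^2 + \theta_k \sqrt{\theta_k^2 + 4}) / 2,
#'       \quad \beta_{k+1} = \theta_k (1 - \theta_k) / (\theta_k^2 + \theta_{k+1}),}
#' with adaptive restart: the momentum is reset whenever
#' `g^T (lambda_{k+1} - lambda_k) > 0`, the sign that the objective is about
#' to increase.
#'
#' @inheritParams solve_active_set
#' @export
solve_apgd <- function(d, n, options = nnls_options()) {
  delta <- options$delta_scale * sum(apply_At(d, n)^2)
  lam <- initial_weights(d, n)
  og <- objective_and_gradient(lam, d, n)
  if (sum(projected_gradient(lam, og$grad)^2) < delta)
    return(nnls_result(lam, d, n, delta, 0L, TRUE))
  L <- estimate_operator_norm(n)
  y <- lam
  theta <- options$theta0
  best <- lam; best_f <- og$f
  for (iter in seq_len(options$max_outer_iterations)) {
    gy <- apply_At(apply_A(y, n) - d, n)
    lam_new <- pmax(y - gy / L, 0)
    theta_new <- (-theta^2 + theta * sqrt(theta^2 + 4)) / 2
    beta <- theta * (1 - theta) / (theta^2 + theta_new)
    y <- lam_new + beta * (lam_new - lam)
    if (sum(gy * (lam_new - lam)) > 0) {   # adaptive restart
      y <- lam_new
      theta_new <- options$theta0
    }
    theta <- theta_new
    lam <- lam_new
    og <- objective_and_gradient(lam, d, n)
    if (og$f <= best_f) { best <- lam; best_f <- og$f }
    if (sum(projected_gradient(lam, og$grad)^2) < delta)
      return(nnls_result(lam, d, n, delta, iter, TRUE))
  }
  nnls_result(best, d, n, delta, options$max_outer_iterations, FALSE)
}

#' Estimate circular split weights for an ordering
#'
#' Sets up all `n(n-1)/2` splits compatible with the circular ordering
#' `theta` and estimates their weights by non-negative least squares against
#' the observed distances.  If the clipped exact inverse already satisfies
#' the optimality certificate (always the case for circular input) it is
#' returned without iterating; otherwise the solver named in `options` runs.
#' Splits with weight at or below the pruning threshold are dropped.
#'
#' @param d distance matrix (or `dist`) on the taxa.
#' @param theta circular ordering as returned by
#'   [compute_circular_ordering()].
#' @param options an [nnls_options()] list.
#' @return A [split_system()] with the ordering attached; solver
#'   diagnostics in attribute `"nnls"`.
#' @export
estimate_split_weights <- function(d, theta, options = nnls_options()) {
  d <- validate_distances(d)
  n <- nrow(d)
  theta <- as.integer(theta)
  if (!identical(sort(theta), seq_len(n)))
    stop("'theta' must be a permutation of the taxon indices")
  if (n < 2L) {
    ss <- split_system(rownames(d), list(), numeric(), ordering = theta)
    attr(ss, "nnls") <- NULL
    return(ss)
  }
  pt <- pair_table(n)
  dv <- d[cbind(theta[pt[, 1L]], theta[pt[, 2L]])]
  if (all(dv == 0)) {
    ss <- split_system(rownames(d), list(), numeric(), ordering = theta)
    attr(ss, "nnls") <- NULL
    return(ss)
  }
  res <- switch(match.arg(options$method,
                          c("active_set", "gradient_projection", "apgd")),
                active_set = solve_active_set(dv, n, options),
                gradient_projection = solve_gradient_projection(dv, n, options),
                apgd = solve_apgd(dv, n, options))
  prune <- if (is.null(options$weight_prune_threshold))
    1e-8 * max(dv) else options$weight_prune_threshold
  keep <- which(res$lambda > prune)
  acs <- all_circular_splits(theta)
  ss <- split_system(rownames(d), acs$splits[keep], res$lambda[keep],
                     ordering = theta)
  attr(ss, "nnls") <- res
  ss
}
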