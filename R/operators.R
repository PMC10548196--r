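# Implicit circular design operator.
#
# For a fixed circular ordering of n taxa, the 0/1 design matrix A has rows
# indexed by taxon pairs ij (i < j) and columns indexed by index pairs kl
# (k < l), with A[ij, kl] = 1 iff the split whose one part is the interval
# {x_k, ..., x_{l-1}} separates x_i and x_j.  A is square of side n(n-1)/2,
# non-singular with |det A| = 2^((n-1)(n-2)/2), and is never materialized:
# products with A, A^T and A^{-1} are evaluated through O(n^2) recurrences.
# All routines take and return pair vectors in the order of pair_table().

#' Multiply by the circular design matrix
#'
#' Computes `y = A x` where `x` holds one weight per circular split (indexed
#' by interval pairs `kl`) and `y` one value per taxon pair, in O(n^2) time.
#' Adjacent pairs are summed directly (each split either contains taxon
#' `i+1`'s interval start or not), and longer-range pairs follow by an
#' inclusion-exclusion recurrence on the pair span.
#'
#' @param x numeric pair vector of length `n(n-1)/2` (split weights).
#' @param n number of taxa.
#' @return Numeric pair vector of length `n(n-1)/2` (distances).
#' @export
apply_A <- function(x, n) {
  m <- n * (n - 1L) / 2L
  if (length(x) != m) stop("'x' must have length n(n-1)/2")
  .apply_A_cpp(as.numeric(x), as.integer(n))
}

#' Multiply by the transpose of the circular design matrix
#'
#' Computes `y = A^T x` (`x` indexed by taxon pairs, `y` by splits) in
#' O(n^2) time.  The trivial split \{x_i\} column sums all n-1 pairs
#' containing x_i; longer intervals follow by inclusion-exclusion.
#'
#' @inheritParams apply_A
#' @export
apply_At <- function(x, n) {
  m <- n * (n - 1L) / 2L
  if (length(x) != m) stop("'x' must have length n(n-1)/2")
  .apply_At_cpp(as.numeric(x), as.integer(n))
}

#' Solve against the circular design matrix
#'
#' Computes `y = A^{-1} x` in O(n^2) time via the combinatorial Crofton
#' formula: with cyclic indices (0 read as n) and `x[a,a] = 0`,
#' \deqn{y_{kl} = (x_{k-1,l-1} + x_{k,l} - x_{k,l-1} - x_{k-1,l}) / 2.}
#' Applied to a circular metric this recovers the isolation weight of each
#' interval split; as a linear map it inverts `A` exactly for any `x`.
#'
#' @inheritParams apply_A
#' @param x numeric pair vector of distances.
#' @return Numeric pair vector of split weights (possibly negative).
#' @export
apply_Ainv <- function(x, n) {
  m <- n * (n - 1L) / 2L
  if (length(x) != m) stop("'x' must have length n(n-1)/2")
  .apply_Ainv_cpp(as.numeric(x), as.integer(n))
}

#' Dense circular design matrix
#'
#' Materializes A explicitly from its definition (row pair `ij` separated by
#' the interval split `kl` or not).  Intended for small n: serves as the
#' reference for the implicit operators and for the determinant identity
#' |det A| = 2^((n-1)(n-2)/2); guarded to n <= 16.
#'
#' @param n number of taxa (2..16).
#' @return A dense `n(n-1)/2` square 0/1 matrix.
#' @export
dense_design_matrix <- function(n) {
  if (n < 2L || n > 16L) stop("dense construction restricted to 2 <= n <= 16")
  pt <- pair_table(n)
  m <- nrow(pt)
  A <- matrix(0, m, m)
  for (col in seq_len(m)) {
    k <- pt[col, 1L]; l <- pt[col, 2L]
    inside <- seq_len(n) >= k & seq_len(n) <= (l - 1L)
    A[, col] <- as.numeric(xor(inside[pt[, 1L]], inside[pt[, 2L]]))
  }
  A
}

#' Least-squares objective and gradient
#'
#' `f(lambda) = 0.5 ||A lambda - d||^2` and its gradient
#' `A^T (A lambda - d)`, evaluated through the implicit operators.
#'
#' @param lambda numeric pair vector of split weights.
#' @param d numeric pair vector of observed distances.
#' @param n number of taxa.
#' @return List with elements `f` (scalar), `grad` (pair vector) and
#'   `residual` (pair vector `A lambda - d`).
#' @export
objective_and_gradient <- function(lambda, d, n) {
  r <- apply_A(lambda, n) - d
  list(f = 0.5 * sum(r^2), grad = apply_At(r, n), residual = r)
}

#' Projected gradient at a feasible point
#'
#' Boundary components of the gradient are clipped: at coordinates with
#' `lambda > 0` the projected gradient equals the gradient; where
#' `lambda = 0` only negative gradient components survive.  Its squared norm
#' is zero exactly at the KKT point of the non-negative least-squares
#' problem.
#'
#' @param lambda non-negative pair vector.
#' @param grad gradient of the objective at `lambda`.
#' @return Pair vector `g`.
#' @export
projected_gradient <- function(lambda, grad) {
  if (any(lambda < 0)) stop("'lambda' must be non-negative")
  g <- grad
  at0 <- lambda == 0
  g[at0] <- pmin(grad[at0], 0)
  g
}

#' Spectral norm of A^T A by power iteration
#'
#' Estimates `||A^T A||_2` (needed for the fixed step of the accelerated
#' projected gradient solver) by deterministic power iteration through the
#' implicit operators, then inflates the estimate by 5 percent: an
#' over-estimate only shortens steps and is always safe.
#'
#' @param n number of taxa.
#' @param tol relative change tolerance of the iteration (default `1e-4`).
#' @param max_iter iteration cap.
#' @return Scalar upper estimate of the spectral norm of `A^T A`.
#' @export
estimate_operator_norm <- function(n, tol = 1e-4, max_iter = 500L) {
  m <- n * (n - 1L) / 2L
  # deterministic, non-symmetric start vector to avoid orthogonal starts
  v <- sin(seq_len(m) * 0.7) + 1.1
  v <- v / sqrt(sum(v^2))
  est <- 0
  for (it in seq_len(max_iter)) {
    w <- apply_At(apply_A(v, n), n)
    nw <- sqrt(sum(w^2))
    if (nw == 0) break
    v <- w / nw
    if (abs(nw - est) <= tol * nw && it > 3L) { est <- nw; break }
    est <- nw
  }
  1.05 * est
}
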