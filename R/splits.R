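# Splits, weighted split systems, circular orderings, and the split metric.
#
# A split A|B is a bipartition of the taxon set.  Splits are stored in
# canonical form as the sorted integer vector of taxon indices of the part
# that does NOT contain taxon 1, so two splits are equal iff their canonical
# parts are identical.

#' Validate a distance matrix
#'
#' Checks and normalizes a pairwise dissimilarity matrix: it must be square,
#' numeric, finite, non-negative, symmetric (within `tol`, symmetrized by
#' averaging with a warning if needed) and have a zero diagonal.  Triangle
#' inequality is deliberately not required; the methods here only assume
#' symmetry and non-negativity.
#'
#' @param d square numeric matrix, or a [stats::dist] object.
#' @param tol absolute tolerance for symmetry and diagonal checks.
#' @return A validated symmetric matrix with taxon labels as dimnames
#'   (labels `t1..tn` are generated when absent).
#' @export
validate_distances <- function(d, tol = 1e-8) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || !is.numeric(d) || nrow(d) != ncol(d))
    stop("'d' must be a square numeric matrix or a 'dist' object")
  n <- nrow(d)
  if (n < 1L) stop("'d' must contain at least one taxon")
  if (any(!is.finite(d))) stop("'d' contains non-finite entries")
  if (any(d < 0)) stop("'d' contains negative entries")
  asym <- max(abs(d - t(d)))
  if (asym > tol)
    stop(sprintf("'d' is asymmetric beyond tolerance (max |d - t(d)| = %g)", asym))
  if (asym > 0) {
    # warn only above float-noise level; always repair by averaging
    if (asym > 1e-12 * max(abs(d), 1))
      warning("'d' slightly asymmetric; symmetrized by averaging")
    d <- (d + t(d)) / 2
  }
  if (max(abs(diag(d))) > tol) stop("'d' must have a zero diagonal")
  diag(d) <- 0
  labs <- rownames(d)
  if (is.null(labs)) labs <- colnames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  if (anyDuplicated(labs)) stop("taxon labels must be unique")
  dimnames(d) <- list(labs, labs)
  d
}

#' Canonical form of a split
#'
#' Returns the part of the bipartition that does not contain taxon 1, as a
#' sorted integer vector.
#'
#' @param part integer vector of taxon indices forming one part.
#' @param n number of taxa.
#' @return Sorted integer vector; the canonical representation of the split.
#' @export
split_canonical <- function(part, n) {
  part <- sort(unique(as.integer(part)))
  if (length(part) == 0L || length(part) >= n)
    stop("a split part must be a proper non-empty subset of the taxa")
  if (any(part < 1L) || any(part > n)) stop("taxon index out of range")
  if (1L %in% part) part <- setdiff(seq_len(n), part)
  part
}

#' Does a split separate two taxa?
#'
#' @param part canonical split part (see [split_canonical()]).
#' @param i,j distinct taxon indices.
#' @return `TRUE` iff exactly one of `i`, `j` lies in `part`.
#' @export
split_separates <- function(part, i, j) {
  if (i == j) stop("'i' and 'j' must be distinct")
  xor(i %in% part, j %in% part)
}

#' Weighted split system
#'
#' Bundles a set of unique splits on `n` taxa with non-negative weights and,
#' optionally, a circular ordering with which all splits are compatible.
#'
#' @param taxa character vector of unique taxon labels.
#' @param splits list of integer vectors; each is brought to canonical form
#'   (part excluding taxon 1).
#' @param weights numeric vector of non-negative split weights, one per split.
#' @param ordering optional integer permutation of `seq_along(taxa)` (a
#'   circular ordering, first element 1 by convention).
#' @return An object of class `split_system`.
#' @export
split_system <- function(taxa, splits = list(), weights = numeric(), ordering = NULL) {
  n <- length(taxa)
  if (n < 1L || anyDuplicated(taxa) || any(!nzchar(taxa)))
    stop("'taxa' must be unique non-empty labels")
  if (length(splits) != length(weights))
    stop("'splits' and 'weights' must have equal length")
  splits <- lapply(splits, split_canonical, n = n)
  keys <- vapply(splits, paste, "", collapse = ",")
  if (anyDuplicated(keys)) stop("duplicate splits are not allowed")
  weights <- as.numeric(weights)
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("'weights' must be finite and non-negative")
  if (!is.null(ordering)) {
    ordering <- as.integer(ordering)
    if (!identical(sort(ordering), seq_len(n)))
      stop("'ordering' must be a permutation of the taxon indices")
  }
  structure(list(taxa = as.character(taxa), splits = splits,
                 weights = weights, ordering = ordering),
            class = "split_system")
}

#' @export
print.split_system <- function(x, ...) {
  cat(sprintf("Weighted split system: %d taxa, %d splits (total weight %.4g)\n",
              length(x$taxa), length(x$splits), sum(x$weights)))
  if (!is.null(x$ordering))
    cat("Circular ordering:", paste(x$taxa[x$ordering], collapse = " "), "\n")
  invisible(x)
}

#' Split distance between two taxa
#'
#' The split metric: the sum of the weights of all splits separating taxa
#' `i` and `j`.  Returns 0 when `i == j`.
#'
#' @param ss a [split_system()].
#' @param i,j taxon indices.
#' @return Non-negative scalar.
#' @export
split_distance <- function(ss, i, j) {
  n <- length(ss$taxa)
  if (i < 1 || j < 1 || i > n || j > n) stop("taxon index out of range")
  if (i == j) return(0)
  sep <- vapply(ss$splits, split_separates, NA, i = i, j = j)
  sum(ss$weights[sep])
}

#' Distance matrix induced by a weighted split system
#'
#' Computes the full split metric \eqn{d_S(i,j) = \sum_{S sep. i,j} \lambda(S)}
#' for all pairs at once.
#'
#' @param ss a [split_system()].
#' @return Symmetric matrix with zero diagonal and the system's taxon labels.
#' @export
distances_from_splits <- function(ss) {
  n <- length(ss$taxa)
  d <- matrix(0, n, n, dimnames = list(ss$taxa, ss$taxa))
  for (s in seq_along(ss$splits)) {
    part <- ss$splits[[s]]
    inpart <- seq_len(n) %in% part
    sep <- outer(inpart, inpart, xor)
    d <- d + ss$weights[s] * sep
  }
  d
}

#' Is a split compatible with a circular ordering?
#'
#' A split is compatible with (an interval of) a circular ordering `theta`
#' when the positions in `theta` of its canonical part (the part not
#' containing taxon 1) form one contiguous block.  Because the part excludes
#' taxon 1 and `theta` starts at taxon 1, contiguity on the line and on the
#' circle coincide.
#'
#' @param part canonical split part.
#' @param theta integer permutation of the taxa (circular ordering).
#' @return Logical scalar.
#' @export
is_compatible_with_ordering <- function(part, theta) {
  n <- length(theta)
  part <- split_canonical(part, n)
  pos <- sort(match(part, theta))
  if (anyNA(pos)) stop("split and ordering refer to different taxa")
  all(diff(pos) == 1L)
}

#' All splits of the circular split system of an ordering
#'
#' Enumerates the \eqn{n(n-1)/2} splits compatible with a circular ordering
#' \eqn{\theta = (x_1, ..., x_n)}: for each index pair \eqn{1 \le k < l \le n}
#' the split whose one part is the interval \eqn{\{x_k, ..., x_{l-1}\}}.
#'
#' @param theta integer permutation of the taxa.
#' @return A list with components `splits` (list of canonical parts, in
#'   row order of `k`/`l`), and integer vectors `k`, `l` giving the interval
#'   index pair of each split.
#' @export
all_circular_splits <- function(theta) {
  n <- length(theta)
  if (n < 2L) stop("need at least two taxa")
  pt <- pair_table(n)
  splits <- lapply(seq_len(nrow(pt)), function(r) {
    k <- pt[r, 1L]; l <- pt[r, 2L]
    split_canonical(theta[k:(l - 1L)], n)
  })
  list(splits = splits, k = pt[, 1L], l = pt[, 2L])
}

#' Least-squares fit between observed and represented distances
#'
#' The percentage fit statistic
#' \deqn{100 (1 - \sum_{i<j} (d_{ij} - p_{ij})^2 / \sum_{i<j} d_{ij}^2)}
#' comparing input distances `d` to the distances `p` realized by a network
#' or split system.  Equal matrices give exactly 100; `p = 0` gives 0.
#'
#' @param d,p symmetric distance matrices on the same taxa.
#' @return Scalar fit percentage (can be negative for very poor fits).
#' @export
fit_percent <- function(d, p) {
  d <- validate_distances(d)
  p <- validate_distances(p)
  if (!all(dim(d) == dim(p))) stop("'d' and 'p' must have the same dimensions")
  dv <- sym_to_pv(d); pv <- sym_to_pv(p)
  denom <- sum(dv^2)
  if (denom == 0) stop("'d' is identically zero; fit is undefined")
  100 * (1 - sum((dv - pv)^2) / denom)
}
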