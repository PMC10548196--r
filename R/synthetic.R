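# Synthetic instances with known ground truth.
#
# The generator emulates the statistical structure the weight-estimation
# step assumes: a circular metric (a non-negative combination of circular
# split metrics) observed with additive Gaussian noise.  All n trivial
# splits are always included so every pair of taxa is separated by positive
# weight and no two taxa coincide, mirroring real distance data.

# run expr with a temporary RNG state seeded by `seed` (NULL = use current)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Random circular-metric instance
#'
#' Draws a circular ordering uniformly at random, selects a circular split
#' system on it (all `n` trivial splits, plus a fraction `split_density` of
#' the internal splits), draws positive weights, and returns the exact
#' split metric together with the generating ground truth.  With
#' `noise_sd > 0` the returned distances are additionally perturbed (see
#' [perturb()]).
#'
#' @param n number of taxa (default 25).
#' @param split_density fraction in (0, 1] of the internal circular splits
#'   given positive weight (default 0.2); trivial splits are always
#'   included.
#' @param weight_distribution `"exponential"` (default) or `"uniform"`.
#' @param scale scale of the weight distribution: the mean of the
#'   exponential, or the upper end of `uniform(0, scale)` (default 1).
#' @param noise_sd standard deviation of the additive Gaussian perturbation
#'   of the distances, in distance units (default 0, i.e. an exact circular
#'   metric).
#' @param seed integer seed for reproducibility (optional).
#' @return List with elements `d` (distance matrix), `ordering` (the
#'   generating circular ordering, normalized), and `splits` (the
#'   generating [split_system()]).
#' @export
random_circular_instance <- function(n = 25, split_density = 0.2,
                                     weight_distribution = c("exponential", "uniform"),
                                     scale = 1, noise_sd = 0, seed = NULL) {
  weight_distribution <- match.arg(weight_distribution)
  stopifnot(n >= 3, split_density > 0, split_density <= 1, noise_sd >= 0)
  with_seed(seed, {
    theta <- normalize_ordering(c(1L, sample(2:n)))
    acs <- all_circular_splits(theta)
    sizes <- lengths(acs$splits)
    trivial <- which(sizes == 1L | sizes == n - 1L)
    internal <- setdiff(seq_along(acs$splits), trivial)
    k <- round(split_density * length(internal))
    keep <- sort(c(trivial, sample(internal, k)))
    w <- switch(weight_distribution,
                exponential = stats::rexp(length(keep), rate = 1 / scale),
                uniform = stats::runif(length(keep), 0, scale))
    ss <- split_system(paste0("t", seq_len(n)), acs$splits[keep], w,
                       ordering = theta)
    d <- distances_from_splits(ss)
    if (noise_sd > 0) d <- perturb(d, noise_sd)
    list(d = d, ordering = theta, splits = ss)
  })
}

#' Random additive (tree-metric) instance
#'
#' A random unrooted binary tree topology with exponential branch lengths;
#' the returned distance matrix is the tree's path-length metric and the
#' ground truth is its split encoding with branch lengths as weights.
#'
#' @param n number of taxa (>= 3).
#' @param seed integer seed (optional).
#' @return List with elements `d` (distance matrix), `tree` (an
#'   [ape::phylo] object) and `splits` (a [split_system()] of the tree
#'   splits weighted by branch length).
#' @export
random_tree_instance <- function(n, seed = NULL) {
  stopifnot(n >= 3)
  with_seed(seed, {
    tr <- ape::rtree(n, rooted = FALSE, br = function(k) stats::rexp(k, 1),
                     tip.label = paste0("t", seq_len(n)))
    d <- ape::cophenetic.phylo(tr)
    o <- order(match(rownames(d), paste0("t", seq_len(n))))
    d <- d[o, o]
    sp <- phangorn::as.splits(tr)
    w <- attr(sp, "weights")
    labs <- attr(sp, "labels")
    idx <- match(labs, paste0("t", seq_len(n)))
    parts <- lapply(sp, function(p) sort(idx[p]))
    proper <- lengths(parts) > 0L & lengths(parts) < n
    parts <- lapply(parts[proper], split_canonical, n = n)
    w <- w[proper]
    # aggregate weights of identical splits (defensive; a proper unrooted
    # tree encoding has none)
    keys <- vapply(parts, paste, "", collapse = ",")
    agg <- rowsum(w, keys)
    uniq <- !duplicated(keys)
    ww <- as.vector(agg[match(keys[uniq], rownames(agg)), 1L])
    ss <- split_system(paste0("t", seq_len(n)), parts[uniq], ww)
    list(d = d, tree = tr, splits = ss)
  })
}

#' Perturb a distance matrix with truncated Gaussian noise
#'
#' Adds independent `N(0, noise_sd^2)` noise to each off-diagonal pair,
#' symmetrically, clamping at zero so the result remains a valid
#' dissimilarity; the diagonal stays zero.
#'
#' @param d distance matrix.
#' @param noise_sd noise standard deviation (>= 0).
#' @param seed integer seed (optional).
#' @return Perturbed distance matrix.
#' @export
perturb <- function(d, noise_sd, seed = NULL) {
  stopifnot(noise_sd >= 0)
  d <- validate_distances(d)
  if (noise_sd == 0) return(d)
  n <- nrow(d)
  with_seed(seed, {
    eps <- stats::rnorm(n * (n - 1) / 2, 0, noise_sd)
    dv <- pmax(sym_to_pv(d) + eps, 0)
    out <- pv_to_sym(dv, n)
    dimnames(out) <- dimnames(d)
    out
  })
}
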