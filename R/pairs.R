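# Linearization of unordered taxon pairs (i, j), i < j, on n taxa.
# The order matches base R's "dist" objects: (1,2), (1,3), ..., (1,n),
# (2,3), ..., (n-1,n).  Pair vectors of length n(n-1)/2 indexed this way
# carry either observed distances or split weights.

#' Linear index of a taxon pair
#'
#' Maps an unordered pair `(i, j)` with `i < j` on `n` taxa to its position
#' in a pair vector of length `n(n-1)/2` (the ordering used by [stats::dist]).
#'
#' @param i,j 1-based taxon indices, `i < j` (vectorized).
#' @param n number of taxa.
#' @return Integer positions in `1:(n*(n-1)/2)`.
#' @keywords internal
pair_index <- function(i, j, n) {
  stopifnot(all(i < j), all(j <= n), all(i >= 1))
  as.integer(n * (i - 1) - i * (i - 1) / 2 + j - i)
}

#' All pairs (i, j), i < j, in pair-vector order
#' @param n number of taxa.
#' @return Integer matrix with columns `i`, `j` and `n(n-1)/2` rows.
#' @keywords internal
pair_table <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  cbind(i = i, j = j)
}

# pair vector -> full symmetric n x n matrix with zero diagonal
pv_to_sym <- function(x, n) {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- x
  m + t(m)
}

# full symmetric matrix -> pair vector (lower triangle, dist order)
sym_to_pv <- function(m) {
  m[lower.tri(m)]
}
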