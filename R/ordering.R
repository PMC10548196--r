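# Agglomerative computation of a circular taxon ordering.
#
# Starting from n isolated nodes, components (singletons and chains) are
# joined n-1 times; each non-singleton component is a simple path whose two
# ends are the "active" nodes.  Selection of which components and which
# chain ends to join uses neighbor-joining-style adjusted distances, and the
# working distance matrix on active nodes is reduced in place after each
# join.  On circular input the resulting Hamiltonian cycle is compatible
# with the generating circular split system.

# Internal state: list of components, each an integer vector (the path, in
# order; ends are active), plus the working distance matrix D over original
# taxon indices (only rows/cols of active nodes are meaningful).

new_agglomeration_state <- function(d) {
  d <- validate_distances(d)
  n <- nrow(d)
  list(D = unname(d), components = lapply(seq_len(n), identity),
       n = n, joins = 0L)
}

comp_active <- function(comp) {
  if (length(comp) == 1L) comp else c(comp[1L], comp[length(comp)])
}

#' Average distance between two components
#'
#' The mean of the working distances between the active nodes (path ends) of
#' two components.
#'
#' @param state internal agglomeration state.
#' @param a,b component indices.
#' @return Scalar average distance.
#' @keywords internal
component_distance <- function(state, a, b) {
  pa <- comp_active(state$components[[a]])
  qa <- comp_active(state$components[[b]])
  mean(state$D[pa, qa])
}

# matrix of pairwise component distances
component_distance_matrix <- function(state) {
  m <- length(state$components)
  act <- lapply(state$components, comp_active)
  cd <- matrix(0, m, m)
  for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
    v <- mean(state$D[act[[a]], act[[b]]])
    cd[a, b] <- v; cd[b, a] <- v
  }
  cd
}

# Select the component pair minimizing the neighbor-joining adjusted
# distance d'(P,Q) = (m-2) d(P,Q) - sum_{S!=P} d(P,S) - sum_{S!=Q} d(Q,S):
# the Q-criterion applied to components, the selection for which adjacency
# in a compatible circular ordering is guaranteed on circular input.
# Components are scanned in order of their smallest taxon and the first
# strict minimum wins, making tie-breaking deterministic.  Returned with
# |P ∩ A| <= |Q ∩ A|.
select_components <- function(state) {
  m <- length(state$components)
  if (m < 2L) stop("component selection needs at least two components")
  ord <- order(vapply(state$components, min, 0L))
  if (m == 2L) { pair <- ord } else {
    cd <- component_distance_matrix(state)
    rs <- rowSums(cd)
    # ties in the criterion are structural (with four components every pair
    # ties its complement exactly), so they are resolved by a
    # label-independent secondary rule -- join the closer pair -- before
    # falling back to the scan order
    best <- Inf; best_cd <- Inf; pair <- NULL
    for (ia in seq_len(m - 1L)) for (ib in (ia + 1L):m) {
      a <- ord[ia]; b <- ord[ib]
      crit <- (m - 2) * cd[a, b] - rs[a] - rs[b]
      tol <- 1e-12 * (abs(crit) + 1)
      if (crit < best - tol ||
          (crit < best + tol && cd[a, b] < best_cd - tol)) {
        best <- crit; best_cd <- cd[a, b]; pair <- c(a, b)
      }
    }
  }
  sizes <- lengths(state$components[pair])
  if (min(2L, sizes[1L]) > min(2L, sizes[2L])) pair <- rev(pair)
  pair
}

# mean distance from a single active node x to the active nodes of each
# component other than the two being joined
mean_to_others <- function(state, x, excl) {
  others <- setdiff(seq_along(state$components), excl)
  vapply(others, function(s) mean(state$D[x, comp_active(state$components[[s]])]), 0)
}

# Select the chain end q of Q to link to singleton p (line-10 criterion):
# r_p = d(q1,p) + d(q2,p) + sum_S d(p,S)
# r_q = d(q1,q2) + d(q,p) + sum_S d(q,S)
# d'(q,p) = (m-1) d(q,p) - r_q - r_p,  prefer q1 on ties (q1 = smaller label).
select_node_in_chain <- function(state, pi, qi) {
  D <- state$D; m <- length(state$components)
  p <- state$components[[pi]][1L]
  ends <- comp_active(state$components[[qi]])
  ends <- sort(ends)  # q1 = end with the smaller taxon index
  q1 <- ends[1L]; q2 <- ends[2L]
  rp <- D[q1, p] + D[q2, p] + sum(mean_to_others(state, p, c(pi, qi)))
  crit <- vapply(c(q1, q2), function(q) {
    rq <- D[q1, q2] + D[q, p] + sum(mean_to_others(state, q, c(pi, qi)))
    (m - 1) * D[q, p] - rq - rp
  }, 0)
  if (crit[1L] <= crit[2L]) q1 else q2
}

# Select ends (p, q) of two chains P and Q.  As in the chain-extension
# criterion above, the four ends are treated as temporary singleton
# components alongside the m-2 untouched components (m+2 entities in all),
# and the Q-criterion is applied to the candidate pair:
# r_p = d(p,q1) + d(p,q2) + sum_S d(p,S),  r_q analogous,
# d'(p,q) = m d(p,q) - r_p - r_q
# (within-chain terms d(p,pbar), d(q,qbar) are constant over the four
# candidates and dropped).  Candidates are scanned in lexicographic order
# of the sorted end labels; the first strict minimum wins.
select_nodes_two_chains <- function(state, pi, qi) {
  D <- state$D; m <- length(state$components)
  pe <- sort(comp_active(state$components[[pi]]))
  qe <- sort(comp_active(state$components[[qi]]))
  sp <- vapply(pe, function(p) sum(mean_to_others(state, p, c(pi, qi))), 0)
  sq <- vapply(qe, function(q) sum(mean_to_others(state, q, c(pi, qi))), 0)
  best <- Inf; best_d <- Inf; sel <- NULL
  for (a in 1:2) for (b in 1:2) {
    p <- pe[a]; q <- qe[b]
    rp <- D[p, qe[1L]] + D[p, qe[2L]] + sp[a]
    rq <- D[pe[1L], q] + D[pe[2L], q] + sq[b]
    crit <- m * D[p, q] - rp - rq
    tol <- 1e-12 * (abs(crit) + 1)
    if (crit < best - tol ||
        (crit < best + tol && D[p, q] < best_d - tol)) {
      best <- crit; best_d <- D[p, q]; sel <- c(p, q)
    }
  }
  sel
}

# Join components pi (P) and qi (Q) and reduce the working distances.
join_and_reduce <- function(state, pi, qi) {
  P <- state$components[[pi]]; Q <- state$components[[qi]]
  D <- state$D
  active <- unlist(lapply(state$components, comp_active))
  if (length(P) == 1L && length(Q) == 1L) {
    newcomp <- c(P, Q)                       # distances unchanged
  } else if (length(P) == 1L) {
    p <- P[1L]
    q <- select_node_in_chain(state, pi, qi)
    qbar <- setdiff(comp_active(Q), q)
    if (Q[1L] != q) Q <- rev(Q)
    newcomp <- c(p, Q)                       # p joined to the q end
    r <- setdiff(active, c(p, q, qbar))
    Dq <- D[q, ]; Dp <- D[p, ]; Dqb <- D[qbar, ]
    D[p, qbar] <- D[qbar, p] <- (Dp[qbar] + Dqb[q] + Dp[q]) / 3
    D[p, r] <- D[r, p] <- 2 / 3 * Dp[r] + 1 / 3 * Dq[r]
    D[qbar, r] <- D[r, qbar] <- 2 / 3 * Dqb[r] + 1 / 3 * Dq[r]
  } else {
    sel <- select_nodes_two_chains(state, pi, qi)
    p <- sel[1L]; q <- sel[2L]
    pbar <- setdiff(comp_active(P), p)
    qbar <- setdiff(comp_active(Q), q)
    if (P[length(P)] != p) P <- rev(P)
    if (Q[1L] != q) Q <- rev(Q)
    newcomp <- c(P, Q)                       # pbar ... p - q ... qbar
    r <- setdiff(active, c(p, q, pbar, qbar))
    Dp <- D[p, ]; Dq <- D[q, ]; Dpb <- D[pbar, ]; Dqb <- D[qbar, ]
    D[pbar, qbar] <- D[qbar, pbar] <-
      (Dpb[p] + Dpb[q] + Dpb[qbar] + Dp[q] + Dp[qbar] + Dq[qbar]) / 6
    D[pbar, r] <- D[r, pbar] <- 1 / 2 * Dpb[r] + 1 / 3 * Dp[r] + 1 / 6 * Dq[r]
    D[qbar, r] <- D[r, qbar] <- 1 / 6 * Dp[r] + 1 / 3 * Dq[r] + 1 / 2 * Dqb[r]
  }
  state$D <- D
  state$components[[pi]] <- newcomp
  state$components[[qi]] <- NULL
  state$joins <- state$joins + 1L
  state
}

#' Circular ordering of taxa from a distance matrix
#'
#' Computes a Hamiltonian cycle on the taxa by agglomeration: components are
#' joined `n - 1` times using neighbor-joining-style adjusted distances, the
#' working distance matrix being reduced after every join, and the final
#' chain is closed into a cycle.  On a circular distance matrix the returned
#' ordering is compatible with the generating circular split system.
#'
#' The returned permutation is normalized to start at taxon 1, oriented so
#' that its second element is the smaller-indexed of taxon 1's two cycle
#' neighbors (circular orderings are equivalence classes under rotation and
#' reflection; the canonical representative makes results reproducible).
#'
#' @param d symmetric non-negative distance matrix (or `dist`).
#' @return Integer permutation `theta` of `1:n` with `theta[1] == 1`; the
#'   taxon labels are attached as the `"labels"` attribute and the number of
#'   join iterations as `"joins"`.
#' @export
compute_circular_ordering <- function(d) {
  d <- validate_distances(d)
  n <- nrow(d)
  if (n <= 3L) {
    theta <- seq_len(n)
  } else {
    state <- new_agglomeration_state(d)
    while (length(state$components) >= 2L) {
      pair <- select_components(state)
      state <- join_and_reduce(state, pair[1L], pair[2L])
    }
    stopifnot(state$joins == n - 1L)
    theta <- state$components[[1L]]        # closing edge joins the two ends
  }
  theta <- normalize_ordering(theta)
  attr(theta, "labels") <- rownames(d)
  attr(theta, "joins") <- if (n <= 3L) max(n - 1L, 0L) else n - 1L
  theta
}

#' Canonical representative of a circular ordering
#'
#' Rotates a permutation so taxon 1 comes first and reflects it so that the
#' second entry is the smaller of taxon 1's two neighbors.
#'
#' @param theta integer permutation.
#' @return Normalized integer permutation.
#' @export
normalize_ordering <- function(theta) {
  theta <- as.integer(theta)
  n <- length(theta)
  if (!identical(sort(theta), seq_len(n)))
    stop("'theta' must be a permutation of 1..n")
  if (n <= 2L) return(theta)
  pos <- match(1L, theta)
  theta <- theta[((seq_len(n) + pos - 2L) %% n) + 1L]
  if (theta[2L] > theta[n]) theta <- c(theta[1L], rev(theta[-1L]))
  theta
}
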