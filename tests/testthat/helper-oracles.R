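# Independent oracles and property checkers used across the suite.

# brute-force split distance: explicit double loop over (split, weight)
brute_split_distance <- function(splits, weights, i, j) {
  tot <- 0
  for (s in seq_along(splits)) {
    ins_i <- i %in% splits[[s]]
    ins_j <- j %in% splits[[s]]
    if (xor(ins_i, ins_j)) tot <- tot + weights[s]
  }
  tot
}

# all permutations of a vector (small n only)
perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# all circular orderings (taxon 1 fixed first) compatible with every split
# of a system, by exhaustive search; n <= 7
compatible_orderings <- function(splits, n) {
  Filter(function(th) all(vapply(splits, is_compatible_with_ordering, NA,
                                 theta = th)),
         lapply(perms(2:n), function(p) c(1L, p)))
}

# random circular split system (used where a ground-truth instance with a
# specific shape is needed); returns a split_system with ordering attached
rand_system <- function(n, n_internal = n, include_trivial = TRUE) {
  theta <- normalize_ordering(c(1L, sample(2:n)))
  acs <- all_circular_splits(theta)
  sizes <- lengths(acs$splits)
  trivial <- which(sizes == 1L | sizes == n - 1L)
  internal <- setdiff(seq_along(acs$splits), trivial)
  keep <- sort(c(if (include_trivial) trivial,
                 sample(internal, min(n_internal, length(internal)))))
  split_system(paste0("t", seq_len(n)), acs$splits[keep],
               stats::rexp(length(keep)), ordering = theta)
}

# dense reference solution of the restricted least-squares problem
dense_restricted_ls <- function(active, d, n) {
  A <- dense_design_matrix(n)
  free <- which(!active)
  x <- numeric(length(active))
  x[free] <- qr.solve(A[, free, drop = FALSE], d)
  x
}

# reference NNLS objective via pracma::lsqnonneg (dense, n <= 12)
dense_nnls_objective <- function(d, n) {
  A <- dense_design_matrix(n)
  x <- pracma::lsqnonneg(A, d)$x
  0.5 * sum((A %*% x - d)^2)
}

# split-network property suite: returns character() when all hold
check_network_properties <- function(net, ss, tol = 1e-9) {
  probs <- character()
  pos <- which(ss$weights > 0)
  n <- length(ss$taxa)
  if (!all(pos %in% net$edges$split)) probs <- c(probs, "N1: split without edge")
  g <- igraph::graph_from_edgelist(cbind(net$edges$from, net$edges$to),
                                   directed = FALSE)
  taxnodes <- net$taxa$node[order(net$taxa$taxon)]
  for (s in pos) {
    g2 <- igraph::delete_edges(g, which(net$edges$split == s))
    comp <- igraph::components(g2)
    if (comp$no != 2) {
      probs <- c(probs, paste("N2: split", s, "->", comp$no, "components"))
      next
    }
    side <- comp$membership[taxnodes]
    ref <- setdiff(seq_len(n), ss$splits[[s]])[1L]
    got <- sort(which(side != side[ref]))
    if (!identical(as.integer(got), as.integer(ss$splits[[s]])))
      probs <- c(probs, paste("N2: split", s, "wrong bipartition"))
  }
  nd <- net$nodes
  for (s in unique(net$edges$split)) {
    es <- net$edges[net$edges$split == s, , drop = FALSE]
    vx <- nd$x[es$to] - nd$x[es$from]
    vy <- nd$y[es$to] - nd$y[es$from]
    if (max(abs(sqrt(vx^2 + vy^2) - ss$weights[s])) > tol)
      probs <- c(probs, paste("N4: edge length, split", s))
    if (max(abs(vx - vx[1L])) > tol || max(abs(vy - vy[1L])) > tol)
      probs <- c(probs, paste("N4: edges not parallel, split", s))
  }
  dm <- network_distances(net)
  dS <- distances_from_splits(ss)
  if (max(abs(dm - dS)) > tol) probs <- c(probs, "geodesics != split distances")
  probs
}

# count proper crossings between edges not sharing an endpoint
count_edge_crossings <- function(net) {
  nd <- net$nodes; ed <- net$edges
  m <- nrow(ed)
  if (m < 2L) return(0L)
  x1 <- nd$x[ed$from]; y1 <- nd$y[ed$from]
  x2 <- nd$x[ed$to];   y2 <- nd$y[ed$to]
  cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
  ncross <- 0L
  eps <- 1e-12
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    if (length(intersect(c(ed$from[i], ed$to[i]),
                         c(ed$from[j], ed$to[j]))) > 0L) next
    # orientation tests
    o1 <- cross2(x2[i] - x1[i], y2[i] - y1[i], x1[j] - x1[i], y1[j] - y1[i])
    o2 <- cross2(x2[i] - x1[i], y2[i] - y1[i], x2[j] - x1[i], y2[j] - y1[i])
    o3 <- cross2(x2[j] - x1[j], y2[j] - y1[j], x1[i] - x1[j], y1[i] - y1[j])
    o4 <- cross2(x2[j] - x1[j], y2[j] - y1[j], x2[i] - x1[j], y2[i] - y1[j])
    if (o1 * o2 < -eps && o3 * o4 < -eps) ncross <- ncross + 1L
  }
  ncross
}

# outline property suite
check_outline_properties <- function(ol, ss, tol = 1e-9) {
  probs <- character()
  pos <- which(ss$weights > 0)
  tab <- table(factor(ol$edges$split, levels = pos))
  if (length(pos) && !all(tab == 2))
    probs <- c(probs, "outline: not exactly 2 edges per split")
  nd <- ol$nodes
  for (s in pos) {
    es <- ol$edges[ol$edges$split == s, , drop = FALSE]
    v <- cbind(nd$x[es$to] - nd$x[es$from], nd$y[es$to] - nd$y[es$from])
    if (max(abs(v[1L, ] + v[2L, ])) > tol)
      probs <- c(probs, paste("outline: edges not antiparallel, split", s))
    if (abs(sqrt(sum(v[1L, ]^2)) - ss$weights[s]) > tol)
      probs <- c(probs, paste("outline: edge length, split", s))
  }
  # closed boundary: signed edge vectors along the walk sum to zero; the
  # walk traverses each edge once, from -> to, in boundary order
  sx <- sum(nd$x[ol$edges$to] - nd$x[ol$edges$from])
  sy <- sum(nd$y[ol$edges$to] - nd$y[ol$edges$from])
  scale <- max(sum(ss$weights), 1)
  if (sqrt(sx^2 + sy^2) > tol * scale)
    probs <- c(probs, "outline: boundary does not close")
  # taxa appear on the boundary in cyclic order theta
  if (!identical(ol$taxa$taxon, ol$ordering))
    probs <- c(probs, "outline: taxa not in cyclic order")
  probs
}
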