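# Construction and layout of outer-labeled planar split networks.
#
# Every split of a system with circular ordering theta is an interval
# [a, b] of ordering positions (the part not containing taxon 1; positions
# run 2..n).  Each split is drawn as a band of parallel edges at its angle
# alpha(S) (the mean angle of the taxa in its interval) with length equal to
# its weight.  Two layouts are provided: the boundary outline polygon, and
# the full split network built by inserting one band at a time along the
# boundary walk.

#' Equally spaced taxon angles
#'
#' Assigns angle `(i - 1) / n * 360` degrees to the taxon at position `i`
#' of the circular ordering.
#'
#' @param theta integer circular ordering.
#' @return Numeric vector of angles in degrees, one per ordering position.
#' @export
taxon_angles <- function(theta) {
  n <- length(theta)
  (seq_len(n) - 1) / n * 360
}

# positions [a, b] (in 2..n) of a split's canonical part along theta;
# errors if the part is not an interval of the ordering
split_interval <- function(part, theta) {
  n <- length(theta)
  part <- split_canonical(part, n)
  pos <- sort(match(part, theta))
  if (anyNA(pos) || any(diff(pos) != 1L))
    stop("split is not compatible with the circular ordering")
  c(pos[1L], pos[length(pos)])
}

#' Drawing angle of a split
#'
#' The mean of the taxon angles over the split part not containing taxon 1.
#'
#' @param part split (canonical part or any part; canonicalized).
#' @param theta integer circular ordering the split must be compatible with.
#' @return Angle in degrees.
#' @export
split_angle <- function(part, theta) {
  iv <- split_interval(part, theta)
  mean(taxon_angles(theta)[iv[1L]:iv[2L]])
}

# intervals, angles and displacement vectors for all splits of a system;
# zero-weight splits are dropped (they would draw zero-length edges)
split_geometry <- function(ss) {
  if (is.null(ss$ordering))
    stop("the split system carries no circular ordering")
  theta <- ss$ordering
  keep <- which(ss$weights > 0)
  iv <- vapply(ss$splits[keep], split_interval, integer(2), theta = theta)
  ang <- vapply(ss$splits[keep], split_angle, 0, theta = theta)
  rad <- ang * pi / 180
  list(idx = keep, a = iv[1L, ], b = iv[2L, ], angle = ang,
       wx = ss$weights[keep] * cos(rad), wy = ss$weights[keep] * sin(rad),
       theta = theta, n = length(theta))
}

#' Outline polygon of a circular split system
#'
#' Walks the taxa in circular order; between consecutive taxa the boundary
#' crosses exactly the splits separating them -- each split once "opening"
#' (entering its interval, drawn as `+weight` at the split angle) and once
#' "closing" (`-weight`), so the polygon closes exactly.  Within a step,
#' closings precede openings; closings are crossed innermost interval first
#' and openings outermost first (the nesting order of intervals sharing an
#' endpoint), which keeps the boundary free of self-crossings.  A trivial
#' split appears as a spike of two antiparallel edges with the taxon at the
#' tip.
#'
#' @param ss a [split_system()] with `ordering` set; all splits must be
#'   compatible with it.
#' @return Object of class `split_outline`: data frames `nodes`
#'   (`id`, `x`, `y`), `edges` (`from`, `to`, `split` -- index into
#'   `splits`), `taxa` (`taxon`, `node`), plus the system's `splits`,
#'   `weights`, `ordering`, `labels`.
#' @export
build_outline <- function(ss) {
  geo <- split_geometry(ss)
  n <- geo$n
  theta <- geo$theta
  xs <- 0; ys <- 0                       # vertex coordinates, start at origin
  from <- integer(); to <- integer(); esplit <- integer()
  taxon_node <- integer(n)               # node of taxon at position i
  taxon_node[1L] <- 1L
  cur <- 1L
  add_edge <- function(sidx, sign) {
    xs[length(xs) + 1L] <<- xs[cur] + sign * geo$wx[sidx]
    ys[length(ys) + 1L] <<- ys[cur] + sign * geo$wy[sidx]
    from[length(from) + 1L] <<- cur
    to[length(to) + 1L] <<- length(xs)
    esplit[length(esplit) + 1L] <<- geo$idx[sidx]
    cur <<- length(xs)
  }
  for (i in seq_len(n)) {
    closing <- which(geo$b == i)
    closing <- closing[order(-geo$a[closing])]     # innermost first
    for (s in closing) add_edge(s, -1)
    if (i < n) {
      opening <- which(geo$a == i + 1L)
      opening <- opening[order(-geo$b[opening])]   # outermost first
      for (s in opening) add_edge(s, +1)
      taxon_node[i + 1L] <- cur
    }
  }
  # the walk has returned to the start vertex; identify the two nodes
  scale <- sum(abs(c(geo$wx, geo$wy)))
  gap <- sqrt((xs[cur] - xs[1L])^2 + (ys[cur] - ys[1L])^2)
  if (length(from) > 0 && gap > 1e-9 * max(scale, 1))
    stop("internal error: outline polygon failed to close")
  if (cur > 1L) {
    to[to == cur] <- 1L
    from[from == cur] <- 1L   # defensive; cur only appears as 'to'
    xs <- xs[-cur]; ys <- ys[-cur]
  }
  structure(list(
    nodes = data.frame(id = seq_along(xs), x = xs, y = ys),
    edges = data.frame(from = from, to = to, split = esplit),
    taxa = data.frame(taxon = theta, node = taxon_node),
    splits = ss$splits, weights = ss$weights,
    ordering = theta, labels = ss$taxa), class = "split_outline")
}

#' @export
print.split_outline <- function(x, ...) {
  cat(sprintf("Split network outline: %d boundary nodes, %d edges, %d taxa\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$taxa)))
  invisible(x)
}

#' Split network of a circular split system
#'
#' Builds the outer-labeled planar split network by inserting splits one at
#' a time, ordered by interval start and decreasing interval length.  Each
#' insertion duplicates the path of boundary nodes spanning the split's
#' interval, connects original and duplicate by a ladder of parallel edges
#' carrying the new split, re-homes the interval-side attachments (taxa and
#' hanging subnetworks) onto the duplicates, and displaces the interval side
#' by the split's weight at its angle.  Coordinates are resolved at the end
#' by accumulating edge displacements over a spanning tree, which makes all
#' edges of one split parallel with length equal to its weight by
#' construction.
#'
#' @param ss a [split_system()] with `ordering` set.
#' @return Object of class `split_network` with data frames `nodes`
#'   (`id`, `x`, `y`), `edges` (`from`, `to`, `split`), `taxa`
#'   (`taxon`, `node`), and the system's `splits`, `weights`, `ordering`,
#'   `labels`.
#' @export
build_split_network <- function(ss) {
  geo <- split_geometry(ss)
  n <- geo$n
  theta <- geo$theta
  ord <- order(geo$a, -geo$b)
  # walk items: type 1 = taxon marker (id = ordering position),
  #             type 2 = edge traversal (id = edge index)
  itype <- rep(1L, n)
  iid <- seq_len(n)
  n_nodes <- 1L
  efrom <- integer(); eto <- integer(); esplit <- integer()
  taxon_node <- rep(1L, n)
  nodeat <- rep(1L, n)          # node just before each item
  recompute_nodeat <- function() {
    cur <- 1L                   # walk starts at the node of taxon 1
    na <- integer(length(itype))
    for (t in seq_along(itype)) {
      na[t] <- cur
      if (itype[t] == 2L) {
        e <- iid[t]
        cur <- if (efrom[e] == cur) eto[e] else {
          if (eto[e] != cur) stop("internal error: inconsistent boundary walk")
          efrom[e]
        }
      }
    }
    na
  }
  for (s in ord) {
    a <- geo$a[s]; b <- geo$b[s]
    ia <- which(itype == 1L & iid == a)
    ib <- which(itype == 1L & iid == b)
    seg <- ia:ib
    # node sequence along the segment (node just before each item; the
    # last item is taxon b's marker, so its node closes the sequence)
    nv <- nodeat[seg]
    # path extraction: from the node of taxon a to the node of taxon b,
    # skipping excursions (sub-walks returning to an earlier node)
    path <- integer(); path_items <- integer()
    t <- 1L
    repeat {
      node <- nv[t]
      occ <- which(nv == node)
      t <- occ[length(occ)]               # jump to last occurrence
      path[length(path) + 1L] <- node
      if (t >= length(nv)) break
      # next item after this occurrence is the edge leading to the next
      # path node
      nxt <- seg[t]                        # item index at position t
      if (itype[nxt] != 2L) { t <- t + 1L; next }
      path_items[length(path_items) + 1L] <- nxt
      t <- t + 1L
    }
    k <- length(path)
    vmap <- seq_len(n_nodes + k)
    newv <- n_nodes + seq_len(k)
    vmap[path] <- newv
    n_nodes <- n_nodes + k
    # rungs: far side -> interval side, displacement +w(S)
    rungs <- integer(k)
    for (i in seq_len(k)) {
      efrom[length(efrom) + 1L] <- path[i]
      eto[length(eto) + 1L] <- newv[i]
      esplit[length(esplit) + 1L] <- geo$idx[s]
      rungs[i] <- length(efrom)
    }
    # transform the segment: path-edge traversals become their duplicates
    # (same split, endpoints mapped); excursion edges are re-pointed at any
    # path-node endpoints; taxon markers are untouched (their node follows
    # from the walk)
    segtype <- itype[seg]; segid <- iid[seg]
    onpath <- logical(length(seg))
    onpath[match(path_items, seg)] <- TRUE
    for (j in seq_along(seg)) {
      if (segtype[j] != 2L) next
      e <- segid[j]
      if (onpath[j]) {
        efrom[length(efrom) + 1L] <- vmap[efrom[e]]
        eto[length(eto) + 1L] <- vmap[eto[e]]
        esplit[length(esplit) + 1L] <- esplit[e]
        segid[j] <- length(efrom)
      } else {
        if (efrom[e] %in% path) efrom[e] <- vmap[efrom[e]]
        if (eto[e] %in% path) eto[e] <- vmap[eto[e]]
      }
    }
    itype <- c(itype[seq_len(ia - 1L)], 2L, segtype, 2L,
               if (ib < length(iid)) itype[(ib + 1L):length(iid)])
    iid <- c(iid[seq_len(ia - 1L)], rungs[1L], segid, rungs[k],
             if (ib < length(iid)) iid[(ib + 1L):length(iid)])
    nodeat <- recompute_nodeat()
    tpos <- which(itype == 1L)
    taxon_node[iid[tpos]] <- nodeat[tpos]
  }
  # coordinates: accumulate oriented displacements over a BFS tree (edges
  # are stored far-side -> interval-side, so the displacement of an edge of
  # split S is +weight(S) at angle(S) when traversed in storage direction)
  xy <- matrix(0, n_nodes, 2L)
  if (length(efrom) > 0) {
    g <- igraph::graph_from_edgelist(cbind(efrom, eto), directed = FALSE)
    disp <- cbind(geo$wx, geo$wy)[match(esplit, geo$idx), , drop = FALSE]
    bf <- igraph::bfs(g, root = 1, father = TRUE)
    ordv <- as.integer(bf$order)
    father <- as.integer(bf$father)
    ekey <- paste(pmin(efrom, eto), pmax(efrom, eto))
    v_seq <- ordv[-1L]
    f_seq <- father[v_seq]
    e_seq <- match(paste(pmin(f_seq, v_seq), pmax(f_seq, v_seq)), ekey)
    sgn <- ifelse(efrom[e_seq] == f_seq, 1, -1)
    dx <- sgn * disp[e_seq, 1L]; dy <- sgn * disp[e_seq, 2L]
    for (t in seq_along(v_seq)) {
      xy[v_seq[t], 1L] <- xy[f_seq[t], 1L] + dx[t]
      xy[v_seq[t], 2L] <- xy[f_seq[t], 2L] + dy[t]
    }
  }
  tn <- integer(n); tn[theta] <- taxon_node
  structure(list(
    nodes = data.frame(id = seq_len(n_nodes), x = xy[, 1L], y = xy[, 2L]),
    edges = data.frame(from = efrom, to = eto, split = esplit),
    taxa = data.frame(taxon = seq_len(n), node = tn),
    splits = ss$splits, weights = ss$weights,
    ordering = theta, labels = ss$taxa), class = "split_network")
}

#' @export
print.split_network <- function(x, ...) {
  cat(sprintf("Split network: %d nodes, %d edges, %d splits, %d taxa\n",
              nrow(x$nodes), nrow(x$edges), length(x$splits), nrow(x$taxa)))
  invisible(x)
}

# igraph representation with split weights on edges
network_graph <- function(net) {
  g <- igraph::graph_from_edgelist(cbind(net$edges$from, net$edges$to),
                                   directed = FALSE)
  igraph::E(g)$weight <- net$weights[net$edges$split]
  igraph::E(g)$split <- net$edges$split
  g
}

#' Patristic distances realized by a split network
#'
#' Weighted shortest-path (geodesic) distances between all pairs of taxa in
#' the network.  For a split network these equal the split distances of the
#' underlying system: any geodesic crosses exactly one edge of each split
#' separating its endpoints.
#'
#' @param net a `split_network` (or `split_outline`) object.
#' @return Symmetric matrix of patristic distances with taxon labels.
#' @export
network_distances <- function(net) {
  g <- network_graph(net)
  vn <- net$taxa$node[order(net$taxa$taxon)]
  dm <- igraph::distances(g, v = vn, to = vn)
  dimnames(dm) <- list(net$labels, net$labels)
  dm
}

#' Network distance between two taxa
#'
#' @param net a `split_network` or `split_outline`.
#' @param x,y taxon indices or labels.
#' @return Length of the shortest path between the nodes of `x` and `y`.
#' @export
network_distance <- function(net, x, y) {
  if (is.character(x)) x <- match(x, net$labels)
  if (is.character(y)) y <- match(y, net$labels)
  if (anyNA(c(x, y))) stop("unknown taxon")
  if (x == y) return(0)
  network_distances(net)[x, y]
}

#' Plot a split network or outline
#'
#' Draws the edges as line segments and labels the taxa at their nodes.
#'
#' @param x a `split_network` or `split_outline`.
#' @param show_labels draw taxon labels (default `TRUE`).
#' @param ... passed to [graphics::plot.default()].
#' @return Invisibly, `x`.
#' @export
plot.split_network <- function(x, show_labels = TRUE, ...) {
  nd <- x$nodes; ed <- x$edges
  graphics::plot(nd$x, nd$y, type = "n", asp = 1, axes = FALSE,
                 xlab = "", ylab = "", ...)
  graphics::segments(nd$x[ed$from], nd$y[ed$from],
                     nd$x[ed$to], nd$y[ed$to], col = "grey30")
  if (show_labels && nrow(x$taxa) > 0) {
    tn <- x$taxa$node
    graphics::text(nd$x[tn], nd$y[tn], labels = x$labels[x$taxa$taxon],
                   col = "firebrick", cex = 0.8, pos = 4, offset = 0.2)
  }
  invisible(x)
}

#' @rdname plot.split_network
#' @export
plot.split_outline <- plot.split_network
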