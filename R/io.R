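# Readers and writers: PHYLIP distance matrices (square and
# lower-triangular), Nexus TAXA/DISTANCES blocks, SplitsTree-compatible
# Nexus SPLITS blocks (with CYCLE statement), GML and SVG network export.

# tokenize a text file, keeping the source line of every token
tokenize_file <- function(lines) {
  toks <- character(); lns <- integer()
  for (i in seq_along(lines)) {
    t <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    t <- t[nzchar(t)]
    toks <- c(toks, t); lns <- c(lns, rep(i, length(t)))
  }
  list(tok = toks, line = lns)
}

num_or_stop <- function(tok, line, path) {
  v <- suppressWarnings(as.numeric(tok))
  if (anyNA(v)) {
    bad <- which(is.na(v))[1L]
    stop(sprintf("%s:%d: expected a number, got '%s'", path, line[bad], tok[bad]))
  }
  v
}

#' Read a distance matrix
#'
#' Reads PHYLIP distance matrices -- square or lower-triangular, with
#' relaxed label lengths and free wrapping -- and Nexus files with
#' TAXA/DISTANCES blocks.  The result is validated: entries must be
#' non-negative and symmetric within `1e-8` (small asymmetries are averaged
#' out with a warning).
#'
#' @param path file to read.
#' @param dialect `"auto"` (default; Nexus is recognized by the `#NEXUS`
#'   header, PHYLIP square/lower by token count), `"square"`, `"lower"`, or
#'   `"nexus"`.
#' @return Validated symmetric distance matrix with taxon labels.
#' @export
read_distances <- function(path, dialect = c("auto", "square", "lower", "nexus")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "auto")
    dialect <- if (any(grepl("^#NEXUS", lines[1], ignore.case = TRUE))) "nexus" else "phylip"
  if (dialect == "nexus") return(read_distances_nexus(lines, path))
  tk <- tokenize_file(lines)
  if (length(tk$tok) < 1L) stop(path, ": empty file")
  n <- suppressWarnings(as.integer(tk$tok[1L]))
  if (is.na(n) || n < 1L)
    stop(sprintf("%s:%d: first token must be the number of taxa", path, tk$line[1L]))
  body <- tk$tok[-1L]; bln <- tk$line[-1L]
  n_square <- n * (n + 1L)          # n labels + n^2 values
  n_lower <- n + n * (n - 1L) / 2L  # n labels + lower triangle
  if (dialect == "phylip")
    dialect <- if (length(body) >= n_square) "square" else "lower"
  d <- matrix(0, n, n); labs <- character(n)
  pos <- 1L
  for (i in seq_len(n)) {
    if (pos > length(body))
      stop(sprintf("%s: truncated matrix at row %d", path, i))
    labs[i] <- body[pos]; pos <- pos + 1L
    want <- if (dialect == "square") n else i - 1L
    if (pos + want - 1L > length(body))
      stop(sprintf("%s:%d: truncated row for taxon '%s'", path,
                   bln[min(pos, length(bln))], labs[i]))
    if (want > 0) {
      idx <- pos:(pos + want - 1L)
      vals <- num_or_stop(body[idx], bln[idx], path)
      if (dialect == "square") d[i, ] <- vals else d[i, seq_len(want)] <- vals
      pos <- pos + want
    }
  }
  if (dialect == "lower") d <- d + t(d)
  dimnames(d) <- list(labs, labs)
  validate_distances(d)
}

read_distances_nexus <- function(lines, path) {
  txt <- paste(lines, collapse = "\n")
  txt <- gsub("\\[[^]]*\\]", " ", txt)       # strip comments
  blocks <- regmatches(txt, gregexpr("(?is)begin\\s+(taxa|distances)\\s*;.*?end\\s*;",
                                     txt, perl = TRUE))[[1]]
  labs <- NULL; n <- NA_integer_; dmat <- NULL
  for (bl in blocks) {
    if (grepl("(?i)^begin\\s+taxa", bl, perl = TRUE)) {
      m <- regmatches(bl, regexpr("(?i)ntax\\s*=\\s*[0-9]+", bl, perl = TRUE))
      n <- as.integer(sub(".*=\\s*", "", m))
      tl <- regmatches(bl, regexpr("(?is)taxlabels(.*?);", bl, perl = TRUE))
      tl <- sub("(?is)^taxlabels", "", tl, perl = TRUE)
      tl <- gsub(";", " ", tl)
      labs <- strsplit(trimws(tl), "[[:space:]]+")[[1]]
      labs <- gsub("^'(.*)'$", "\\1", labs)
    } else {
      fmt <- regmatches(bl, regexpr("(?is)format[^;]*;", bl, perl = TRUE))
      tri <- "both"
      if (length(fmt) && grepl("(?i)triangle\\s*=\\s*lower", fmt, perl = TRUE)) tri <- "lower"
      if (length(fmt) && grepl("(?i)triangle\\s*=\\s*upper", fmt, perl = TRUE)) tri <- "upper"
      mx <- regmatches(bl, regexpr("(?is)matrix(.*?);", bl, perl = TRUE))
      if (!length(mx)) stop(path, ": DISTANCES block without MATRIX")
      mx <- sub("(?is)^matrix", "", mx, perl = TRUE)
      mx <- sub(";\\s*$", "", mx)
      rows <- strsplit(trimws(mx), "\n")[[1]]
      rows <- rows[nzchar(trimws(rows))]
      if (is.na(n)) n <- length(rows)
      dmat <- matrix(0, n, n); rl <- character(n)
      for (i in seq_along(rows)) {
        tks <- strsplit(trimws(rows[i]), "[[:space:]]+")[[1]]
        rl[i] <- gsub("^'(.*)'$", "\\1", tks[1L])
        vals <- suppressWarnings(as.numeric(tks[-1L]))
        if (anyNA(vals))
          stop(sprintf("%s: bad number in DISTANCES row '%s'", path, rl[i]))
        if (tri == "both") {
          if (length(vals) != n) stop(path, ": wrong row length in DISTANCES")
          dmat[i, ] <- vals
        } else if (tri == "lower") {
          dmat[i, seq_along(vals)] <- vals   # with or without diagonal
        } else {
          dmat[i, n - length(vals) + seq_along(vals)] <- vals
        }
      }
      if (tri != "both") dmat <- dmat + t(dmat)
      diag(dmat) <- 0
      if (is.null(labs)) labs <- rl
      dimnames(dmat) <- list(rl, rl)
    }
  }
  if (is.null(dmat)) stop(path, ": no DISTANCES block found")
  if (!is.null(labs) && !all(rownames(dmat) %in% labs))
    stop(path, ": DISTANCES labels do not match TAXLABELS")
  validate_distances(dmat)
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param d distance matrix.
#' @param path output file.
#' @export
write_phylip <- function(d, path) {
  d <- validate_distances(d)
  n <- nrow(d)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%5d", n), con)
  for (i in seq_len(n))
    writeLines(paste(format(rownames(d)[i], width = 10),
                     paste(sprintf("%.10g", d[i, ]), collapse = " ")), con)
  invisible(path)
}

#' Write a split system as a SplitsTree-compatible Nexus file
#'
#' Emits TAXA, optionally DISTANCES, and a SPLITS block carrying the
#' circular ordering as a CYCLE statement and one MATRIX row per split
#' (id, weight, then the taxa of the side containing taxon 1), plus a
#' `fit` property when supplied.  Round-trips through
#' [read_splits_nexus()].
#'
#' @param ss a [split_system()].
#' @param path output file.
#' @param d optional distance matrix to embed as a DISTANCES block.
#' @param fit optional fit percentage recorded as a SPLITS property.
#' @export
write_splits_nexus <- function(ss, path, d = NULL, fit = NULL) {
  n <- length(ss$taxa)
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("#NEXUS")
  w("")
  w("BEGIN TAXA;")
  w("\tDIMENSIONS ntax=%d;", n)
  w("\tTAXLABELS %s;", paste(sprintf("'%s'", ss$taxa), collapse = " "))
  w("END;")
  if (!is.null(d)) {
    d <- validate_distances(d)
    w("")
    w("BEGIN DISTANCES;")
    w("\tDIMENSIONS ntax=%d;", n)
    w("\tFORMAT triangle=both diagonal labels=left;")
    w("\tMATRIX")
    for (i in seq_len(n))
      w("\t'%s' %s", rownames(d)[i], paste(sprintf("%.12g", d[i, ]), collapse = " "))
    w("\t;")
    w("END;")
  }
  w("")
  w("BEGIN SPLITS;")
  w("\tDIMENSIONS ntax=%d nsplits=%d;", n, length(ss$splits))
  w("\tFORMAT labels=no weights=yes;")
  if (!is.null(fit)) w("\tPROPERTIES fit=%.6f;", fit)
  if (!is.null(ss$ordering))
    w("\tCYCLE %s;", paste(ss$ordering, collapse = " "))
  w("\tMATRIX")
  for (s in seq_along(ss$splits)) {
    side1 <- setdiff(seq_len(n), ss$splits[[s]])   # the side containing taxon 1
    w("\t[%d, size=%d]\t%.15g\t%s,", s, length(side1), ss$weights[s],
      paste(side1, collapse = " "))
  }
  w("\t;")
  w("END;")
  invisible(path)
}

#' Read a split system from a Nexus SPLITS block
#'
#' Parses the TAXA and SPLITS blocks written by [write_splits_nexus()] (and
#' by other programs using the same dialect); unknown statements inside the
#' SPLITS block are ignored.
#'
#' @param path file to read.
#' @return A [split_system()] (ordering attached when a CYCLE statement is
#'   present); the `fit` property, when present, is in attribute `"fit"`.
#' @export
read_splits_nexus <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("\\[[^]]*\\]", " ", txt)
  taxa_bl <- regmatches(txt, regexpr("(?is)begin\\s+taxa\\s*;.*?end\\s*;", txt, perl = TRUE))
  if (!length(taxa_bl)) stop(path, ": no TAXA block")
  tl <- regmatches(taxa_bl, regexpr("(?is)taxlabels(.*?);", taxa_bl, perl = TRUE))
  tl <- gsub("(?is)^taxlabels|;", " ", tl, perl = TRUE)
  labs <- strsplit(trimws(tl), "[[:space:]]+")[[1]]
  labs <- gsub("^'(.*)'$", "\\1", labs)
  n <- length(labs)
  spl_bl <- regmatches(txt, regexpr("(?is)begin\\s+splits\\s*;.*?end\\s*;", txt, perl = TRUE))
  if (!length(spl_bl)) stop(path, ": no SPLITS block")
  ordering <- NULL
  cy <- regmatches(spl_bl, regexpr("(?is)cycle([^;]*);", spl_bl, perl = TRUE))
  if (length(cy)) {
    ordering <- as.integer(strsplit(trimws(gsub("(?is)cycle|;", " ", cy, perl = TRUE)),
                                    "[[:space:]]+")[[1]])
  }
  fit <- NULL
  pr <- regmatches(spl_bl, regexpr("(?i)fit\\s*=\\s*[0-9.eE+-]+", spl_bl, perl = TRUE))
  if (length(pr)) fit <- as.numeric(sub(".*=\\s*", "", pr))
  mx <- regmatches(spl_bl, regexpr("(?is)matrix(.*?)\n\\s*;", spl_bl, perl = TRUE))
  if (!length(mx)) stop(path, ": SPLITS block without MATRIX")
  mx <- sub("(?is)^matrix", "", mx, perl = TRUE)
  rows <- strsplit(mx, ",")[[1]]
  rows <- trimws(gsub("[;]", " ", rows))
  rows <- rows[nzchar(rows)]
  parsed <- lapply(rows, function(r) {
    tks <- strsplit(r, "[[:space:]]+")[[1]]
    tks <- tks[nzchar(tks)]
    vals <- suppressWarnings(as.numeric(tks))
    if (anyNA(vals)) stop(path, ": bad SPLITS matrix row: ", r)
    vals
  })
  # some writers prefix each row with its running split id; detect that
  # dialect by every first value counting 1, 2, 3, ...
  has_id <- length(parsed) > 0 &&
    all(vapply(parsed, function(v) length(v) >= 3, NA)) &&
    identical(vapply(parsed, `[`, 0, 1L), as.numeric(seq_along(parsed)))
  splits <- list(); weights <- numeric()
  for (vals in parsed) {
    if (has_id) vals <- vals[-1L]
    weights[length(weights) + 1L] <- vals[1L]
    splits[[length(splits) + 1L]] <- split_canonical(as.integer(vals[-1L]), n)
  }
  ss <- split_system(labs, splits, weights, ordering = ordering)
  attr(ss, "fit") <- fit
  ss
}

#' Export a split network or outline
#'
#' GML output (via igraph) carries node coordinates, taxon labels and the
#' split index of every edge, and can be read back by any GML-capable tool;
#' SVG output is a plain drawing for visual inspection.
#'
#' @param net a `split_network` or `split_outline`.
#' @param path output file.
#' @param format `"gml"` or `"svg"`.
#' @export
write_network <- function(net, path, format = c("gml", "svg")) {
  format <- match.arg(format)
  if (format == "gml") {
    g <- network_graph(net)
    lab <- rep("", nrow(net$nodes))
    lab[net$taxa$node] <- net$labels[net$taxa$taxon]
    igraph::V(g)$label <- lab
    igraph::V(g)$x <- net$nodes$x
    igraph::V(g)$y <- net$nodes$y
    igraph::write_graph(g, path, format = "gml")
  } else {
    write_network_svg(net, path)
  }
  invisible(path)
}

write_network_svg <- function(net, path, size = 600) {
  nd <- net$nodes; ed <- net$edges
  rngx <- range(nd$x); rngy <- range(nd$y)
  span <- max(rngx[2] - rngx[1], rngy[2] - rngy[1], 1e-9)
  pad <- 0.08 * span
  sc <- function(x, r) (x - r[1] + pad) / (span + 2 * pad) * size
  X <- sc(nd$x, rngx); Y <- size - sc(nd$y, rngy)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">', size, size),
    sprintf('<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="black" stroke-width="1"/>',
            X[ed$from], Y[ed$from], X[ed$to], Y[ed$to]),
    sprintf('<text x="%.2f" y="%.2f" font-size="11" fill="firebrick">%s</text>',
            X[net$taxa$node] + 3, Y[net$taxa$node] - 3, net$labels[net$taxa$taxon]),
    '</svg>'), con)
  invisible(path)
}
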