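# The full pipeline: circular ordering -> split-weight estimation ->
# network construction, plus the command-line driver.

#' Compute a phylogenetic split network from a distance matrix
#'
#' Runs the three stages in sequence: an agglomerative circular ordering of
#' the taxa, non-negative least-squares estimation of the weights of all
#' circular splits compatible with that ordering, and construction of the
#' outer-labeled planar split network (and its boundary outline).  The fit
#' percentage compares the input distances to the geodesic (patristic)
#' distances of the network.
#'
#' @param d symmetric non-negative distance matrix (or `dist`) on the taxa.
#' @param method weight-estimation solver: `"active_set"` (default),
#'   `"gradient_projection"` or `"apgd"`.
#' @param options an [nnls_options()] list; `method` overrides its method
#'   field when given.
#' @param network build the full split network (default `TRUE`; the outline
#'   is always built).  For very dense systems on many taxa the full
#'   network can be large, while the outline stays linear in the number of
#'   splits.
#' @return Object of class `neighbor_net`: the validated input `d`, the
#'   `ordering`, the estimated `splits` (a [split_system()]), `outline`,
#'   `network` (or `NULL`), `fit` (percentage), and `nnls` diagnostics.
#' @examples
#' inst <- random_circular_instance(n = 8, seed = 1)
#' nn <- neighbor_net(inst$d)
#' nn$fit          # 100 on circular input
#' @export
neighbor_net <- function(d, method = NULL, options = nnls_options(),
                         network = TRUE) {
  d <- validate_distances(d)
  if (!is.null(method)) options$method <- match.arg(
    method, c("active_set", "gradient_projection", "apgd"))
  theta <- compute_circular_ordering(d)
  ss <- estimate_split_weights(d, as.integer(theta), options)
  ol <- build_outline(ss)
  net <- if (network) build_split_network(ss) else NULL
  p <- if (!is.null(net)) network_distances(net) else distances_from_splits(ss)
  fit <- if (any(d > 0)) fit_percent(d, p) else NA_real_
  structure(list(d = d, ordering = theta, splits = ss, outline = ol,
                 network = net, fit = fit, nnls = attr(ss, "nnls")),
            class = "neighbor_net")
}

#' @export
print.neighbor_net <- function(x, ...) {
  n <- nrow(x$d)
  nnl <- x$nnls
  cat(sprintf("Neighbor-net of %d taxa\n", n))
  cat(sprintf("  circular ordering: %s\n",
              paste(attr(x$ordering, "labels")[x$ordering], collapse = " ")))
  ntriv <- sum(lengths(x$splits$splits) %in% c(1L, n - 1L))
  cat(sprintf("  splits: %d (%d trivial, %d internal), total weight %.4g\n",
              length(x$splits$splits), ntriv,
              length(x$splits$splits) - ntriv, sum(x$splits$weights)))
  if (!is.null(nnl))
    cat(sprintf("  solver: %s after %d iteration(s), ||g||^2 = %.3e\n",
                if (nnl$converged) "converged" else "not converged",
                nnl$outer_iterations, nnl$projected_gradient_sq_norm))
  if (!is.null(x$network))
    cat(sprintf("  network: %d nodes, %d edges\n",
                nrow(x$network$nodes), nrow(x$network$edges)))
  cat(sprintf("  fit: %.2f%%\n", x$fit))
  invisible(x)
}

#' @export
plot.neighbor_net <- function(x, layout = c("network", "outline"), ...) {
  layout <- match.arg(layout)
  obj <- if (layout == "network" && !is.null(x$network)) x$network else x$outline
  plot(obj, ...)
}

#' Run the pipeline on files
#'
#' Reads a distance matrix, computes the split network, and writes a Nexus
#' SPLITS file (`<out>.splits.nex`), a GML graph (`<out>.gml`) and an SVG
#' drawing (`<out>.svg`).  On error, partially written outputs are removed.
#'
#' @param input path to the input distance matrix.
#' @param out output path prefix.
#' @param format input dialect passed to [read_distances()].
#' @param method solver name (see [neighbor_net()]).
#' @param layout `"outline"` (default) or `"network"`: which construction
#'   the GML/SVG exports describe.
#' @param delta_scale,rho solver options (see [nnls_options()]).
#' @param verbose print per-stage timings and the fit.
#' @return Invisibly, the `neighbor_net` object.
#' @export
run_pipeline <- function(input, out, format = "auto", method = "active_set",
                         layout = c("outline", "network"),
                         delta_scale = 1e-8, rho = 0.6, verbose = TRUE) {
  layout <- match.arg(layout)
  say <- function(...) if (verbose) message(sprintf(...))
  outputs <- paste0(out, c(".splits.nex", ".gml", ".svg"))
  ok <- FALSE
  on.exit(if (!ok) unlink(outputs))
  t0 <- proc.time()[["elapsed"]]
  d <- read_distances(input, format)
  say("read %d taxa from %s", nrow(d), input)
  opts <- nnls_options(method = method, delta_scale = delta_scale, rho = rho)
  t1 <- proc.time()[["elapsed"]]
  theta <- compute_circular_ordering(d)
  t2 <- proc.time()[["elapsed"]]
  say("ordering computed in %.2fs", t2 - t1)
  ss <- estimate_split_weights(d, as.integer(theta), opts)
  nnl <- attr(ss, "nnls")
  t3 <- proc.time()[["elapsed"]]
  say("weights estimated in %.2fs (%d splits, %d solver iterations)",
      t3 - t2, length(ss$splits),
      if (is.null(nnl)) 0L else nnl$outer_iterations)
  obj <- if (layout == "network") build_split_network(ss) else build_outline(ss)
  p <- if (layout == "network") network_distances(obj) else distances_from_splits(ss)
  fit <- if (any(d > 0)) fit_percent(d, p) else NA_real_
  t4 <- proc.time()[["elapsed"]]
  say("%s built in %.2fs; fit = %.2f%%", layout, t4 - t3, fit)
  write_splits_nexus(ss, outputs[1L], d = d, fit = fit)
  write_network(obj, outputs[2L], "gml")
  write_network(obj, outputs[3L], "svg")
  say("wrote %s, %s, %s (total %.2fs)", outputs[1L], outputs[2L], outputs[3L],
      t4 - t0)
  ok <- TRUE
  res <- structure(list(d = d, ordering = theta, splits = ss,
                        outline = if (layout == "outline") obj else NULL,
                        network = if (layout == "network") obj else NULL,
                        fit = fit, nnls = nnl),
                   class = "neighbor_net")
  invisible(res)
}

#' Simulate a circular-metric instance to files
#'
#' Writes the distances of a [random_circular_instance()] in PHYLIP square
#' format plus a plain-text ground-truth sidecar (`<out>.truth.txt`) listing
#' the generating ordering and each split with its weight.
#'
#' @param out output path for the PHYLIP file; the sidecar adds
#'   `.truth.txt`.
#' @inheritParams random_circular_instance
#' @return Invisibly, the generated instance.
#' @export
simulate_instance <- function(out, n = 25, split_density = 0.2,
                              noise_sd = 0, seed = NULL) {
  inst <- random_circular_instance(n = n, split_density = split_density,
                                   noise_sd = noise_sd, seed = seed)
  write_phylip(inst$d, out)
  side <- paste0(out, ".truth.txt")
  con <- file(side, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("# ground truth for %s", out),
    sprintf("cycle %s", paste(inst$ordering, collapse = " ")),
    vapply(seq_along(inst$splits$splits), function(s)
      sprintf("%.12g %s", inst$splits$weights[s],
              paste(inst$splits$splits[[s]], collapse = " ")), "")), con)
  invisible(inst)
}

#' Command-line entry point
#'
#' Implements `circularnet run --in <file> [--format phylip|nexus]
#' [--method active-set|gradproj|apgd] [--delta-scale x] [--rho x]
#' [--layout outline|network] --out <prefix>` and `circularnet simulate
#' --n <int> [--density x] [--noise x] [--seed int] --out <file>`.
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return Integer exit status (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: circularnet run --in dist.phy [--format auto|phylip|nexus]",
    "         [--method active-set|gradproj|apgd] [--delta-scale 1e-8]",
    "         [--rho 0.6] [--layout outline|network] --out prefix",
    "       circularnet simulate --n 50 [--density 0.3] [--noise 0.01]",
    "         [--seed 7] --out sim.phy", sep = "\n")
  if (length(args) < 1L) { message(usage); return(1L) }
  cmd <- args[1L]
  opt <- list()
  rest <- args[-1L]
  while (length(rest) >= 1L) {
    key <- sub("^--", "", rest[1L])
    if (!startsWith(rest[1L], "--") || length(rest) < 2L) {
      message("bad argument: ", rest[1L]); message(usage); return(1L)
    }
    opt[[key]] <- rest[2L]
    rest <- rest[-(1:2)]
  }
  getopt <- function(name, default = NULL) {
    if (!is.null(opt[[name]])) opt[[name]] else default
  }
  status <- tryCatch({
    if (cmd == "run") {
      if (is.null(opt[["in"]]) || is.null(opt[["out"]]))
        stop("run requires --in and --out")
      method <- switch(getopt("method", "active-set"),
                       "active-set" = "active_set",
                       "gradproj" = "gradient_projection",
                       "apgd" = "apgd",
                       stop("unknown --method"))
      fmt <- getopt("format", "auto")
      if (fmt == "phylip") fmt <- "auto"
      run_pipeline(opt[["in"]], opt[["out"]], format = fmt, method = method,
                   layout = getopt("layout", "outline"),
                   delta_scale = as.numeric(getopt("delta-scale", "1e-8")),
                   rho = as.numeric(getopt("rho", "0.6")))
      0L
    } else if (cmd == "simulate") {
      if (is.null(opt[["out"]])) stop("simulate requires --out")
      simulate_instance(opt[["out"]],
                        n = as.integer(getopt("n", "25")),
                        split_density = as.numeric(getopt("density", "0.2")),
                        noise_sd = as.numeric(getopt("noise", "0")),
                        seed = if (!is.null(opt[["seed"]]))
                          as.integer(opt[["seed"]]))
      message("wrote ", opt[["out"]], " and ", opt[["out"]], ".truth.txt")
      0L
    } else {
      message("unknown command: ", cmd); message(usage); 1L
    }
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  status
}
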