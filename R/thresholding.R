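# Thresholding: from a scored network to a series of simple unweighted
# graphs. Applying threshold theta discards every edge scoring strictly
# below theta (an edge scoring exactly theta is kept) and keeps the full
# node set, so nodes may become isolated but are never removed. Thresholds
# are handled as integer hundredths to keep the default sweep
# 0.15, 0.16, ..., 0.99 exact.

#' Apply a confidence-score threshold to a scored network
#'
#' @param net a [scored_network].
#' @param theta threshold in hundredths (integer; `theta = 40` means 0.40).
#' @return an object of class `thresholded_network`: a list with `theta`
#'   (hundredths) and `graph` (an unweighted [igraph][igraph::graph] on the
#'   full node set of `net`).
#' @export
apply_threshold <- function(net, theta) {
  stopifnot(inherits(net, "scored_network"))
  theta <- check_hundredths(theta)
  if (theta < 0L || theta > 100L)
    stop("theta must be between 0 and 100 hundredths", call. = FALSE)
  keep <- net$edges$score >= theta_value(theta) - .score_eps
  g <- igraph::graph_from_data_frame(
    net$edges[keep, c("node_a", "node_b"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
  structure(list(theta = theta, graph = g), class = "thresholded_network")
}

#' @export
print.thresholded_network <- function(x, ...) {
  cat(sprintf("<thresholded_network> theta = %.2f: %d nodes, %d edges\n",
              theta_value(x$theta), igraph::vcount(x$graph),
              igraph::ecount(x$graph)))
  invisible(x)
}

#' Sweep a threshold over a scored network
#'
#' Produces the ordered series of thresholded networks for thresholds
#' `lo, lo + step, ..., hi` (in hundredths). The default sweep 0.15-0.99 at
#' 0.01 steps yields 85 networks. Edge sets are nested: raising the
#' threshold can only remove edges.
#'
#' @param net a [scored_network].
#' @param lo,hi,step grid bounds and step, in hundredths.
#' @return a list of `thresholded_network` objects (class
#'   `threshold_series`), named by threshold.
#' @export
threshold_series <- function(net, lo = 15L, hi = 99L, step = 1L) {
  lo <- check_hundredths(lo, "lo"); hi <- check_hundredths(hi, "hi")
  step <- check_hundredths(step, "step")
  if (step <= 0L) stop("step must be a positive number of hundredths",
                       call. = FALSE)
  if (lo > hi) stop("lo must not exceed hi", call. = FALSE)
  thetas <- seq.int(lo, hi, by = step)
  out <- lapply(thetas, function(th) apply_threshold(net, th))
  names(out) <- sprintf("%d", thetas)
  structure(out, class = "threshold_series")
}

#' Per-threshold structural summaries of a threshold series
#'
#' For each thresholded network reports the average degree `2|E|/N`, the
#' average local clustering coefficient (nodes of degree < 2 contribute 0),
#' and the fraction of nodes in the largest connected component. These are
#' the standard curves used to eyeball how thresholding erodes a network.
#'
#' @param series a `threshold_series`.
#' @param path optional path; when given, the table is also written as TSV.
#' @return data frame with columns `theta` (hundredths), `avg_degree`,
#'   `avg_local_clustering`, `giant_component_fraction`.
#' @export
series_summaries <- function(series, path = NULL) {
  stopifnot(inherits(series, "threshold_series"), length(series) > 0L)
  rows <- lapply(series, function(tn) {
    g <- tn$graph
    n <- igraph::vcount(g)
    lc <- igraph::transitivity(g, type = "local", isolates = "zero")
    comp <- igraph::components(g)
    data.frame(theta = tn$theta,
               avg_degree = 2 * igraph::ecount(g) / n,
               avg_local_clustering = mean(lc),
               giant_component_fraction = max(comp$csize) / n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}

#' Define a medium-high confidence region
#'
#' The interval of thresholds (inclusive, in hundredths) over which rank
#' robustness is assessed; e.g. 60-90 for STRING-style combined scores or
#' 15-28 for HitPredict-style scores.
#'
#' @param mu,nu lower and upper bounds in hundredths, `mu <= nu`.
#' @return an object of class `confidence_region`.
#' @export
confidence_region <- function(mu, nu) {
  mu <- check_hundredths(mu, "mu"); nu <- check_hundredths(nu, "nu")
  if (mu > nu) stop("mu must not exceed nu", call. = FALSE)
  structure(list(mu = mu, nu = nu), class = "confidence_region")
}
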