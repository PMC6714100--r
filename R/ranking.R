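# Rankings: metric values -> full permutations of the node universe.
#
# Rank N is the best (largest metric value); rank 1 the worst. Nodes with
# NA metric values (LOUD metrics at leaves/isolated nodes) take the
# smallest ranks, permuted uniformly at random among themselves, and exact
# value ties are likewise permuted uniformly. Tie-break randomness is drawn
# from per-(metric, threshold) substreams so results do not depend on the
# order in which cells are computed.

#' Rank a set of node values
#'
#' @param values named numeric vector over the whole node universe; may
#'   contain NA.
#' @param seed optional integer; when given, tie-breaking uses a local RNG
#'   stream seeded with it (the caller's RNG state is untouched). When
#'   `NULL`, the current RNG stream is used.
#' @return named integer vector of ranks: a permutation of `1..N`, highest
#'   value = rank N, NA block at the bottom.
#' @export
rank_nodes <- function(values, seed = NULL) {
  if (is.null(names(values)) || anyDuplicated(names(values)))
    stop("values must be uniquely named by node", call. = FALSE)
  v <- as.numeric(values)
  v[is.na(v)] <- -Inf # NA block ties at the bottom
  r <- with_seed(seed, rank(v, ties.method = "random"))
  r <- as.integer(r)
  names(r) <- names(values)
  r
}

#' Build a rank matrix from a metric table
#'
#' Converts a long-format [metric_table] into per-(metric, threshold) full
#' rankings. Each (metric, threshold) cell draws its tie-breaks from an
#' independent substream derived from `seed` via [substream_seed()].
#'
#' @param mt a `metric_table`.
#' @param seed master integer seed for tie-breaking.
#' @return an object of class `rank_matrix`: list with `nodes`, `thetas`,
#'   `metrics` and `ranks` (per metric, an integer matrix of dimension
#'   thresholds x nodes, rows named by theta).
#' @export
build_rank_matrix <- function(mt, seed = 1L) {
  stopifnot(is.data.frame(mt),
            all(c("theta", "node", "metric", "value") %in% colnames(mt)))
  nodes <- sort(unique(mt$node))
  thetas <- sort(unique(mt$theta))
  metrics <- unique(mt$metric)
  ranks <- list()
  for (m in metrics) {
    sub <- mt[mt$metric == m, , drop = FALSE]
    rk <- matrix(NA_integer_, nrow = length(thetas), ncol = length(nodes),
                 dimnames = list(as.character(thetas), nodes))
    for (i in seq_along(thetas)) {
      th <- thetas[i]
      rows <- sub[sub$theta == th, , drop = FALSE]
      if (nrow(rows) != length(nodes))
        stop(sprintf("metric %s at theta %d: %d values for %d nodes",
                     m, th, nrow(rows), length(nodes)), call. = FALSE)
      vals <- stats::setNames(rows$value, rows$node)[nodes]
      rk[i, ] <- rank_nodes(vals, seed = substream_seed(seed, m, th))
    }
    ranks[[m]] <- rk
  }
  structure(list(nodes = nodes, thetas = as.integer(thetas),
                 metrics = metrics, ranks = ranks),
            class = "rank_matrix")
}

#' @export
print.rank_matrix <- function(x, ...) {
  cat(sprintf("<rank_matrix> %d nodes x %d thresholds x %d metrics\n",
              length(x$nodes), length(x$thetas), length(x$metrics)))
  invisible(x)
}

#' Extract one ranking from a rank matrix
#'
#' @param rm a `rank_matrix`.
#' @param metric metric name.
#' @param theta threshold in hundredths.
#' @return named integer ranking (permutation of `1..N`).
#' @export
get_ranking <- function(rm, metric, theta) {
  stopifnot(inherits(rm, "rank_matrix"))
  if (!metric %in% rm$metrics) stop("no such metric: ", metric, call. = FALSE)
  theta <- check_hundredths(theta)
  if (!theta %in% rm$thetas)
    stop("no ranking at theta = ", theta, call. = FALSE)
  r <- rm$ranks[[metric]][as.character(theta), ]
  stats::setNames(as.integer(r), rm$nodes)
}

region_thetas <- function(rm, region) {
  stopifnot(inherits(region, "confidence_region"))
  want <- seq.int(region$mu, region$nu)
  missing <- setdiff(want, rm$thetas)
  if (length(missing))
    stop("rank matrix is missing theta = ", missing[1L], call. = FALSE)
  want
}

#' Overall ranking over a confidence region
#'
#' Node ranks are averaged over every threshold of the region (0.01 steps,
#' both ends inclusive), and the mean ranks are ranked again; ties in the
#' means are resolved uniformly at random.
#'
#' @param rm a `rank_matrix`.
#' @param metric metric name.
#' @param region a [confidence_region].
#' @param seed optional integer seed for the tie-break draw.
#' @return an object of class `overall_ranking`: list with `metric`,
#'   `region` and `ranks` (named integer permutation of `1..N`).
#' @export
overall_ranking <- function(rm, metric, region, seed = NULL) {
  want <- region_thetas(rm, region)
  rk <- rm$ranks[[metric]]
  if (is.null(rk)) stop("no such metric: ", metric, call. = FALSE)
  mean_ranks <- colMeans(rk[as.character(want), , drop = FALSE])
  structure(list(metric = metric, region = region,
                 ranks = rank_nodes(mean_ranks, seed = seed)),
            class = "overall_ranking")
}

# Accept either a bare named ranking or an overall_ranking object.
as_ranking <- function(x) {
  if (inherits(x, "overall_ranking")) x$ranks
  else if (is.numeric(x) && !is.null(names(x))) {
    r <- as.integer(x)
    names(r) <- names(x)
    r
  } else stop("expected a named ranking or an overall_ranking", call. = FALSE)
}

#' Write a rank matrix as TSV
#'
#' Columns `theta`, `metric`, `node`, `rank`.
#'
#' @param rm a `rank_matrix`.
#' @param path output path.
#' @param comments optional `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
write_rank_matrix <- function(rm, path, comments = NULL) {
  stopifnot(inherits(rm, "rank_matrix"))
  rows <- do.call(rbind, lapply(rm$metrics, function(m) {
    rk <- rm$ranks[[m]]
    data.frame(theta = rep(rm$thetas, times = length(rm$nodes)),
               metric = m,
               node = rep(rm$nodes, each = length(rm$thetas)),
               rank = as.integer(rk),
               stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$metric, rows$theta, rows$node), , drop = FALSE]
  con <- file(path, "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rank matrix written by [write_rank_matrix()]
#'
#' @param path TSV path with columns `theta`, `metric`, `node`, `rank`.
#' @return a `rank_matrix`.
#' @export
read_rank_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = c(theta = "integer", metric = "character",
                                         node = "character", rank = "integer"))
  nodes <- sort(unique(df$node))
  thetas <- sort(unique(df$theta))
  metrics <- unique(df$metric)
  ranks <- list()
  for (m in metrics) {
    sub <- df[df$metric == m, , drop = FALSE]
    rk <- matrix(NA_integer_, nrow = length(thetas), ncol = length(nodes),
                 dimnames = list(as.character(thetas), nodes))
    rk[cbind(match(sub$theta, thetas), match(sub$node, nodes))] <- sub$rank
    if (anyNA(rk))
      stop("rank file does not cover every (theta, node) cell for metric ",
           m, call. = FALSE)
    ranks[[m]] <- rk
  }
  structure(list(nodes = nodes, thetas = as.integer(thetas),
                 metrics = metrics, ranks = ranks),
            class = "rank_matrix")
}
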