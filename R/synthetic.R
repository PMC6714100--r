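# Synthetic scored networks.
#
# Two generators mirror the reference synthetic designs: a Bernoulli
# (Erdos-Renyi G(n, p)) graph whose edge scores are resampled with
# replacement from an empirical score pool, and a score shuffle that takes
# a random induced subgraph of an existing scored network and permutes its
# scores over the fixed edge set (PIN-like topology, random score
# placement). A preferential-attachment fixture with a bimodal score
# distribution stands in for a real scored PIN when none is available.

synthetic_node_ids <- function(n) {
  width <- max(4L, nchar(as.character(n)))
  sprintf("n%0*d", width, seq_len(n))
}

#' Bernoulli scored network
#'
#' Each of the `n(n-1)/2` node pairs is an edge independently with
#' probability `p`; each edge's score is drawn uniformly with replacement
#' from `score_pool`. Node ids are zero-padded (`n0001`, ...) so sorting is
#' stable.
#'
#' @param n number of nodes (`>= 2`).
#' @param p edge probability in `[0, 1]`.
#' @param score_pool non-empty numeric vector of scores in `[0, 1]`.
#' @param seed integer seed; identical seeds give identical networks.
#' @return a [scored_network] with all `n` nodes in the universe.
#' @export
bernoulli_scored <- function(n, p = 0.06, score_pool, seed = 1L) {
  stopifnot(n >= 2, p >= 0, p <= 1)
  if (length(score_pool) == 0L)
    stop("score_pool must be non-empty", call. = FALSE)
  if (min(score_pool) < 0 || max(score_pool) > 1)
    stop("score_pool values must lie in [0, 1]", call. = FALSE)
  ids <- synthetic_node_ids(n)
  with_seed(seed, {
    pairs <- utils::combn(n, 2L)
    on <- stats::runif(ncol(pairs)) < p
    edges <- data.frame(
      node_a = ids[pairs[1L, on]],
      node_b = ids[pairs[2L, on]],
      score = sample(score_pool, sum(on), replace = TRUE),
      stringsAsFactors = FALSE)
    scored_network(edges, nodes = ids)
  })
}

#' Score-shuffled induced subgraph
#'
#' Chooses `n_sub` nodes uniformly at random, takes the induced subgraph,
#' and permutes its multiset of edge scores uniformly over the fixed edge
#' set. Topology and the score multiset are preserved exactly; any local
#' dependency between scores and network position is destroyed.
#'
#' @param net a [scored_network].
#' @param n_sub number of nodes to keep (default: all of them).
#' @param seed integer seed.
#' @return a [scored_network] on the sampled nodes.
#' @export
score_shuffle <- function(net, n_sub = NULL, seed = 1L) {
  stopifnot(inherits(net, "scored_network"))
  N <- length(net$nodes)
  if (is.null(n_sub)) n_sub <- N
  if (n_sub > N) stop("n_sub exceeds the number of nodes", call. = FALSE)
  with_seed(seed, {
    keep <- sort(sample(net$nodes, n_sub))
    e <- net$edges
    e <- e[e$node_a %in% keep & e$node_b %in% keep, , drop = FALSE]
    if (nrow(e)) e$score <- sample(e$score)
    scored_network(e, nodes = keep)
  })
}

#' Empirical score pool of a scored network
#'
#' Returns the multiset of edge scores (for resampling in
#' [bernoulli_scored()]).
#'
#' @param net a [scored_network] with at least one edge.
#' @return numeric vector of scores, one per edge.
#' @export
empirical_score_pool <- function(net) {
  stopifnot(inherits(net, "scored_network"))
  if (nrow(net$edges) == 0L)
    stop("network has no edges; score pool would be empty", call. = FALSE)
  net$edges$score
}

#' Histogram of edge scores
#'
#' Bins the score distribution at a fixed bin width (default 0.01, the
#' threshold-grid resolution). Bins are left-closed: `[b, b + width)`, the
#' last bin closed at 1.
#'
#' @param net a [scored_network].
#' @param binwidth bin width in `(0, 1]`.
#' @return data frame with columns `bin_lo`, `bin_hi`, `count`; counts sum
#'   to the number of edges.
#' @export
score_histogram <- function(net, binwidth = 0.01) {
  stopifnot(inherits(net, "scored_network"), binwidth > 0, binwidth <= 1)
  breaks <- seq(0, 1, by = binwidth)
  if (max(breaks) < 1) breaks <- c(breaks, 1)
  cut_idx <- pmin(findInterval(net$edges$score, breaks,
                               rightmost.closed = TRUE),
                  length(breaks) - 1L)
  counts <- tabulate(cut_idx, nbins = length(breaks) - 1L)
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
             count = counts)
}

#' Heterogeneous scored fixture
#'
#' A stand-in for a real scored protein interaction network: linear
#' preferential-attachment topology (right-skewed degree distribution) with
#' a right-skewed, bimodal score distribution — a broad low-confidence mode
#' near 0.25 and a high-confidence mode near 0.85, all scores in
#' `[0.15, 1]`. Synthetic: it reproduces qualitative features (hubs, score
#' bimodality), not any particular organism's network.
#'
#' @param n number of nodes (`>= 10`).
#' @param seed integer seed.
#' @param m edges attached per new node (controls density; `m = 9` gives a
#'   pre-threshold density near 0.06 at `n = 300`).
#' @return a [scored_network].
#' @export
heterogeneous_scored_fixture <- function(n, seed = 1L, m = 9L) {
  stopifnot(n >= 10)
  with_seed(seed, {
    g <- igraph::sample_pa(n, power = 1, m = m, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    # sample_pa can emit multi-edges; scored_network collapses duplicates
    ids <- synthetic_node_ids(n)
    ne <- nrow(el)
    low <- 0.15 + 0.30 * stats::rbeta(ne, 2, 4)
    high <- 0.60 + 0.40 * stats::rbeta(ne, 3, 2)
    score <- ifelse(stats::runif(ne) < 0.65, low, high)
    scored_network(data.frame(node_a = ids[el[, 1L]],
                              node_b = ids[el[, 2L]],
                              score = score, stringsAsFactors = FALSE),
                   nodes = ids)
  })
}
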