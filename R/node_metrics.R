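# The twelve per-node centralities.
#
# Conventions that matter for downstream ranking:
#   * local clustering of degree-<2 nodes is 0, never NA, so centrality
#     cells are always numeric;
#   * closeness in disconnected graphs sums distances to reachable nodes
#     only (no finite-size rescaling: affine maps do not change ranks) and
#     is 0 for nodes with nothing reachable;
#   * betweenness is unnormalized with endpoints excluded;
#   * the step-2 neighbourhood count n_two includes the ego itself, so
#     n_ratio = (degree + 1) / n_two. The inclusion convention is isolated
#     in `ego_counts()` should it ever need flipping.

as_metric_graph <- function(G) {
  if (inherits(G, "thresholded_network")) G$graph
  else if (inherits(G, "igraph")) G
  else stop("expected a thresholded_network or igraph object", call. = FALSE)
}

# deg, per-node triangle count and unweighted distance matrix, computed once
# and shared by the metric families and by the global summaries.
node_metric_core <- function(g) {
  list(deg = igraph::degree(g),
       tri = igraph::count_triangles(g),
       D = igraph::distances(g, algorithm = "unweighted"))
}

ego_counts <- function(deg, tri, D) {
  n_two <- rowSums(D <= 2) # finite by construction; includes the ego (d = 0)
  n_diff <- rowSums(D == 2)
  list(e_one = deg + tri,
       n_two = n_two,
       n_diff = n_diff,
       n_sqdiff = n_two - deg^2,
       n_ratio = (deg + 1) / n_two)
}

#' Degree-based centralities
#'
#' Degree, local clustering coefficient and redundancy
#' (`clustering * (degree - 1)`) for every node.
#'
#' @param G a `thresholded_network` or igraph graph (simple, undirected).
#' @return a list of three named numeric vectors: `degree`,
#'   `local_clustering`, `redundancy`.
#' @export
degree_family <- function(G) {
  g <- as_metric_graph(G)
  deg <- igraph::degree(g)
  lc <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(lc) <- names(deg)
  list(degree = deg, local_clustering = lc, redundancy = lc * (deg - 1))
}

#' Shortest-path and flow centralities
#'
#' Closeness (reciprocal sum of distances to reachable nodes), harmonic
#' centrality (sum of reciprocal distances), unnormalized shortest-path
#' betweenness, and PageRank.
#'
#' @inheritParams degree_family
#' @param damping PageRank damping factor.
#' @return a list of named numeric vectors: `closeness`, `harmonic`,
#'   `betweenness`, `pagerank`.
#' @export
path_family <- function(G, damping = 0.85) {
  g <- as_metric_graph(G)
  D <- igraph::distances(g, algorithm = "unweighted")
  path_family_from_D(g, D, damping)
}

path_family_from_D <- function(g, D, damping = 0.85) {
  Dr <- D
  diag(Dr) <- Inf
  fin <- is.finite(Dr)
  harm <- rowSums(ifelse(fin, 1 / Dr, 0))
  dist_sum <- rowSums(ifelse(fin, Dr, 0))
  clo <- ifelse(dist_sum > 0, 1 / dist_sum, 0)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  pr <- igraph::page_rank(g, damping = damping)$vector
  nm <- igraph::V(g)$name
  names(harm) <- names(clo) <- nm
  list(closeness = clo, harmonic = harm, betweenness = btw, pagerank = pr)
}

#' Ego-network centralities
#'
#' Counts derived from the step-1 and step-2 ego networks of each node:
#' `e_one` (edges in the subgraph induced by the node and its neighbours),
#' `n_two` (nodes within distance 2, ego included), `n_diff` (nodes at
#' exactly distance 2), `n_sqdiff = n_two - degree^2`, and
#' `n_ratio = (degree + 1) / n_two`.
#'
#' @inheritParams degree_family
#' @return a list of five named numeric vectors.
#' @export
ego_family <- function(G) {
  g <- as_metric_graph(G)
  core <- node_metric_core(g)
  out <- ego_counts(core$deg, core$tri, core$D)
  lapply(out, function(v) { names(v) <- names(core$deg); v })
}

#' Canonical metric names
#'
#' The 25 node metrics in canonical order: 12 centralities followed by the
#' 13 leave-one-out-difference (LOUD) metrics, whose names carry a `loud_`
#' prefix on top of the corresponding global-summary name.
#'
#' @return character vector of length 25.
#' @export
metric_names <- function() {
  c("degree", "local_clustering", "redundancy", "pagerank", "closeness",
    "harmonic", "betweenness", "e_one", "n_two", "n_diff", "n_sqdiff",
    "n_ratio",
    paste0("loud_", loud_summary_names()))
}

centrality_names <- function() metric_names()[1:12]

#' All twelve centralities for one thresholded network
#'
#' @inheritParams degree_family
#' @param damping PageRank damping factor.
#' @return a data frame with a `node` column and one column per centrality.
#' @export
centrality_table <- function(G, damping = 0.85) {
  g <- as_metric_graph(G)
  core <- node_metric_core(g)
  deg <- core$deg
  lc <- igraph::transitivity(g, type = "local", isolates = "zero")
  pf <- path_family_from_D(g, core$D, damping)
  ego <- ego_counts(deg, core$tri, core$D)
  data.frame(node = names(deg),
             degree = as.numeric(deg),
             local_clustering = lc,
             redundancy = lc * (deg - 1),
             pagerank = as.numeric(pf$pagerank),
             closeness = as.numeric(pf$closeness),
             harmonic = as.numeric(pf$harmonic),
             betweenness = as.numeric(pf$betweenness),
             e_one = as.numeric(ego$e_one),
             n_two = as.numeric(ego$n_two),
             n_diff = as.numeric(ego$n_diff),
             n_sqdiff = as.numeric(ego$n_sqdiff),
             n_ratio = as.numeric(ego$n_ratio),
             stringsAsFactors = FALSE, row.names = NULL)
}
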