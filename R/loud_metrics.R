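# Leave-one-out-difference (LOUD) metrics.
#
# A global summary f is evaluated on the thresholded network G and on G_v,
# the same network with node v disconnected from all of its neighbours;
# the node metric is f_LOUD(v) = f(G) - f(G_v). Because the computational
# cost is dominated by the leave-one-out recomputation, LOUD metrics are
# only evaluated for nodes of degree >= 2; leaves and isolated nodes get NA
# (and are later sent to the bottom of the ranking).

#' Names of the thirteen global summaries
#'
#' @return character vector of the 13 summary names underlying the LOUD
#'   metrics.
#' @export
loud_summary_names <- function() {
  c("avg_local_clustering", "global_clustering", "avg_redundancy",
    "avg_closeness", "avg_path_length", "connected_pairs",
    "avg_betweenness", "natural_connectivity",
    "avg_e_one", "avg_n_two", "avg_n_diff", "avg_n_sqdiff", "avg_n_ratio")
}

#' Isolate a node from its neighbours
#'
#' Returns the graph with every edge incident to `v` deleted; the node set
#' is unchanged, so `v` remains as an isolated vertex.
#'
#' @param g an igraph graph (or `thresholded_network`).
#' @param v node name (or vertex id).
#' @return an igraph graph.
#' @export
isolate_node <- function(g, v) {
  g <- as_metric_graph(g)
  if (is.character(v) && !(v %in% igraph::V(g)$name))
    stop("unknown node: ", v, call. = FALSE)
  igraph::delete_edges(g, igraph::incident(g, v))
}

#' Natural connectivity of a graph
#'
#' `ln((1/N) * sum_i exp(lambda_i))` over the adjacency eigenvalues
#' `lambda_i`; a spectral summary of how many closed walks (and hence
#' redundant routes) the network supports. Computed by dense symmetric
#' eigendecomposition with a log-sum-exp overflow guard. An empty graph has
#' natural connectivity 0.
#'
#' @param g an igraph graph (or `thresholded_network`).
#' @return a single number.
#' @export
natural_connectivity <- function(g) {
  g <- as_metric_graph(g)
  n <- igraph::vcount(g)
  if (n == 0L) stop("graph has no nodes", call. = FALSE)
  if (igraph::ecount(g) == 0L) return(0)
  A <- igraph::as_adjacency_matrix(g, type = "both", sparse = FALSE)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  m <- max(ev)
  m + log(mean(exp(ev - m)))
}

# All thirteen summaries (or a subset) in one pass, sharing the distance
# matrix, triangle counts and betweenness across summaries.
graph_summaries <- function(g, names = loud_summary_names()) {
  g <- as_metric_graph(g)
  bad <- setdiff(names, loud_summary_names())
  if (length(bad)) stop("unknown global summary: ", bad[1L], call. = FALSE)
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  out <- numeric(0)

  need <- function(...) any(c(...) %in% names)

  if (need("avg_local_clustering", "avg_redundancy", "global_clustering",
           "avg_e_one")) {
    tri <- igraph::count_triangles(g)
    lc <- igraph::transitivity(g, type = "local", isolates = "zero")
    if ("avg_local_clustering" %in% names)
      out["avg_local_clustering"] <- mean(lc)
    if ("avg_redundancy" %in% names)
      out["avg_redundancy"] <- mean(lc * (deg - 1))
    if ("global_clustering" %in% names) {
      triples <- sum(deg * (deg - 1) / 2)
      out["global_clustering"] <-
        if (triples > 0) sum(tri) / triples else 0
    }
    if ("avg_e_one" %in% names) out["avg_e_one"] <- mean(deg + tri)
  }

  if (need("avg_closeness", "avg_path_length", "connected_pairs",
           "avg_n_two", "avg_n_diff", "avg_n_sqdiff", "avg_n_ratio")) {
    D <- igraph::distances(g, algorithm = "unweighted")
    diag(D) <- Inf
    inf <- is.infinite(D)
    Dz <- D
    Dz[inf] <- 0 # finite distances only; one copy, reused below
    if ("avg_closeness" %in% names) {
      ds <- rowSums(Dz)
      ds[ds == 0] <- Inf
      out["avg_closeness"] <- mean(1 / ds)
    }
    if (need("avg_path_length", "connected_pairs")) {
      npairs <- (length(inf) - sum(inf)) / 2
      if ("connected_pairs" %in% names) out["connected_pairs"] <- npairs
      if ("avg_path_length" %in% names)
        out["avg_path_length"] <-
          if (npairs > 0) sum(Dz) / 2 / npairs else 0
    }
    if (need("avg_n_two", "avg_n_diff", "avg_n_sqdiff", "avg_n_ratio")) {
      n_two <- rowSums(Dz == 1) + rowSums(Dz == 2) + 1 # ego counts itself
      n_diff <- rowSums(Dz == 2)
      if ("avg_n_two" %in% names) out["avg_n_two"] <- mean(n_two)
      if ("avg_n_diff" %in% names) out["avg_n_diff"] <- mean(n_diff)
      if ("avg_n_sqdiff" %in% names) out["avg_n_sqdiff"] <- mean(n_two - deg^2)
      if ("avg_n_ratio" %in% names) out["avg_n_ratio"] <- mean((deg + 1) / n_two)
    }
  }

  if ("avg_betweenness" %in% names)
    out["avg_betweenness"] <-
      mean(igraph::betweenness(g, directed = FALSE, normalized = FALSE))
  if ("natural_connectivity" %in% names)
    out["natural_connectivity"] <- natural_connectivity(g)

  out[names]
}

#' Evaluate one global summary
#'
#' @param g an igraph graph (or `thresholded_network`).
#' @param name one of [loud_summary_names()].
#' @return a single number. Averaged summaries (`avg_*`) are means over all
#'   N nodes of the corresponding node metric; `global_clustering` is
#'   3 x triangles / connected triples (0 when there are no triples);
#'   `avg_path_length` averages over connected pairs only (0 when there are
#'   none); `connected_pairs` counts unordered pairs sharing a component.
#' @export
global_summary <- function(g, name) {
  stopifnot(length(name) == 1L)
  unname(graph_summaries(g, name))
}

#' Leave-one-out-difference table
#'
#' For each requested node `v` with degree >= 2, computes
#' `f(G) - f(G_v)` for every requested summary `f`, where `G_v` isolates
#' `v`. Nodes of degree < 2 get NA in every LOUD column.
#'
#' @param G a `thresholded_network` or igraph graph.
#' @param names subset of [loud_summary_names()].
#' @param nodes optional character vector restricting the (expensive)
#'   leave-one-out recomputation to a node subset; other nodes get NA.
#' @return a data frame with a `node` column and one `loud_<name>` column
#'   per summary.
#' @export
loud_table <- function(G, names = loud_summary_names(), nodes = NULL) {
  g <- as_metric_graph(G)
  bad <- setdiff(names, loud_summary_names())
  if (length(bad)) stop("unknown global summary: ", bad[1L], call. = FALSE)
  all_nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- all_nodes
  deg <- igraph::degree(g)

  f_full <- graph_summaries(g, names)
  vals <- matrix(NA_real_, nrow = length(all_nodes), ncol = length(names),
                 dimnames = list(all_nodes, names))
  eligible <- intersect(nodes, all_nodes[deg >= 2])
  for (v in eligible) {
    gv <- igraph::delete_edges(g, igraph::incident(g, v))
    vals[v, ] <- f_full - graph_summaries(gv, names)
  }
  out <- data.frame(node = all_nodes, vals, stringsAsFactors = FALSE,
                    row.names = NULL)
  colnames(out) <- c("node", paste0("loud_", names))
  out
}
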