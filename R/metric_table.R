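# Long-format metric table: one row per (theta, node, metric).

#' Compute node metrics across a threshold series
#'
#' Evaluates the requested metrics (any subset of [metric_names()]) on
#' every network of a threshold series and stacks the results in long
#' format. Centrality cells are always numeric; LOUD cells are NA for nodes
#' of degree < 2 at that threshold.
#'
#' @param series a `threshold_series` (or a list of `thresholded_network`s).
#' @param metrics subset of [metric_names()].
#' @param damping PageRank damping factor.
#' @param loud_nodes optional node subset for the leave-one-out
#'   recomputations (cost control on large networks).
#' @return a data frame with columns `theta` (hundredths), `node`, `metric`,
#'   `value`, of class `metric_table`.
#' @export
metric_table <- function(series, metrics = metric_names(), damping = 0.85,
                         loud_nodes = NULL) {
  bad <- setdiff(metrics, metric_names())
  if (length(bad)) stop("unknown metric: ", bad[1L], call. = FALSE)
  cents <- intersect(metrics, centrality_names())
  louds <- sub("^loud_", "", grep("^loud_", metrics, value = TRUE))

  blocks <- lapply(series, function(tn) {
    cols <- NULL
    if (length(cents)) {
      ct <- centrality_table(tn, damping = damping)
      cols <- ct[, c("node", cents), drop = FALSE]
    }
    if (length(louds)) {
      lt <- loud_table(tn, names = louds, nodes = loud_nodes)
      cols <- if (is.null(cols)) lt else cbind(cols, lt[, -1L, drop = FALSE])
    }
    mcols <- setdiff(colnames(cols), "node")
    data.frame(theta = tn$theta,
               node = rep(cols$node, times = length(mcols)),
               metric = rep(mcols, each = nrow(cols)),
               value = unlist(cols[mcols], use.names = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  class(out) <- c("metric_table", "data.frame")
  out
}

#' Write a metric table as TSV
#'
#' Long format, columns `theta`, `node`, `metric`, `value`; missing values
#' are spelled `NA`.
#'
#' @param mt a `metric_table`.
#' @param path output path.
#' @param comments optional character vector written as `#`-prefixed header
#'   lines (provenance).
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(mt, path, comments = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(mt, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
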