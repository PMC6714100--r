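# Reading, cleaning and writing scored edge lists.
#
# A scored network is the raw object of the whole pipeline: a fixed node
# universe plus undirected edges, each carrying a confidence score in [0, 1].
# Two on-disk dialects are supported: STRING-style combined scores (integers
# 0-999, divided by 1000 on read) and generic floats already in [0, 1].

#' Construct a scored network
#'
#' @param edges data frame with columns `node_a`, `node_b`, `score`
#'   (undirected; scores in `[0, 1]`). Self-loops are dropped and duplicate
#'   unordered pairs are collapsed keeping the maximum score.
#' @param nodes optional character vector pinning the node universe; must
#'   contain every edge endpoint. Defaults to the sorted set of endpoints.
#'   Extra names add isolated nodes (an edge list cannot represent them on
#'   its own).
#' @return an object of class `scored_network` with fields `nodes`
#'   (sorted character vector) and `edges` (data frame, canonical
#'   `node_a < node_b` order).
#' @export
scored_network <- function(edges, nodes = NULL) {
  if (!is.data.frame(edges))
    stop("edges must be a data frame", call. = FALSE)
  if (nrow(edges) == 0L) {
    edges <- data.frame(node_a = character(), node_b = character(),
                        score = numeric(), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(node_a = as.character(edges[[1L]]),
                        node_b = as.character(edges[[2L]]),
                        score  = as.numeric(edges[[3L]]),
                        stringsAsFactors = FALSE)
  }
  if (anyNA(edges$score))
    stop("edge scores must be numeric and non-missing", call. = FALSE)
  if (nrow(edges) && (min(edges$score) < 0 || max(edges$score) > 1))
    stop("edge scores must lie in [0, 1]", call. = FALSE)

  # canonical unordered-pair representation, drop self-loops
  edges <- edges[edges$node_a != edges$node_b, , drop = FALSE]
  if (nrow(edges)) {
    swap <- edges$node_a > edges$node_b
    tmp <- edges$node_a[swap]
    edges$node_a[swap] <- edges$node_b[swap]
    edges$node_b[swap] <- tmp
    # duplicates keep the strongest evidence
    key <- paste(edges$node_a, edges$node_b, sep = "\r")
    score <- tapply(edges$score, key, max)
    parts <- strsplit(names(score), "\r", fixed = TRUE)
    edges <- data.frame(node_a = vapply(parts, `[`, "", 1L),
                        node_b = vapply(parts, `[`, "", 2L),
                        score  = as.numeric(score),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
    rownames(edges) <- NULL
  }

  endpoints <- sort(unique(c(edges$node_a, edges$node_b)))
  if (is.null(nodes)) {
    nodes <- endpoints
  } else {
    nodes <- sort(unique(as.character(nodes)))
    missing <- setdiff(endpoints, nodes)
    if (length(missing))
      stop("edge endpoints not in node universe: ",
           paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "scored_network")
}

#' @export
print.scored_network <- function(x, ...) {
  cat(sprintf("<scored_network> %d nodes, %d scored edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges))
    cat(sprintf("  score range [%.3f, %.3f]\n",
                min(x$edges$score), max(x$edges$score)))
  invisible(x)
}

#' Read a scored edge list from a TSV file
#'
#' Parses a whitespace/tab-delimited file with at least three columns
#' (`node_a`, `node_b`, `score`). Lines starting with `#` are ignored, and a
#' single header line is auto-detected by a non-numeric third field.
#' Cleaning mirrors the usual database curation step: self-interactions are
#' dropped, duplicate unordered pairs are collapsed (keeping the maximum
#' score), and rows whose endpoints fail `node_filter` are discarded.
#'
#' @param path file path.
#' @param dialect `"generic"` (scores are floats in `[0, 1]`) or
#'   `"string_v10"` (scores are integers in 0-999, divided by 1000).
#' @param node_filter optional predicate: a function taking a node id and
#'   returning `TRUE` to keep it. Rows with either endpoint rejected are
#'   dropped (e.g. to remove cross-organism interactions).
#' @return a [scored_network].
#' @export
read_scored_edgelist <- function(path, dialect = c("generic", "string_v10"),
                                 node_filter = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- lineno[keep]

  if (!length(lines))
    return(scored_network(data.frame(node_a = character(),
                                     node_b = character(),
                                     score = numeric())))

  fields <- strsplit(trimws(lines), "[ \t]+")
  nfield <- lengths(fields)
  bad <- which(nfield < 3L)
  if (length(bad))
    stop(sprintf("line %d: expected >= 3 fields, got %d",
                 lineno[bad[1L]], nfield[bad[1L]]), call. = FALSE)

  third <- vapply(fields, `[`, "", 3L)
  num <- suppressWarnings(as.numeric(third))
  start <- 1L
  if (is.na(num[1L])) start <- 2L # header line
  if (length(bad_num <- which(is.na(num) & seq_along(num) >= start)) > 0L)
    stop(sprintf("line %d: non-numeric score '%s'",
                 lineno[bad_num[1L]], third[bad_num[1L]]), call. = FALSE)
  if (start > length(fields))
    return(scored_network(data.frame(node_a = character(),
                                     node_b = character(),
                                     score = numeric())))

  idx <- start:length(fields)
  node_a <- vapply(fields[idx], `[`, "", 1L)
  node_b <- vapply(fields[idx], `[`, "", 2L)
  score <- num[idx]

  if (dialect == "string_v10") {
    if (any(score != floor(score) | score < 0 | score > 999))
      stop("string_v10 scores must be integers in [0, 999]; offending value: ",
           score[which(score != floor(score) | score < 0 | score > 999)[1L]],
           call. = FALSE)
    score <- score / 1000
  } else if (any(score < 0 | score > 1)) {
    stop("generic scores must lie in [0, 1]; offending value: ",
         score[which(score < 0 | score > 1)[1L]], call. = FALSE)
  }

  if (!is.null(node_filter)) {
    ok <- vapply(node_a, node_filter, logical(1L)) &
      vapply(node_b, node_filter, logical(1L))
    node_a <- node_a[ok]; node_b <- node_b[ok]; score <- score[ok]
  }
  scored_network(data.frame(node_a = node_a, node_b = node_b, score = score,
                            stringsAsFactors = FALSE))
}

#' Write a scored network as a three-column TSV
#'
#' Writes a header line plus one row per edge; scores are printed with 12
#' decimals so that a write/read round trip preserves them to well below the
#' threshold-grid resolution. Isolated nodes are not representable in an
#' edge list; pass the node universe separately when re-reading if it
#' matters.
#'
#' @param net a [scored_network].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scored_edgelist <- function(net, path) {
  stopifnot(inherits(net, "scored_network"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("node_a\tnode_b\tscore", con)
  if (nrow(net$edges))
    writeLines(sprintf("%s\t%s\t%.12f",
                       net$edges$node_a, net$edges$node_b, net$edges$score),
               con)
  invisible(path)
}
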