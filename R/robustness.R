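# Rank robustness: top-k overlap statistics and the three summary measures.
#
# Top sets are defined on rankings where rank N is best: the top-n set of a
# ranking A is {v : A(v) > N - n}. The realized set size n_k =
# max(1, round(N * k)) (half away from zero) is also the normalizer, which
# keeps every similarity in [0, 1] even when N * k is not an integer.

top_set <- function(ranks, n) names(ranks)[ranks > length(ranks) - n]

check_same_universe <- function(a, b) {
  if (length(a) != length(b) || !setequal(names(a), names(b)))
    stop("rankings are not over the same node universe", call. = FALSE)
}

#' k-similarity of two rankings
#'
#' The overlap between the top 100k% node sets of two rankings over the
#' same universe: `|top(A) n top(A2)| / n_k` with
#' `n_k = max(1, round(N * k))`. Symmetric; in `[0, 1]`.
#'
#' @param A,A2 named rankings (permutations of `1..N`, rank N = best) or
#'   `overall_ranking` objects.
#' @param k top fraction in `(0, 1]`.
#' @return a number in `[0, 1]`.
#' @export
k_similarity <- function(A, A2, k) {
  A <- as_ranking(A); A2 <- as_ranking(A2)
  check_same_universe(A, A2)
  if (k <= 0 || k > 1) stop("k must be in (0, 1]", call. = FALSE)
  n_k <- max(1, round_half_up(length(A) * k))
  length(intersect(top_set(A, n_k), top_set(A2, n_k))) / n_k
}

#' Relaxed (asymmetric) k-similarity
#'
#' The proportion of the top 100k% nodes of the reference ranking `B` that
#' appear within the top 100k*alpha% of ranking `A`. Reduces to
#' [k_similarity()] at `alpha = 1`; not symmetric in its arguments.
#'
#' @param A the ranking being tested (e.g. a single-threshold ranking).
#' @param B the reference ranking (e.g. an overall ranking).
#' @param k top fraction in `(0, 1]`.
#' @param alpha relaxation factor `>= 1`; `k * alpha` must not exceed 1.
#' @return a number in `[0, 1]`.
#' @export
relaxed_k_similarity <- function(A, B, k, alpha = 1.5) {
  A <- as_ranking(A); B <- as_ranking(B)
  check_same_universe(A, B)
  if (k <= 0 || k > 1) stop("k must be in (0, 1]", call. = FALSE)
  if (alpha < 1) stop("alpha must be >= 1", call. = FALSE)
  if (k * alpha > 1 + 1e-12)
    stop("k * alpha must not exceed 1", call. = FALSE)
  N <- length(A)
  n_k <- max(1, round_half_up(N * k))
  n_ka <- max(n_k, round_half_up(N * k * alpha))
  length(intersect(top_set(B, n_k), top_set(A, n_ka))) / n_k
}

#' Rank continuity
#'
#' The fraction of (consecutive-threshold pair, k) cells whose k-similarity
#' reaches the cutoff, over all pairs (theta, theta + 0.01) with both
#' endpoints inside the region and all k in the grid. Because the k grid
#' stops at 0.05, high-ranking nodes dominate the measure.
#'
#' @param rm a `rank_matrix` covering the region at 0.01 steps.
#' @param metric metric name.
#' @param region a [confidence_region] spanning at least two thresholds.
#' @param k_grid top fractions to scan.
#' @param cutoff similarity threshold counted as "stable" (`>=` cutoff).
#' @return a number in `[0, 1]`.
#' @export
rank_continuity <- function(rm, metric, region,
                            k_grid = seq(0.001, 0.05, by = 0.001),
                            cutoff = 0.90) {
  want <- region_thetas(rm, region)
  if (length(want) < 2L)
    stop("rank continuity needs a region spanning at least two thresholds",
         call. = FALSE)
  rk <- rm$ranks[[metric]]
  if (is.null(rk)) stop("no such metric: ", metric, call. = FALSE)
  N <- length(rm$nodes)
  hits <- 0L
  total <- 0L
  for (i in seq_len(length(want) - 1L)) {
    a <- stats::setNames(rk[as.character(want[i]), ], rm$nodes)
    b <- stats::setNames(rk[as.character(want[i + 1L]), ], rm$nodes)
    for (k in k_grid) {
      hits <- hits + (k_similarity(a, b, k) >= cutoff)
      total <- total + 1L
    }
  }
  hits / total
}

#' Rank identifiability
#'
#' The worst-case relaxed similarity, across the region, between the
#' single-threshold rankings and the overall (region-averaged) ranking:
#' `min_theta M_k^alpha(A_theta, B | k = top_n/N, alpha)`. A value of 0.9
#' with the defaults means at least 90 of the overall top 100 nodes sit
#' within the top 150 at every single threshold.
#'
#' @param rm a `rank_matrix`.
#' @param metric metric name.
#' @param B the overall ranking (an `overall_ranking` or named ranking);
#'   its region is reused unless `region` is supplied.
#' @param region optional [confidence_region] to minimize over.
#' @param top_n size of the overall top set; `NULL` defaults to
#'   `min(100, floor(N / alpha))`, with a warning when lowered below 100
#'   (small networks).
#' @param alpha relaxation factor.
#' @return a number in `[0, 1]`.
#' @export
rank_identifiability <- function(rm, metric, B, region = NULL, top_n = NULL,
                                 alpha = 1.5) {
  if (is.null(region)) {
    if (!inherits(B, "overall_ranking"))
      stop("supply a region or an overall_ranking carrying one", call. = FALSE)
    region <- B$region
  }
  want <- region_thetas(rm, region)
  rk <- rm$ranks[[metric]]
  if (is.null(rk)) stop("no such metric: ", metric, call. = FALSE)
  N <- length(rm$nodes)
  if (is.null(top_n)) {
    top_n <- min(100L, as.integer(floor(N / alpha)))
    if (top_n < 100L)
      warning(sprintf("top_n lowered to %d for N = %d", top_n, N),
              call. = FALSE)
  }
  if (top_n * alpha > N)
    stop("top_n * alpha must not exceed the number of nodes", call. = FALSE)
  Br <- as_ranking(B)
  k <- top_n / N
  sims <- vapply(want, function(th) {
    a <- stats::setNames(rk[as.character(th), ], rm$nodes)
    relaxed_k_similarity(a, Br, k, alpha)
  }, numeric(1L))
  min(sims)
}

#' Rank instability
#'
#' The overall top `top_frac` of nodes (by the overall ranking `B`) are
#' followed across the region; for each, `range(v)` is the spread between
#' its best and worst single-threshold rank. Instability is the mean of
#' `range(v) / N`: 0 for perfectly stable ranks, approaching 1 for
#' near-random ones. Low values additionally certify that top nodes keep
#' their ordering, which the overlap-based measures ignore.
#'
#' @param rm a `rank_matrix`.
#' @param metric metric name.
#' @param B the overall ranking (an `overall_ranking` or named ranking).
#' @param region optional [confidence_region]; defaults to `B`'s region.
#' @param top_frac fraction of nodes followed; the set size is
#'   `max(1, round(top_frac * N))`.
#' @return a number in `[0, (N-1)/N]`.
#' @export
rank_instability <- function(rm, metric, B, region = NULL, top_frac = 0.01) {
  if (is.null(region)) {
    if (!inherits(B, "overall_ranking"))
      stop("supply a region or an overall_ranking carrying one", call. = FALSE)
    region <- B$region
  }
  want <- region_thetas(rm, region)
  rk <- rm$ranks[[metric]]
  if (is.null(rk)) stop("no such metric: ", metric, call. = FALSE)
  N <- length(rm$nodes)
  Br <- as_ranking(B)
  U <- top_set(Br, max(1L, round_half_up(top_frac * N)))
  sub <- rk[as.character(want), U, drop = FALSE]
  ranges <- apply(sub, 2L, function(col) max(col) - min(col))
  mean(ranges) / N
}

#' Per-metric robustness report
#'
#' Computes rank continuity, identifiability and instability for every
#' metric of a rank matrix over a confidence region, with shared
#' parameters. The overall ranking of each metric uses an independent
#' tie-break substream derived from `seed`.
#'
#' @param rm a `rank_matrix` covering `region` at 0.01 steps.
#' @param region a [confidence_region].
#' @param metrics metrics to report on; defaults to all in `rm`.
#' @param k_grid,cutoff continuity parameters.
#' @param top_n,alpha identifiability parameters (`top_n = NULL` for the
#'   size-adaptive default).
#' @param top_frac instability parameter.
#' @param seed master seed for overall-ranking tie-breaks.
#' @return a data frame (class `robustness_report`) with columns `metric`,
#'   `continuity`, `identifiability`, `instability`; the parameters used
#'   are attached as attribute `params`.
#' @export
robustness_report <- function(rm, region, metrics = rm$metrics,
                              k_grid = seq(0.001, 0.05, by = 0.001),
                              cutoff = 0.90, top_n = NULL, alpha = 1.5,
                              top_frac = 0.01, seed = 1L) {
  stopifnot(inherits(rm, "rank_matrix"))
  missing <- setdiff(metrics, rm$metrics)
  if (length(missing))
    stop("rank matrix lacks metric: ", missing[1L], call. = FALSE)
  rows <- lapply(metrics, function(m) {
    B <- overall_ranking(rm, m, region,
                         seed = substream_seed(seed, paste0("overall:", m)))
    data.frame(metric = m,
               continuity = rank_continuity(rm, m, region, k_grid, cutoff),
               identifiability = rank_identifiability(rm, m, B,
                                                      top_n = top_n,
                                                      alpha = alpha),
               instability = rank_instability(rm, m, B, top_frac = top_frac),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "params") <- list(mu = region$mu, nu = region$nu,
                              k_grid = k_grid, cutoff = cutoff,
                              top_n = top_n, alpha = alpha,
                              top_frac = top_frac, seed = seed)
  class(out) <- c("robustness_report", "data.frame")
  out
}

#' Write a robustness report as TSV
#'
#' The parameters used are echoed as `#`-prefixed header comments.
#'
#' @param report a `robustness_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_robustness_report <- function(report, path) {
  p <- attr(report, "params")
  con <- file(path, "wt")
  on.exit(close(con))
  if (!is.null(p)) {
    writeLines(sprintf("# region: [%d, %d] (hundredths)", p$mu, p$nu), con)
    writeLines(sprintf("# k_grid: %g..%g (%d values); cutoff: %g",
                       min(p$k_grid), max(p$k_grid), length(p$k_grid),
                       p$cutoff), con)
    writeLines(sprintf("# top_n: %s; alpha: %g; top_frac: %g; seed: %d",
                       ifelse(is.null(p$top_n), "auto", as.character(p$top_n)),
                       p$alpha, p$top_frac, p$seed), con)
  }
  utils::write.table(as.data.frame(report), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
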