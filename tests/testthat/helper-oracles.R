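# Independent brute-force oracles, implemented on plain adjacency matrices
# with base R only (no igraph), so they share no code path with the package.

# random simple graph as a symmetric 0/1 adjacency matrix with node names
oracle_random_adj <- function(n, p = 0.2) {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  A <- A + t(A)
  dimnames(A) <- list(sprintf("v%03d", 1:n), sprintf("v%03d", 1:n))
  A
}

adj_to_graph <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# all-pairs shortest paths by Floyd-Warshall
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in 1:n) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

# shortest-path counts from every source (BFS layer DP)
oracle_path_counts <- function(A, D) {
  n <- nrow(A)
  S <- matrix(0, n, n, dimnames = dimnames(A))
  for (s in 1:n) {
    sigma <- numeric(n)
    sigma[s] <- 1
    for (d in sort(unique(D[s, is.finite(D[s, ]) & D[s, ] > 0]))) {
      for (v in which(D[s, ] == d)) {
        pred <- which(A[, v] > 0 & D[s, ] == d - 1)
        sigma[v] <- sum(sigma[pred])
      }
    }
    S[s, ] <- sigma
  }
  S
}

# betweenness via the pair-sum formula over sigma counts
oracle_betweenness <- function(A) {
  D <- oracle_distances(A)
  S <- oracle_path_counts(A, D)
  n <- nrow(A)
  b <- numeric(n)
  for (v in 1:n) {
    acc <- 0
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(D[s, t])) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t])
        acc <- acc + S[s, v] * S[v, t] / S[s, t]
    }
    b[v] <- acc
  }
  names(b) <- rownames(A)
  b
}

oracle_local_clustering <- function(A) {
  n <- nrow(A)
  lc <- numeric(n)
  deg <- rowSums(A)
  for (v in 1:n) {
    if (deg[v] < 2) next
    nb <- which(A[v, ] > 0)
    lc[v] <- sum(A[nb, nb]) / 2 / choose(deg[v], 2)
  }
  names(lc) <- rownames(A)
  lc
}

oracle_pagerank <- function(A, damping = 0.85, tol = 1e-14) {
  n <- nrow(A)
  deg <- rowSums(A)
  x <- rep(1 / n, n)
  repeat {
    spread <- numeric(n)
    for (v in which(deg > 0))
      spread[A[v, ] > 0] <- spread[A[v, ] > 0] + x[v] / deg[v]
    dangling <- sum(x[deg == 0]) / n
    x2 <- (1 - damping) / n + damping * (spread + dangling)
    if (sum(abs(x2 - x)) < tol) break
    x <- x2
  }
  names(x2) <- rownames(A)
  x2
}

# the twelve centralities from scratch
oracle_centralities <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  D <- oracle_distances(A)
  lc <- oracle_local_clustering(A)
  e_one <- vapply(1:n, function(v) {
    nb <- c(v, which(A[v, ] > 0))
    sum(A[nb, nb]) / 2
  }, numeric(1))
  n_two <- vapply(1:n, function(v) sum(D[v, ] <= 2), numeric(1))
  n_diff <- vapply(1:n, function(v) sum(D[v, ] == 2), numeric(1))
  Dr <- D; diag(Dr) <- Inf
  harm <- rowSums(ifelse(is.finite(Dr), 1 / Dr, 0))
  ds <- rowSums(ifelse(is.finite(Dr), Dr, 0))
  clo <- ifelse(ds > 0, 1 / ds, 0)
  out <- list(degree = deg, local_clustering = lc,
              redundancy = lc * (deg - 1),
              pagerank = oracle_pagerank(A),
              closeness = clo, harmonic = harm,
              betweenness = oracle_betweenness(A),
              e_one = e_one, n_two = n_two, n_diff = n_diff,
              n_sqdiff = n_two - deg^2, n_ratio = (deg + 1) / n_two)
  lapply(out, function(v) { names(v) <- rownames(A); v })
}

# natural connectivity via the trace of the matrix exponential
oracle_natural_connectivity <- function(A) {
  n <- nrow(A)
  tr <- sum(diag(as.matrix(Matrix::expm(Matrix::Matrix(A * 1.0)))))
  log(tr / n)
}

# the thirteen global summaries from scratch
oracle_global_summaries <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  cen <- oracle_centralities(A)
  D <- oracle_distances(A)
  Dr <- D; diag(Dr) <- Inf
  fin <- is.finite(Dr)
  npairs <- sum(fin) / 2
  triangles <- sum(diag(A %*% A %*% A)) / 6
  triples <- sum(choose(deg, 2))
  c(avg_local_clustering = mean(cen$local_clustering),
    global_clustering = if (triples > 0) 3 * triangles / triples else 0,
    avg_redundancy = mean(cen$redundancy),
    avg_closeness = mean(cen$closeness),
    avg_path_length = if (npairs > 0) sum(Dr[fin]) / 2 / npairs else 0,
    connected_pairs = npairs,
    avg_betweenness = mean(cen$betweenness),
    natural_connectivity = oracle_natural_connectivity(A),
    avg_e_one = mean(cen$e_one),
    avg_n_two = mean(cen$n_two),
    avg_n_diff = mean(cen$n_diff),
    avg_n_sqdiff = mean(cen$n_sqdiff),
    avg_n_ratio = mean(cen$n_ratio))
}

# LOUD values from scratch: recompute the summary on a copy with v's row
# and column zeroed
oracle_loud <- function(A, v) {
  Av <- A
  Av[v, ] <- 0L
  Av[, v] <- 0L
  oracle_global_summaries(A) - oracle_global_summaries(Av)
}

# ---- rank / similarity oracles -------------------------------------------

oracle_random_ranking <- function(n) {
  stats::setNames(sample(n), sprintf("v%03d", 1:n))
}

oracle_top <- function(r, n) names(sort(r, decreasing = TRUE))[seq_len(n)]

oracle_k_similarity <- function(a, b, k) {
  n_k <- max(1, floor(length(a) * k + 0.5))
  length(intersect(oracle_top(a, n_k), oracle_top(b, n_k))) / n_k
}

oracle_relaxed <- function(a, b, k, alpha) {
  N <- length(a)
  n_k <- max(1, floor(N * k + 0.5))
  n_ka <- max(n_k, floor(N * k * alpha + 0.5))
  length(intersect(oracle_top(b, n_k), oracle_top(a, n_ka))) / n_k
}

# a rank "matrix" as a plain list of named rankings keyed by theta string
oracle_random_rankmat <- function(n, thetas) {
  out <- lapply(thetas, function(th) oracle_random_ranking(n))
  names(out) <- as.character(thetas)
  out
}

oracle_continuity <- function(rl, k_grid, cutoff = 0.90) {
  ths <- as.integer(names(rl))
  hits <- 0; total <- 0
  for (i in seq_len(length(ths) - 1)) for (k in k_grid) {
    hits <- hits + (oracle_k_similarity(rl[[i]], rl[[i + 1]], k) >= cutoff)
    total <- total + 1
  }
  hits / total
}

oracle_identifiability <- function(rl, B, top_n, alpha) {
  N <- length(B)
  min(vapply(rl, function(a) oracle_relaxed(a, B, top_n / N, alpha),
             numeric(1)))
}

oracle_instability <- function(rl, B, top_frac) {
  N <- length(B)
  U <- oracle_top(B, max(1, floor(top_frac * N + 0.5)))
  rng <- vapply(U, function(v) {
    rs <- vapply(rl, function(a) a[[v]], numeric(1))
    max(rs) - min(rs)
  }, numeric(1))
  mean(rng) / N
}

# wrap a list of named rankings into the package rank_matrix layout
as_pkg_rank_matrix <- function(rl, metric = "m") {
  nodes <- sort(names(rl[[1]]))
  thetas <- as.integer(names(rl))
  rk <- t(vapply(rl, function(r) as.integer(r[nodes]),
                 integer(length(nodes))))
  dimnames(rk) <- list(as.character(thetas), nodes)
  structure(list(nodes = nodes, thetas = thetas, metrics = metric,
                 ranks = stats::setNames(list(rk), metric)),
            class = "rank_matrix")
}

# tiny scored-network fixture used across test files
tiny_scored <- function() {
  scored_network(data.frame(
    node_a = c("a", "b", "c", "a", "d"),
    node_b = c("b", "c", "d", "c", "e"),
    score = c(0.9, 0.8, 0.2, 0.5, 0.35)))
}
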