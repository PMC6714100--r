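test_that("k-similarity: identity, disjoint, explicit sets, symmetry", {
  A <- stats::setNames(1:10, sprintf("v%03d", 1:10))
  expect_equal(k_similarity(A, A, 0.3), 1)
  expect_equal(k_similarity(A, stats::setNames(11 - A, names(A)), 0.3), 0)
  # N=10, k=0.3: top-3 sets {8,9,10} vs {7,9,10} -> 2/3
  B <- A
  B[c("v007", "v008")] <- c(8L, 7L)
  expect_equal(k_similarity(A, B, 0.3), 2 / 3)
  expect_error(k_similarity(A, A[1:5], 0.3), "universe")
  expect_error(k_similarity(A, A, 0), "in \\(0, 1\\]")

  set.seed(15)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    a <- oracle_random_ranking(n)
    b <- oracle_random_ranking(n)
    k <- stats::runif(1, 0.01, 1)
    expect_equal(k_similarity(a, b, k), k_similarity(b, a, k))
    expect_equal(k_similarity(a, b, k), oracle_k_similarity(a, b, k))
  }
})

test_that("relaxed k-similarity: construction, reduction at alpha = 1, oracle", {
  # N=10, k=0.2, alpha=1.5: B top-2 {u,v}; A holds u 9th (in top-3), v 5th
  nodes <- sprintf("v%03d", 1:10)
  B <- stats::setNames(1:10, nodes) # top-2 of B: v009, v010
  A <- stats::setNames(c(2L, 3L, 4L, 6L, 7L, 8L, 10L, 1L, 9L, 5L), nodes)
  expect_equal(relaxed_k_similarity(A, B, 0.2, 1.5), 1 / 2)
  expect_equal(relaxed_k_similarity(B, B, 0.2, 1.5), 1)
  expect_error(relaxed_k_similarity(A, B, 0.8, 1.5), "exceed 1")

  set.seed(16)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    a <- oracle_random_ranking(n)
    b <- oracle_random_ranking(n)
    k <- stats::runif(1, 0.01, 0.6)
    expect_equal(relaxed_k_similarity(a, b, k, 1), k_similarity(a, b, k))
    alpha <- stats::runif(1, 1, 1 / k)
    expect_equal(relaxed_k_similarity(a, b, k, alpha),
                 oracle_relaxed(a, b, k, alpha))
  }
})

test_that("the three measures are exact on degenerate rank matrices", {
  rl <- oracle_random_rankmat(200, 60:70)
  for (th in names(rl)) rl[[th]] <- rl[["60"]]
  rm_ <- as_pkg_rank_matrix(rl)
  region <- confidence_region(60, 70)
  B <- overall_ranking(rm_, "m", region, seed = 1)
  expect_equal(rank_continuity(rm_, "m", region), 1)
  expect_equal(rank_identifiability(rm_, "m", B), 1)
  expect_equal(rank_instability(rm_, "m", B), 0)
  expect_error(rank_continuity(rm_, "m", confidence_region(60, 60)),
               "at least two")
})

test_that("constructed cases: continuity 0, identifiability 0.60, instability 0.99", {
  # reversing rankings have disjoint top-5% sets at every pair
  n <- 100
  fwd <- stats::setNames(1:n, sprintf("v%03d", 1:n))
  rev_ <- stats::setNames(n:1, sprintf("v%03d", 1:n))
  rl <- list("60" = fwd, "61" = rev_, "62" = fwd, "63" = rev_)
  rm_ <- as_pkg_rank_matrix(rl)
  expect_equal(rank_continuity(rm_, "m", confidence_region(60, 63)), 0)

  # one threshold whose top-150 misses 40 of B's top-100 (N = 300)
  N <- 300
  nodes <- sprintf("v%03d", 1:N)
  B <- stats::setNames(1:N, nodes)
  good <- B
  bad <- B
  # send 40 of B's top-100 (ranks 201..240) to the bottom of A
  bad[nodes[201:240]] <- 1:40
  bad[nodes[1:40]] <- 201:240
  rl2 <- list("60" = good, "61" = bad, "62" = good)
  rm2 <- as_pkg_rank_matrix(rl2)
  expect_equal(rank_identifiability(rm2, "m", B,
                                    region = confidence_region(60, 62),
                                    top_n = 100, alpha = 1.5),
               0.60)
  expect_error(rank_identifiability(rm2, "m", B,
                                    region = confidence_region(60, 62),
                                    top_n = 250, alpha = 1.5),
               "must not exceed")

  # top node swinging between rank 1 and rank N, N = 100, |U| = 1
  top <- names(fwd)[fwd == n]
  swung <- fwd
  swung[top] <- 1L
  swung[names(fwd)[fwd == 1L]] <- n
  rl3 <- list("60" = fwd, "61" = swung)
  rm3 <- as_pkg_rank_matrix(rl3)
  expect_equal(rank_instability(rm3, "m", fwd,
                                region = confidence_region(60, 61),
                                top_frac = 0.01),
               0.99)
})

test_that("measures match brute-force oracles on random rank matrices", {
  set.seed(21)
  k_grid <- seq(0.001, 0.05, by = 0.001)
  for (i in 1:10) {
    n <- sample(c(30, 80, 150, 200), 1)
    rl <- oracle_random_rankmat(n, 60:(60 + sample(3:6, 1)))
    rm_ <- as_pkg_rank_matrix(rl)
    region <- confidence_region(60, max(as.integer(names(rl))))
    expect_equal(rank_continuity(rm_, "m", region, k_grid),
                 oracle_continuity(rl, k_grid))
    B <- overall_ranking(rm_, "m", region, seed = i)
    top_n <- min(20, floor(n / 1.5))
    expect_equal(rank_identifiability(rm_, "m", B, top_n = top_n),
                 oracle_identifiability(rl, B$ranks, top_n, 1.5))
    expect_equal(rank_instability(rm_, "m", B, top_frac = 0.01),
                 oracle_instability(rl, B$ranks, 0.01))
  }
})

test_that("identifiability is non-increasing as the region widens", {
  set.seed(33)
  rl <- oracle_random_rankmat(120, 60:70)
  # correlate rankings so the measure is not trivially 0
  base <- oracle_random_ranking(120)
  for (th in names(rl)) {
    r <- base
    swap <- sample(120, 10)
    r[swap] <- r[rev(swap)]
    rl[[th]] <- r
  }
  rm_ <- as_pkg_rank_matrix(rl)
  wide <- confidence_region(60, 70)
  B <- overall_ranking(rm_, "m", wide, seed = 1)
  vals <- vapply(62:70, function(nu)
    rank_identifiability(rm_, "m", B, region = confidence_region(60, nu),
                         top_n = 12), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("robustness_report equals component-wise recomputation", {
  net <- heterogeneous_scored_fixture(40, seed = 6, m = 4)
  series <- threshold_series(net, 55, 65)
  mt <- metric_table(series, metrics = c("degree", "betweenness",
                                         "loud_natural_connectivity"))
  rm_ <- build_rank_matrix(mt, seed = 8)
  region <- confidence_region(55, 65)
  rep <- suppressWarnings(robustness_report(rm_, region, seed = 8))
  expect_equal(rep$metric, c("degree", "betweenness",
                             "loud_natural_connectivity"))
  expect_true(all(rep$continuity >= 0 & rep$continuity <= 1))
  expect_true(all(rep$identifiability >= 0 & rep$identifiability <= 1))
  expect_true(all(rep$instability >= 0 & rep$instability <= 1))
  for (j in seq_len(nrow(rep))) {
    m <- rep$metric[j]
    B <- overall_ranking(rm_, m, region,
                         seed = substream_seed(8, paste0("overall:", m)))
    expect_equal(rep$continuity[j], rank_continuity(rm_, m, region))
    expect_equal(rep$identifiability[j],
                 suppressWarnings(rank_identifiability(rm_, m, B)))
    expect_equal(rep$instability[j], rank_instability(rm_, m, B))
  }
})
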