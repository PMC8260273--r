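test_that("node strengths: chain, diagonal exclusion, brute-force oracle", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 2
  expect_equal(node_strengths(connectome(W, "SC")), c(1, 3, 2),
               ignore_attr = TRUE)
  fc <- connectome(random_fc_values(6, 1), "FC")
  expect_equal(node_strengths(fc),
               rowSums(fc$values) - diag(fc$values), ignore_attr = TRUE)
  m <- random_sc(30, 2)$values
  oracle <- numeric(30)
  for (i in 1:30) for (j in 1:30) if (i != j) oracle[i] <- oracle[i] + m[i, j]
  expect_equal(node_strengths(m), oracle, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("weighted clustering: clique, star, exhaustive triangle oracle", {
  clique <- matrix(1, 4, 4); diag(clique) <- 0
  expect_equal(weighted_clustering(clique), rep(1, 4))
  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(weighted_clustering(star), rep(0, 5))
  # sparse weighted graph vs O(n^3) brute force (Onnela geometric mean)
  set.seed(3)
  W <- random_sc(20, 3)$values
  W[W < 0.7] <- 0
  w_hat <- W / max(W)
  oracle <- numeric(20)
  for (i in 1:20) {
    acc <- 0
    for (j in 1:20) for (h in 1:20) {
      if (j != i && h != i && j != h)
        acc <- acc + (w_hat[i, j] * w_hat[i, h] * w_hat[j, h])^(1 / 3)
    }
    k <- sum(W[i, ] > 0)
    oracle[i] <- if (k >= 2) acc / (k * (k - 1)) else 0
  }
  expect_equal(weighted_clustering(W), oracle, tolerance = 1e-12)
})

test_that("PageRank: ring symmetry, normalization, direct-solve oracle", {
  ring <- matrix(0, 8, 8)
  for (i in 1:8) { j <- i %% 8 + 1; ring[i, j] <- ring[j, i] <- 1 }
  expect_equal(pagerank_centrality(ring), rep(1 / 8, 8), tolerance = 1e-9)
  W <- random_sc(10, 4)$values
  pr <- pagerank_centrality(W, damping = 0.9)
  expect_equal(sum(pr), 1, tolerance = 1e-9)
  # dense linear-system solution (I - d P) p = (1 - d)/n
  P <- sweep(W, 2, colSums(W), "/")
  p_direct <- solve(diag(10) - 0.9 * P, rep(0.1 / 10, 10))
  p_direct <- p_direct / sum(p_direct)
  expect_equal(pr, unname(p_direct), tolerance = 1e-8)
})

test_that("PageRank agrees with igraph on a positive weighted graph", {
  skip_if_not_installed("igraph")
  W <- random_sc(12, 7)$values
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  ig <- igraph::page_rank(g, damping = 0.9)$vector
  expect_equal(unname(pagerank_centrality(W)), unname(ig),
               tolerance = 1e-6)
})

test_that("Louvain: disconnected cliques, planted blocks, determinism", {
  W <- matrix(0, 10, 10)
  W[1:5, 1:5] <- 1; W[6:10, 6:10] <- 1; diag(W) <- 0
  part <- louvain_partition(connectome(W, "SC"), seed = 1)
  expect_equal(max(part), 2)
  expect_equal(relative_mutual_information(part, rep(1:2, each = 5)), 1)
  # planted 3-block SBM with strong contrast
  sc <- generate_sc(synth_spec(n_regions = 30, n_modules = 3,
                               density = 0.5, intra_module_boost = 10,
                               weight_log_sigma = 0.5, seed = 2))
  p3 <- louvain_partition(sc, seed = 1)
  expect_gt(relative_mutual_information(p3, sc$meta$modules), 0.9)
  expect_identical(louvain_partition(sc, seed = 9),
                   louvain_partition(sc, seed = 9))
})

test_that("signed Louvain separates anticorrelated groups", {
  # two groups, positive within, negative between
  W <- matrix(-0.5, 8, 8)
  W[1:4, 1:4] <- 0.8; W[5:8, 5:8] <- 0.8
  diag(W) <- 1
  part <- louvain_partition(connectome(W, "FC"), seed = 0)
  expect_equal(relative_mutual_information(part, rep(1:2, each = 4)), 1)
})

test_that("RMI: identity, label permutation, independence, edge cases", {
  p <- rep(1:4, times = 5)
  expect_equal(relative_mutual_information(p, p), 1)
  relab <- c(4, 1, 3, 2)[p]
  expect_equal(relative_mutual_information(p, relab), 1)
  expect_identical(relative_mutual_information(p, relab),
                   relative_mutual_information(relab, p))
  set.seed(5)
  a <- sample(1:4, 1e4, replace = TRUE)
  b <- sample(1:4, 1e4, replace = TRUE)
  expect_lt(relative_mutual_information(a, b), 0.01)
  expect_equal(relative_mutual_information(rep(1, 6), rep(2, 6)), 1)
  expect_equal(relative_mutual_information(rep(1, 6), rep(1:2, 3)), 0)
})

test_that("RMI chance level calibrates an independence test", {
  expect_equal(rmi_chance_level(rep(1:2, 10), rep(7, 20), n_perm = 100), 0)
  p1 <- rep(1:4, times = 10)
  p2 <- rep(1:4, each = 10)
  expect_identical(rmi_chance_level(p1, p2, n_perm = 200, seed = 3),
                   rmi_chance_level(p1, p2, n_perm = 200, seed = 3))
  # independent labelings fall below chance level in most trials
  set.seed(11)
  hits <- mean(vapply(1:20, function(k) {
    a <- sample(1:3, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    relative_mutual_information(a, b) <=
      rmi_chance_level(a, b, n_perm = 200, seed = k)
  }, logical(1)))
  expect_gte(hits, 0.95)
  expect_error(rmi_chance_level(p1, p2, n_perm = 50), "100")
})

test_that("delta coefficients: exact arithmetic and loop oracle", {
  expect_equal(delta_trivial(0.30, 0.30), 0)
  expect_equal(delta_trivial(0.36, 0.30), 20)
  expect_equal(delta_trivial(0.24, 0.30), -20)
  expect_error(delta_trivial(0.3, 0), "nonzero")
  m <- matrix(0.50, 4, 4); diag(m) <- 0.61
  expect_equal(delta_pers(m), 100 * (0.61 - 0.50) / 0.50)
  expect_equal(delta_pers(matrix(0.4, 3, 3)), 0)
  set.seed(6)
  r <- matrix(runif(64, 0.1, 0.9), 8, 8)
  pers <- mean(diag(r))
  gen_sum <- 0; k <- 0
  for (i in 1:8) for (j in 1:8) if (i != j) { gen_sum <- gen_sum + r[i, j]; k <- k + 1 }
  expect_equal(delta_pers(r), 100 * (pers - gen_sum / k) / (gen_sum / k),
               tolerance = 1e-9)
})

test_that("IQR-restricted correlation masks extreme-x outliers", {
  x <- 1:20; y <- 2 * (1:20) + 3
  expect_equal(iqr_restricted_correlation(x, y), 1)
  # linear core plus flipped-y outliers at extreme x
  x2 <- c(1:20, 100, 110); y2 <- c(1:20, -100, -110)
  expect_gt(iqr_restricted_correlation(x2, y2), cor(x2, y2))
  # explicit masking oracle
  set.seed(7)
  xr <- rnorm(50); yr <- xr + rnorm(50)
  q <- quantile(xr, c(0.25, 0.75))
  keep <- xr >= q[1] & xr <= q[2]
  expect_equal(iqr_restricted_correlation(xr, yr),
               cor(xr[keep], yr[keep]), tolerance = 1e-12)
  expect_error(iqr_restricted_correlation(1:5, 1:5), "8")
})

test_that("inter-subject distance correspondence: identity, oracle, null", {
  subj <- lapply(1:4, function(s) random_sc(10, 50 + s))
  expect_equal(intersubject_distance_correspondence(subj, subj), 1)
  # hand-assembled oracle on 4 subjects
  other <- lapply(1:4, function(s) random_sc(10, 90 + s))
  d_a <- c(); d_b <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    d_a <- c(d_a, 1 - fit_correlation(subj[[i]], subj[[j]]))
    d_b <- c(d_b, 1 - fit_correlation(other[[i]], other[[j]]))
  }
  expect_equal(intersubject_distance_correspondence(subj, other),
               cor(d_a, d_b), tolerance = 1e-12)
  # unrelated sets show weak correspondence
  rs <- vapply(1:10, function(seed) {
    a <- lapply(1:10, function(s) random_sc(12, 1000 * seed + s))
    b <- lapply(1:10, function(s) random_sc(12, 5000 * seed + s))
    intersubject_distance_correspondence(a, b)
  }, numeric(1))
  expect_lt(median(abs(rs)), 0.3)
})
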