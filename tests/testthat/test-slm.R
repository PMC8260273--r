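test_that("critical coupling: normalized SC gives 1, matches eigen oracle", {
  sc <- connectome(matrix(c(0, 0.5, 0.5, 0), 2), kind = "SC")
  expect_equal(critical_coupling(sc), 2.0)
  for (seed in 1:3) {
    s <- random_sc(12, seed)
    lam <- max(eigen(s$values, symmetric = TRUE, only.values = TRUE)$values)
    expect_equal(critical_coupling(s), 1 / lam, tolerance = 1e-10)
    expect_equal(critical_coupling(spectral_normalize(s)), 1.0,
                 tolerance = 1e-9)
  }
})

test_that("analytic covariance: uncoupled limit and 2-node closed form", {
  sc <- random_sc(5, 1, normalize = TRUE)
  C0 <- analytic_covariance(sc, slm_params(G = 0))$values
  expect_equal(C0, diag(5) / 2, ignore_attr = TRUE)
  # symbolic 2x2: A = -I + GW, W = [[0,w],[w,0]]
  w <- 0.4; G <- 0.9; sig <- 1.3
  sc2 <- connectome(matrix(c(0, w, w, 0), 2), kind = "SC")
  C2 <- analytic_covariance(sc2, slm_params(G = G, sigma = sig))$values
  det_a <- 1 - G^2 * w^2
  C_hand <- (sig^2 / 2) / det_a * matrix(c(1, G * w, G * w, 1), 2)
  expect_equal(C2, C_hand, tolerance = 1e-12, ignore_attr = TRUE)
  # supercritical coupling is refused
  expect_error(analytic_covariance(sc, slm_params(G = 1.0)), "supercritical")
})

test_that("simulated covariance agrees with the analytic form", {
  sc <- random_sc(8, 2, normalize = TRUE)
  p <- slm_params(G = 0.7)
  C <- analytic_covariance(sc, p)$values
  ts <- simulate_slm(sc, p, T_steps = 2e5, dt = 0.01, seed = 3)
  Cs <- cov(ts$samples)
  # batch-means Monte-Carlo standard error per entry
  nb <- 20
  idx <- cut(seq_len(nrow(ts$samples)), nb, labels = FALSE)
  batches <- vapply(seq_len(nb),
                    function(b) cov(ts$samples[idx == b, ]),
                    matrix(0, 8, 8))
  se <- apply(batches, c(1, 2), sd) / sqrt(nb)
  expect_true(all(abs(Cs - C) < 3 * se + 1e-12))
  expect_gt(cor(upper_tri(Cs), upper_tri(C)), 0.9)
})

test_that("simulate_slm: determinism, uncoupled decorrelation, dt guard", {
  sc <- random_sc(6, 4, normalize = TRUE)
  p <- slm_params(G = 0.3)
  a <- simulate_slm(sc, p, T_steps = 500, seed = 7)
  b <- simulate_slm(sc, p, T_steps = 500, seed = 7)
  expect_identical(a$samples, b$samples)
  ts0 <- simulate_slm(sc, slm_params(G = 0), T_steps = 1e6, seed = 8)
  expect_lt(max(abs(upper_tri(cor(ts0$samples)))), 0.05)
  expect_error(simulate_slm(sc, p, T_steps = 10, dt = 3), "unstable dt")
})

test_that("linear SC-to-FC: uncoupled identity and sigma invariance", {
  sc <- random_sc(10, 5, normalize = TRUE)
  fc0 <- linear_sc_to_fc(sc, slm_params(G = 0))
  expect_equal(fc0$values, diag(10), ignore_attr = TRUE)
  f1 <- linear_sc_to_fc(sc, slm_params(sigma = 1))
  f5 <- linear_sc_to_fc(sc, slm_params(sigma = 5))
  expect_lt(max(abs(f1$values - f5$values)), 1e-12)
  expect_identical(f1$provenance, "virtual_slm")
  expect_true(all(abs(f1$values) <= 1))
  expect_equal(unname(diag(f1$values)), rep(1, 10))
})

test_that("linear round trip recovers W up to positive scale", {
  for (seed in 1:3) {
    sc <- random_sc(9, seed + 20, normalize = TRUE)
    p <- slm_params(G = 0.83)
    cov_obj <- analytic_covariance(sc, p)
    w_raw <- linear_fc_to_sc(cov_obj, p, clip_negative = FALSE)
    expect_gt(fit_correlation(w_raw$values, sc$values), 1 - 1e-10)
    # raw off-diagonal is exactly proportional to W: (2G/sigma^2 Gref) W
    off <- upper.tri(sc$values)
    ratio <- w_raw$values[off][sc$values[off] != 0] /
      sc$values[off][sc$values[off] != 0]
    expect_lt(diff(range(ratio)), 1e-8)
  }
})

test_that("linear FC-to-SC: zero diagonal, symmetry, clipping policy", {
  sc <- random_sc(8, 31, normalize = TRUE)
  fc <- linear_sc_to_fc(sc)
  w <- linear_fc_to_sc(fc)
  expect_equal(unname(diag(w$values)), rep(0, 8))
  expect_equal(w$values, t(w$values))
  expect_true(all(w$values >= 0))
  w_raw <- linear_fc_to_sc(fc, clip_negative = FALSE)
  expect_equal(unname(diag(w_raw$values)), rep(0, 8))
  # clipped version equals raw with negatives zeroed
  expect_equal(w$values, pmax(w_raw$values, 0), ignore_attr = TRUE)
  # FC input treated as unit-variance covariance: accepts bold input too
  set.seed(1)
  ts <- bold_ts(matrix(rnorm(50 * 8), 50, 8), 1)
  expect_s3_class(linear_fc_to_sc(ts), "connectome")
  short <- bold_ts(matrix(rnorm(5 * 8), 5, 8), 1)
  expect_error(linear_fc_to_sc(short), "timepoints")
})

test_that("best linear fit occurs near the generating coupling", {
  # scan property: FC_SLM(G) fits an SLM ground truth best at G ~ G_true
  sc <- random_sc(12, 41, normalize = TRUE)
  g_true <- 0.7
  fc_true <- linear_sc_to_fc(sc, slm_params(G = g_true))
  gs <- seq(0.1, 0.95, by = 0.05)
  fits <- vapply(gs, function(g)
    fit_correlation(linear_sc_to_fc(sc, slm_params(G = g)), fc_true),
    numeric(1))
  expect_equal(gs[which.max(fits)], g_true, tolerance = 0.051)
})
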