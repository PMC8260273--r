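# Shared fixtures: everything is generated in code, no stored data.

upper_tri <- function(m) m[upper.tri(m, diag = FALSE)]

# small random symmetric nonnegative SC with zero diagonal
random_sc <- function(n, seed, normalize = FALSE) {
  set.seed(seed)
  W <- matrix(stats::runif(n * n), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  sc <- connectome(W, kind = "SC")
  if (normalize) spectral_normalize(sc) else sc
}

# random symmetric matrix with unit diagonal (valid FC-shaped values)
random_fc_values <- function(n, seed) {
  set.seed(seed)
  W <- matrix(stats::runif(n * n, -1, 1), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 1
  W
}

# multivariate Gaussian draws with covariance S (via Cholesky)
gaussian_bold <- function(n_samples, S, seed, dt = 1) {
  set.seed(seed)
  L <- chol(S)
  x <- matrix(stats::rnorm(n_samples * nrow(S)), n_samples) %*% L
  bold_ts(x, dt)
}

# fast MFM parameter set for tests (short runs, working point fixed)
test_mfm <- function(T_ms = 8e4, G = 1.5, tau = 25) {
  mfm_params(G = G, tau_s_ms = tau, T_ms = T_ms)
}
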