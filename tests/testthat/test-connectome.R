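test_that("connectome constructor enforces kind-specific invariants", {
  expect_error(connectome(matrix(1, 3, 4)), "square")
  expect_error(connectome(matrix(c(0, 1, 2, 0), 2), kind = "SC"),
               "asymmetry")
  expect_error(connectome(matrix(c(0, -1, -1, 0), 2), kind = "SC"),
               "nonnegative")
  expect_error(connectome(matrix(c(1, 2, 2, 1), 2), kind = "FC"),
               "\\[-1, 1\\]")
  m <- connectome(matrix(c(5, 1, 1, 7), 2), kind = "SC")
  expect_equal(diag(m$values), c(R000 = 0, R001 = 0))  # diagonal forced
  f <- connectome(matrix(c(0.2, 0.5, 0.5, 0.9), 2), kind = "FC")
  expect_equal(unname(diag(f$values)), c(1, 1))
})

test_that("read/write round trip is lossless and keeps sidecar metadata", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sc.tsv")
  for (seed in 1:3) {
    sc <- random_sc(7, seed)
    sc$meta <- list(method = "unit-test", seed = seed)
    sc$provenance <- "virtual_mfm"
    write_matrix(sc, path)
    back <- read_matrix(path, "SC")
    expect_lt(max(abs(back$values - sc$values)), 1e-12)
    expect_identical(back$region_labels, sc$region_labels)
    expect_identical(back$provenance, "virtual_mfm")
    expect_equal(back$meta$seed, seed)
    expect_equal(back$meta$method, "unit-test")
  }
  # headerless whitespace matrices are accepted with default labels
  plain <- file.path(dir, "plain.txt")
  writeLines(c("0 0 0", "0 0 0", "0 0 0"), plain)
  z <- read_matrix(plain, "SC")
  expect_identical(z$region_labels, c("R000", "R001", "R002"))
  expect_true(all(z$values == 0))
})

test_that("timeseries round trip preserves samples and dt", {
  dir <- withr::local_tempdir()
  set.seed(4)
  ts <- bold_ts(matrix(rnorm(60), 20, 3), 2.0)
  p <- file.path(dir, "bold.tsv")
  write_timeseries(ts, p)
  back <- read_timeseries(p)
  expect_lt(max(abs(back$samples - ts$samples)), 1e-12)
  expect_equal(back$dt_seconds, 2.0)
})

test_that("pearson_fc: exact limits and large-sample null", {
  set.seed(1)
  x <- rnorm(100)
  ts <- bold_ts(cbind(x, x), 1)
  expect_equal(pearson_fc(ts)$values[1, 2], 1.0)
  ts2 <- bold_ts(cbind(x, -x), 1)
  expect_equal(pearson_fc(ts2)$values[1, 2], -1.0)
  # independent channels decorrelate at large samples
  set.seed(2)
  tsw <- bold_ts(matrix(rnorm(4e5), 1e5, 4), 1)
  fc <- pearson_fc(tsw)
  expect_lt(max(abs(upper_tri(fc$values))), 0.05)
  # zero-variance region is reported by index
  bad <- bold_ts(cbind(rnorm(10), rep(1, 10)), 1)
  expect_error(pearson_fc(bad), "2")
})

test_that("pearson_fc output satisfies FC invariants on random inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    fc <- pearson_fc(bold_ts(matrix(rnorm(200), 20), 1))
    expect_true(all(abs(fc$values) <= 1))
    expect_equal(unname(diag(fc$values)), rep(1, 10))
    expect_equal(fc$values, t(fc$values))
  }
})

test_that("spectral_normalize: exact 2x2, idempotence, scale equivariance", {
  sc <- connectome(matrix(c(0, 2, 2, 0), 2), kind = "SC")
  nm <- spectral_normalize(sc)
  expect_equal(nm$values, matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)
  for (seed in 1:3) {
    s <- random_sc(10, seed)
    n1 <- spectral_normalize(s)
    expect_lt(abs(max(eigen(n1$values, symmetric = TRUE,
                            only.values = TRUE)$values) - 1), 1e-9)
    expect_lt(max(abs(spectral_normalize(n1)$values - n1$values)), 1e-12)
    s3 <- s
    s3$values <- 3.7 * s$values
    expect_lt(max(abs(spectral_normalize(s3)$values - n1$values)), 1e-12)
  }
  zero <- connectome(matrix(0, 3, 3), kind = "SC")
  expect_error(spectral_normalize(zero), "eigenvalue")
})

test_that("fit_correlation matches enumeration oracle and its invariances", {
  a <- random_sc(20, 11)
  b <- random_sc(20, 12)
  # explicit pair-enumeration oracle
  va <- c(); vb <- c()
  for (i in 1:19) for (j in (i + 1):20) {
    va <- c(va, a$values[i, j]); vb <- c(vb, b$values[i, j])
  }
  expect_equal(fit_correlation(a, b), cor(va, vb), tolerance = 1e-12)
  expect_identical(fit_correlation(a, b), fit_correlation(b, a))
  expect_equal(fit_correlation(a, a), 1.0)
  neg <- a; neg$values <- -a$values
  expect_equal(fit_correlation(a$values, neg$values), -1.0)
  # diagonal does not matter
  ad <- a$values; diag(ad) <- 99
  expect_equal(fit_correlation(ad, b$values), fit_correlation(a, b))
  expect_error(fit_correlation(a, random_sc(10, 1)), "mismatch")
})
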