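# Transfer entropy: binning, plug-in estimator, lag scan, surrogates,
# multivariate conditioning, pair identification.

test_that("spike-train binning is binary occupancy", {
  b <- bin_spike_train(c(0.5, 1.5), 1, 5)
  expect_equal(b$bins, c(1L, 1L, 0L, 0L, 0L))
  expect_equal(bin_spike_train(numeric(0), 1, 4)$bins, rep(0L, 4))
  expect_equal(bin_spike_train(c(2.1, 2.9), 1, 4)$bins, c(0L, 0L, 1L, 0L))
  expect_error(bin_spike_train(c(-1, 2), 1, 4), "outside")
  expect_error(bin_spike_train(c(1, 5), 1, 4), "outside")
})

test_that("plug-in TE matches theory on copy and independent processes", {
  set.seed(10)
  n <- 1e4
  y <- rbinom(n, 1, 0.1)
  x <- c(0L, y[-n])                      # x_t = y_{t-1}
  h01 <- -(0.1 * log2(0.1) + 0.9 * log2(0.9))
  expect_equal(bivariate_te(x, y, k = 1, delta = 1), h01, tolerance = 0.05)
  x2 <- rbinom(n, 1, 0.1)
  expect_lt(bivariate_te(x2, y, k = 1, delta = 1), 0.01)
  expect_equal(bivariate_te(x2, rep(0L, n)), 0)   # degenerate source
  expect_error(bivariate_te(c(0L, 1L), c(1L, 0L), k = 3, delta = 1), "short")
})

test_that("TE equals an independent enumeration oracle on random fixtures", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(60:200, 1)
    x <- rbinom(n, 1, runif(1, 0.05, 0.5))
    y <- rbinom(n, 1, runif(1, 0.05, 0.5))
    k <- sample(1:3, 1); delta <- sample(1:4, 1)
    expect_equal(bivariate_te(x, y, k, delta), oracle_te(x, y, k, delta),
                 tolerance = 1e-12)
  }
})

test_that("TE is non-negative on arbitrary inputs", {
  set.seed(12)
  for (i in 1:50) {
    n <- sample(30:100, 1)
    expect_gte(bivariate_te(rbinom(n, 1, 0.3), rbinom(n, 1, 0.3),
                            sample(1:4, 1), sample(1:5, 1)), 0)
  }
})

test_that("lag scan recovers the generative delay with the smallest-lag tie rule", {
  set.seed(13)
  n <- 1e4
  y <- rbinom(n, 1, 0.1)
  x <- c(rep(0L, 4), y[1:(n - 4)])       # copy at lag 4
  sc <- scan_lags(x, y, tau_source = 10, k_grid = 1:5)
  expect_equal(sc$delta_star, 4)
  # all-zero source: every (delta, k) ties at TE = 0 -> smallest kept
  sc0 <- scan_lags(x, rep(0L, n), tau_source = 10, k_grid = 1:5)
  expect_equal(sc0$delta_star, 1)
  expect_equal(sc0$k_star, 1)
})

test_that("permutation test is exact at the extremes and calibrated under the null", {
  set.seed(14)
  n <- 5000
  y <- rbinom(n, 1, 0.1)
  x <- c(rep(0L, 4), y[1:(n - 4)])
  te <- bivariate_te(x, y, 1, 4)
  p <- permutation_test(te, x, y, k = 1, delta = 4, n_perm = 200)
  expect_equal(p, 1 / 201)
  p0 <- permutation_test(0, x, rep(0L, n), k = 1, delta = 1, n_perm = 50)
  expect_equal(p0, 1)
  # null calibration of the scanning test at reduced scale (the acceptance
  # suite runs the full 400-pair version)
  rej <- replicate(80, {
    a <- bin_spike_train(sort(runif(150, 0, 3000)), 1, 3000)
    b <- bin_spike_train(sort(runif(150, 0, 3000)), 1, 3000)
    te_test(a, b, te_config(n_perm = 100))$p_value <= 0.05
  })
  expect_lt(mean(rej), 0.12)
})

test_that("multivariate TE reduces to bivariate and separates chains", {
  set.seed(15)
  for (i in 1:50) {
    n <- sample(80:150, 1)
    x <- rbinom(n, 1, 0.3); y <- rbinom(n, 1, 0.3)
    k <- sample(1:2, 1); d <- sample(1:3, 1)
    expect_identical(multivariate_te(x, y, list(), k, d), bivariate_te(x, y, k, d))
  }
  # chain Y -> Z -> X: conditioning on Z removes the indirect flow
  n <- 2e4
  y <- rbinom(n, 1, 0.2)
  z <- c(0L, y[-n])
  x <- c(0L, z[-n])
  te_raw <- bivariate_te(x, y, k = 1, delta = 2)
  te_cond <- multivariate_te(x, y, list(z), k = 1, delta = 2)
  expect_lt(te_cond, te_raw)
  # conditioning on an all-zero series changes nothing
  expect_equal(multivariate_te(x, y, list(rep(0L, n)), 1, 2),
               bivariate_te(x, y, 1, 2), tolerance = 1e-12)
  expect_equal(oracle_te(x, y, 1, 2, cond = list(z)), te_cond, tolerance = 1e-12)
})

test_that("pair identification finds a planted coupling among independent units", {
  set.seed(16)
  dur <- 1e4
  mk <- function() bin_spike_train(sort(runif(rpois(1, dur * 0.02), 0, dur)), 1, dur)
  trains <- list(a = mk(), b = mk(), c = mk(), d = mk())
  # plant b -> d at lag 4 ms
  src <- sort(runif(600, 0, dur - 20))
  copied <- src + 4 + runif(600, 0, 0.4)
  trains$b <- bin_spike_train(src, 1, dur)
  trains$d <- bin_spike_train(sort(c(copied, runif(80, 0, dur))), 1, dur)
  # n_perm must exceed n_pairs/alpha for BH to be able to reject at all
  # (the permutation p cannot fall below 1/(n_perm + 1))
  res <- identify_pairs(trains, te_config(n_perm = 400))
  hit <- res[res$source == "b" & res$target == "d", ]
  expect_equal(nrow(hit), 1)
  expect_true(hit$significant)
  expect_equal(hit$lag_ms, 4)
  # no significant backward direction
  back <- res[res$source == "d" & res$target == "b", ]
  expect_true(nrow(back) == 0 || !back$significant)
})

test_that("identify_pairs returns an empty frame for independent ensembles", {
  set.seed(17)
  dur <- 5e3
  trains <- lapply(1:3, function(i)
    bin_spike_train(sort(runif(100, 0, dur)), 1, dur))
  names(trains) <- c("u1", "u2", "u3")
  res <- identify_pairs(trains, te_config(n_perm = 100))
  expect_true(is.data.frame(res))
  expect_true(all(c("source", "target", "te_bits", "lag_ms", "p", "p_bh",
                    "significant") %in% names(res)))
})
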