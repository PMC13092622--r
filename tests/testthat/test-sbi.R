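# Prior sampling, the mixture density network, posterior access, MAP.

test_that("prior sampling is uniform over the box and seed-reproducible", {
  set.seed(31)
  th <- sample_prior(1e4)
  box <- prior_box()
  for (i in 1:9) {
    expect_gte(min(th[, i]), box$lower[i])
    expect_lte(max(th[, i]), box$upper[i])
    mid <- (box$lower[i] + box$upper[i]) / 2
    se <- (box$upper[i] - box$lower[i]) / sqrt(12) / sqrt(nrow(th))
    expect_lt(abs(mean(th[, i]) - mid), 3.5 * se)
  }
  set.seed(99); a <- sample_prior(10)
  set.seed(99); b <- sample_prior(10)
  expect_identical(a, b)
})

test_that("MDN gradients match finite differences", {
  set.seed(32)
  net <- neuropair:::mdn_init(3, 2, n_comp = 4, n_hidden = 8)
  X <- matrix(rnorm(18), 6, 3); Y <- matrix(rnorm(12), 6, 2)
  lg <- neuropair:::mdn_loss_grad(net, X, Y)
  eps <- 1e-6
  for (nm in c("W1", "W2", "W3", "b1", "b3")) {
    w <- net[[nm]]
    pick <- if (is.matrix(w)) cbind(sample(nrow(w), 4, TRUE), sample(ncol(w), 4, TRUE)) else cbind(sample(length(w), 4, TRUE))
    for (r in seq_len(nrow(pick))) {
      n2 <- net
      if (is.matrix(w)) n2[[nm]][pick[r, 1], pick[r, 2]] <- w[pick[r, 1], pick[r, 2]] + eps
      else n2[[nm]][pick[r, 1]] <- w[pick[r, 1]] + eps
      num <- (neuropair:::mdn_loss_grad(n2, X, Y)$loss - lg$loss) / eps
      ana <- if (is.matrix(w)) lg$grads[[nm]][pick[r, 1], pick[r, 2]] else lg$grads[[nm]][pick[r, 1]]
      expect_equal(num, ana, tolerance = 1e-4)
    }
  }
})

test_that("training-set construction filters uncoupled draws and is deterministic", {
  # prior squashed to zero synaptic weights: every pair is uncoupled, so the
  # TE filter should reject (almost) everything
  box0 <- prior_box()
  box0$upper[box0$name %in% c("mu_ampa", "sigma_ampa", "mu_nmda", "sigma_nmda")] <- 1e-12
  expect_error(build_training_set(10, duration = 3000, seed = 41, prior = box0,
                                  config = te_config(n_perm = 100)),
               "empty training set")
  ts1 <- build_training_set(6, duration = 3000, seed = 42,
                            config = te_config(n_perm = 100))
  ts2 <- build_training_set(6, duration = 3000, seed = 42,
                            config = te_config(n_perm = 100))
  expect_identical(ts1$theta, ts2$theta)
  expect_identical(ts1$stats, ts2$stats)
  expect_lte(ts1$n_valid, ts1$n_attempted)
})

test_that("posterior sampling respects the prior box and is amortized", {
  set.seed(33)
  # synthetic training table (no simulator): theta ~ prior, x = cheap stats
  th <- sample_prior(1500)
  x <- cbind(th[, "lambda_pre"] * 0.6 + rnorm(1500, 0, 2),
             th[, "lambda_post"] * 0.6 + rnorm(1500, 0, 2),
             0.4 * sqrt(th[, "d_pre"]) + rnorm(1500, 0, 0.02),
             0.4 * sqrt(th[, "d_post"]) + rnorm(1500, 0, 0.02),
             pmin(1, th[, "mu_ampa"] / 0.002 + rnorm(1500, 0, 0.05)),
             4 + rnorm(1500, 0, 0.5))
  colnames(x) <- summary_stat_names()
  pm <- train_posterior(list(theta = th, stats = x), max_epochs = 60, seed = 2)
  post <- posterior_for_observation(pm, x[7, ])
  s <- post$sample(2000)
  box <- prior_box()
  for (i in 1:9) {
    expect_gte(min(s[, i]), box$lower[i])
    expect_lte(max(s[, i]), box$upper[i])
  }
  expect_gt(attr(s, "acceptance"), 0)
  # same observation twice: identical density evaluations (amortized)
  post2 <- posterior_for_observation(pm, x[7, ])
  probe <- sample_prior(20)
  expect_identical(post$log_density(probe), post2$log_density(probe))
  # posterior contraction relative to the prior for an informative parameter
  expect_lt(sd(s[, "d_pre"]), (box$upper[1] - box$lower[1]) / sqrt(12))
})

test_that("MAP ascent never falls below its best initializing sample", {
  set.seed(34)
  th <- sample_prior(1200)
  x <- cbind(th[, "lambda_pre"], th[, "lambda_post"],
             sqrt(th[, "d_pre"]), sqrt(th[, "d_post"]),
             th[, "mu_ampa"] * 500, rep(4, 1200))
  colnames(x) <- summary_stat_names()
  pm <- train_posterior(list(theta = th, stats = x), max_epochs = 50, seed = 3)
  post <- posterior_for_observation(pm, x[11, ])
  set.seed(8)
  s <- post$sample(3000)
  # the ascent works in the unconstrained parameterization; its reported
  # density must dominate every initializing sample in that same space
  Y <- neuropair:::zapply(pm$zt, neuropair:::theta_to_u(s))
  best_sample <- max(neuropair:::mdn_logdens_at(
    pm$net, neuropair:::zapply(pm$zx,
      matrix(neuropair:::stat_transform(unlist(x[11, ]), pm$transform),
             nrow = 1))[1, ], Y))
  set.seed(8)
  mp <- map_estimate(pm, x[11, ], n_samples = 3000, n_top = 50)
  expect_gte(mp$log_density, best_sample - 1e-9)
  box <- prior_box()
  expect_true(all(mp$theta_star >= box$lower & mp$theta_star <= box$upper))
  expect_named(mp$theta_star, box$name)
})
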