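# Synthetic generators: coupled point processes, prior populations,
# condition shifts.

test_that("coupled point processes obey their generative contract", {
  # full transmission, no jitter, no baseline: p_syn = 1 at the exact lag
  cp <- generate_coupled_point_process(
    coupling_spec(rate_pre = 5, rate_post_baseline = 0, p_transmit = 1,
                  jitter_sd = 0, lag = 4, duration = 60000, seed = 2))
  expect_equal(postsynaptic_spike_probability(cp$pre, cp$post, 4, 1), 1)
  expect_true(all(diff(cp$pre) >= 1))   # merge refractory
  expect_true(all(cp$post >= 0 & cp$post < 60000))
  # determinism
  cp2 <- generate_coupled_point_process(
    coupling_spec(rate_pre = 5, rate_post_baseline = 0, p_transmit = 1,
                  jitter_sd = 0, lag = 4, duration = 60000, seed = 2))
  expect_identical(cp, cp2)
})

test_that("uncoupled point processes rarely pass the TE pipeline", {
  set.seed(61)
  hits <- 0
  for (i in 1:12) {
    cp <- generate_coupled_point_process(
      coupling_spec(rate_pre = 6, rate_post_baseline = 6, p_transmit = 0,
                    duration = 60000, seed = 100 + i))
    bt <- bin_spike_train(cp$pre, 1, cp$duration)
    bp <- bin_spike_train(cp$post, 1, cp$duration)
    r <- te_test(bp, bt, te_config(n_perm = 100))
    hits <- hits + r$significant
  }
  expect_lte(hits, 2)   # ~ alpha with wide margin at n = 12
})

test_that("generative lag and transmission probability are recovered", {
  for (lag in c(2, 4, 8)) {
    for (p in c(0.1, 0.3, 0.5)) {
      cp <- generate_coupled_point_process(
        coupling_spec(rate_pre = 5, rate_post_baseline = 2, p_transmit = p,
                      lag = lag, jitter_sd = 0.3, duration = 240000,
                      seed = 1000 + lag * 10 + p * 100))
      bt <- bin_spike_train(cp$pre, 1, cp$duration)
      bp <- bin_spike_train(cp$post, 1, cp$duration)
      set.seed(3)
      sc <- scan_lags(bp, bt, 10, 1:5)
      expect_equal(sc$delta_star, lag, info = sprintf("lag=%d p=%.1f", lag, p))
      psyn <- postsynaptic_spike_probability(cp$pre, cp$post, sc$delta_star, 1)
      # baseline coincidences push the estimate slightly above p_transmit
      expect_lt(abs(psyn - p), 0.05 + 0.02)
    }
  }
})

test_that("populations report attrition and reproduce under a fixed seed", {
  pop <- generate_population(6, duration = 3000, seed = 71,
                             config = te_config(n_perm = 100))
  expect_equal(nrow(pop$theta), 6)
  expect_equal(length(pop$valid), 6)
  expect_true(all(pop$p_syn_keep[pop$p_syn_keep] &
                    pop$stats[pop$p_syn_keep, "p_syn"] > 0.05))
  pop2 <- generate_population(6, duration = 3000, seed = 71,
                              config = te_config(n_perm = 100))
  expect_identical(pop$stats, pop2$stats)
  expect_identical(pop$valid, pop2$valid)
})

test_that("condition shifts respect the box and move p_syn in the right direction", {
  base <- pair_parameters(d_pre = 1, d_post = 4.8, mu_ampa = 3e-4,
                          sigma_ampa = 2e-4, mu_nmda = 2e-5, sigma_nmda = 1e-5,
                          lambda_pre = 20, lambda_post = 20, z_syn = 1500)
  expect_error(generate_condition_shift(4, base, c(mu_ampa = 10),
                                        duration = 1000, seed = 1),
               "leaves the prior box")
  expect_error(generate_condition_shift(4, base, c(nonsense = 1.5),
                                        duration = 1000, seed = 1),
               "unknown parameter")
  cs <- generate_condition_shift(8, base, c(mu_ampa = 1.5), duration = 4000,
                                 seed = 72, config = te_config(n_perm = 100))
  expect_true(all(cs$after$theta[, "mu_ampa"] ==
                    cs$before$theta[, "mu_ampa"] * 1.5))
  expect_gt(median(cs$after$stats[, "p_syn"], na.rm = TRUE),
            median(cs$before$stats[, "p_syn"], na.rm = TRUE))
  # zero shift with identical seeds reproduces "before" exactly
  cs0 <- generate_condition_shift(4, base, c(mu_ampa = 1), duration = 2000,
                                  seed = 73, config = te_config(n_perm = 100))
  expect_identical(cs0$before$stats, cs0$after$stats)
})
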