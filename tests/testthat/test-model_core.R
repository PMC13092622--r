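# Membrane biophysics: gating rates, steady states, ionic currents,
# morphology, and the cable integrator.

test_that("gating rate functions hit their removable-singularity limits", {
  vt <- -30.4
  r <- gating_rates(vt + 13, vt)
  expect_equal(r$alpha_m, 0.32 * 4, tolerance = 1e-9)
  r <- gating_rates(vt + 40, vt)
  expect_equal(r$beta_m, 0.28 * 5, tolerance = 1e-9)
  expect_equal(r$beta_h, 2)
  r <- gating_rates(vt + 17, vt)
  expect_equal(r$alpha_h, 0.128)
  r <- gating_rates(vt + 15, vt)
  expect_equal(r$alpha_n, 0.032 * 5, tolerance = 1e-9)
  r <- gating_rates(vt + 10, vt)
  expect_equal(r$beta_n, 0.5)
  expect_error(gating_rates(NaN), "non-finite")
})

test_that("rate functions are finite and continuous across the singularities", {
  vt <- -30.4
  for (v0 in c(vt + 13, vt + 40, vt + 15)) {
    eps <- c(-1e-7, -1e-9, 0, 1e-9, 1e-7)
    r <- gating_rates(v0 + eps, vt)
    expect_true(all(is.finite(as.matrix(r))), info = paste("at", v0))
    # continuity: series evaluation within 1e-6 relative of nearby direct one
    ref <- gating_rates(v0 + 1e-4, vt)
    for (col in names(r)) {
      expect_lt(abs(r[[col]][3] - ref[[col]]) / ref[[col]], 5e-4)
    }
  }
})

test_that("steady states are probabilities and tau scales with temperature", {
  v <- seq(-100, 60, by = 2.5)
  it <- gating_inf_tau(v)
  expect_true(all(it$m_inf >= 0 & it$m_inf <= 1))
  expect_true(all(it$h_inf >= 0 & it$h_inf <= 1))
  expect_true(all(it$n_inf >= 0 & it$n_inf <= 1))
  expect_true(all(it[, c("tau_m", "tau_h", "tau_n")] > 0))
  hot <- gating_inf_tau(v, membrane_params(temperature = 47))
  expect_equal(hot$tau_m, it$tau_m / 3, tolerance = 1e-12)
  expect_equal(hot$m_inf, it$m_inf)
  expect_equal(temperature_factor(membrane_params()), 1)
})

test_that("ionic current densities respect driving-force zeros and summation", {
  p <- membrane_params()
  expect_equal(ionic_current_density(p$e_na, 0.5, 0.5, 0.5, p)$i_na, 0)
  ic <- ionic_current_density(-50, 0, 0, 0, p)
  expect_equal(ic$total, p$g_l * (-50 - p$e_l))
  expect_equal(ionic_current_density(p$e_l, 0, 0, 0, p)$total, 0)
  ic <- ionic_current_density(-20, 0.4, 0.3, 0.6, p)
  expect_equal(ic$total, ic$i_na + ic$i_k + ic$i_l)
})

test_that("pair morphologies follow the stated geometry", {
  m <- build_pair_morphologies(1.0, 0.2)
  expect_equal(nrow(m$pre), 101)
  expect_equal(m$pre$kind[1], "soma")
  expect_equal(m$pre$z_start[1], 0)
  expect_equal(m$pre$z_end[1], 10)
  expect_equal(m$pre$z_end[101], 2000, tolerance = 1e-9)
  expect_true(all(m$pre$length[-1] == 19.9))
  # contiguity
  expect_equal(m$pre$z_start[-1], m$pre$z_end[-101])
  expect_equal(m$post$z_start[1], 1000)
  expect_equal(m$post$z_end[1], 1010)
  expect_equal(m$post$z_end[101], 3000, tolerance = 1e-9)
  expect_error(build_pair_morphologies(6.0, 1), "0.2")
  expect_error(build_pair_morphologies(1, 0.1), "0.2")
})

test_that("passive cable keeps a uniform potential uniform and relaxes to E_L", {
  p <- membrane_params()
  res <- run_cable(rep(1, 20), rep(19.9, 20), p, dt = 0.1, duration = 30,
                   v0 = p$e_l + 20, active = FALSE)
  expect_lt(diff(range(res$v_final)), 1e-9)       # Laplacian of constant = 0
  expect_lt(abs(res$v_final[1] - p$e_l), 20 * exp(-30 / (p$c_m / (p$g_l * 1000))) + 0.01)
})

test_that("gating variables stay inside [0,1] on randomized active runs", {
  set.seed(42)
  for (rep in 1:3) {
    inj <- numeric(51)
    inj[sample(51, 3)] <- runif(3, 0, 0.3)
    res <- run_cable(c(10, rep(runif(1, 0.3, 4), 50)),
                     c(10, rep(19.9, 50)), dt = 0.1, duration = 1000,
                     i_inj = inj, record_segments = 1)
    for (g in c("m", "h", "n"))
      expect_true(all(res[[g]] >= 0 & res[[g]] <= 1))
  }
})

test_that("somatic spike times converge as dt is halved", {
  # per-spike timing error; over long periodic trains the (converging)
  # period error accumulates as phase drift, so the first spike after onset
  # is the clean observable
  m <- neuron_morphology(1)
  first_spike <- function(dt, i0) {
    inj <- numeric(101); inj[1] <- i0
    res <- run_cable(m$diameter, m$length, dt = dt, duration = 30,
                     i_inj = inj, record_segments = 1)
    detect_spikes(res$v[1, ], dt)[1]
  }
  for (i0 in c(0.15, 0.25)) {
    t1 <- first_spike(0.1, i0)
    t2 <- first_spike(0.05, i0)
    t3 <- first_spike(0.025, i0)
    expect_lt(abs(t1 - t2), 0.05)
    expect_lt(abs(t2 - t3), 0.05)
    expect_lt(abs(t2 - t3), abs(t1 - t2))  # shrinking with dt
  }
})

test_that("suprathreshold drive spikes periodically; silence stays silent", {
  m <- neuron_morphology(1)
  inj <- numeric(101); inj[1] <- 0.2
  res <- run_cable(m$diameter, m$length, dt = 0.1, duration = 2000,
                   i_inj = inj, record_segments = 1)
  spikes <- detect_spikes(res$v[1, ], 0.1)
  expect_gt(length(spikes), 10)
  expect_gt(max(res$v[1, ]) - membrane_params()$e_l, 60)
  isi <- diff(spikes)
  expect_lt(sd(isi[-(1:2)]) / mean(isi[-(1:2)]), 0.05)  # periodic
  quiet <- run_cable(m$diameter, m$length, dt = 0.1, duration = 10000,
                     record_segments = 1)
  expect_length(detect_spikes(quiet$v[1, ], 0.1), 0)
})
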