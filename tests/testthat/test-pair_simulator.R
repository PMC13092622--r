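# Two-neuron simulations: determinism, spike bookkeeping, matching,
# extracellular potentials.

quick_theta <- function(...) {
  args <- utils::modifyList(
    list(d_pre = 1, d_post = 4, mu_ampa = 6e-4, sigma_ampa = 2e-4,
         mu_nmda = 2e-5, sigma_nmda = 1e-5, lambda_pre = 20,
         lambda_post = 10, z_syn = 1500),
    list(...))
  do.call(pair_parameters, args)
}

test_that("simulation is bit-reproducible and respects time bounds", {
  th <- quick_theta()
  a <- run_pair_simulation(th, simulation_config(duration = 2000, seed = 5))
  b <- run_pair_simulation(th, simulation_config(duration = 2000, seed = 5))
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$synapse_events, b$synapse_events)
  for (s in a$spikes) {
    expect_true(all(s >= 0 & s < 2000))
    if (length(s) > 1) expect_true(all(diff(s) > 0))
  }
  expect_true(a$valid)
  d <- run_pair_simulation(th, simulation_config(duration = 2000, seed = 6))
  expect_false(identical(a$spikes$pre_soma, d$spikes$pre_soma))
})

test_that("parameters outside the prior box are rejected", {
  th <- unclass(quick_theta()); th$d_pre <- 5.5
  expect_error(run_pair_simulation(th), "outside prior")
  expect_error(validate_theta(list(d_pre = 1)), "missing")
  expect_error(pair_parameters(mu_ampa = 0.003), "outside prior")
})

test_that("presynaptic spikes propagate forward with positive latency", {
  sim <- run_pair_simulation(quick_theta(), simulation_config(duration = 3000, seed = 2))
  mt <- match_spikes(sim$spikes$pre_z200, sim$spikes$pre_pre_syn)
  expect_gt(nrow(mt), 5)
  expect_true(all(mt$latency > 0))
  # extracellular: electrode 1 (z=60) sees a presynaptic spike before
  # electrode 2 (z=1060) -- propagation direction
  tr <- run_pair_simulation(quick_theta(lambda_post = 5),
                            simulation_config(duration = 500, seed = 3,
                                              record_traces = TRUE))
  expect_equal(dim(tr$traces$phi)[1], 2)
  # locate the first presynaptic somatic spike and compare extremum times
  t1 <- tr$spikes$pre_soma[1]
  win <- which(tr$traces$t >= t1 - 1 & tr$traces$t <= t1 + 8)
  e1 <- tr$traces$t[win][which.min(tr$traces$phi[1, win])]
  e2 <- tr$traces$t[win][which.min(tr$traces$phi[2, win])]
  expect_gt(e2, e1)
})

test_that("with the synapse silenced, the postsynaptic train depends only on its own drive", {
  base <- quick_theta(mu_ampa = 0, sigma_ampa = 0, mu_nmda = 0, sigma_nmda = 0)
  alt <- quick_theta(mu_ampa = 0, sigma_ampa = 0, mu_nmda = 0, sigma_nmda = 0,
                     d_pre = 2.5, lambda_pre = 60)
  a <- run_pair_simulation(base, simulation_config(duration = 2000, seed = 9))
  b <- run_pair_simulation(alt, simulation_config(duration = 2000, seed = 9))
  expect_identical(a$spikes$post_soma, b$spikes$post_soma)
  expect_false(identical(a$spikes$pre_soma, b$spikes$pre_soma))
})

test_that("spike detection handles thresholds, refractoriness, interpolation", {
  expect_length(detect_spikes(rep(-50, 100), 0.1), 0)
  # single clean crossing
  v <- c(seq(-60, -10, by = 10), 20, 30, -20, -60)
  s <- detect_spikes(v, 0.1)
  expect_length(s, 1)
  # crossings at 5.00 and 5.50 ms with 2 ms refractory -> one spike at 5.00
  t <- seq(0, 10, by = 0.1)
  v <- rep(-60, length(t))
  v[t >= 5.0 & t < 5.2] <- 10
  v[t >= 5.5 & t < 5.7] <- 10
  s <- detect_spikes(v, 0.1, threshold = 0, refractory = 2)
  expect_length(s, 1)
  expect_equal(s, 5.0, tolerance = 0.1)
  # sub-dt interpolation: crossing from -10 at t=1.0 to +30 at t=1.1
  v2 <- c(-10, 30)
  expect_equal(detect_spikes(v2, 0.1, t0 = 1.0), 1.0 + 0.1 * 10 / 40)
})

test_that("spike matching is order-preserving and matches the exhaustive oracle", {
  m <- match_spikes(c(10, 50), c(12.0, 12.1, 52.0), 30)
  expect_equal(m$t_b, c(12.0, 52.0))
  expect_equal(match_spikes(1:5, (1:5) + 2.4)$latency, rep(2.4, 5))
  expect_equal(nrow(match_spikes(1:5, numeric(0))), 0)
  set.seed(21)
  for (i in 1:25) {
    a <- sort(runif(sample(0:6, 1), 0, 100))
    b <- sort(runif(sample(0:6, 1), 0, 100))
    got <- match_spikes(a, b, 30)
    want <- oracle_match(a, b, 30)
    expect_equal(nrow(got), want$n)
    expect_equal(sum(got$latency), want$lat, tolerance = 1e-9)
  }
})

test_that("line-source potential has the right limits and scaling", {
  m <- neuron_morphology(1)
  expect_equal(extracellular_potential(numeric(101), m, c(0, 0, 50)), 0)
  # far field: one segment, 1 nA, 1000 um radial -> point source I/(4 pi sigma r)
  one <- m[2, , drop = FALSE]
  i <- 1
  phi <- extracellular_potential(i, one, c(1000, 0, (one$z_start + one$z_end) / 2), 0.3)
  point <- 1000 * i / (4 * pi * 0.3 * 1000)
  expect_equal(phi, point, tolerance = 1e-3 * point)
  # 1/sigma scaling
  phi2 <- extracellular_potential(i, one, c(1000, 0, 30), 0.6)
  phi1 <- extracellular_potential(i, one, c(1000, 0, 30), 0.3)
  expect_equal(phi1, 2 * phi2)
})

test_that("spike CSV serialization round-trips", {
  sim <- run_pair_simulation(quick_theta(), simulation_config(duration = 1000, seed = 4))
  f <- tempfile(fileext = ".csv")
  write_sim_spikes(sim, f)
  df <- read.csv(f)
  expect_setequal(unique(df$site), names(Filter(length, sim$spikes)))
  back <- df$time_ms[df$site == "pre_soma"]
  expect_equal(back, round(sim$spikes$pre_soma, 2), tolerance = 0.011)
})
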