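# Full two-neuron simulations: parameter containers, the pair runner,
# spike detection / matching utilities, extracellular potentials.

#' The nine free parameters of a neuron pair
#'
#' Axon diameters, synaptic weight-distribution parameters, spontaneous
#' drive rates and the synapse coordinate. Each parameter must lie inside
#' the uniform prior box (see [prior_box()]).
#'
#' @param d_pre,d_post axon diameters \[um\], in \[0.2, 5\]
#' @param mu_ampa,sigma_ampa AMPA weight distribution \[mS\], in
#'   \[0, 0.002\] / \[0, 0.001\]
#' @param mu_nmda,sigma_nmda NMDA weight distribution \[mS\], in
#'   \[0, 2e-4\] / \[0, 1e-4\]
#' @param lambda_pre,lambda_post spontaneous Poisson rates \[Hz\], in
#'   \[5, 100\]
#' @param z_syn synapse coordinate \[um\], in \[1000, 2000\]
#' @return named list of class `pair_parameters`
#' @export
pair_parameters <- function(d_pre = 1, d_post = 1,
                            mu_ampa = 0.001, sigma_ampa = 0.0002,
                            mu_nmda = 1e-4, sigma_nmda = 2e-5,
                            lambda_pre = 20, lambda_post = 20,
                            z_syn = 1500) {
  theta <- list(d_pre = d_pre, d_post = d_post, mu_ampa = mu_ampa,
                sigma_ampa = sigma_ampa, mu_nmda = mu_nmda,
                sigma_nmda = sigma_nmda, lambda_pre = lambda_pre,
                lambda_post = lambda_post, z_syn = z_syn)
  validate_theta(theta)
}

#' @rdname pair_parameters
#' @param theta named list or numeric vector with the nine parameters
#' @export
validate_theta <- function(theta) {
  theta <- as.list(theta)
  box <- prior_box()
  for (p in box$name) {
    v <- theta[[p]]
    if (is.null(v) || !is.finite(v)) stop("missing or non-finite parameter: ", p)
    lo <- box$lower[box$name == p]; hi <- box$upper[box$name == p]
    if (v < lo || v > hi)
      stop(sprintf("parameter %s = %g outside prior range [%g, %g]", p, v, lo, hi))
  }
  structure(theta[box$name], class = "pair_parameters")
}

#' Uniform prior box over the nine pair parameters
#'
#' @return data.frame with columns `name`, `lower`, `upper`
#' @export
prior_box <- function() {
  data.frame(
    name = c("d_pre", "d_post", "mu_ampa", "sigma_ampa", "mu_nmda",
             "sigma_nmda", "lambda_pre", "lambda_post", "z_syn"),
    lower = c(0.2, 0.2, 0, 0, 0, 0, 5, 5, 1000),
    upper = c(5, 5, 0.002, 0.001, 2e-4, 1e-4, 100, 100, 2000)
  )
}

#' Simulation configuration
#'
#' @param duration simulated (recorded) time \[ms\]
#' @param dt integration step \[ms\], in (0, 0.1\]
#' @param seed integer seed; the run is bit-reproducible given
#'   `(theta, seed)`
#' @param settle silent settling time excluded from all outputs \[ms\]
#' @param record_traces record per-site membrane potential and extracellular
#'   electrode traces sampled at `dt`
#' @return list of class `simulation_config`
#' @export
simulation_config <- function(duration = 10000, dt = 0.1, seed = 1,
                              settle = 200, record_traces = FALSE) {
  stopifnot(duration > 0, dt > 0, dt <= 0.1, settle >= 0)
  structure(list(duration = duration, dt = dt, seed = as.integer(seed),
                 settle = settle, record_traces = record_traces),
            class = "simulation_config")
}

#' Extracellular electrode configuration
#'
#' Two point electrodes in a homogeneous, isotropic medium. Radial distances
#' to a cable are clamped to the segment radius so that electrodes on the
#' cable axis (as the defaults are) read the potential at the membrane
#' surface.
#'
#' @param positions 2 x 3 matrix of electrode coordinates \[um\]
#' @param sigma_ext extracellular conductivity \[S/m\]
#' @return list of class `electrode_config`
#' @export
electrode_config <- function(positions = rbind(c(0, 0, 60), c(0, 0, 1060)),
                             sigma_ext = 0.3) {
  stopifnot(sigma_ext > 0, ncol(positions) == 3)
  structure(list(positions = positions, sigma_ext = sigma_ext),
            class = "electrode_config")
}

# per-segment line-source kernel weights [uV per nA] for one electrode
line_source_weights <- function(morph, electrode, sigma_ext) {
  r <- sqrt(electrode[1]^2 + electrode[2]^2)
  r_seg <- pmax(r, morph$diameter / 2) # clamp to membrane surface
  a <- electrode[3] - morph$z_start
  b <- electrode[3] - morph$z_end
  1000 / (4 * pi * sigma_ext * morph$length) *
    (asinh(a / r_seg) - asinh(b / r_seg))
}

#' Extracellular potential by the line-source approximation
#'
#' Potential at a point electrode generated by per-segment transmembrane
#' currents of a cable, treating each segment as a uniform line source in a
#' homogeneous medium of conductivity `sigma_ext`.
#'
#' @param i_membrane per-segment transmembrane current \[nA\]: a vector, or a
#'   matrix (segments x time) for a full trace
#' @param morph the source [neuron_morphology()]
#' @param electrode electrode position, length-3 \[um\]
#' @param sigma_ext extracellular conductivity \[S/m\]
#' @return potential \[uV\], scalar or vector over time
#' @export
extracellular_potential <- function(i_membrane, morph, electrode,
                                    sigma_ext = 0.3) {
  stopifnot(sigma_ext > 0, length(electrode) == 3)
  w <- line_source_weights(morph, electrode, sigma_ext)
  if (is.matrix(i_membrane)) {
    stopifnot(nrow(i_membrane) == nrow(morph))
    drop(crossprod(i_membrane, w))
  } else {
    stopifnot(length(i_membrane) == nrow(morph))
    sum(w * i_membrane)
  }
}

#' Detect spikes by threshold crossing
#'
#' Upward crossings of `threshold`, with crossings inside the refractory
#' window of the previous spike suppressed and sub-step linear interpolation
#' of the crossing time.
#'
#' @param v sampled membrane potential \[mV\]
#' @param dt sampling interval \[ms\]
#' @param threshold detection threshold \[mV\]
#' @param refractory minimal inter-spike interval \[ms\]
#' @param t0 time of the first sample \[ms\]
#' @return sorted spike times \[ms\]
#' @export
detect_spikes <- function(v, dt, threshold = 0, refractory = 2, t0 = 0) {
  n <- length(v)
  if (n < 2) return(numeric(0))
  idx <- which(v[-n] < threshold & v[-1] >= threshold)
  if (!length(idx)) return(numeric(0))
  tc <- t0 + (idx - 1) * dt + dt * (threshold - v[idx]) / (v[idx + 1] - v[idx])
  out <- numeric(0)
  last <- -Inf
  for (t in tc) {
    if (t - last > refractory) { out <- c(out, t); last <- t }
  }
  out
}

#' Match propagating spikes across two detection sites
#'
#' Order-preserving one-to-one matching of spikes at an upstream site to
#' spikes at a downstream site, keeping only forward-in-time pairs with
#' latency in `(0, max_latency]`. Among all order-preserving matchings the
#' one with the maximal number of pairs is chosen, ties broken by minimal
#' total latency (dynamic program over the sorted trains).
#'
#' @param site_a spike times at the upstream site \[ms\]
#' @param site_b spike times at the downstream site \[ms\]
#' @param max_latency maximal propagation delay \[ms\]
#' @return data.frame with columns `t_a`, `t_b`, `latency` \[ms\]
#' @export
match_spikes <- function(site_a, site_b, max_latency = 30) {
  site_a <- sort(site_a); site_b <- sort(site_b)
  idx <- match_spikes_cpp(site_a, site_b, max_latency)
  ta <- site_a[idx[, 1]]; tb <- site_b[idx[, 2]]
  data.frame(t_a = ta, t_b = tb, latency = tb - ta)
}

# named recording sites for a pair simulation; z_syn decides four of them
pair_sites <- function(morphs, z_syn) {
  spec <- list(
    pre_soma = list(0L, 1L),
    post_soma = list(1L, 1L),
    pre_z200 = list(0L, nearest_segment(morphs$pre, 200)),
    pre_pre_syn = list(0L, nearest_segment(morphs$pre, z_syn - 100)),
    post_post_syn = list(1L, nearest_segment(morphs$post, z_syn + 100)),
    post_z3000 = list(1L, nearest_segment(morphs$post, 3000))
  )
  data.frame(
    site = names(spec),
    neuron = vapply(spec, function(s) s[[1]], integer(1)),
    segment = vapply(spec, function(s) as.integer(s[[2]]), integer(1)),
    z = vapply(seq_along(spec), function(i) {
      m <- if (spec[[i]][[1]] == 0) morphs$pre else morphs$post
      segment_centers(m)[spec[[i]][[2]]]
    }, numeric(1))
  )
}

# derive independent named seed streams from one root seed
stream_seeds <- function(seed, n = 4) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

#' Simulate a synaptically coupled neuron pair
#'
#' Runs both cables with spontaneous Poisson conductance input at their
#' initial axon segments and an AMPA+NMDA synapse from the presynaptic
#' segment nearest `z_syn` onto the postsynaptic segment nearest `z_syn`.
#' The synapse activates, with freshly sampled weights for both components,
#' whenever the presynaptic trigger segment crosses 0 mV upward (2 ms
#' refractory, no additional delay). A silent settling period precedes
#' recording; all reported times are relative to its end. Deterministic
#' given `(theta, config$seed)`.
#'
#' @param theta a [pair_parameters()] object (or coercible list)
#' @param config a [simulation_config()]
#' @param electrodes an [electrode_config()]
#' @param membrane a [membrane_params()]
#' @return object of class `pair_sim`: list with `spikes` (named site ->
#'   sorted spike times \[ms\]), `synapse_events`, `sites`, `parameters`,
#'   `config`, `valid`, `diagnostics`, and (if requested) `traces` with
#'   `t`, site potentials `v_sites` and electrode potentials `phi` \[uV\]
#' @export
run_pair_simulation <- function(theta, config = simulation_config(),
                                electrodes = electrode_config(),
                                membrane = membrane_params()) {
  theta <- validate_theta(theta)
  morphs <- build_pair_morphologies(theta$d_pre, theta$d_post)
  gpre <- morph_geometry(morphs$pre, membrane$r_a)
  gpost <- morph_geometry(morphs$post, membrane$r_a)

  ss <- stream_seeds(config$seed, 4)
  ev_pre <- with_seed(ss[1], {
    ev <- generate_poisson_events(theta$lambda_pre, config$duration)
    list(t = ev, w = sample_weight(length(ev), 0.02 * theta$d_pre,
                                   0.02 * theta$d_pre))
  })
  ev_post <- with_seed(ss[2], {
    ev <- generate_poisson_events(theta$lambda_post, config$duration)
    list(t = ev, w = sample_weight(length(ev), 0.02 * theta$d_post,
                                   0.02 * theta$d_post))
  })
  n_pool <- ceiling(config$duration / 2) + 10
  # pair-synapse weight distributions are parameterized in mS; the core
  # works in uS (the spontaneous drive is already uS-scale)
  ampa_w <- with_seed(ss[3], sample_weight(n_pool, theta$mu_ampa, theta$sigma_ampa)) * 1000
  nmda_w <- with_seed(ss[4], sample_weight(n_pool, theta$mu_nmda, theta$sigma_nmda)) * 1000

  sites <- pair_sites(morphs, theta$z_syn)
  trigger_seg <- nearest_segment(morphs$pre, theta$z_syn)
  target_seg <- nearest_segment(morphs$post, theta$z_syn)

  phi_w_pre <- t(apply(electrodes$positions, 1, function(e)
    line_source_weights(morphs$pre, e, electrodes$sigma_ext)))
  phi_w_post <- t(apply(electrodes$positions, 1, function(e)
    line_source_weights(morphs$post, e, electrodes$sigma_ext)))

  spk <- spont_kinetics(); ak <- ampa_kinetics(); nk <- nmda_kinetics()
  n_steps <- as.integer(round(config$duration / config$dt))
  res <- run_pair_cpp(
    gpre, gpost, mem_internal(membrane, config$dt), config$dt,
    as.integer(round(config$settle / config$dt)), n_steps,
    as.integer(floor(ev_pre$t / config$dt)), ev_pre$w,
    as.integer(floor(ev_post$t / config$dt)), ev_post$w,
    spk$tau1, spk$tau2, spk$reversal, 1L,
    trigger_seg - 1L, target_seg - 1L,
    ak$tau1, ak$tau2, ampa_w, nk$tau1, nk$tau2, nmda_w, ak$reversal,
    0, 2, as.matrix(cbind(sites$neuron, sites$segment - 1L)),
    config$record_traces, config$record_traces, phi_w_pre, phi_w_post)

  spikes <- res$spikes
  names(spikes) <- sites$site
  out <- list(
    spikes = spikes,
    synapse_events = res$syn_times,
    sites = sites,
    parameters = theta,
    config = config,
    valid = res$valid,
    diagnostics = if (res$valid) NULL else
      list(step = res$bad_step, segment = res$bad_seg, neuron = res$bad_neuron,
           parameters = theta)
  )
  if (config$record_traces) {
    out$traces <- list(t = seq(0, by = config$dt, length.out = n_steps + 1),
                       v_sites = res$v_sites, phi = res$phi)
    rownames(out$traces$v_sites) <- sites$site
  }
  class(out) <- "pair_sim"
  out
}

#' @export
print.pair_sim <- function(x, ...) {
  cat("Neuron-pair simulation:", x$config$duration, "ms, dt =", x$config$dt,
      "ms, seed =", x$config$seed, "\n")
  cat("  valid:", x$valid, "\n")
  for (s in names(x$spikes))
    cat(sprintf("  %-14s %d spikes\n", s, length(x$spikes[[s]])))
  cat("  synapse activations:", length(x$synapse_events), "\n")
  invisible(x)
}

#' Serialize / read pair-simulation spike times
#'
#' @param result a `pair_sim` object
#' @param path CSV path; columns `site`, `time_ms`
#' @export
write_sim_spikes <- function(result, path) {
  df <- do.call(rbind, lapply(names(result$spikes), function(s) {
    t <- result$spikes[[s]]
    if (!length(t)) return(NULL)
    data.frame(site = s, time_ms = round(t, 2))
  }))
  if (is.null(df)) df <- data.frame(site = character(0), time_ms = numeric(0))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
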