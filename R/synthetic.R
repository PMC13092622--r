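# Synthetic-data generators: coupled point-process "recordings", prior
# populations simulated through the biophysical model, and pre/post
# condition-shift experiments emulating a stimulation study.

#' Specification of a coupled point-process pair
#'
#' Emulates what sorted spike trains of a synaptically coupled pair look
#' like without the biophysics: a Poisson presynaptic train and a
#' postsynaptic train that superposes baseline Poisson activity with
#' lagged, jittered, probabilistic copies of the presynaptic spikes.
#'
#' @param rate_pre presynaptic Poisson rate \[Hz\]
#' @param rate_post_baseline postsynaptic baseline rate \[Hz\]
#' @param p_transmit probability a presynaptic spike elicits a postsynaptic
#'   spike, in \[0, 1\]
#' @param lag transmission delay \[ms\], > 0
#' @param jitter_sd Gaussian jitter of transmitted spikes \[ms\]
#' @param duration \[ms\]
#' @param seed integer seed
#' @return list of class `coupling_spec`
#' @export
coupling_spec <- function(rate_pre = 5, rate_post_baseline = 2,
                          p_transmit = 0.4, lag = 4, jitter_sd = 0.3,
                          duration = 600000, seed = 1) {
  stopifnot(p_transmit >= 0, p_transmit <= 1, lag > 0, jitter_sd >= 0,
            rate_pre >= 0, rate_post_baseline >= 0, duration > 0)
  structure(list(rate_pre = rate_pre,
                 rate_post_baseline = rate_post_baseline,
                 p_transmit = p_transmit, lag = lag, jitter_sd = jitter_sd,
                 duration = duration, seed = as.integer(seed)),
            class = "coupling_spec")
}

#' Generate a coupled point-process pair
#'
#' Spike times are rounded to 0.1 ms (spike-sorter resolution) and
#' postsynaptic spikes closer than 1 ms to their predecessor are merged.
#'
#' @param spec a [coupling_spec()]
#' @return list with sorted `pre` and `post` spike-time vectors \[ms\] and
#'   `duration`
#' @export
generate_coupled_point_process <- function(spec) {
  stopifnot(inherits(spec, "coupling_spec"))
  set.seed(spec$seed)
  pre <- generate_poisson_events(spec$rate_pre, spec$duration)
  base <- generate_poisson_events(spec$rate_post_baseline, spec$duration)
  transmitted <- numeric(0)
  if (length(pre) && spec$p_transmit > 0) {
    sel <- runif(length(pre)) < spec$p_transmit
    transmitted <- pre[sel] + spec$lag +
      rnorm(sum(sel), 0, spec$jitter_sd)
  }
  post <- sort(c(base, transmitted))
  post <- post[post >= 0 & post < spec$duration]
  pre <- round(pre, 1); post <- round(post, 1)
  pre <- unique(pre)
  post <- unique(post)
  # 1 ms merge refractory: drop spikes closer than 1 ms to the previous kept
  keep_refractory <- function(t) {
    if (length(t) < 2) return(t)
    out <- t[1]; last <- t[1]
    for (x in t[-1]) if (x - last >= 1) { out <- c(out, x); last <- x }
    out
  }
  list(pre = keep_refractory(pre), post = keep_refractory(post),
       duration = spec$duration)
}

#' Simulate a population of prior-drawn neuron pairs
#'
#' Draws `n_pairs` parameter vectors from the prior, simulates each, and
#' extracts summary statistics. Validity (significant TE interaction, all
#' statistics defined) is recorded per pair; attrition is reported, never
#' hidden.
#'
#' @param n_pairs number of pairs
#' @param duration per-pair simulated time \[ms\]
#' @param seed root seed (reproducible)
#' @param prior a [prior_box()]
#' @param config a [te_config()]
#' @param keep_sims keep the full `pair_sim` objects (memory!)
#' @return object of class `pair_population`: list with `theta` (n x 9),
#'   `stats` (n x 6, NA rows where undefined), `valid` (logical), `p_syn_keep`
#'   (valid & p_syn > 0.05), `seeds`, optionally `sims`
#' @export
generate_population <- function(n_pairs, duration = 10000, seed = 1,
                                prior = prior_box(), config = te_config(),
                                keep_sims = FALSE) {
  stopifnot(n_pairs >= 1)
  set.seed(seed)
  theta <- sample_prior(n_pairs, prior)
  seeds <- sample.int(.Machine$integer.max - 1L, n_pairs)
  stats <- matrix(NA_real_, n_pairs, 6,
                  dimnames = list(NULL, summary_stat_names()))
  valid <- logical(n_pairs)
  sims <- if (keep_sims) vector("list", n_pairs) else NULL
  for (i in seq_len(n_pairs)) {
    sim <- run_pair_simulation(as.list(theta[i, ]),
                               simulation_config(duration = duration,
                                                 seed = seeds[i]))
    set.seed(seeds[i] %% 1000000L + 13L)
    st <- extract_summary(sim, config)
    stats[i, ] <- unlist(st[1, summary_stat_names()])
    valid[i] <- isTRUE(st$valid)
    if (keep_sims) sims[[i]] <- sim
  }
  structure(list(theta = theta, stats = stats, valid = valid,
                 p_syn_keep = valid & !is.na(stats[, "p_syn"]) &
                   stats[, "p_syn"] > 0.05,
                 seeds = seeds, duration = duration, sims = sims),
            class = "pair_population")
}

#' Generate matched pre/post-stimulation populations
#'
#' "Before" pairs are simulated at `theta_base` plus a small per-pair
#' scatter (5% of each prior range, truncated to the box); "after" pairs
#' reuse the identical per-pair parameters and simulation seeds with the
#' named multiplicative shifts applied (e.g., `c(mu_ampa = 1.5)` for a +50%
#' AMPA weight change). A zero shift therefore reproduces "before" exactly.
#'
#' @param n_pairs pairs per condition
#' @param theta_base central parameter vector (list or named vector)
#' @param shift named multiplicative factors applied to "after" parameters;
#'   shifted values must stay inside the prior box
#' @param duration per-pair simulated time \[ms\]
#' @param seed root seed
#' @param scatter per-pair jitter as a fraction of each prior range
#' @param config a [te_config()]
#' @return list with `before` and `after` (each like a
#'   [generate_population()] result, plus the per-pair `theta`), and
#'   `shift`
#' @export
generate_condition_shift <- function(n_pairs, theta_base, shift,
                                     duration = 10000, seed = 1,
                                     scatter = 0.05, config = te_config()) {
  stopifnot(n_pairs >= 2, length(shift) >= 1, !is.null(names(shift)))
  box <- prior_box()
  base <- unlist(validate_theta(theta_base))
  if (!all(names(shift) %in% box$name)) stop("unknown parameter in shift")
  set.seed(seed)
  span <- box$upper - box$lower
  theta_before <- matrix(rep(base, each = n_pairs), n_pairs, 9,
                         dimnames = list(NULL, box$name))
  theta_before <- theta_before +
    matrix(rnorm(n_pairs * 9, 0, 1), n_pairs, 9) *
    rep(scatter * span, each = n_pairs)
  theta_before <- pmin(pmax(theta_before,
                            rep(box$lower, each = n_pairs)),
                       rep(box$upper, each = n_pairs))
  theta_after <- theta_before
  for (nm in names(shift)) {
    theta_after[, nm] <- theta_after[, nm] * shift[[nm]]
    i <- match(nm, box$name)
    if (any(theta_after[, nm] < box$lower[i] - 1e-12) ||
        any(theta_after[, nm] > box$upper[i] + 1e-12))
      stop("shifted parameter ", nm, " leaves the prior box")
  }
  seeds <- sample.int(.Machine$integer.max - 1L, n_pairs)
  run_cond <- function(theta, label) {
    stats <- matrix(NA_real_, n_pairs, 6,
                    dimnames = list(NULL, summary_stat_names()))
    valid <- logical(n_pairs)
    for (i in seq_len(n_pairs)) {
      sim <- run_pair_simulation(as.list(theta[i, ]),
                                 simulation_config(duration = duration,
                                                   seed = seeds[i]))
      set.seed(seeds[i] %% 1000000L + 13L)
      st <- extract_summary(sim, config)
      stats[i, ] <- unlist(st[1, summary_stat_names()])
      valid[i] <- isTRUE(st$valid)
    }
    list(label = label, theta = theta, stats = stats, valid = valid,
         seeds = seeds)
  }
  list(before = run_cond(theta_before, "before"),
       after = run_cond(theta_after, "after"),
       shift = shift)
}
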