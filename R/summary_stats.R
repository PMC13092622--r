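# The six-dimensional observable vector: firing rates, conduction speeds,
# postsynaptic spike probability, coupling lag.

#' Firing rate of a spike train
#'
#' @param train spike times \[ms\]
#' @param duration total duration \[ms\]
#' @return rate \[Hz\]
#' @export
firing_rate <- function(train, duration) {
  stopifnot(duration > 0)
  length(train) / duration * 1000
}

#' Conduction velocity from matched spikes
#'
#' Mean propagation latency of matched spike pairs divided into the axial
#' distance between the two detection sites.
#'
#' @param matches data.frame from [match_spikes()] (needs column `latency`)
#' @param dz axial distance between the detection sites \[um\]
#' @return velocity \[m/s\] (um/ms = mm/s)
#' @export
conduction_velocity <- function(matches, dz) {
  if (nrow(matches) == 0) stop("no matched spikes: velocity undefined")
  dz / mean(matches$latency) / 1000
}

#' Postsynaptic spike probability
#'
#' Fraction of presynaptic spikes followed by a postsynaptic spike within
#' `[lag - delta_t, lag + delta_t]`. Each postsynaptic spike is credited to
#' at most one presynaptic spike (the nearest), so the probability cannot
#' exceed 1 at high rates.
#'
#' @param pre,post spike times \[ms\]; `pre` must be non-empty
#' @param lag coupling lag \[ms\]
#' @param delta_t half-width of the counting window \[ms\]
#' @return probability in \[0, 1\]
#' @export
postsynaptic_spike_probability <- function(pre, post, lag, delta_t) {
  if (!length(pre)) stop("empty presynaptic train: probability undefined")
  stopifnot(delta_t > 0)
  if (!length(post)) return(0)
  expected <- sort(pre) + lag
  # distance from each post spike to the nearest expected arrival time
  i <- findInterval(post, expected)
  d_lo <- ifelse(i >= 1, post - expected[pmax(i, 1)], Inf)
  d_hi <- ifelse(i < length(expected), expected[pmin(i + 1, length(expected))] - post, Inf)
  hits <- sum(pmin(d_lo, d_hi) <= delta_t)
  min(1, hits / length(pre))
}

#' Extract the six summary statistics
#'
#' Assembles the observable vector `x = (f_pre, f_post, v_pre, v_post,
#' p_syn, lag)` from a pair simulation or from a raw pair of spike trains.
#' The coupling lag is the lag maximizing bivariate transfer entropy
#' (somatic trains binned at `config$bin_ms`); its significance is assessed
#' by the permutation test and a non-significant interaction flags the
#' vector invalid. For simulated pairs the spike-probability window is
#' `delta_t = 0.5` ms; for raw experimental-style train pairs it is 1 ms
#' and the conduction velocities must be supplied externally (or stay NA).
#'
#' @param x a `pair_sim` object, or a list with `pre`, `post` (spike times
#'   \[ms\]) and `duration` \[ms\]
#' @param config a [te_config()]
#' @param ... passed to methods
#' @return object of class `summary_stats`: one-row data.frame with columns
#'   `f_pre, f_post, v_pre, v_post, p_syn, lag, valid` and attributes
#'   `te` (the `te_result`) and `reason` (if invalid)
#' @export
extract_summary <- function(x, config = te_config(), ...) {
  UseMethod("extract_summary")
}

summary_row <- function(f_pre, f_post, v_pre, v_post, p_syn, lag, valid,
                        te = NULL, reason = NULL) {
  out <- data.frame(f_pre = f_pre, f_post = f_post, v_pre = v_pre,
                    v_post = v_post, p_syn = p_syn, lag = lag, valid = valid)
  attr(out, "te") <- te
  attr(out, "reason") <- reason
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' @rdname extract_summary
#' @param delta_t counting window half-width \[ms\]; default 0.5 for
#'   simulations, 1 for raw train pairs
#' @export
extract_summary.pair_sim <- function(x, config = te_config(), delta_t = 0.5,
                                     ...) {
  dur <- x$config$duration
  pre <- x$spikes$pre_soma
  post <- x$spikes$post_soma
  f_pre <- firing_rate(pre, dur)
  f_post <- firing_rate(post, dur)
  fail <- function(reason)
    summary_row(f_pre, f_post, NA, NA, NA, NA, FALSE, reason = reason)
  if (!x$valid) return(fail("simulation flagged invalid"))
  if (!length(pre) || !length(post)) return(fail("empty somatic train"))

  mt_pre <- match_spikes(x$spikes$pre_z200, x$spikes$pre_pre_syn)
  mt_post <- match_spikes(x$spikes$post_post_syn, x$spikes$post_z3000)
  if (!nrow(mt_pre) || !nrow(mt_post)) return(fail("no propagating spikes"))
  dz_pre <- abs(diff(x$sites$z[match(c("pre_z200", "pre_pre_syn"), x$sites$site)]))
  dz_post <- abs(diff(x$sites$z[match(c("post_post_syn", "post_z3000"), x$sites$site)]))
  v_pre <- conduction_velocity(mt_pre, dz_pre)
  v_post <- conduction_velocity(mt_post, dz_post)

  bt <- bin_spike_train(pre, config$bin_ms, dur)
  bp <- bin_spike_train(post, config$bin_ms, dur)
  te <- te_test(bp, bt, config)
  p_syn <- postsynaptic_spike_probability(pre, post, te$delta_star, delta_t)
  out <- summary_row(f_pre, f_post, v_pre, v_post, p_syn, te$delta_star,
                     te$significant, te = te,
                     reason = if (!te$significant) "no significant interaction")
  out
}

#' @rdname extract_summary
#' @param velocities optional numeric length-2 vector `(v_pre, v_post)`
#'   \[m/s\] for raw train pairs (point-process inputs carry no conduction
#'   information)
#' @export
extract_summary.default <- function(x, config = te_config(), delta_t = 1,
                                    velocities = c(NA_real_, NA_real_), ...) {
  stopifnot(is.list(x), !is.null(x$pre), !is.null(x$duration))
  pre <- x$pre; post <- x$post; dur <- x$duration
  f_pre <- firing_rate(pre, dur)
  f_post <- firing_rate(post, dur)
  if (!length(pre))
    return(summary_row(f_pre, f_post, velocities[1], velocities[2], NA, NA,
                       FALSE, reason = "empty presynaptic train"))
  bt <- bin_spike_train(pre, config$bin_ms, dur)
  bp <- bin_spike_train(post, config$bin_ms, dur)
  te <- te_test(bp, bt, config)
  p_syn <- postsynaptic_spike_probability(pre, post, te$delta_star, delta_t)
  summary_row(f_pre, f_post, velocities[1], velocities[2], p_syn,
              te$delta_star, te$significant, te = te,
              reason = if (!te$significant) "no significant interaction")
}

#' Summary-statistic columns in canonical order
#' @return character vector of the six statistic names
#' @export
summary_stat_names <- function() {
  c("f_pre", "f_post", "v_pre", "v_post", "p_syn", "lag")
}
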