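# Conductance-based synaptic machinery: beta-function kinetics, truncated
# normal weights, Poisson event trains.

#' Synaptic kinetics
#'
#' Rise/decay time constants and reversal potential of one conductance
#' component. The beta-function profile is symmetric under swapping the two
#' time constants, so their ordering is immaterial numerically.
#'
#' @param tau1 decay time constant \[ms\]
#' @param tau2 rise time constant \[ms\]
#' @param reversal synaptic reversal potential \[mV\]
#' @return object of class `synaptic_kinetics`
#' @export
synaptic_kinetics <- function(tau1, tau2, reversal = 0) {
  stopifnot(tau1 > 0, tau2 > 0)
  if (tau1 == tau2)
    stop("degenerate kinetics: tau1 == tau2 (alpha-function limit not supported)")
  structure(list(tau1 = tau1, tau2 = tau2, reversal = reversal),
            class = "synaptic_kinetics")
}

#' Time of the conductance peak of a beta-function synapse
#'
#' `tau_peak = tau1 tau2 / (tau2 - tau1) * log(tau2 / tau1)`; invariant
#' under swapping the two time constants.
#'
#' @param tau1,tau2 time constants \[ms\], positive and distinct
#' @return time of the conductance maximum after activation \[ms\]
#' @export
tau_peak <- function(tau1, tau2) {
  stopifnot(all(tau1 > 0), all(tau2 > 0))
  if (any(tau1 == tau2))
    stop("degenerate kinetics: tau1 == tau2")
  tau1 * tau2 / (tau2 - tau1) * log(tau2 / tau1)
}

#' Beta-function conductance profile
#'
#' Conductance at time `t` after a single activation event with weight `w`:
#' a difference of exponentials normalized so the peak value equals `w`
#' exactly at [tau_peak()]. Zero for `t < 0`. Contributions of successive
#' events superpose linearly.
#'
#' @param t time since the activation event \[ms\], vectorized
#' @param w synaptic weight = peak conductance \[uS\]
#' @param kinetics a [synaptic_kinetics()] object
#' @return conductance \[uS\]
#' @export
beta_conductance <- function(t, w, kinetics) {
  stopifnot(w >= 0)
  t1 <- kinetics$tau1; t2 <- kinetics$tau2
  tp <- tau_peak(t1, t2)
  norm <- exp(-tp / t1) - exp(-tp / t2)
  g <- ifelse(t >= 0, w * (exp(-t / t1) - exp(-t / t2)) / norm, 0)
  g
}

#' Sample synaptic weights from a truncated normal distribution
#'
#' Draws from a normal with parent mean `mu` and standard deviation `sigma`,
#' truncated below at `lower` (default 0: conductances are non-negative).
#' Exact inverse-CDF sampling, one fresh draw per activation event.
#'
#' @param n number of draws
#' @param mu,sigma parameters of the parent normal \[uS\]
#' @param lower truncation point \[uS\]
#' @return numeric vector of weights, all `>= lower`
#' @export
sample_weight <- function(n, mu, sigma, lower = 0) {
  stopifnot(sigma >= 0, n >= 0)
  if (n == 0) return(numeric(0))
  if (sigma == 0) return(rep(max(mu, lower), n))
  p_lo <- pnorm((lower - mu) / sigma)
  u <- runif(n, p_lo, 1)
  mu + sigma * qnorm(pmin(u, 1 - 1e-16))
}

#' Homogeneous Poisson event train
#'
#' @param rate event rate \[Hz\]
#' @param duration \[ms\]
#' @return strictly increasing event times in `[0, duration)` \[ms\]
#' @export
generate_poisson_events <- function(rate, duration) {
  if (!is.finite(rate) || rate < 0) stop("rate must be non-negative")
  stopifnot(duration > 0)
  if (rate == 0) return(numeric(0))
  n <- rpois(1, rate * duration / 1000)
  if (n == 0) return(numeric(0))
  t <- sort(runif(n, 0, duration))
  # enforce strict ordering at double precision (ties have probability ~0)
  t[c(TRUE, diff(t) > 0)]
}

#' Synaptic point current
#'
#' Ohmic current through an open synaptic conductance,
#' `I = G (V - reversal)`; negative values are inward (depolarizing for
#' `V < reversal`). With `G` in uS and potentials in mV, the current is nA.
#'
#' @param g conductance \[uS\]
#' @param v local membrane potential \[mV\]
#' @param reversal synaptic reversal potential \[mV\]
#' @return current \[nA\]
#' @export
synaptic_point_current <- function(g, v, reversal = 0) {
  stopifnot(all(g >= 0))
  g * (v - reversal)
}

# fixed kinetics of the model (AMPA fast, NMDA slow, spontaneous drive)
ampa_kinetics <- function() synaptic_kinetics(tau1 = 0.3, tau2 = 0.1, reversal = 0)
nmda_kinetics <- function() synaptic_kinetics(tau1 = 30, tau2 = 10, reversal = 0)
spont_kinetics <- function() synaptic_kinetics(tau1 = 0.2, tau2 = 0.4, reversal = 0)
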