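# Membrane biophysics of the ball-and-stick neuron: parameters, HH gating,
# ionic current densities, morphology, and the single-cable driver.

#' Membrane parameters of the Hodgkin-Huxley model
#'
#' Container for the fixed biophysical constants of the model. Defaults are
#' the values used throughout: conductance densities in S/cm^2, potentials in
#' mV, axial resistivity in Ohm cm, capacitance in uF/cm^2, temperature in
#' degrees Celsius. `v_t` is a global offset shifting the voltage dependence
#' of all gating rate functions.
#'
#' @param r_a specific axial resistivity \[Ohm cm\]
#' @param c_m specific membrane capacitance \[uF/cm^2\]
#' @param g_na,g_k,g_l maximal Na+/K+/leak conductance densities \[S/cm^2\]
#' @param e_na,e_k,e_l reversal potentials \[mV\]
#' @param v_t global voltage offset of the gating rate functions \[mV\]
#' @param temperature \[degrees C\]; gating kinetics are scaled by
#'   `3^((temperature - 37)/10)`
#' @return object of class `membrane_params`
#' @export
membrane_params <- function(r_a = 100, c_m = 1, g_na = 0.05, g_k = 0.005,
                            g_l = 3e-4, e_na = 70, e_k = -80, e_l = -39.2,
                            v_t = -30.4, temperature = 37) {
  stopifnot(g_na >= 0, g_k >= 0, g_l >= 0, r_a > 0, c_m > 0)
  if (!(e_k < e_l && e_l < e_na))
    stop("reversal potentials must satisfy e_k < e_l < e_na")
  structure(list(r_a = r_a, c_m = c_m, g_na = g_na, g_k = g_k, g_l = g_l,
                 e_na = e_na, e_k = e_k, e_l = e_l, v_t = v_t,
                 temperature = temperature),
            class = "membrane_params")
}

#' Temperature scaling factor of gating kinetics
#'
#' `phi = 3^((T - 37)/10)` with T in degrees Celsius; divides all gating
#' time constants.
#'
#' @param params a [membrane_params()] object
#' @return scalar scaling factor
#' @export
temperature_factor <- function(params) 3^((params$temperature - 37) / 10)

# x / (exp(x/a) - 1), removable singularity at x = 0 evaluated by series
vtrap <- function(x, a) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-6
  out[small] <- a - x[small] / 2 + x[small]^2 / (12 * a)
  out[!small] <- x[!small] / expm1(x[!small] / a)
  out
}

#' Voltage-dependent gating rate functions
#'
#' Forward/backward rates of the m, h, n gates (1/ms) as functions of
#' membrane potential, with the global offset `v_t` shifting all voltage
#' dependencies. Removable singularities (denominators `exp(x/a) - 1` at
#' `x -> 0`) are evaluated by their analytic limits.
#'
#' @param v membrane potential \[mV\], vectorized
#' @param v_t global voltage offset \[mV\]
#' @return data.frame with columns `alpha_m, beta_m, alpha_h, beta_h,
#'   alpha_n, beta_n` \[1/ms\]
#' @export
gating_rates <- function(v, v_t = -30.4) {
  if (any(!is.finite(v))) stop("non-finite membrane potential")
  u <- v - v_t
  data.frame(
    alpha_m = 0.32 * vtrap(13 - u, 4),
    beta_m  = 0.28 * vtrap(u - 40, 5),
    alpha_h = 0.128 * exp((17 - u) / 18),
    beta_h  = 4 / (1 + exp((40 - u) / 5)),
    alpha_n = 0.032 * vtrap(15 - u, 5),
    beta_n  = 0.5 * exp((10 - u) / 40)
  )
}

#' Gating steady states and time constants
#'
#' For each gate x: `x_inf = alpha/(alpha + beta)` and
#' `tau_x = 1/(phi (alpha + beta))`, where phi is the temperature factor
#' (unity at 37 C).
#'
#' @param v membrane potential \[mV\], vectorized
#' @param params a [membrane_params()] object
#' @return data.frame with columns `m_inf, tau_m, h_inf, tau_h, n_inf, tau_n`
#' @export
gating_inf_tau <- function(v, params = membrane_params()) {
  r <- gating_rates(v, params$v_t)
  phi <- temperature_factor(params)
  data.frame(
    m_inf = r$alpha_m / (r$alpha_m + r$beta_m),
    tau_m = 1 / (phi * (r$alpha_m + r$beta_m)),
    h_inf = r$alpha_h / (r$alpha_h + r$beta_h),
    tau_h = 1 / (phi * (r$alpha_h + r$beta_h)),
    n_inf = r$alpha_n / (r$alpha_n + r$beta_n),
    tau_n = 1 / (phi * (r$alpha_n + r$beta_n))
  )
}

#' Ionic membrane current densities
#'
#' Hodgkin-Huxley current densities: fast sodium `g_na m^3 h (V - E_Na)`,
#' delayed-rectifier potassium `g_k n^4 (V - E_K)` and leak
#' `g_l (V - E_L)`. Positive values are outward. With conductances in
#' S/cm^2 and potentials in mV the densities are in mA/cm^2.
#'
#' @param v membrane potential \[mV\]
#' @param m,h,n gating variables in \[0, 1\]
#' @param params a [membrane_params()] object
#' @return list with components `i_na`, `i_k`, `i_l` and their sum `total`
#' @export
ionic_current_density <- function(v, m, h, n, params = membrane_params()) {
  stopifnot(all(m >= 0 & m <= 1), all(h >= 0 & h <= 1), all(n >= 0 & n <= 1))
  i_na <- params$g_na * m^3 * h * (v - params$e_na)
  i_k <- params$g_k * n^4 * (v - params$e_k)
  i_l <- params$g_l * (v - params$e_l)
  list(i_na = i_na, i_k = i_k, i_l = i_l, total = i_na + i_k + i_l)
}

#' Ball-and-stick neuron morphology
#'
#' One cylindrical soma segment (10 um long, 10 um diameter) followed by 100
#' axon segments of 19.9 um each, aligned along the z axis starting at
#' `origin_z`.
#'
#' @param d_axon axon diameter \[um\], identical for all axon segments;
#'   must lie in \[0.2, 5\]
#' @param origin_z z coordinate of the proximal soma end \[um\]
#' @return object of class `neuron_morphology`: data.frame with columns
#'   `index, kind, z_start, z_end, length, diameter` plus attribute
#'   `origin_z`
#' @export
neuron_morphology <- function(d_axon, origin_z = 0) {
  if (!is.finite(d_axon) || d_axon < 0.2 || d_axon > 5)
    stop("axon diameter must lie in [0.2, 5] um")
  n_axon <- 100
  len <- c(10, rep(19.9, n_axon))
  z_start <- origin_z + cumsum(c(0, len[-length(len)]))
  m <- data.frame(
    index = seq_along(len),
    kind = c("soma", rep("axon", n_axon)),
    z_start = z_start,
    z_end = z_start + len,
    length = len,
    diameter = c(10, rep(d_axon, n_axon))
  )
  structure(m, origin_z = origin_z, class = c("neuron_morphology", "data.frame"))
}

#' Morphologies of a presynaptic / postsynaptic neuron pair
#'
#' The presynaptic soma spans z = 0..10 um with its axon reaching z = 2000
#' um; the postsynaptic neuron is identical but shifted by 1000 um (soma
#' 1000..1010, axon to 3000 um).
#'
#' @param d_pre,d_post axon diameters \[um\] in \[0.2, 5\]
#' @return list with elements `pre` and `post`, each a [neuron_morphology()]
#' @export
build_pair_morphologies <- function(d_pre, d_post) {
  list(pre = neuron_morphology(d_pre, origin_z = 0),
       post = neuron_morphology(d_post, origin_z = 1000))
}

#' Segment centers of a morphology
#' @param morph a [neuron_morphology()]
#' @return numeric vector of z coordinates \[um\]
#' @export
segment_centers <- function(morph) (morph$z_start + morph$z_end) / 2

#' Index of the segment whose center is nearest a z coordinate
#' @param morph a [neuron_morphology()]
#' @param z target coordinate \[um\]
#' @return integer segment index (1-based)
#' @export
nearest_segment <- function(morph, z) which.min(abs(segment_centers(morph) - z))

# Discretized electrical geometry: lateral membrane areas (cm^2) and axial
# couplings between segment centers (mS). The axial conductance between
# adjacent centers is the series combination of each segment's half axial
# resistance 4 r_a (L/2) / (pi d^2).
morph_geometry <- function(morph, r_a) {
  d_cm <- morph$diameter * 1e-4
  l_cm <- morph$length * 1e-4
  area <- pi * d_cm * l_cm
  r_half <- 4 * r_a * (l_cm / 2) / (pi * d_cm^2) # Ohm
  n <- nrow(morph)
  gax <- 1000 / (r_half[-n] + r_half[-1]) # mS
  list(area = area, gax = gax)
}

# membrane_params in the internal unit system of the C++ core
mem_internal <- function(params, dt) {
  list(cm = params$c_m,
       gna = params$g_na * 1000, gk = params$g_k * 1000, gl = params$g_l * 1000,
       ena = params$e_na, ek = params$e_k, el = params$e_l,
       vt = params$v_t, phi = temperature_factor(params))
}

#' Integrate a single cable
#'
#' Low-level driver for one (possibly passive) cable of arbitrary segment
#' geometry with constant injected currents. Used for validation against
#' closed-form passive solutions and for single-neuron experiments.
#'
#' @param diameters,lengths per-segment geometry \[um\]
#' @param params a [membrane_params()]; set `g_na`/`g_k` to zero (or use
#'   `active = FALSE`) for a passive cable
#' @param dt time step \[ms\]
#' @param duration simulated time \[ms\]
#' @param i_inj constant injected current per segment \[nA\]
#' @param v0 initial (uniform) potential \[mV\]
#' @param active include the voltage-gated Na/K currents
#' @param record_segments segment indices whose potential is recorded
#' @param record_every record every k-th step
#' @return list with `t` \[ms\], voltage trace matrix `v` (segments x time),
#'   final state `v_final`, `m`, `h`, `n`
#' @export
run_cable <- function(diameters, lengths, params = membrane_params(),
                      dt = 0.1, duration = 100, i_inj = NULL, v0 = params$e_l,
                      active = TRUE, record_segments = NULL, record_every = 1) {
  stopifnot(length(diameters) == length(lengths), dt > 0, duration > 0)
  n <- length(diameters)
  if (is.null(i_inj)) i_inj <- numeric(n)
  stopifnot(length(i_inj) == n)
  if (is.null(record_segments)) record_segments <- seq_len(n)
  d_cm <- diameters * 1e-4
  l_cm <- lengths * 1e-4
  area <- pi * d_cm * l_cm
  r_half <- 4 * params$r_a * (l_cm / 2) / (pi * d_cm^2)
  gax <- if (n > 1) 1000 / (r_half[-n] + r_half[-1]) else numeric(0)
  mem <- mem_internal(params, dt)
  if (!active) { mem$gna <- 0; mem$gk <- 0 }
  res <- run_cable_cpp(area, gax, mem, dt, as.integer(round(duration / dt)),
                       i_inj, v0, active, as.integer(record_segments - 1L),
                       as.integer(record_every))
  rownames(res$v) <- record_segments
  res
}
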