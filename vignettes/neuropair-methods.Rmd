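---
title: "neuropair: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{neuropair: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`neuropair` is a self-contained pipeline for studying synaptic transmission
between *pairs* of neurons, the configuration produced when two cells grow
their axons toward each other through a narrow microchannel over a
microelectrode array. The package covers four stages: (1) a mechanistic
two-neuron simulator, (2) reduction of spike trains to six summary
statistics, (3) identification of coupled pairs by transfer entropy, and
(4) amortized Bayesian inference of the nine free biophysical parameters,
with downstream comparisons of inferred parameters across experimental
conditions. Everything runs on synthetic data; no recordings are required.

# The biophysical model

## Morphology and geometry

Each neuron is a ball-and-stick cable: one cylindrical soma segment (10 um
long, 10 um diameter) followed by 100 axonal segments of 19.9 um, all
sharing one diameter $d \in [0.2, 5]$ um. The presynaptic cell spans
$z = 0$–$2000$ um; the postsynaptic cell is shifted by 1000 um
($z = 1000$–$3000$ um), mimicking two somata at opposite channel ends with
overlapping axons. Note the axon's 100 segments of 19.9 um span 1990 um;
the geometry section's z-extents are treated as authoritative and the
nominal 2000 um axon length is realized as soma end + 1990 um.

## Membrane dynamics

Per segment $n$, the discretized cable equation couples the membrane
potential to its axial neighbors through the half-segment series axial
resistance $4 r_a (L/2) / (\pi d^2)$ and balances capacitive, ionic, and
point (synaptic) currents:

$$ c_m \frac{dV_n}{dt} \; = \; \frac{d}{4 r_a l^2}\left(V_{n-1} - 2 V_n +
V_{n+1}\right) + \frac{I_{\mathrm{spont}} + I_{\mathrm{syn}}}{\pi d l} -
\sum_{\mathrm{ion}} i_{\mathrm{ion}}(V_n, t), $$

with sealed ends. Ionic currents follow the Hodgkin–Huxley formalism with
Traub-style rate functions shifted by a global voltage offset
$V_T = -30.4$ mV: $i_{Na} = g_{Na} m^3 h (V - E_{Na})$,
$i_K = g_K n^4 (V - E_K)$, $i_L = g_L (V - E_L)$. Gating rates with
removable singularities (terms $x/(e^{x/a} - 1)$) are evaluated by their
series near the singular point (continuous to $10^{-6}$ relative). Gating
time constants carry the temperature factor $\phi = 3^{(T - 37)/10}$
evaluated in degrees Celsius (the printed "310 K (37 °C)" only makes
dimensional sense in °C for this exponent); at the default 37 °C,
$\phi = 1$.

The resting state is *not* $E_L = -39.2$ mV exactly: with the standard
channel densities the sodium/potassium window currents pull the rest
potential slightly away from the leak reversal. A silent 200 ms settling
run from $V = E_L$, gating at $x_\infty(E_L)$, absorbs this onset
transient; all reported spike times and traces start after it.

## Numerics

The axial + conductive terms are integrated by Crank–Nicolson (a
tridiagonal solve per neuron per step), gating by the Rush–Larsen
exponential update with voltage-indexed lookup tables (0.025 mV grid,
linear interpolation), and synaptic conductances by the exact
two-exponential recursion of the beta function evaluated at the step
midpoint. The scheme is unconditionally stable at the default
$\Delta t = 0.1$ ms; spike times are refined below $\Delta t$ by linear
interpolation of the threshold crossing (0 mV, 2 ms refractory). Halving
$\Delta t$ moves individual spike times by well under 0.05 ms; over long
periodic trains the (second-order-small) period error accumulates as phase
drift, which is why convergence is asserted on spike latencies rather than
late spikes of a 1 s train.

Numerical failure (a non-finite potential) aborts the run and flags the
result invalid with the offending step and segment; batch runners record
such draws rather than dropping them silently.

## Synapses and spontaneous drive

All inputs are conductance-based with a beta-function time course
normalized so its peak equals the sampled weight $w$ exactly at
$\tau_{peak} = \frac{\tau_1 \tau_2}{\tau_2 - \tau_1}\ln(\tau_2/\tau_1)$.
The profile is symmetric under $\tau_1 \leftrightarrow \tau_2$, so the
printed ordering of the spontaneous-drive constants (0.2/0.4 ms) is
numerically irrelevant. Weights are drawn fresh per activation event from a
normal truncated at zero (the parent mean/SD are the distribution
parameters), modeling probabilistic vesicle release.

Spontaneous activity: each neuron's initial axon segment receives Poisson
events (rate $\lambda \in [5, 100]$ Hz) with weights from
$\mathcal{T}(0.02 d, 0.02 d)$ **uS** — the diameter scaling keeps synaptic
efficacy roughly size-independent because the soma load is constant while
the downstream cable load grows with $d$.

The pair synapse joins the presynaptic segment nearest $z_{syn}$ to the
postsynaptic segment nearest $z_{syn}$, activating both an AMPA component
($\tau_2 = 0.1$, $\tau_1 = 0.3$ ms) and an NMDA component ($\tau_2 = 10$,
$\tau_1 = 30$ ms), each with its own freshly sampled weight, whenever the
presynaptic trigger segment crosses 0 mV upward (2 ms refractory, no added
delay). No voltage-dependent magnesium block is modeled.

**Units of the pair-synapse weights.** The weight-distribution parameters
($\mu_{AMPA} \in [0, 0.002]$ etc.) are interpreted in **mS**, following the
model description's explicit statement that the synaptic conductance is
measured in millisiemens. This is a consequential choice: read in uS, the
entire prior box produces peak conductances 10–100x below the local input
conductance of the postsynaptic axon, the synapse is electrically inert,
and none of the documented phenomenology (graded saturating dose–response
of the postsynaptic spike probability, stochastic transmission,
TE-detectable coupling) can occur. Read in mS, the truncated-normal weight
distribution straddles the local spike threshold — which scales roughly as
$d_{post}^{3/2}$, from ~0.008 uS at $d = 0.2$ um to ~0.4 uS at $d = 5$ um —
so transmission is probabilistic per event, rises with $\mu_{AMPA}$, and
saturates, exactly the reported behavior. The spontaneous-drive weights
stay in uS as printed ("0.02 uS/um").

## Extracellular electrodes

Two point electrodes at $(0,0,60)$ and $(0,0,1060)$ um read the summed
line-source potential of every segment's transmembrane current in a
homogeneous medium ($\sigma = 0.3$ S/m). Because the electrodes lie on the
very axis both cables occupy, the textbook line-source kernel is singular
there; as in LFPy, the radial distance is clamped to the segment radius, so
an on-axis electrode reads the potential at the membrane surface. The
far-field kernel converges to the point-source $I/(4\pi\sigma r)$ (verified
to 0.1%). Transmembrane current is computed as net axial inflow, which sums
to zero over each cell as charge conservation requires.

# Summary statistics

Six observables describe one pair: somatic firing rates $f_{pre},
f_{post}$ (spike count / duration); conduction speeds $v_{pre}, v_{post}$
from the mean latency of matched spikes between $z = 200$ and
$z_{syn} - 100$ (pre) and between $z_{syn} + 100$ and $z = 3000$ (post),
divided into the detector separation (forward-propagating only); the
coupling lag, defined as the source–target delay maximizing bivariate
transfer entropy; and the postsynaptic spike probability $p_{syn}$, the
fraction of presynaptic spikes followed by a postsynaptic spike within
$[lag - \Delta t, lag + \Delta t]$, each postsynaptic spike counted at most
once and the ratio capped at 1. $\Delta t$ defaults to 0.5 ms for
simulated pairs and 1 ms for point-process ("experimental-style") pairs.
Spike matching across sites maximizes the number of order-preserving
forward pairs with latency <= 30 ms and, among maximal matchings, minimizes
the total latency (dynamic program); 30 ms comfortably bounds the slowest
plausible propagation over <= 1.8 mm.

A summary vector with any undefined component, or whose pre/post
interaction is not TE-significant, is flagged invalid and rejected upstream
(never encoded as sentinel values).

# Transfer entropy

Spike trains are binned at 1 ms into binary occupancy series (the analysis
reports integer-millisecond lags, which fixes the resolution). Transfer
entropy is the plug-in conditional mutual information
$I(X_t; Y_{t-\delta} \mid X_{t-1}^{(k)})$ with one bin of source history;
the multivariate variant additionally conditions on one past bin of each
conditioning series and reduces exactly to the bivariate one for an empty
set. No bias correction is applied: significance comes from surrogates
that share the estimator's bias.

The lag scan covers $\delta = 1..10$ ms and target histories $k = 1..5$ ms
(10 ms in the multivariate stage). Because the reported statistic is a
*maximum* over ~50 candidate embeddings, surrogate testing at the selected
embedding alone is badly anticalibrated (we measured 37% false positives at
$\alpha = 0.05$). The package therefore uses a maximum-statistic test:
every surrogate — a uniformly random circular shift of the source by at
least 10 ms, which preserves the source's autocorrelation and bin count
exactly — undergoes the identical scan, and
$p = (1 + \#\{\max TE_{surr} \ge \max TE_{obs}\}) / (1 + n_{perm})$. This
restores calibration (2–9% empirical rejection under the null) without
costing power on genuine couplings. All embeddings in one scan share a
common valid-sample range, making the maxima exchangeable.

Pair identification runs the bivariate scan test over all directed pairs,
applies Benjamini–Hochberg at $\alpha = 0.05$ across the batch, then
re-tests survivors with multivariate TE (source lag fixed at the stage-1
maximizer, target history searched to 10 ms, conditioning on the other
significant sources of the same target) and corrects again. Since the
add-one permutation p-value cannot fall below $1/(n_{perm}+1)$, BH can only
reject when $n_{perm} > n_{pairs}/\alpha$; for more than a handful of
units, raise `n_perm` accordingly.

# Simulation-based inference

The posterior over the nine pair parameters given the six summary
statistics is amortized with a mixture density network: two tanh hidden
layers of 64 units, 10 diagonal-Gaussian components, trained by negative
log-likelihood with Adam (defaults, batch 256) and early stopping on a 10%
validation split (patience 20). The architecture is the smallest that
solves a linear-Gaussian toy problem to 0.05 in the posterior mean;
depth/width/components are package choices, not constrained by the source
material. Gradients are hand-derived and checked against finite
differences in the test suite.

Two fixed transformations precede the z-scoring. The firing rates pass
through `log1p` (they are heavy-tailed: NMDA-dominated prior draws fire at
hundreds of Hz), which stabilizes the conditioning features. More
consequentially, the *parameters* are mapped through the elementwise logit
of their position in the prior box, so the density estimator lives on all
of $\mathbb{R}^9$. Fitting Gaussian mixtures directly on the bounded box
systematically underweights mass near the bounds — a flat, prior-like
conditional (typical for the weakly identified weight parameters) gets
Gaussian tails where it should have edge mass — which we observed as
U-shaped simulation-based-calibration ranks ($\chi^2$ p ≈ 0) and 75–80%
coverage of nominally 95% diameter intervals. In logit space a uniform
marginal is approximately logistic and well represented; with the same
training data the SBC ranks become uniform and the coverage nominal.
Samples map back strictly inside the box, so no posterior mass leaks out
(the rejection step the bounded-space design needed becomes a no-op, and
the reported acceptance fraction is identically 1). Densities are reported
on the natural parameter scale via the change-of-variables Jacobian.

Training data are prior draws pushed through the simulator; only draws
whose pre-to-post transfer entropy is significant at $\alpha = 0.05$ enter
training (uncoupled or undefined draws are counted as attrition, never
silently dropped). The reference configuration at publication scale is
122,000 simulations of 10 s; the package's desk-scale default — used by the
test suite — is 2,000 simulations of 5 s, the lower end of the sanctioned
range, chosen to keep the full suite within a CI-scale time budget. About
three quarters of prior draws pass the filter in this regime.

The MAP estimate draws 10,000 posterior samples, takes the 200 with the
highest density, and runs 100 monotone gradient-ascent steps from each
(initial step 0.01 in standardized units, per-start backtracking: a step
that lowers the density is rejected and the step size halved — a fixed
step oscillates hopelessly on the sharp, anisotropic modes of a fitted
mixture). The mode is defined in the unconstrained (logit)
parameterization: on the natural scale the Jacobian creates integrable
density spikes at the box boundary, so a natural-scale argmax would chase
representation artifacts rather than posterior mass (the convention
matches how Stan reports modes of constrained parameters). Because every
accepted step improves the density, the reported value never falls below
any initializing sample.

Calibration is monitored two ways: credible-interval coverage for the axon
diameters (the sharpest parameters, dominating conduction speed with
$r \approx 0.99$) on held-out simulated observations, and simulation-based
calibration — the rank of the true parameter among posterior samples must
be uniform across held-out observations drawn from the same filtered
simulator distribution.

# Synthetic data

`generate_coupled_point_process()` emulates sorted MEA spike trains of a
coupled pair without biophysics: presynaptic Poisson spikes, postsynaptic
baseline Poisson spikes plus lagged, jittered, probabilistic copies of the
presynaptic ones, rounded to 0.1 ms (spike-sorter resolution) with spikes
closer than 1 ms merged. Defaults (5 Hz presynaptic, 2 Hz baseline,
transmission 0.4, lag 4 ms, jitter 0.3 ms) mirror sparse culture activity
with the few-millisecond synaptic delay band reported for microchannel
pairs. What it deliberately lacks: conduction information (velocities are
undefined for point processes), bursting, waveform noise, and sorting
errors.

`generate_condition_shift()` builds matched pre/post-stimulation
populations: "before" pairs scatter around a base parameter vector (5% of
each prior range, truncated to the box), "after" pairs reuse identical
per-pair parameters and simulation seeds with named multiplicative shifts
(e.g. `mu_ampa = 1.5` for the +50% AMPA-weight change emulating synaptic
potentiation). A zero shift reproduces "before" bit-for-bit, giving an
exact null. The base used in the acceptance tests ($d_{post} = 4.8$ um,
$\mu_{AMPA} = 3 \cdot 10^{-4}$ mS) sits on the steep flank of the
dose–response curve where the weight distribution straddles the spike
threshold — the only region where a weight change is observable at all;
most synapses weak, consistent with the potentiation narrative the shift
emulates.

# Condition comparisons

`compare_conditions()` applies the two-sided two-sample KS test per
parameter (or per summary statistic) with BH adjustment across the tested
columns, reporting the median shift and each side's sample skewness; the
skewness accompanies the KS result as a descriptive, never as the test
itself. For three or more conditions, `kruskal_dunn()` provides the
Kruskal–Wallis omnibus test followed by Dunn's pairwise rank comparisons
(tie-corrected, BH-adjusted). KL divergence between binned distributions
uses 20 bins over the pooled range with additive smoothing of $10^{-6}$ of
the total mass per bin.

# Known limitations

* Dendrites, multiple synaptic contacts, magnesium block, short-term
  plasticity, and channel noise are out of scope; the nine-parameter model
  absorbs any such effects into its synaptic parameters.
* The NMDA upper prior range (0.2 uS equivalent) produces sustained
  depolarization and high postsynaptic rates in part of the prior box;
  these draws are legitimate model behavior and are retained.
* Posterior quality is limited by the desk-scale training set; the
  publication-scale configuration is a documented setting, not a test
  requirement.
* The weight spreads ($\sigma_{AMPA}$, $\sigma_{NMDA}$) and, in the
  saturated regime, $\mu_{AMPA}$ and $\lambda_{post}$ are only weakly
  identified by the six summary statistics: their posteriors stay close to
  the prior. A calibrated estimator therefore cannot *contract* them —
  its posterior standard deviation fluctuates around the prior's — and
  only the identified parameters (diameters, presynaptic rate, NMDA mean,
  synapse position) show genuine contraction.
* Traces are serialized as CSV/JSON rather than HDF5 (no HDF5 R binding in
  the supported environment), and full per-segment voltage recording of
  long simulations is memory-hungry — record sites, not cables, for runs
  beyond a few seconds.
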