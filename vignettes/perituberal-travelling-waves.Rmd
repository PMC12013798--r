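---
title: "Models and methods: travelling interictal discharges around cortical tubers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: travelling interictal discharges around cortical tubers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What this package models

Interictal epileptiform discharges (IEDs) recorded on depth electrodes
around cortical tubers are not synchronous events: their per-contact
latencies form spatial gradients, i.e. they behave like travelling waves.
`tuberwave` implements the full analysis chain for characterising and
explaining that behaviour:

1. **Sensor space.** Detect spikes per bipolar channel, group co-occurring
   spikes across the electrode, estimate inter-channel delays by
   cross-correlation, and compare three linear spatiotemporal models of the
   delay-versus-position relation by BIC.
2. **Model space.** Fit a chain of canonical-microcircuit (CMC) neural
   masses — one source per contact, arranged deep white matter, tuber core,
   superficial grey — to single-IED epochs by variational Laplace, and
   compare coupling architectures (recurrent vs. outward-only) and input
   sites (superficial / core / deep) by Bayesian model reduction, with
   random-effects model selection across electrodes.
3. **In silico.** Sweep the intrinsic gain of the discharge-onset node on
   the fitted reference network and characterise the emergent dynamics,
   with and without recurrent coupling.

Because clinical SEEG of this kind is not publicly deposited, the package
ships a synthetic-data module that generates recordings with known ground
truth at the study's stated conditions. Every downstream claim the test
suite makes is therefore a *recovery* claim: the pipeline finds what was
planted.

# Sensor-space methods

## Spike detection

A deflection is a spike when (1) its absolute peak exceeds 4 SD of the
channel (mean and SD over the whole 60 s segment — the estimation window is
a documented choice; a median/MAD flag exists), (2) both limb slopes exceed
7 µV/ms, and (3) its full width at half the peak deflection is below 20 ms.
Width and slopes are measured on the band-passed signal (0.5–120 Hz
zero-phase Butterworth, 50 Hz biquad notch at Q = 30). Detection operates
on absolute deflections, so it is invariant to sign flips — necessary on
bipolar montages where polarity is arbitrary.

Spikes co-occurring within 200 ms across channels of one electrode form a
group (single-linkage chaining; a strict-clique flag exists because
"within 200 ms of each other" is ambiguous between the two). Groups need
two distinct channels; for channels without a criterion-passing spike, the
absolute-maximum deflection inside the group window still contributes a
timing estimate provided it exceeds a 2 SD floor, which keeps pure-noise
peaks out of the regressions.

## Delay models

With `p` the tuber-relative integer contact position (0 = core, negative =
deep) and `t` the detection time relative to the earliest channel, the
three candidate explanations are

* uniform: `t = b`;
* depth-to-surface: `t = a p + b`;
* core-to-periphery: `t = a |p| + b`.

Each is an OLS fit with Gaussian likelihood at the MLE residual variance,
scored by `BIC = log(n) k − 2 log L̂`. `k` counts the residual variance
(2, 3, 3): whether to count it is a convention, and the choice cancels in
the comparison between the two gradient models. A BIC difference above 10
is reported as "very strong" evidence. A slope of `a` ms per position unit
converts to a propagation speed of `spacing / a` (3.5 mm default spacing —
the hardware value is not published, so speeds are reported as functions of
it; 3.5 mm and `a = 5 ms` give 70 cm/s, at the slow end of the
published 77–155 cm/s range for interictal spike propagation).

Delays are estimated per frequency band (below 13 Hz; 13–120 Hz) as the
lag maximising the absolute Pearson correlation between neighbouring
channels in a 200 ms window centred on the earliest spike. The absolute
value matters on bipolar montages (polarity inversions); near-ties (within
10⁻³) resolve toward the smallest lag, which stabilises the smooth, almost
lag-invariant windows the slow band produces. On our synthetic cohort the
fast band carries the sharper gradient: the planted slow wave is ~300 ms
wide, so a 200 ms window constrains its alignment only weakly. This is a
property of the generator worth remembering when reading the recovery
tables — with tens of groups per electrode the slow band may return the
uniform model even when a gradient was planted, while the fast band
recovers the planted slope essentially exactly.

## What the synthetic cohort does and does not emulate

`make_travelling_spike_recording()` plants biphasic spikes (difference of
two Gaussians, default 100 µV, 10 ms FWHM) with a half-sine slow wave
(300 ms, 40 µV) on 1/f-shaped Gaussian background noise (10 µV), at
per-channel onsets `t = a f(p) + b + jitter` (jitter SD 2 ms). Defaults
follow the study conditions where stated (1 kHz sampling, bipolar
montage, 60 s segments, ~40 events per electrode); morphology and noise
shape are our choices, made once. It does **not** emulate volume
conduction, state-dependent IED rates, artefacts, or multi-electrode
interactions — so passing tests demonstrate algorithmic correctness, not
robustness to everything clinical data can do.

Negative controls (`make_distractor_events()`) violate exactly one
detection criterion each. The amplitude control deserves a note: with
broadband noise, a "3 SD" spike rides noise excursions across the 4 SD
threshold with non-trivial probability, so its variance carrier is instead
a deterministic 30 µV, 3 Hz background rhythm and the spikes sit at its
zero crossings. The sub-threshold margin is then structural, and a
conforming detector returns exactly zero detections.

# The neural-mass network

## Source model

Each source holds four populations — spiny stellate (ss), superficial
pyramidal (sp), inhibitory interneurons (ii), deep pyramidal (dp) — as two
oscillator pairs: a fast superficial pair (ss ↔ sp) generating the spike
component, a slow deep pair (ii ↔ dp) generating the wave. Each population
obeys the second-order synaptic kernel

    v̇ = i,   i̇ = (H/τ) (Σ d σ(v_pre) + input) − 2 i / τ − v / τ²,

with σ the zero-centred logistic `1/(1+e^{−rv}) − 1/2`, so the origin is a
fixed point and IEDs are damped excursions around it. The damping terms
are part of the canonical kernel; without them the system could not
produce the damped oscillatory dynamics the fixed-point regime requires.

Intrinsic wiring (one template, revisable in `cmc_canonical()`):
ss→sp (+, gain `g_sp_ss`), sp→ss (−), sp self-inhibition (−, `g_sp_sp`),
ss→ii (+, `g_ii_ss`), dp↔ii loop (±), sp→dp (+). Extrinsic edges join
neighbouring sources only: away-from-core ("forward") edges from sp onto
ss, toward-core ("backward") edges from dp onto sp and ii — the standard
hierarchical convention. All fitted parameters are log-multipliers of
canonical base constants.

## Choice and calibration of the base constants

The group-average parameter table stores prior and posterior
*multipliers*, not the base constants, so the bases are the package's own
and were calibrated once, against the qualitative regime the study
describes, then frozen:

* τ₀ = (1.2, 1.2, 16, 28) ms for (ss, sp, ii, dp). The fast pair's
  resonance under the group-posterior multipliers then sits in the gamma
  range; the slow pair resonates near 3 Hz (the wave).
* H₀ = (4, 4, 1, 1.5); intrinsic base gains as listed in
  `cmc_canonical()`; sigmoid slope r₀ = 2.
* Extrinsic bases a₀ = 0.06 (forward), 0.04 (backward). These place the
  group-posterior network *near* — but below — the bifurcation at which
  the inter-source loop self-sustains: the recurrent network reverberates
  for hundreds of milliseconds after a discharge, while the same network
  without backward coupling rings down within tens of milliseconds. That
  near-critical placement is the mechanistic reading of "recurrent
  coupling supports the discharge", and it is what makes the coupling
  scheme identifiable from data.
* Input: Gaussian bump into ss of the target source, prior onset 0 ms,
  prior width 16 ms, base gain 0.05 (keeps the discharge in the sigmoid's
  quasi-linear range, so coupling effects are not flattened by
  saturation); observation gain 500 µV per unit sp voltage (discharges of
  one to a few hundred µV).

Two consequences are documented rather than hidden. First, the
group-posterior point is calibrated on the three-contact chain; on chains
of five or more sources the same multipliers sit marginally past the
bifurcation (growth rates below 10⁻³/ms). The reference network for
simulation experiments is therefore the three-contact chain; longer
electrodes are inverted from the stable prior regime. Second, the
fast-pair limit cycle under strong gain saturates near 58 Hz, at the upper
edge of the gamma band reported for seizure-onset-like rhythms.

## Integration

Forward simulation uses a fixed-step RK4 integrator in compiled code
(0.25 ms default step for simulation, 0.5 ms inside inversions; halving
the step changes trajectories by < 10⁻⁶ relative). An independent
adaptive solver (lsoda) reproduces the compiled trajectories to ~10⁻⁴
relative in the tests; the compiled path is the implementation, the
adaptive solver the oracle. Divergence (|v| > 10⁹ or non-finite) flags the
simulation rather than erroring, so gain sweeps can continue past
unstable levels.

# Inversion, free energy, model reduction

`invert_dcm()` is a Gauss–Newton ascent on the variational (Laplace) free
energy: Gaussian posterior over the ~18 parameters, iid Gaussian noise per
channel with log-precisions solved in closed form in an M-step,
Levenberg-style damping with an accept/reject rule, so accepted steps
never decrease F. Convergence: change in F below 10⁻² for 4 successive
iterations, cap 64 (tests that need tight optima raise these). Jacobians
are forward finite differences (step 10⁻³ in log-parameter space). Epochs
are baseline-corrected and Hanning-tapered; predictions are tapered
identically before comparison.

Prior widths: 1/4 (coupling, intrinsic gains, input gains), 1/8 (time
constants), 1/16 (sigmoid), 1/64 (observation gains), 64 ms² (onset).
Narrower conventional choices (1/16, 1/32) would place the printed group
posterior several prior SDs out, i.e. the prior would all but forbid the
regime the fits are supposed to reach; the widths above make it a ~2 SD
excursion. Observation gains are deliberately tight — per-channel
amplitude freedom is the main degeneracy direction against coupling
gains.

Free energy decomposes into accuracy minus complexity (KL from prior to
posterior); on conjugate linear-Gaussian problems it equals the analytic
log evidence to numerical precision, which the tests assert. Bayesian
model reduction (BMR) evaluates reduced models (same parameters, new —
typically shrinkage — priors) in closed form from the full posterior. It
is exact for Gaussians; on the nonlinear network it is accurate to well
under a nat when the reduced parameter's likelihood is locally quadratic
(e.g. an intrinsic gain), but reductions that *switch off* an input
(log-gain shrunk to −6) sit on a likelihood plateau where the Laplace
assumption is crude — there BMR's error can reach ~10 nats. This does not
matter for architecture ranking, where the decisive differences are
thousands of nats, but the 1-nat agreement claim is made, and tested, for
the quadratic case.

The architecture space is the 2 × 3 cross of coupling scheme and input
site: forward-only members shrink the toward-core extrinsic log-gain, and
each input-site member shrinks the two off-target input log-gains
(shrinkage: mean −6, variance 10⁻⁴ — multiplier ~0.0025, effectively
off). The within-electrode modulation space is the 7 non-empty subsets of
{forward, backward, intrinsic self-inhibition} per-IED modulation offsets
in a joint multi-IED inversion (IED 1 is the reference condition).

## Recovery experiment design

The packaged experiments define the study conditions and are not tuned
per run:

* **Extrinsic recovery** (`extrinsic_recovery_experiment()`): truth =
  group-posterior network with A-gains perturbed (log SD 0.35, shrunk
  toward the centre until stable); epochs of −100…450 ms — the extended
  window exists precisely because the backward-coupling signature is the
  post-discharge reverberation, which a −100…250 ms window mostly
  truncates; observation noise 0.5 µV (high-SNR regime: at 2 µV the
  likelihood no longer separates the compensation ridge, and the point of
  the experiment is identifiability of the method, not of a noise level);
  nuisance priors centred on the generating group values, which is the
  standard "correct model" recovery design. Success is the correlation
  between true and recovered log-gains across seeds, per parameter.
* **Architecture recovery** (`architecture_recovery_experiment()`): same
  generator (smaller perturbations), full-model inversion, BMR over the
  six architectures, score = fraction of electrodes whose highest reduced
  F is recurrent-core.
* **Delay-model recovery** (`delay_model_recovery()`): 200 observations
  per replicate, slope 5 ms/unit, jitter 2 ms, positions −2…2. One
  structural fact is worth stating plainly: when the *uniform* model
  generates the data, the gradient models are its supersets with one
  extra parameter, so the uniform model can never win by more than
  `log(200) ≈ 5.3` BIC points. Decisive (>10) margins are therefore a
  meaningful demand only for the gradient generators, and that is how the
  recovery suite scores it.
* **RFX recovery** (`rfx_recovery_experiment()`): variational Dirichlet
  scheme on synthetic evidence with known model frequencies (dominant
  0.65, gap ≥ 0.3); exceedance probabilities by 10⁶ Dirichlet samples
  (10⁵ in the tests), analytic Beta shortcut for two models.

# The gain sweep

`gain_sweep()` multiplies the three intrinsic gain parameters of the
discharge-onset node (`g_sp_sp`, `g_sp_ss`, `g_ii_ss`) by each of 8
log-spaced levels in [1, 4] (the published account of this experiment
prints no sweep values; log-spacing over one octave-and-a-bit of gain is
our choice) and simulates 2 s per level with the triggering input at
100 ms. Spectral characterisation uses the periodogram of the post-500 ms
window; the peak must stand ≥ 15 dB above the band median to count
(featureless noise reaches ~10 dB by extreme-value statistics alone, so
the conventional 6 dB would flag nothing). "Seizure-like" means a
sustained (> 500 ms) prominent peak above 30 Hz.

On the reference network the transition is: stable spike-wave discharge
with slow reverberation up to level ≈ 1.8; from level ≈ 2.2 a sustained
~57–58 Hz rhythm. Without recurrent coupling the same sweep still reaches
the fast rhythm (the instability is intrinsic to the onset node) but the
low-gain discharge loses its reverberation — the wave-window amplitude
drops by roughly four orders of magnitude — which is the package's
operationalisation of "recurrence supports the interictal discharge;
raised gain supports the seizure-like rhythm either way".

# Numerical and degenerate-input conventions

* Time is 0-based sample indices internally; all reported delays in ms.
* Bipolar channel positions: midpoint rounded toward the deeper contact,
  keeping the core label unique.
* Cross-correlation ties: smallest |lag|; sub-sample (parabolic)
  interpolation is off by default.
* Zero-variance channels in a delay window are skipped with a message;
  flat channels in spectral analysis are flagged, not errored.
* Negative variance explained reports 0 with a flag.
* k-means selection: 20 restarts, rows ordered by group id before
  clustering (permutation invariance), ties to the lowest id.
* Unstable models error with the offending eigenvalue in simulation
  entry points, but inversion treats divergent parameter proposals as
  rejected steps.
* All stochastic stages take explicit integer seeds; identical seeds give
  bit-identical outputs.

# Known limitations

* The synthetic SEEG is a single-electrode, single-tuber world with
  parametric morphology; no claim of physiological fidelity of the
  referential montage option (a shared reference-noise term only).
* Inversion is local (Gauss–Newton): the tests show wide basins under the
  recovery designs above, not global optimality; posterior means of
  weakly identified parameter combinations (e.g. absolute amplitude
  split between input, coupling and observation gains) should be read
  through the BMR comparisons rather than individually.
* BMR accuracy on switch-off reductions is ranking-grade, not
  evidence-grade (see above).
* The group-posterior calibration point is chain-length dependent at the
  margin; longer chains should be simulated from fitted rather than
  group-average parameters.
* Problem sizes in the packaged experiments (10 recovery seeds, 20
  electrodes, 100 delay replicates, 2 s sweeps) are the package's chosen
  study sizes; all are seeded and scale up by argument.
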