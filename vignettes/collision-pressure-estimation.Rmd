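---
title: "Estimating vocal fold collision pressure from glottal area waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating vocal fold collision pressure from glottal area waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonopress)
```

## The problem

During voiced speech the vocal folds collide roughly a hundred times per
second. The mechanical stress of those collisions is the leading candidate
mechanism for phonotraumatic lesions, yet it is one of the hardest
quantities in voice science to measure: a sensor must sit inside the
glottis of a phonating speaker, in the exact inferior–superior plane where
contact occurs (the *strike zone*). When such a measurement succeeds, the
intraglottal pressure waveform shows three signatures per cycle: an
impulsive peak at the start of the closed phase (tissue collision), a
more-rounded peak during the open phase (aerodynamic pressure build-up),
and a minimum near zero just before the next impulse.

Because direct measurement is impractical outside heroic experiments,
model-based estimators derive collision pressure from quantities that are
routine to acquire — above all the glottal area waveform extracted from
high-speed videoendoscopy (2000 frames/s here, with sensor channels at
8000 Hz). `phonopress` implements two such estimators together with the
forward model, a synthetic-recording generator, and the signal-processing
procedures needed to validate them end to end by parameter recovery:
because the generator's ground truth is known exactly, every stage of the
chain can be tested without any recorded data.

## The forward model

The simulator (`bcm_params()`, `bcm_simulate()`) is the classic three-mass
body-cover model: each fold is an upper and a lower cover mass riding on a
body mass, coupled by springs and dampers. Displacements are medial
positions relative to the glottal midline; only one fold is integrated and
the other is its mirror image (the symmetric condition), or a rigid plane
in the hemilarynx configuration (`symmetric = FALSE`).

Three constitutive choices close the model:

* **Driving pressure.** Quasi-steady Bernoulli flow with the jet pressure
  applied to the lower mass up to the minimum-diameter detachment point
  and zero supraglottal recovery: `p = P_sub (1 - (a_min/a_l)^2)` while
  the lower margin is open, the full stagnation pressure when the flow is
  blocked above, and zero when the lower margin itself is closed. This is
  the simplest standard choice and keeps the estimator's process model
  cheap.
* **Collision law.** A one-sided spring engaging when a mass crosses the
  contact plane, with cubic hardening in the penetration normalized by the
  mass thickness: `F = k_col d (1 + eta_col (d/T)^2)`. The reported
  collision pressure is the contact force divided by the loaded plate area
  `L_g × T` — the quantity a flush-mounted sensor reports — and is zero
  exactly when the glottis is open.
* **Integration.** Fixed-step 4th-order Runge–Kutta at 1/80000 s,
  decimated to the 8000 Hz output grid. A fixed step makes runs
  bit-reproducible; halving the step changes per-cycle collision peaks by
  well under 1% (tested), so the default step is converged for the
  default regime.

### Muscle activation rules

`rules_to_params()` maps normalized cricothyroid and thyroarytenoid
activations to parameters with the structure of the published rule sets
for low-dimensional fold models: an elongation strain
`eps = G (R a_CT - a_TA)` (`G = 0.2`, `R = 3`), a cover fiber-tension
multiplier `exp(2.2 eps)` applied to the cover and collision springs, an
active body stiffening `1 + 3 a_TA`, length scaling `1 + eps` with
thickness scaling `1/(1 + eps)` (volume conservation, masses unchanged),
and dampings scaled to keep the damping ratios constant. At zero
activation the passive baseline is returned unchanged. The cover exponent
2.2 was set during model construction: with a steeper law the high-`a_CT`
corner of the activation square exceeds its oscillation onset pressure at
9 cm H2O and stops phonating, which contradicts the intended use of the
activation plane.

### Baseline parameters and what "calibrated" means here

The paper-style reference condition — comfortable male phonation — pins
the regime, not the parameters: cycle rate near 125 Hz, mean subglottal
pressure 9 cm H2O, and a peak-collision-to-subglottal ratio near 1:1
(reported values from hemilarynx work span 0.5–3.8). The baseline defaults
(masses 0.025/0.125/0.2 g, cover springs 5.8/58 N/m, body 385 N/m,
collision spring 3.6 × the lower cover spring, 16 mm fold length, 0.15/0.3
mm convergent rest gaps, 2 mm^2 posterior gap) are generic adult-male
values tuned once, while the model was built, so that the mid-activation
operating point reproduces that regime:

```{r sim}
params <- rules_to_params(activations(0.5, 0.5))
sim <- bcm_simulate(params, sim_config(p_sub = cmh2o_to_pa(9),
                                       duration = 0.4))
sim
estimate_f0(sim$area[sim$t > 0.15], sim$fs)
```

The convergent rest posture matters: with a rectangular rest glottis the
jet pressure vanishes identically at equilibrium and the model never
starts. The oscillation onset pressure at this operating point is about
330 Pa (3.4 cm H2O), located by bisection in the tests; below it the
startup transient rings down, above it oscillation is sustained.

## The synthetic-recording generator

`generate_recording()` emulates the acquisition chain of an in vivo
probe session so that every downstream procedure sees data with the right
failure modes:

* channels IGP (collision + jet pressure at the sensor), SGP (subglottal
  pressure with a small flow-coupled ripple), MIC (scaled flow
  derivative), EGG and ACC (stylized contact and band-limited
  flow-derivative proxies — transduction physics is deliberately not
  modeled; these channels exist so co-location and corroboration logic is
  testable);
* linear voltage coding with the slopes 1.596 and 1.722 (cm H2O)/V for
  the two pressure sensors, DC offsets of −1.3 and +3.4 cm H2O, a slow
  sinusoidal drift (0.5 cm H2O amplitude, 20 s period by default — drift
  is reported in probe recordings but its magnitude is not, so this is a
  package choice), Gaussian voltage noise, and 16-bit quantization with
  the full-scale range kept in a JSON side-car (WAV normalization
  destroys physical units);
* a silence lead-in for the silence-period zeroing procedure;
* the glottal area at 2000 frames/s (exactly one quarter of the signal
  rate, sharing the time origin), scaled down by a constant probe
  occlusion fraction and coded in pixel units with the 4.4 mm probe-tip
  width as the imaging ruler;
* a truth block (driving pressure, per-cycle collision peaks and times,
  cycle rate, activations, posterior gap, occlusion, seed).

A seed is mandatory; two calls with the same seed are identical to the
bit. What the generator does **not** emulate is as important for reading
the test results: no left–right asymmetry, no cycle-to-cycle tissue
variability, no motion of the probe, no segmentation errors beyond
additive area noise, and proxies instead of physical EGG/ACC/MIC
transduction. Passing recovery tests on these data therefore demonstrates
internal consistency of the estimators under the model's own physics, not
performance on recorded humans.

`generate_stylized_igp()` is the second, purely phenomenological
generator: a raised-cosine impulse at the start of the closed phase, a
wider raised-cosine aerodynamic hump centered in the open phase, and a
configurable pre-impulse trough, with period jitter and noise. Its three
"negative controls" (no impulse; no rounded peak; raised trough) are what
the strike-zone classifier must reject, and its geometry was chosen so
the controls fail the intended criterion with margin at the classifier's
default thresholds.

## Measurement procedures

The `signals` functions mirror standard practice. Hydrostatic calibration
is ordinary least squares of pressure (= depth in cm) on voltage;
noiseless collinear points give the slope to machine precision with
R² = 1 exactly. Subglottal zero is the mean over a pre-phonatory silence
window (≥ 50 ms); intraglottal zero anchors the most negative per-cycle
trough to zero, ties broken by first occurrence (the offset is identical
either way). Cycle detection finds local maxima above an adaptive
threshold, greedily thinned to a 0.6-period minimum spacing, after the
period is fixed by the f0 estimator. The f0 estimator is a normalized
autocorrelation over the full segment, searched in 70–300 Hz with
parabolic peak interpolation and a 0.3 voicing threshold; below threshold
it reports *unvoiced* (`NA`), which is deliberately not an error. SPL is
`20 log10(rms / 20 µPa)`.

The strike-zone classifier evaluates each cycle in a window anchored 0.2
periods before the impulse: (c1) the impulse's half-height width must be
below 0.25 periods, (c2) a later open-phase peak must be at least twice as
wide with non-negligible prominence, (c3) the pre-impulse trough magnitude
must stay below 10% of the impulse height; the overall verdict requires
all three on 80% of cycles. All thresholds are configurable; the defaults
are conventional, not inferred from any recording. The co-location test
declares two sensors "same site" when their zero-lag correlation reaches
0.9 (amplitude-invariant); distinct waveshapes at a shared cycle rate are
the desired "different" verdict.

## Contact pressure analysis (Hertz route)

The kinematic estimator consumes only edge kinematics. The mid-membranous
edge displacement — either the apex of a parabola constrained through the
anterior/posterior anchor points (`fit_edge_parabola()`), or the
area-derived half-gap — is tracked by a constant-acceleration Kalman
filter (`track_edge_kalman()`; process noise 1e8, chosen so a noiseless
125 Hz sinusoid is reproduced to 0.2% with under 1° of velocity phase
error). During the closed phase the edge is unobservable, so a lumped
contact oscillator continues the motion: mass `m_eff` against the
linearized cylinder-contact stiffness `(pi/2) E* L_contact` gives
`delta(tau) = (v_in/omega) sin(omega tau)`, with the entry velocity taken
from the track at closure onset. Closure itself is detected as runs of at
least three consecutive frames below 5% of the large-area quantile —
shorter dips are smooth passages through the minimum of a non-colliding
cycle, which must (and do) yield zero estimates.

Two pressures are reported per cycle. `p_peak` is the Hertzian peak at the
contact-strip center, `p0 = E* sqrt(delta / 2R)` with
`E* = E/(1 - nu^2)`; this closed form is pinned by an independent
brute-force oracle in the tests (bisection on the line load until the
Hertz half-width matches the geometric interference half-width) and is
monotone in overlap and modulus and decreasing in radius. `p_est` spreads
the same Hertz line load `F' = (pi/2) E* delta` over the loaded plate
height `T_plate` (2.5 mm): this is the quantity a flat sensor — or the
simulator's plate-averaged collision law — reports, and it is the one
compared per cycle against truth. The distinction matters because the
strip-center peak exceeds the plate average by `2 T_plate / (pi b)`
(about 4× at these overlaps); validating `p0` against a plate-type
reference would build a systematic factor into the comparison.

The material constants are generic (`E = 24.75 kPa`, `nu = 0.5`). The
lumped mass default (`m_eff = 3.5e-6` kg, a cover ribbon of roughly
0.65 mm × 0.65 mm cross-section along the 8 mm contact length) and
`T_plate` were fixed together, as the estimator's calibration, so that
`p_est` is approximately unbiased in the simulator's comfortable-phonation
regime; this mirrors how such estimators are calibrated in practice
(generic constants plus manual adjustment against a known configuration).
On that regime the per-cycle mean absolute percentage error against truth
is below 10% (the acceptance bound is 20%), the estimates double when the
driving pressure doubles, and pooled across driving pressures of 5–18
cm H2O the per-cycle correlation with truth exceeds 0.95. At a single
operating point the per-cycle truth barely varies, so a within-condition
correlation is dominated by estimator noise and is not a meaningful
recovery metric — hence the pooled design.

## Bayesian estimation (Case-I extended Kalman filter)

`run_case1()` estimates, from the calibrated glottal area waveform alone,
the subglottal pressure, posterior gap area, both activations, and the
collision pressure, each with a 95% band (mean ± 1.96 posterior sd — the
convention adopted for "95% confidence intervals"). The augmented state
stacks the six mechanical states with the four parameters; parameters
follow a random walk whose per-step standard deviations
(4 Pa, 4e-9 m², 2e-3) trade tracking speed against steady-state variance.
Jacobians of the simulator transition are central finite differences —
robustness was preferred over hand-derived forms, and the FD transition is
validated against the simulator by construction. The observation is the
scalar area; the filter updates at 2000 Hz with 8 internal RK4 substeps
(1/16000 s, comfortably inside the stability margin of the stiffened
collision dynamics).

Numerical choices that matter:

* **Initial uncertainty.** The initial covariance inflates the parameter
  block (default ×10) to encode "large initial uncertainty"; the
  mechanical state keeps its nominal near-rest uncertainty. Inflating the
  mechanical block as well lets the first linearized updates fling the
  fold into centimeter-scale penetration of the cubic collision spring
  and destroys the run — the parameters, not the fold position, are what
  is actually unknown at onset.
* **Constraints.** Activations are reflected into [0, 1], pressure and
  gap area floored at zero, displacements and velocities clamped to
  generous physical bounds as a safeguard; the covariance is kept
  symmetric PSD by the Joseph-form update, symmetrization, and an
  eigenvalue floor engaged only on detected loss of positivity.
* **Collision-pressure output.** The 2000 Hz grid undersamples the
  1–2 ms collision impulse by about 10%, so the filter also records the
  collision pressure along the predicted mean trajectory at the substep
  rate; `posterior_collision_peaks()` reads per-cycle peaks from that
  track. Its uncertainty band at the observation grid is first-order
  (delta-method) propagation through the collision law; at rest that
  band has zero width by construction (no contact), which is why the
  band-contraction test references the early-transient maximum for this
  one output and the literal t = 0 width for the four parameters.
* **Divergence.** Persistently large normalized innovations (|z| > 8 for
  over 100 ms) flag divergence and return the partial series.

On simulated area data with small observation noise the filter recovers
the 9 cm H2O driving pressure within 10% (truth inside the 95% band),
both activations and the posterior gap, and a peak-collision-to-
subglottal ratio of ~1.0, inside the hemilarynx range 0.5–3.8. Across 20
noisy replicates the 95% band covers the true driving pressure in ≥ 80%
of runs — EKF linearization makes exact nominal coverage unattainable,
which is why the contract is 80%, not 95%. With the oscillation removed
(area replaced by its mean) the posterior still tightens somewhat —
static deflection genuinely carries pressure information in this model —
but stays above half the nominal prior sd, confirming the filter does not
manufacture information from a flat signal.

## Problem sizes

The shipped tests and the acceptance script run the simulator for 0.3–0.5
s segments (40–60 cycles), the filter on 700–1000 frames, 20-replicate
coverage experiments, and 100-seed classifier sweeps; these sizes were
chosen so the full chain exercises every contract while a complete run
stays in the minutes range on a single core.

## Known limitations

* Baseline parameters are generic, not subject-specific; everything
  downstream is conditioned on this one operating regime.
* No vocal tract load, no source–filter interaction, no left–right
  asymmetry, no continuum tissue mechanics, no 3-D contact.
* The EGG/ACC/MIC channels are stylized proxies; analyses that depend on
  their physical transduction are out of scope.
* The estimator validations are inverse-crime experiments (the filter's
  process model is the generator's model); recovery here bounds what is
  possible, not what recorded data will deliver.
* The Hertz route's lumped contact mass is an effective, calibrated
  constant, not a measured tissue property; away from the calibration
  regime `p_est` keeps its ordering properties but its absolute scale
  should be treated as indicative.
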