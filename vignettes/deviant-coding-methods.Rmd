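---
title: "Methods: layer-resolved analysis of sensory deviant encoding"
author: "deviantcoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: layer-resolved analysis of sensory deviant encoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deviantcoding)
```

# The scientific problem

When a repeated tactile stimulus suddenly changes — an oddball or *deviant* —
cortical circuits can respond to the change itself rather than to the absolute
stimulus value. In mouse barrel cortex this has been probed with trains of
seven whisker deflections at 10 Hz in which one deflection deviates in
amplitude by ±5–15% from the preceding baseline deflections. Because the
deviant can be either an increase or a decrease around a near-neutral
baseline, classical stimulus-specific adaptation (which predicts elevated
firing for *any* deviant) is avoided, and one can ask instead whether neurons
carry a *signed* change signal.

The central quantity is the per-neuron **change coefficient**: the mean spike
count per deflection in response to amplitude-increase deviants minus the
mean for amplitude-decrease deviants. A population in which all driven cells
share a positive coefficient (the granular-layer pattern) encodes the current
amplitude; a population with coefficients of both signs (the supragranular
pattern) encodes *change relative to stimulus history*, visible not as a
median shift but as a **broadening** of the coefficient distribution relative
to a surrogate null. Layer 6 corticothalamic cells, though sparsely driven
(~13% stimulus-responsive), encode stimulus amplitude in their integrated
calcium signals; weak optogenetic depolarization of this population shuffles
*which* cells are sensory-driven without changing mean rates, and removes both
the heterogeneous change code and its behavioral benefit.

This package implements that full analysis chain — detection of driven units,
change coefficients, surrogate-null broadening tests, a penalized Poisson GLM,
a ΔF/F calcium pipeline with flyback-artifact correction, and psychometric
behavior analysis — together with synthetic-data generators that plant known
encoding structure, so that every stage is validated against ground truth.

# Data model and conventions

* Times are in seconds. Deflection onsets are train-relative with the first
  deflection at 0; spike times are trial-relative, with the stimulus train
  beginning `pre_window_s` (default 0.5 s) into the trial window, so all
  spike times are non-negative.
* Deflection positions are 0-based. Count windows are half-open,
  `[onset, onset + w)`, with `w = 100` ms by default — the full
  inter-deflection epoch at 10 Hz, matching the span of the driven-unit
  classifier's basis. A shorter phasic window is a parameter, not a code
  change.
* Only the first deviant of a train is analyzed and deflections after it are
  excluded (`excluded` slot of the `CountTensor`), because post-deviant
  deflections are contaminated by the deviant's own history effect.
* Depth-to-layer mapping: L2/3 100–350 µm, L4 350–450, L5 450–650, L6 >650,
  boundaries to the deeper layer. RS/FS split at 0.4 ms trough-to-peak width
  (configurable; the classifier only consumes the resulting label).
* On-disk formats are plain text: CSV tables for trains, spikes, units and
  behavior trials; YAML for configuration; JSON for stage results. Identical
  configuration and seed give byte-identical outputs.

# Stimulus construction and matching

`buildTrain()` produces deflection trains; a deviant requires at least one
preceding baseline deflection (position ≥ 1). Generators draw ephys deviant
positions uniformly from 0-based positions 1–5 and behavioral deviants from
train positions 2–4.

Deviants occur at random positions, so deviant and baseline deflections
differ in adaptation state and count. `histogramMatchPositions()` subsamples
the baseline pool to the deviant set's exact position histogram, and
`matchAmplitudeDistributions()` subsamples two trial sets to equal per-bin
deviant-amplitude histograms (bin width defaulting to 5% of baseline), so
that a remaining contrast reflects stimulus history only. When the increase
and decrease deviant sets are compared directly, both are subsampled to the
per-position minimum. The larger set is always the one subsampled.

# Synthetic data: what is emulated, and what is not

`simulatePopulationSpikes()` draws spikes from an inhomogeneous Poisson
process: a homogeneous background (default 1 Hz) plus, for driven units, a
per-deflection evoked response with expected count
`adaptation(pos) * (response_gain + amplitude_gain * (amp - baseline))` and a
half-cosine response kernel (25 ms wide, 10 ms latency — any phasic kernel
inside the 100 ms window would do; it is configurable). The deviant adds
`(c/2) * sign` spikes *outside* the adaptation factor, so the planted change
coefficient satisfies `E[count | increase] - E[count | decrease] = c` exactly
at every position; this identity is the anchor for all recovery tests.
Defaults encode the layer pattern qualitatively: L4 driven units share
`c = +0.015` spikes/deflection, L2/3 units split evenly between `c = ±0.05`,
L5 and L6 are null, and only L6 carries amplitude gain. The magnitudes are
of the order reported for real supragranular populations (median differences
above ~0.03 spikes/deflection, single-cell effects below 0.1); they are
modelling choices, not claims of fidelity to any recorded animal.

`response_gain = 0.1` spikes/deflection and `base_rate = 1` Hz describe a
sparse, weakly driven cortical unit — the regime in which the matching and
surrogate machinery matters. `adaptation(pos) = 0.9^pos` produces the
repetition adaptation that the position-matching procedures exist to control
for. On weak-laser trials a fraction of L6 units swap driven identity
pairwise ("ensemble shuffle"), preserving the layer's mean rate exactly in
expectation while relabeling which cells respond.

`simulateCountPopulation()` draws per-deflection window counts from the
Poisson marginal implied by the same model (the kernel lies inside the count
window, so marginally the count is Poisson with the evoked mean added to
`base_rate * w`). It exists because the population-scale calibration and
power studies need hundreds of 90-unit populations, where spike times carry
no extra information. A test verifies that both routes recover the same
planted coefficient. It can also plant a *multiplicative* deviation
(`deviation_beta`, a log-link rate ratio) for GLM coverage studies where the
fitted model should be well-specified.

`simulateCalcium()` builds `F = F0(t) * (1 + dff + noise)` with transients
from a double-exponential GCaMP6s kernel (rise 0.18 s, decay 1.5 s —
indicator-literature values), anchored at stimulus onset because the
indicator integrates the train's response; a slow sinusoidal baseline drift;
neuropil traces sharing a scaled population signal; and ~13% driven ROIs by
default. `simulateArtifactStack()` produces small frame stacks in which
laser-on frames brighten every `line_step`-th x-scan line multiplicatively
and add a diffuse offset — the two components the two correction stages
remove. `simulateDetectionBehavior()` is a cumulative-Gaussian observer with
guess and lapse rates, a deviant benefit `δ` on sub-threshold amplitudes with
deviants before 400 ms, impulsive (<50 ms) licks and late deviants planted so
the exclusion rules have work to do.

None of the generators emulate: correlated spike-count noise across neurons,
non-Poisson firing statistics, electrode drift, neuropil contamination of
somatic traces beyond the artifact pathway, or motion artifacts. Passing
tests therefore certify the *statistics*, not robustness to those real-data
features.

# The driven-unit classifier

A unit is phasically driven if either Poisson-GLM criterion holds
(`classifyPhasicDriven()`):

* **Condition i** — offset plus six 16.7 ms boxcar bins spanning the first
  100 ms of the first deflection; driven if ≥2 bin coefficients have Wald
  p < 0.03 and some non-offset coefficient's lower bound
  (estimate − 1·SE) exceeds 0.002. "Six bins" admits several bases; boxcars
  are the simplest consistent choice. The lower-bound reading uses 1 SE by
  default with the CI-bound multiplier behind a parameter, and no
  multiple-comparison correction is applied across the six bins — the
  two-coefficient conjunction already deflates the effective level, and the
  null false-positive rate is checked empirically instead.
* **Condition ii** — the same six bin coefficients *shared* across
  deflections 1–3 (capturing weak but sustained drive), plus one nuisance
  constant per later 100 ms deflection period so that slow within-trial rate
  drifts load on the nuisance terms rather than the shared coefficients.
  Without the nuisance terms the model covers only the shared deflections,
  and a monotone drift inflates the shared coefficients; the paired
  drift-unit test asserts the nuisance variant never produces more false
  positives.

The offset of a GLM fit only on the stimulus window is not identifiable from
six bin means and an intercept; it is identified here from six pre-stimulus
baseline bins covering the 100 ms before the first deflection. Counts are
aggregated over trials before fitting (equivalent for a Poisson likelihood,
and much faster). A unit with no spikes at all is returned as not-driven with
a `degenerate` flag rather than an error.

# Change coefficients and the broadening test

`changeCoefficient()` uses the **mean** (not median) count difference per
unit: per-deflection counts are small integers, where medians degenerate.
`surrogatePopulation()` builds the null by drawing position-matched baseline
deflections from no-deviant trains and splitting them into pseudo-increase
and pseudo-decrease groups with the true group sizes, without replacement
within a draw; each unit's pseudo-coefficient is computed from its own counts
on those deflections, so the null inherits each cell's count variability
exactly as the observed distribution does. Stimulus selections are shared
across units within a draw; since counts are conditionally independent across
units given the stimulus, this is distributionally equivalent to independent
per-unit splits and far cheaper.

`broadeningTest()` compares spread via the interquartile range (75th − 25th
percentile) and the Shannon entropy in bits,
`H(h) = -Σ P(h_i) log2 P(h_i)`, computed on 15 equal-width bins spanning the
pooled observed-plus-surrogate range — entropy differences are only
meaningful on identical bin edges, and a test asserts the sign of ΔH is
stable across 10–30 bins. One-sided p-values use the add-one convention
`p = (1 + #{draws ≥ observed}) / (1 + n_draws)`, which cannot return zero.
The median-shift test (signed rank against zero, with a bootstrap CI of the
median) is reported alongside: the two tests dissociate uniformly shifted
from heterogeneous two-signed populations. Defaults are 1,000 surrogate
draws and 10,000 bootstrap resamples.

For paired conditions (control vs laser in the same cells),
`pairedConditionTest()` bootstraps `S = median |coeff − median(coeff)|` over
units; a positive `S_control − S_laser` is sharpening. Ties in the bootstrap
null (exactly zero differences) are counted half, so identical inputs give
p ≈ 0.5 rather than 1.

Calibration and power are verified empirically at the package's study sizes:
200 null populations of 90 units for calibration and 100 populations per
regime for power (90 units, 150 increase plus 150 decrease deviant
deflections per unit, 300 baseline trains), with 200 surrogate draws per
population to keep the suite inside a practical runtime; the add-one p at
200 draws resolves well below the 0.05 working level. Under these conditions
the IQR rejection rate at α = 0.05 is mildly conservative-to-nominal
(~2–6% over large seed batches), a property of resampling from a single
realized baseline pool that the published procedure shares.

# The penalized per-neuron GLM

`buildGlmDesign()` assembles, per analyzed deflection: a constant; a signed
deviation regressor (−1 decrease, +1 increase, 0 on baseline deflections —
a per-direction indicator variant is available); session-standardized
baseline amplitude; spike-count history of the seven preceding deflection
windows, zero-padded before the train start (raw counts, the simplest causal
encoding); and one adaptation indicator per deflection position. The penalty
is `Q = I + 10 · DᵀD` with the identity zeroed on the constant and `D` the
first-difference operator over adjacent adaptation coefficients: the ridge
discourages large weights, the difference term makes the adaptation profile
smooth. (A literal `I + 10·D` is not a valid quadratic form, since `D` maps
k coefficients to k−1 differences; `DᵀD` is the positive-semidefinite matrix
that the phrase "quadratic penalty on the pairwise difference" defines.)

`fitPenalizedGlm()` minimizes the Poisson negative log-likelihood (log link —
the standard spike-count likelihood; a Gaussian variant is out of scope) plus
`0.5 wᵀQw` by damped Newton iteration with step halving; the problem is
convex, the objective trace is monotone, and convergence means the L2 norm
of the penalized gradient falls below 1e−8. With all penalties zero and a
full-rank design (`drop_reference = TRUE`, since the constant aliases the
full set of position indicators) the solution matches `stats::glm` to better
than 1e−6 — the package's independent oracle. Confidence intervals come from
a 100-fold bootstrap over deflection rows; false-positive rates are measured
by refitting deviant-free data with randomly relabeled deviants
(`nullRelabelDesign()`).

# The calcium chain

`computeDff()` uses the 30th percentile of a centered 200 s sliding window as
`F0`, shrinking at the trace edges (a centered window avoids startup bias),
and `ΔF/F = (F − F0)/F0`, which is invariant under global gain. The sliding
percentile is evaluated at anchor frames one-twentieth of a window apart and
linearly interpolated between them; the percentile of a 200 s window varies
slowly, and `stride = 1` recovers the exact computation.

`neuropilAnnulus()` dilates each somatic ROI by 20 px along x only — so a
per-scan-line artifact strikes soma and annulus equally — and excludes every
somatic ROI; an empty annulus is flagged, not fatal. The annulus traces are
used for the artifact brightening profile; no scaled neuropil subtraction
from somatic traces is applied by default (estimation, not subtraction, is
the documented use), though a 0.7-coefficient subtraction exists behind a
parameter for users who want it.

`correctLightArtifact()` is two-stage: stage 1 replaces every affected x-scan
line in every frame (LED on or off) with the mean of its unaffected
neighbors; stage 2 subtracts the per-frame mean excess of all neuropil annuli
over their laser-off level from the somatic traces on laser-on frames. The
closed-loop test plants a 5% line brightening plus a diffuse additive offset
and requires the residual laser-vs-control trace bias below 0.5%.

`classifyResponsive()` calls an ROI responsive when the 10% quantile of
stimulus-period ΔF/F (500–1500 ms after onset) exceeds the 90% quantile of
the pre-stimulus period (−1500–0 ms) — non-overlapping quantiles — pooled
over the selected trials, so the same function classifies in control trials,
laser trials, or both. `evokedResponse()` integrates ΔF/F 0–2 s after
stimulus *offset* (the indicator is too slow for per-deflection analysis; the
classification window and the evoked window are deliberately distinct
constants). `evokedEncodingStats()` gives per-ROI condition differences, a
population signed-rank test with a bootstrap median CI, and a per-ROI
trial-bootstrap two-sided p (threshold 0.0025 for single-cell laser effects;
"at the 1 s time point" is implemented as the evoked window statistic, with
the window a parameter). Selection effects (regression to the mean) are
controlled by classifying responsiveness on one half of trials and measuring
encoding on the held-out half; a paired test on pure-noise ROIs shows the
naive same-trials variant inflates evoked estimates while the cross-validated
one does not.

# Behavior

`fitPsychometric()` fits `P(hit|a) = guess + (1 − guess − lapse) ·
Φ((a − μ)/σ)` by binomial maximum likelihood (the natural likelihood for
Bernoulli hit/miss data; bounded L-BFGS-B with guess ≤ 0.5, lapse ≤ 0.2).
The threshold is the curve's *median point* — the amplitude halfway between
the guess floor and the lapse ceiling — which is `μ` in this
parameterization; subsequent analyses normalize amplitudes by it, and
rescaling all amplitudes by k rescales μ by k exactly. Flat or
single-response data are flagged non-identifiable rather than fitted.
`dprime()` clips rates to `[1/(2N), 1 − 1/(2N)]` before the normal quantiles.
`filterTrials()` applies named, audited exclusions: session d′ ≤ 1.2,
responses within 50 ms of stimulus onset, deviants later than 400 ms.
`hitRateCi()` is exact Clopper–Pearson; `compareRatesBootstrap()` draws
10,000 parametric binomial resamples of each rate and returns a two-sided p
for the difference (ties counted half, so identical inputs give p ≈ 1).
`deviantBenefit()` chains the whole pipeline: filter, fit on deviant-free
trials, normalize, and compare hit rates below 60% of threshold between
deviant and deviant-free trials.

# Numerical choices and degenerate inputs

* Every stochastic function takes an explicit seed and restores the caller's
  RNG state; the CLI stages are byte-reproducible.
* Add-one p-value estimators avoid p = 0; bootstrap tie handling is
  half-weight.
* Negative instantaneous rates in the generators are clipped at zero with a
  counted warning (unreachable at the defaults).
* All-zero count vectors: the GLM returns a large negative constant and
  ~zero effects; the classifier returns not-driven with a flag.
* Units missing a deviant sign, ROIs with empty annuli, and non-identifiable
  psychometric fits are reported with reasons, never silently dropped.

# Problem sizes used by the validation suite

The test suite and the acceptance script size their simulations to run on a
single CPU in minutes: 90-unit populations with ~300 deviant deflections per
unit and 200 surrogate draws for the broadening studies; 100 repetitions for
power and coverage estimates (40–60 in the faster acceptance script); 500
trials for classifier operating points; 200–500 null ROIs for responsiveness
calibration. These sizes are the package's validation design; all of them
are function arguments that scale up unchanged.

# Known limitations

* The broadening test conditions on one realized baseline pool per session;
  its null rejection rate runs slightly below nominal in small populations.
* The driven classifier's 0.002 coefficient floor is on the log-rate scale
  of the aggregated GLM; with very long sessions the Wald criterion, not the
  floor, is binding.
* The GLM history block is raw counts; strongly bursty units would motivate
  a basis expansion that is deliberately out of scope.
* The calcium simulator plants trace-level signals; it does not model
  imaging noise sources (shot noise scaling, motion) beyond white noise and
  the flyback artifact.
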