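---
title: "Models and methods behind laminattn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind laminattn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(laminattn)
```

`laminattn` analyses how spatial attention modulates contrast responses of
single units across cortical layers and waveform-defined cell classes, and
simulates the two circuit models that account for layer-specific contrast
dependence. This vignette records the models, the tunable parameters, the
numerical choices, and what the synthetic data do and do not emulate.

## The synthetic population

`make_population()` draws units with a cell class (narrow/medium/broad), a
laminar compartment (superficial/input/deep), a waveform template, an
attend-away contrast response function, an attention effect, and a true
onset latency. The defaults define the study conditions used throughout the
tests:

* **Waveform widths.** Peak-to-trough durations are a three-component
  Gaussian mixture with modes 0.20/0.35/0.55 ms and SD 0.03 ms — narrow
  enough to be trimodal by the dip test yet overlapping like real
  extracellular data. Class proportions 0.28/0.29/0.43 reflect the typical
  preponderance of broad-spiking units. Templates are biphasic
  (trough-then-peak) with lobe widths tied to the PTD; because overlapping
  lobes shift the extrema of a sum of Gaussians, the generator re-centres
  the peak once so the *measured* spline-interpolated PTD equals the
  sampled one to within half a sampling step (40 kHz sampling).
* **Contrast responses.** Attend-away CRFs are hyperbolic-ratio functions
  with log-normal parameter priors (median r_max 30 sp/s, c50 15%,
  exponent 2, baseline 5 sp/s) — typical V4 magnitudes. Spiking is
  piecewise-homogeneous Poisson: baseline before stimulus onset plus the
  unit's latency, the CRF rate afterwards. Real spike trains are
  non-Poisson (refractoriness, bursting, trial-to-trial gain drift), so
  passing tests show correctness of the estimators under their nominal
  noise model, not robustness to every biological departure.
* **Attention scenario (`paper_like`).** Narrow and medium units get pure
  response/baseline gain (uniform scaling, so their true CDI is exactly 0);
  broad units get contrast gain (c50 reduced by 1.6x plus a small response
  gain) in the superficial and input layers and pure response gain
  (1.15x) in the deep layer. This injects the qualitative laminar pattern
  the pipeline is expected to recover. The `null` preset removes all
  attention effects and collapses the PTD mixture to one mode.
* **Latencies.** Class means 65/50/70 ms (medium fastest), SD 5 ms.
* **Trial structure.** Six log-spaced contrasts in [2.5, 80]% plus 0%
  blanks; span −200…+400 ms around onset; equal trial counts per attention
  condition. The source recordings' exact contrast levels and trial counts
  are not public, so these are configurable stand-ins; the pipeline default
  of 48 trials per contrast and condition at 240 units comes from a power
  consideration spelled out below.

## CRF fitting, AMI and CDI

Rates are spike counts in the half-open window [60, 260) ms divided by
0.2 s. `fit_crf()` minimises the ordinary least-squares objective over
(r_max, c50, n, m) with L-BFGS-B inside the box r_max ∈ [0, 5·max rate],
c50 ∈ [0.5, 100], n ∈ [0.3, 6], m ∈ [0, max rate], restarting from the grid
c50 ∈ {5, 10, 20, 40, 80} × n ∈ {1, 2, 4}; the best converged start wins.
Noiseless rates are recovered to <1e-4 relative error, and the test suite
checks the returned SSE against a 50×50×20×20 brute-force grid. A fit whose
r_max collapses to ~0 is flagged `flat` (c50 and n are then unidentified).

AMI(c) = (R_in − R_away)/(R_in + R_away) is evaluated on the fitted curves
at the stimulus contrasts. The CDI averages the AMI over contrasts at or
below the attend-away c50 ("low") and above it ("high") and divides their
difference by the grand-mean AMI. Two exact limits anchor the sign
conventions: pure response gain g gives AMI ≡ (g−1)/(g+1) and CDI = 0;
halving c50 gives a strictly decreasing AMI and CDI > 0. Units with
|mean AMI| < 0.01 (unstable denominator) or |CDI| > 10 are excluded from
group aggregates as outliers.

**Why 48 trials and 240 units.** The per-unit CDI is a ratio of noisy
fitted quantities and is heavy-tailed. With ~20 trials per contrast the
group bootstrap CIs of the injected-null classes are dominated by a few
extreme units; from roughly 50 trials per contrast and condition and ~25
units per class × layer cell, their 95% CIs behave at the nominal level.
Note the corollary: even then, each of the six null-effect groups excludes
zero in ~5% of runs purely by CI construction, so "no contrast dependence
anywhere" should be read as "exclusions at chance level", which is what the
end-to-end test asserts (at most one of six).

## Waveform classification

PTD is measured on a 10x cubic-spline upsampling as the time from the
global minimum (trough) to the following global maximum; inverted or
monotone waveforms are rejected. "Meta-clustering" is realised as consensus
k-means: many random-restart k-means runs (500 by default) vote into a
co-assignment matrix, and the final partition is an average-linkage cut of
one minus that matrix. AIC/BIC use a hard-assignment 1-D Gaussian-mixture
log-likelihood with parameter count 3k − 1 and a variance floor equal to
the squared waveform sampling step (0.025 ms) for singleton clusters, so
both criteria live on a likelihood scale. The kneedle elbow is the global
maximum of the normalised difference curve (1 − k̂) − ĉrit(k̂), smallest k on
ties, with an exactly linear curve returning "no elbow". Classes are named
narrow/medium/broad by ascending cluster-mean PTD.

The dip statistic follows Hartigan's greatest-convex-minorant /
least-concave-majorant iteration on the empirical CDF. The implementation
was checked against analytic values (any 3-point sample gives 1/6, balanced
two-point masses approach 0.25, an equally spaced sample gives 1/(2n)) and
against an exact linear-programming oracle on small samples; the p-value is
calibrated against uniform(0,1) null samples of the same size (2000 by
default), which is the standard conservative reference for unimodality.

## Latency estimation

`adaptive_rate()` selects, for every 1-ms bin, a Gaussian kernel bandwidth
from 12 log-spaced candidates in [1, 50] ms by minimising a localised
least-squares cross-validation (MISE) cost for Poisson intensities,
computed on the binned pooled spike counts. Two stabilisers matter in
practice and are deliberate design choices: the local cost is averaged over
a compact ±80 ms boxcar *plus twice the whole-trace mean cost* (shrinkage
toward the global optimum — raw per-bin LSCV jitters between near-optimal
bandwidths in flat epochs, and the resulting variance spikes produce false
threshold crossings), and the selected log-bandwidth profile is smoothed
with a 20-ms Gaussian. Near a sharp rate change the localised bias term
dominates and the bandwidth still collapses, which is the behaviour the
adaptivity exists for.

`response_time()` thresholds the rate estimate at the upper bound of the
95% bootstrap CI computed from pre-stimulus spontaneous activity. The bound
is taken on the bootstrap distribution of the *maximum* of the re-estimated
pre-stimulus rate trace (trials resampled with replacement), not of its
mean: a mean-level bound compared bin-wise against a 1-ms trace has
uncontrolled familywise error over a several-hundred-bin scan window
(~20% false detections), whereas the trace-maximum bound holds the null
detection rate at ~3% with the required run length of 30 consecutive
supra-threshold 1-ms bins ("consistently greater"). Both constants were
calibrated once against the null operating characteristic (no rate change
⇒ no detection in ≥95% of runs) before any acceptance checks were written.

One bias is irreducible with symmetric Gaussian kernels: the smoothed
estimate starts rising about two bandwidths *before* a step onset, so
detected response times sit a few milliseconds early (≈ −2 to −10 ms on a
10× step with 200 trials) rather than late. The fixed-bandwidth variant
(kernels 1–10 ms, threshold = pre-stimulus maximum, 5 consecutive bins,
median over bandwidths) shares the bias and is additionally anticonservative
on long post-stimulus windows under Poisson noise; it is provided as the
robustness cross-check for *between-class comparisons*, where the early
bias cancels. Class summaries bootstrap the mean response time per class
and compare classes by rank-sum tests at the Bonferroni-corrected threshold
0.05/3 = 0.0167.

## Estimation statistics

`boot_mean()` resamples with replacement and reports percentile intervals
whose endpoints are order statistics (quantile type 1), n_boot = 10000 by
default; percentile rather than BCa because it is the plain
estimation-statistics default and exactly reproducible. Rank tests use the
normal approximation with continuity correction throughout (sample sizes
here make exact enumeration pointless, and ties are common).

## Normalization model of attention

Space is one-dimensional with two mirror-symmetric stimuli (±4°, orthogonal
orientations) on a 128-point grid over ±16°; orientation is a 64-point
circular axis over 180°. The stimulus drive (contrast × Gaussian in space,
σ 1°, and orientation, σ 20°) is raised to the input–output exponent
(default 2), pooled by the stimulation field (Gaussian, space σ 1°,
orientation σ 30°), multiplied by the attention field
(1 + (gain − 1)·Gaussian(σ 4°) at the attended location, gain 2), divisively
normalised by the suppressive pool (Gaussian in space σ 3°, full orientation
pooling) plus a semisaturation constant (0.01), and read out at the probed
neuron (attended-stimulus position and orientation). Attend-in places the
attention field on the probe, attend-away on the mirror location. These
values put the default model in a contrast-gain regime (AMI falling with
contrast, CDI > 0); none are fit to data.

The CDI uses the attend-away half-maximum contrast as the low/high split
(linear interpolation on the simulated CRF). Contrasts default to 16
log-spaced levels in [1, 100]%: with coarse contrast sampling the CDI
inherits ~1e-4 discretisation wiggle from the split, which matters because
the field-size sweeps are asserted monotone to 1e-6. `sweep_fields()`
varies the stimulation- and suppressive-field σ with everything else fixed;
`robustness_suite()` repeats the sweep across attention-field sizes
(3/4/6°), stimulus sizes (0.75/1/1.5°) and exponents (1, 2). Doubling all
spatial σ together with the grid leaves the CDI unchanged (units
invariance), and a flat attention field gives AMI ≡ 0 exactly.

## The columnar E–I spiking network

Nine columns in a line (open ends), each with 80 excitatory and 20
inhibitory conductance-based leaky integrate-and-fire neurons (4:1).
Membrane time constants 20/10 ms (E/I), rest −70 mV, threshold −50 mV,
reset −60 mV, reversal potentials 0/−80 mV, synaptic decays 5/10 ms,
refractory 2 ms, Euler step 0.1 ms. Only E cells project across columns;
the cross-column factor is a Gaussian in column distance with SD σ_E onto E
targets and σ_I onto I targets, normalised per target so total input weight
is independent of σ — the sweeps therefore change *where* input comes from,
not how much. Inhibition is within-column. Per-population total weights
(w_EE = 0.5, w_EI = 8, w_IE = 4, w_II = 8, in leak-conductance units, with
external Poisson drive 1100→2200 Hz per neuron at 0.075 per event) were
calibrated once for stable asynchronous activity (E ≈ 15 sp/s,
I ≈ 26 sp/s) with a small positive pooled E–I correlogram peak; near-zero E→E
recurrence keeps σ_E from shaping local correlations, which is the regime
in which inhibitory pooling width is the operative variable. I rates above
E rates by ~2x are the expected fast-spiking pattern.

`ei_correlation_vs_sigma()` pools centre-column E and I spikes from the
steady state (250 ms after step onset), chops them into 500-ms
pseudo-trials, computes the shift-predictor-corrected cross-correlogram
(coincidences per spike, geometric-mean normalisation, 1-ms lag bins) and
records the peak within ±10 ms and the ±25-ms window mean. The corrected
CCG has a sharp E→I peak at +1 ms and an inhibitory trough at −1/−2 ms, so
window means are small (and slightly negative); it is their *ordering*
across σ_I that carries the prediction. A decoupled network (all recurrent
weights zero) gives a corrected CCG consistent with zero.

## Known limitations

* Poisson spiking only: no refractoriness, bursting or rate drift in the
  generator, so Fano-factor- or correlation-based analyses of the synthetic
  trials are not meaningful.
* Layer labels are generator-supplied; no LFP/CSD-based layer assignment.
* Latency estimates carry the ~2-bandwidth early bias discussed above; use
  them for comparisons, not as absolute conduction delays.
* The normalization model is 1-D in space; absolute CDI values depend on
  the (unfit) field parameters and only orderings should be interpreted.
* Network weights are not matched to any recording; the σ_I/σ_E sweeps test
  a qualitative mechanism at desk scale (9 columns, seconds of activity).

## Problem sizes used by the tests and the acceptance script

CRF recovery uses 200 units × 100 trials/contrast; classification fixtures
use 300 units; latency fixtures 100–200 trials × 20–100 seeds; the network
sweeps 3 σ values × 10 seeds × 6 s; the pipeline 240 units × 48 trials with
4000-resample bootstrap CIs. These sizes keep every stage's sampling error
comfortably below the effect sizes being asserted while remaining
single-core friendly.
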