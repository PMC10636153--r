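# laminattn

Layer- and cell-class-specific analysis of attentional modulation of
contrast responses in visual cortex.

Spatial attention changes how neurons in area V4 respond to luminance
contrast, and it does not do so uniformly: putative excitatory (broad-
spiking) neurons in the superficial and input layers are preferentially
boosted at low contrasts, while deep-layer neurons are scaled independently
of contrast. `laminattn` packages the full analysis chain needed to study
this kind of laminar compartmentalization, together with the two
computational models that explain it, and a synthetic-data generator that
emulates laminar V4 recordings so everything runs end-to-end without any
external data.

## What the package computes

**Contrast response functions.** Trial-mean firing rates (spikes counted
60–260 ms after stimulus onset) are fit per unit and attention condition
with the hyperbolic-ratio (Naka–Rushton) function

    R(c) = m + R_max * c^n / (c^n + c50^n)

by bounded multi-start least squares (`fit_crf`). Attentional modulation is
quantified per contrast by the attentional modulation index

    AMI(c) = (R_in(c) − R_away(c)) / (R_in(c) + R_away(c))

and per fitted parameter (`ami_curve`, `ami_params`). The contrast
dependence index

    CDI = (mean AMI, c ≤ c50 − mean AMI, c > c50) / mean AMI

separates contrast-gain-like modulation (CDI > 0) from pure response gain
(CDI = 0) (`compute_cdi`), with the low/high split at the attend-away c50.

**Cell classes from waveforms.** Units are classified as narrow-, medium-
or broad-spiking from the peak-to-trough duration (PTD) of their spike
waveform: spline-interpolated PTD measurement (`measure_ptd`), consensus
k-means meta-clustering (`meta_kmeans`), Gaussian-mixture AIC/BIC with
kneedle elbow detection (`information_criteria`, `kneedle_elbow`),
Hartigan's dip test of multimodality (`dip_test`) and a PCA cross-check on
the full waveforms (`pca_crosscheck`).

**Response latency.** Firing rates are estimated with a variable-bandwidth
Gaussian kernel whose width is optimised per time bin by a localised
MISE criterion (`adaptive_rate`); the response time is the first sustained
crossing of the 95% bootstrap bound of the pre-stimulus rate
(`response_time`), with a fixed-bandwidth alternative
(`response_time_fixed`).

**Estimation statistics.** Bootstrap sampling distributions of means with
percentile CIs (`boot_mean`), Wilcoxon signed-rank/rank-sum tests and
Bonferroni correction (`signed_rank_vs_zero`, `rank_sum`,
`bonferroni_adjust`).

**Mechanistic models.** A normalization model of attention on a 1-D space ×
orientation grid (stimulation, suppressive and attention fields;
`simulate_nm`), swept over field sizes to map the predicted CDI
(`sweep_fields`, `robustness_suite`); and a columnar conductance-based
E–I spiking network (4:1 ratio, Gaussian cross-column excitation,
`run_simulation`) whose pooled E–I spike-time cross-correlograms
(`pooled_ccg`) test how the inhibitory pooling width σ_I controls local
correlation (`ei_correlation_vs_sigma`).

**Pipeline.** `run_all(run_config(...))` chains simulation → waveform
classification → CRF/AMI/CDI by class × layer → latency, and writes CSV/JSON
reports.

## Worked example

```r
library(laminattn)

pop <- make_population(population_config(n_units = 60), seed = 1)
trials <- simulate_trials(pop, n_trials = 30, seed = 2)

## classify by waveform width
ptd <- sapply(pop$units, function(u) measure_ptd(u$waveform))
sol <- meta_kmeans(ptd, k = 3, n_restarts = 200, seed = 3)
table(name_classes_by_width(sol$labels, ptd))
#>  broad medium narrow
#>     24     19     17

dip_test(ptd, seed = 4)$p_value
#> [1] 0.0004997501           # widths are clearly multimodal

## attentional modulation of one unit (ground truth: broad, superficial)
prof <- unit_crf_profile(trials, 1)
prof$fit_away$params
#> CRF: r_max=24.9 sp/s, c50=18.1%, n=2.15, m=4.29 sp/s
round(prof$ami, 3)
#> [1] 0.064 0.231 0.261 0.160 0.091 0.075
prof$cdi$cdi
#> [1] 0.5212235   # modulation concentrated below c50: contrast-gain-like
```

The positive CDI says this unit's attentional boost is strongest at low
contrasts, as injected for broad superficial units. Single-unit CDIs are
noisy ratio estimates, so group-level conclusions use the bootstrap
summaries of `aggregate_by_group` / `run_all`. At the default pipeline
scale (240 units, 48 trials per contrast and condition) the injected
class-by-layer pattern is recovered with 95% CIs:

```r
rep <- run_all(run_config(preset = "paper_like", seed = 7, n_boot = 4000))
print(rep)
#>   k (AIC/BIC elbows): 3 / 3; selected 3
#>   class agreement with ground truth: 99.6%
#>   CDI by class x layer:  broad.superficial mean 0.79, CI [0.64, 0.94] ...
```

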