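## Synthetic laminar V4 population generator: units, waveforms, trials and
## correlated pooled spike trains.

#' Attention effect on a contrast response function
#'
#' Encodes how attention transforms the attend-away CRF into the attend-in
#' CRF: \code{response_gain} multiplies r_max, \code{contrast_gain} (>= 1)
#' shifts c50 leftward (c50 / contrast_gain), \code{baseline_gain}
#' multiplies m.  All gains 1 leaves the CRF unchanged.
#'
#' @param response_gain,contrast_gain,baseline_gain Dimensionless gains.
#' @return Named numeric vector of class \code{"attention_effect"}.
#' @export
attention_effect <- function(response_gain = 1, contrast_gain = 1,
                             baseline_gain = 1) {
  if (response_gain < 0) stop_config("response_gain must be >= 0")
  if (contrast_gain < 1) stop_config("contrast_gain must be >= 1")
  if (baseline_gain < 0) stop_config("baseline_gain must be >= 0")
  structure(c(response_gain = response_gain, contrast_gain = contrast_gain,
              baseline_gain = baseline_gain), class = "attention_effect")
}

## attend-in CRF implied by the attend-away CRF and an attention effect
apply_attention <- function(crf_away, effect) {
  crf_params(crf_away[["r_max"]] * effect[["response_gain"]],
             crf_away[["c50"]] / effect[["contrast_gain"]],
             crf_away[["n"]],
             crf_away[["m"]] * effect[["baseline_gain"]])
}

## the class x layer attention scenarios shipped with the generator
attention_scenarios <- function(name = c("paper_like", "null")) {
  name <- match.arg(name)
  layers <- c("superficial", "input", "deep")
  grid <- expand.grid(cls = c("narrow", "medium", "broad"), layer = layers,
                      stringsAsFactors = FALSE)
  eff <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    eff[[i]] <- if (name == "null") {
      attention_effect()
    } else if (grid$cls[i] == "narrow") {
      ## pure response gain in every layer (contrast-independent)
      attention_effect(response_gain = 1.12, baseline_gain = 1.12)
    } else if (grid$cls[i] == "medium") {
      ## uniform scaling of evoked and baseline response: CDI ~ 0
      attention_effect(response_gain = 1.15, baseline_gain = 1.15)
    } else if (grid$layer[i] %in% c("superficial", "input")) {
      ## broad, superficial/input: contrast gain -> positive CDI
      attention_effect(response_gain = 1.05, contrast_gain = 1.6,
                       baseline_gain = 1.05)
    } else {
      ## broad, deep: pure response gain -> CDI ~ 0
      attention_effect(response_gain = 1.15, baseline_gain = 1.15)
    }
  }
  grid$effect <- eff
  grid
}

#' Configuration for the synthetic population generator
#'
#' Defaults emulate a laminar V4 attention study: a trimodal distribution of
#' waveform peak-to-trough durations (narrow/medium/broad classes), three
#' laminar compartments, log-normal CRF parameter priors, class-specific
#' onset latencies (medium fastest), and a class-by-layer attention-effect
#' scenario in which narrow and medium units are modulated by pure
#' response/baseline gain everywhere while broad units show contrast gain in
#' the superficial and input layers but pure response gain in the deep layer.
#'
#' @param n_units Number of units.
#' @param class_props Named proportions for narrow/medium/broad (sum to 1).
#' @param layer_props Named proportions for superficial/input/deep.
#' @param ptd_modes,ptd_sd Per-class PTD mode means and common SD, ms.
#' @param crf_priors List of log-normal priors (meanlog, sdlog) for r_max,
#'   c50, n, m.
#' @param latency_means,latency_sd Per-class true onset latency means and SD
#'   (ms after stimulus onset).
#' @param scenario \code{"paper_like"} or \code{"null"}, or a data.frame as
#'   returned by the internal scenario table (columns cls, layer, effect).
#' @return List of class \code{"population_config"}.
#' @export
population_config <- function(n_units = 180,
                              class_props = c(narrow = 0.28, medium = 0.29,
                                              broad = 0.43),
                              layer_props = c(superficial = 1/3, input = 1/3,
                                              deep = 1/3),
                              ptd_modes = c(narrow = 0.20, medium = 0.35,
                                            broad = 0.55),
                              ptd_sd = 0.03,
                              crf_priors = list(
                                r_max = c(meanlog = log(30), sdlog = 0.35),
                                c50 = c(meanlog = log(15), sdlog = 0.35),
                                n = c(meanlog = log(2), sdlog = 0.25),
                                m = c(meanlog = log(5), sdlog = 0.4)),
                              latency_means = c(narrow = 65, medium = 50,
                                                broad = 70),
                              latency_sd = 5,
                              scenario = "paper_like") {
  if (abs(sum(class_props) - 1) > 1e-8)
    stop_config("class proportions must sum to 1 (sum = %g)", sum(class_props))
  if (abs(sum(layer_props) - 1) > 1e-8)
    stop_config("layer proportions must sum to 1 (sum = %g)", sum(layer_props))
  if (is.character(scenario)) scenario <- attention_scenarios(scenario)
  structure(list(n_units = n_units, class_props = class_props,
                 layer_props = layer_props, ptd_modes = ptd_modes,
                 ptd_sd = ptd_sd, crf_priors = crf_priors,
                 latency_means = latency_means, latency_sd = latency_sd,
                 scenario = scenario),
            class = "population_config")
}

#' Generate a synthetic population of ground-truth units
#'
#' Samples cell classes and layers from the configured proportions, a
#' peak-to-trough duration from the class's Gaussian mode, attend-away CRF
#' parameters from log-normal priors, the class-by-layer attention effect,
#' a true onset latency, and a biphasic waveform template whose measured PTD
#' equals the sampled one up to the template sampling step.
#'
#' @param config A \code{\link{population_config}}.
#' @param seed RNG seed; the population is deterministic given (config, seed).
#' @return List of class \code{"gt_population"} with elements \code{units}
#'   (list of per-unit records) and \code{config}.  Use
#'   \code{as.data.frame()} for a tabular view.
#' @export
make_population <- function(config = population_config(), seed = 1) {
  stopifnot(inherits(config, "population_config"))
  with_seed(seed, {
    n <- config$n_units
    classes <- sample(names(config$class_props), n, replace = TRUE,
                      prob = config$class_props)
    layers <- sample(names(config$layer_props), n, replace = TRUE,
                     prob = config$layer_props)
    units <- vector("list", n)
    for (i in seq_len(n)) {
      cls <- classes[i]
      ptd <- max(0.08, rnorm(1, config$ptd_modes[[cls]], config$ptd_sd))
      pri <- config$crf_priors
      crf_away <- crf_params(
        r_max = rlnorm(1, pri$r_max["meanlog"], pri$r_max["sdlog"]),
        c50 = min(95, rlnorm(1, pri$c50["meanlog"], pri$c50["sdlog"])),
        n = min(5.5, max(0.5, rlnorm(1, pri$n["meanlog"], pri$n["sdlog"]))),
        m = rlnorm(1, pri$m["meanlog"], pri$m["sdlog"]))
      row <- config$scenario$cls == cls & config$scenario$layer == layers[i]
      if (!any(row))
        stop_config("no attention effect configured for %s x %s",
                    cls, layers[i])
      latency <- max(20, rnorm(1, config$latency_means[[cls]],
                               config$latency_sd))
      wf <- make_waveform(cls, ptd, noise_sd = 0,
                          seed = child_seed(seed, i))
      units[[i]] <- list(unit_id = i, layer = layers[i], cls = cls,
                         ptd_true = ptd, crf_away = crf_away,
                         attention_effect = config$scenario$effect[[which(row)]],
                         latency_true = latency, waveform = wf)
    }
    structure(list(units = units, config = config, seed = seed),
              class = "gt_population")
  })
}

#' @export
as.data.frame.gt_population <- function(x, ...) {
  do.call(rbind, lapply(x$units, function(u)
    data.frame(unit_id = u$unit_id, layer = u$layer, cls = u$cls,
               ptd_true = u$ptd_true, latency_true = u$latency_true,
               r_max = u$crf_away[["r_max"]], c50 = u$crf_away[["c50"]],
               n = u$crf_away[["n"]], m = u$crf_away[["m"]],
               response_gain = u$attention_effect[["response_gain"]],
               contrast_gain = u$attention_effect[["contrast_gain"]],
               baseline_gain = u$attention_effect[["baseline_gain"]])))
}

#' @export
print.gt_population <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("Synthetic population: %d units\n", nrow(df)))
  print(table(df$cls, df$layer))
  invisible(x)
}

#' Generate a biphasic spike waveform template
#'
#' Trough-then-peak action-potential template sampled at \code{fs_khz} kHz:
#' a narrow negative Gaussian trough followed by a broader positive peak at
#' \code{ptd_true} ms after the trough.  At zero noise the measured
#' trough-to-peak duration equals \code{ptd_true} up to half a sampling step.
#'
#' @param cls_template Class label (narrow/medium/broad); only sets the
#'   relative peak width.
#' @param ptd_true Peak-to-trough duration, ms (>= 2 sampling steps).
#' @param noise_sd Additive Gaussian noise SD in units of trough amplitude.
#' @param seed RNG seed (used only when noise_sd > 0).
#' @param fs_khz Sampling rate in kHz (default 40, i.e. 0.025 ms step).
#' @param span_ms Total template duration, ms.
#' @return List of class \code{"spike_waveform"}: time (ms), amplitude
#'   (a.u., trough = -1), dt.
#' @export
make_waveform <- function(cls_template, ptd_true, noise_sd = 0, seed = NULL,
                          fs_khz = 40, span_ms = 2.5) {
  dt <- 1 / fs_khz
  if (ptd_true < 2 * dt)
    stop_config("ptd_true = %g ms is below template resolution (2 steps = %g ms)",
                ptd_true, 2 * dt)
  t <- seq(0, span_ms, by = dt)
  t_trough <- 0.6
  t_peak <- t_trough + ptd_true
  if (t_peak > span_ms - 0.3) {
    span_ms <- t_peak + 0.5
    t <- seq(0, span_ms, by = dt)
  }
  trough_w <- min(0.07, ptd_true / 3.5)
  peak_w <- min(0.10 + 0.25 * ptd_true, ptd_true / 2)
  shape <- function(tp) -exp(-0.5 * ((t - t_trough) / trough_w)^2) +
    0.55 * exp(-0.5 * ((t - tp) / peak_w)^2)
  ## overlapping lobes shift the extrema; one corrective re-centering of the
  ## peak keeps the measured trough-to-peak time at ptd_true
  amp <- shape(t_peak)
  for (it in 1:2) {
    sp <- spline(t, amp, n = length(t) * 10)
    i_tr <- which.min(sp$y)
    i_pk <- i_tr + which.max(sp$y[i_tr:length(sp$y)]) - 1L
    measured <- sp$x[i_pk] - sp$x[i_tr]
    if (abs(measured - ptd_true) < dt / 4) break
    t_peak <- t_peak + (ptd_true - measured)
    amp <- shape(t_peak)
  }
  if (noise_sd > 0)
    amp <- amp + with_seed(seed, rnorm(length(amp), 0, noise_sd))
  structure(list(time = t, amplitude = amp, dt = dt,
                 cls_template = cls_template, ptd_true = ptd_true),
            class = "spike_waveform")
}

## piecewise-constant-rate Poisson spikes on [t0, t1), rate in spikes/s
rpois_segment <- function(rate_hz, t0, t1) {
  if (t1 <= t0 || rate_hz <= 0) return(numeric(0))
  k <- rpois(1, rate_hz * (t1 - t0) / 1000)
  if (k == 0) return(numeric(0))
  sort(runif(k, t0, t1))
}

#' Simulate trial-structured spike trains for a population
#'
#' Spikes are inhomogeneous Poisson: baseline rate m before stimulus onset
#' plus the unit's true onset latency, then the condition-specific CRF rate
#' R(c).  The attend-in CRF is derived from the attend-away CRF via the
#' unit's attention effect.  Trial counts are equal in the two conditions.
#'
#' @param population A \code{\link{make_population}} result.
#' @param contrasts Contrast levels in percent; values in (0, 100], plus
#'   optional 0 for blank trials.
#' @param n_trials Trials per contrast per attention condition.
#' @param span Trial span \code{c(start, end)} in ms around stimulus onset.
#' @param seed RNG seed.
#' @return List of class \code{"trial_set"}: contrasts, span, n_trials, and
#'   \code{spikes[[unit]][[condition]][[contrast_index]][[trial]]} spike-time
#'   vectors (ms relative to stimulus onset).
#' @export
simulate_trials <- function(population,
                            contrasts = c(0, round(exp(seq(log(2.5), log(80),
                                                           length.out = 6)), 1)),
                            n_trials = 20, span = c(-200, 400), seed = 1) {
  stopifnot(inherits(population, "gt_population"))
  if (any(contrasts < 0 | contrasts > 100))
    stop_config("contrasts must lie in [0, 100] percent")
  with_seed(seed, {
    spikes <- vector("list", length(population$units))
    for (i in seq_along(population$units)) {
      u <- population$units[[i]]
      crf_by_cond <- list(away = u$crf_away,
                          "in" = apply_attention(u$crf_away,
                                                 u$attention_effect))
      per_cond <- list()
      for (cond in c("in", "away")) {
        p <- crf_by_cond[[cond]]
        per_contrast <- vector("list", length(contrasts))
        for (ci in seq_along(contrasts)) {
          rate_evoked <- crf_response(contrasts[ci], p)
          rate_base <- p[["m"]]
          onset <- u$latency_true
          per_contrast[[ci]] <- lapply(seq_len(n_trials), function(tr) {
            c(rpois_segment(rate_base, span[1], min(onset, span[2])),
              rpois_segment(rate_evoked, min(onset, span[2]), span[2]))
          })
        }
        per_cond[[cond]] <- per_contrast
      }
      spikes[[i]] <- per_cond
    }
    structure(list(contrasts = contrasts, span = span, n_trials = n_trials,
                   seed = seed, spikes = spikes),
              class = "trial_set")
  })
}

#' Correlated pooled excitatory/inhibitory spike trains
#'
#' Two pooled Poisson spike trains sharing a common source: each pool is a
#' superposition of a private Poisson process and a shared one whose rate is
#' \code{common_fraction} of the smaller pooled rate.  The zero-lag
#' cross-correlation grows monotonically with \code{common_fraction}.
#'
#' @param n_E,n_I Number of units per pool.
#' @param rate_E,rate_I Per-unit rates, spikes/s.
#' @param common_fraction Shared-source fraction in [0, 1].
#' @param duration Duration in ms.
#' @param seed RNG seed.
#' @param delay_ms Transmission delay added to the shared spikes in the
#'   second (inhibitory) pool.
#' @return List with sorted spike-time vectors \code{e}, \code{i} (ms) and
#'   the generating parameters.
#' @export
make_correlated_pools <- function(n_E, n_I, rate_E, rate_I, common_fraction,
                                  duration, seed = 1, delay_ms = 0) {
  if (common_fraction < 0 || common_fraction > 1)
    stop_config("common_fraction must be in [0, 1] (got %g)", common_fraction)
  pooled_E <- n_E * rate_E
  pooled_I <- n_I * rate_I
  shared_rate <- common_fraction * min(pooled_E, pooled_I)
  with_seed(seed, {
    shared <- rpois_segment(shared_rate, 0, duration)
    e <- sort(c(rpois_segment(pooled_E - shared_rate, 0, duration), shared))
    i <- sort(c(rpois_segment(pooled_I - shared_rate, 0, duration),
                shared + delay_ms))
    i <- i[i < duration]
    list(e = e, i = i, duration = duration,
         common_fraction = common_fraction, delay_ms = delay_ms)
  })
}
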