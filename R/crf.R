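## Contrast response functions, attentional modulation (AMI) and
## contrast-dependence (CDI) indices.

#' Hyperbolic-ratio contrast-response parameters
#'
#' Bundles the four parameters of the hyperbolic-ratio (Naka-Rushton)
#' contrast response function
#' \deqn{R(c) = m + R_{max} \frac{c^n}{c^n + c_{50}^n}}
#' where \code{r_max} is the attainable maximum response above baseline
#' (spikes/s), \code{c50} the contrast (percent) at which the evoked response
#' is half-maximal, \code{n} the exponent controlling the nonlinearity, and
#' \code{m} the baseline activity (spikes/s).
#'
#' @param r_max Maximum evoked response above baseline, spikes/s (>= 0).
#' @param c50 Half-maximal contrast, percent, in (0, 100].
#' @param n Dimensionless exponent (> 0).
#' @param m Baseline rate, spikes/s (>= 0).
#' @return An object of class \code{"crf_params"} (named numeric vector).
#' @examples
#' p <- crf_params(50, 20, 2, 5)
#' crf_response(c(5, 20, 80), p)
#' @export
crf_params <- function(r_max, c50, n, m) {
  if (r_max < 0) stop_config("r_max must be >= 0 (got %g)", r_max)
  if (c50 <= 0 || c50 > 100) stop_config("c50 must be in (0, 100] (got %g)", c50)
  if (n <= 0) stop_config("exponent n must be > 0 (got %g)", n)
  if (m < 0) stop_config("baseline m must be >= 0 (got %g)", m)
  structure(c(r_max = r_max, c50 = c50, n = n, m = m), class = "crf_params")
}

#' Evaluate a hyperbolic-ratio contrast response function
#'
#' @param contrast Contrast levels in percent (>= 0); 0 returns the baseline.
#' @param params A \code{\link{crf_params}} object (or named vector with
#'   elements r_max, c50, n, m).
#' @return Firing rates in spikes/s, same length as \code{contrast}.
#' @export
crf_response <- function(contrast, params) {
  p <- as.numeric(params[c("r_max", "c50", "n", "m")])
  cn <- contrast^p[3]
  p[4] + p[1] * cn / (cn + p[2]^p[3])
}

#' @export
print.crf_params <- function(x, ...) {
  cat(sprintf("CRF: r_max=%.3g sp/s, c50=%.3g%%, n=%.3g, m=%.3g sp/s\n",
              x["r_max"], x["c50"], x["n"], x["m"]))
  invisible(x)
}

#' Trial-averaged firing rates per contrast
#'
#' Counts spikes in a half-open analysis window (default 60-260 ms after
#' stimulus onset) and converts to spikes/s, averaged over trials.
#'
#' @param trial_set A trial set from \code{\link{simulate_trials}} (or any
#'   list with the same layout).
#' @param unit Unit index.
#' @param condition \code{"in"} or \code{"away"}.
#' @param window Analysis window \code{c(start, end)} in ms; spikes with
#'   \code{start <= t < end} are counted.
#' @return A data.frame with columns contrast, rate, sem, n_trials.
#' @export
spike_counts_to_rates <- function(trial_set, unit, condition = c("away", "in"),
                                  window = c(60, 260)) {
  condition <- match.arg(condition)
  trains <- trial_set$spikes[[unit]][[condition]]
  if (is.null(trains) || length(trains) == 0L)
    stop_config("no trials for unit %s, condition %s", unit, condition)
  dur_s <- diff(window) / 1000
  out <- lapply(seq_along(trial_set$contrasts), function(ci) {
    counts <- vapply(trains[[ci]], function(t)
      sum(t >= window[1] & t < window[2]), numeric(1))
    rates <- counts / dur_s
    data.frame(contrast = trial_set$contrasts[ci],
               rate = mean(rates),
               sem = stats::sd(rates) / sqrt(length(rates)),
               n_trials = length(rates))
  })
  do.call(rbind, out)
}

## default multistart grid per the fitting strategy: coarse c50 x n lattice
crf_start_grid <- function() {
  expand.grid(c50 = c(5, 10, 20, 40, 80), n = c(1, 2, 4))
}

#' Fit a hyperbolic-ratio contrast response function by least squares
#'
#' Ordinary least squares on trial-mean rates, solved by bounded
#' quasi-Newton minimisation (L-BFGS-B) from a fixed grid of starting points
#' (c50 in \{5,10,20,40,80\}, n in \{1,2,4\}); the best converged start is
#' returned.  Bounds: r_max in [0, 5 max(rate)], c50 in [0.5, 100],
#' n in [0.3, 6], m in [0, max(rate)].
#'
#' @param contrasts Contrast levels in percent; at least 5 distinct levels.
#' @param mean_rates Trial-mean rates (spikes/s) at those contrasts.
#' @return A list of class \code{"crf_fit"}: \code{params}
#'   (\code{\link{crf_params}}), \code{sse}, \code{fitted}, \code{flat}
#'   (TRUE when the response is constant so c50 and n are unidentified),
#'   \code{convergence}.
#' @export
fit_crf <- function(contrasts, mean_rates) {
  stopifnot(length(contrasts) == length(mean_rates))
  keep <- is.finite(contrasts) & is.finite(mean_rates)
  contrasts <- contrasts[keep]; mean_rates <- mean_rates[keep]
  if (length(unique(contrasts)) < 5L)
    stop_config("need >= 5 contrast levels to fit 4 parameters (got %d)",
                length(unique(contrasts)))
  ymax <- max(mean_rates)
  ymin <- min(mean_rates)
  lower <- c(r_max = 0, c50 = 0.5, n = 0.3, m = 0)
  upper <- c(r_max = max(5 * ymax, 1), c50 = 100, n = 6, m = max(ymax, 1e-6))
  sse_fun <- function(p) {
    cn <- contrasts^p[3]
    r <- p[4] + p[1] * cn / (cn + p[2]^p[3])
    sum((r - mean_rates)^2)
  }
  grid <- crf_start_grid()
  best <- NULL
  n_conv <- 0L
  for (i in seq_len(nrow(grid))) {
    p0 <- c(r_max = max(ymax - ymin, 1e-3), c50 = grid$c50[i], n = grid$n[i],
            m = max(ymin, 0))
    p0 <- pmin(pmax(p0, lower), upper)
    fit <- tryCatch(
      optim(p0, sse_fun, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_conv <- n_conv + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop_config("CRF fit failed to converge from every starting point")
  p <- best$par
  flat <- (p[["r_max"]] < max(1e-6, 1e-3 * max(ymax, 1)))
  params <- crf_params(p[["r_max"]], p[["c50"]], p[["n"]], p[["m"]])
  structure(list(params = params, sse = best$value,
                 fitted = crf_response(contrasts, params),
                 contrasts = contrasts, rates = mean_rates,
                 flat = flat, convergence = best$convergence,
                 n_starts_converged = n_conv),
            class = "crf_fit")
}

#' @export
print.crf_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("  SSE = %.4g over %d contrasts%s\n", x$sse, length(x$contrasts),
              if (x$flat) " [flat: c50/n unidentified]" else ""))
  invisible(x)
}

#' Attentional modulation index as a function of contrast
#'
#' AMI(c) = (R_in(c) - R_away(c)) / (R_in(c) + R_away(c)), evaluated on the
#' fitted contrast response functions of the two attention conditions.
#' Antisymmetric under swapping the conditions.  Contrasts at which the two
#' responses sum to zero yield NA.
#'
#' @param crf_in,crf_away \code{\link{crf_params}} (or \code{crf_fit}) for
#'   the attend-in and attend-away conditions.
#' @param contrasts Contrast levels (percent) at which to evaluate.
#' @return Numeric vector of AMI values in [-1, 1] (NA where undefined).
#' @export
ami_curve <- function(crf_in, crf_away, contrasts) {
  if (inherits(crf_in, "crf_fit")) crf_in <- crf_in$params
  if (inherits(crf_away, "crf_fit")) crf_away <- crf_away$params
  ri <- crf_response(contrasts, crf_in)
  ra <- crf_response(contrasts, crf_away)
  s <- ri + ra
  out <- (ri - ra) / s
  out[s == 0] <- NA_real_
  out
}

#' AMI of each fitted CRF parameter
#'
#' Applies the index (in - away)/(in + away) to each of r_max, c50, n, m.
#'
#' @inheritParams ami_curve
#' @return Named numeric vector (ami_r_max, ami_c50, ami_n, ami_m).
#' @export
ami_params <- function(crf_in, crf_away) {
  if (inherits(crf_in, "crf_fit")) crf_in <- crf_in$params
  if (inherits(crf_away, "crf_fit")) crf_away <- crf_away$params
  a <- as.numeric(crf_in[c("r_max", "c50", "n", "m")])
  b <- as.numeric(crf_away[c("r_max", "c50", "n", "m")])
  s <- a + b
  out <- (a - b) / s
  out[s == 0] <- NA_real_
  names(out) <- c("ami_r_max", "ami_c50", "ami_n", "ami_m")
  out
}

#' Contrast dependence index
#'
#' AMIs are averaged within the low-contrast range (c <= threshold) and the
#' high-contrast range (c > threshold), with the threshold at the attend-away
#' best-fitting c50; the CDI is their difference normalised by the AMI
#' averaged over all contrasts.  CDI = 0 for contrast-independent (pure
#' response-gain) modulation; CDI > 0 when modulation is stronger at low
#' contrasts (contrast-gain-like).
#'
#' @param ami_by_contrast AMI values per contrast.
#' @param contrasts Corresponding contrast levels (percent).
#' @param c50_away Low/high split threshold (attend-away c50), percent.
#' @param eps Instability threshold on |mean AMI| for the denominator.
#' @return List with \code{cdi}, \code{valid} (>= 1 contrast on each side),
#'   \code{unstable} (|mean AMI| < eps), \code{ami_low}, \code{ami_high},
#'   \code{ami_mean}.
#' @export
compute_cdi <- function(ami_by_contrast, contrasts, c50_away, eps = 0.01) {
  stopifnot(length(ami_by_contrast) == length(contrasts))
  ok <- is.finite(ami_by_contrast)
  a <- ami_by_contrast[ok]; cc <- contrasts[ok]
  low <- cc <= c50_away
  valid <- any(low) && any(!low)
  m_all <- mean(a)
  unstable <- abs(m_all) < eps
  cdi <- if (!valid || m_all == 0) NA_real_ else
    (mean(a[low]) - mean(a[!low])) / m_all
  list(cdi = cdi, valid = valid, unstable = unstable,
       ami_low = if (any(low)) mean(a[low]) else NA_real_,
       ami_high = if (any(!low)) mean(a[!low]) else NA_real_,
       ami_mean = m_all)
}

#' Screen a unit for visual responsiveness
#'
#' A unit is responsive when its evoked rate (analysis window, highest
#' contrast, both attention conditions pooled) exceeds its pre-stimulus
#' baseline rate by a one-sided Wilcoxon rank-sum test at alpha.
#'
#' @inheritParams spike_counts_to_rates
#' @param alpha Test level (default 0.05).
#' @param evoked_window,baseline_window Windows in ms relative to onset.
#' @return Logical.
#' @export
screen_visual_responsiveness <- function(trial_set, unit, alpha = 0.05,
                                         evoked_window = c(60, 260),
                                         baseline_window = c(-200, 0)) {
  ci <- which.max(trial_set$contrasts)
  ev <- c(); bl <- c()
  for (cond in c("in", "away")) {
    trains_c <- trial_set$spikes[[unit]][[cond]][[ci]]
    ev <- c(ev, vapply(trains_c, function(t)
      sum(t >= evoked_window[1] & t < evoked_window[2]), numeric(1)) /
        (diff(evoked_window) / 1000))
    ## baseline from every contrast: pre-stimulus epochs are stimulus-free
    for (trains_b in trial_set$spikes[[unit]][[cond]]) {
      bl <- c(bl, vapply(trains_b, function(t)
        sum(t >= baseline_window[1] & t < baseline_window[2]), numeric(1)) /
          (diff(baseline_window) / 1000))
    }
  }
  if (all(ev == 0)) return(FALSE)
  p <- tryCatch(
    wilcox.test(ev, bl, alternative = "greater", exact = FALSE)$p.value,
    error = function(e) 1)
  isTRUE(p < alpha)
}

#' Full per-unit CRF/AMI/CDI profile
#'
#' Fits both attention conditions of one unit, evaluates the AMI at the
#' stimulus contrasts, the AMIs of the fitted parameters, and the CDI (split
#' at the attend-away c50).
#'
#' @inheritParams spike_counts_to_rates
#' @param min_contrast Contrasts strictly below this value (e.g. 0% blanks)
#'   are excluded from the fit.
#' @return List with fits, ami, ami_params, cdi and flags.
#' @export
unit_crf_profile <- function(trial_set, unit, window = c(60, 260),
                             min_contrast = 1e-9) {
  r_in <- spike_counts_to_rates(trial_set, unit, "in", window)
  r_aw <- spike_counts_to_rates(trial_set, unit, "away", window)
  keep <- r_in$contrast >= min_contrast
  fit_in <- fit_crf(r_in$contrast[keep], r_in$rate[keep])
  fit_aw <- fit_crf(r_aw$contrast[keep], r_aw$rate[keep])
  cc <- r_in$contrast[keep]
  ami <- ami_curve(fit_in, fit_aw, cc)
  cdi <- compute_cdi(ami, cc, fit_aw$params[["c50"]])
  list(unit = unit, fit_in = fit_in, fit_away = fit_aw,
       contrasts = cc, ami = ami, mean_ami = mean(ami, na.rm = TRUE),
       ami_params = ami_params(fit_in, fit_aw), cdi = cdi,
       flat = fit_in$flat || fit_aw$flat)
}

#' Aggregate AMI/CDI profiles by group (cell class x layer)
#'
#' Computes per-group mean AMI curves with SEM and the mean CDI with a
#' percentile bootstrap CI.  Units with an unstable CDI denominator
#' (|mean AMI| < eps) or extreme CDI (|CDI| > cdi_cap) are excluded as
#' outliers.
#'
#' @param profiles List of per-unit profiles from
#'   \code{\link{unit_crf_profile}}.
#' @param groups Factor/character vector, one group label per profile.
#' @param n_boot Bootstrap resamples for the CDI CI.
#' @param seed RNG seed.
#' @param eps,cdi_cap Outlier rule thresholds.
#' @return A list with \code{summary} (data.frame: group, n, n_used,
#'   mean_cdi, ci_low, ci_high, mean_ami) and \code{ami_curves} (per-group
#'   mean AMI by contrast with SEM).
#' @export
aggregate_by_group <- function(profiles, groups, n_boot = 10000, seed = 1,
                               eps = 0.01, cdi_cap = 10) {
  stopifnot(length(profiles) == length(groups))
  groups <- as.character(groups)
  out <- list(); curves <- list()
  for (g in sort(unique(groups))) {
    idx <- which(groups == g)
    if (length(idx) == 0L) next
    prof <- profiles[idx]
    cdis <- vapply(prof, function(p) p$cdi$cdi, numeric(1))
    mamis <- vapply(prof, function(p) p$mean_ami, numeric(1))
    use <- is.finite(cdis) & abs(mamis) >= eps & abs(cdis) <= cdi_cap
    amat <- do.call(rbind, lapply(prof, function(p) p$ami))
    curves[[g]] <- data.frame(
      contrast = prof[[1]]$contrasts,
      ami_mean = colMeans(amat, na.rm = TRUE),
      ami_sem = apply(amat, 2, function(v)
        stats::sd(v, na.rm = TRUE) / sqrt(sum(is.finite(v)))))
    if (sum(use) >= 3) {
      bm <- boot_mean(cdis[use], n_boot = n_boot,
                      seed = child_seed(seed, match(g, sort(unique(groups)))))
      row <- data.frame(group = g, n = length(idx), n_used = sum(use),
                        mean_cdi = bm$point, ci_low = bm$ci_low,
                        ci_high = bm$ci_high, mean_ami = mean(mamis))
    } else {
      warning(sprintf("group %s has < 3 usable units; CI omitted", g))
      row <- data.frame(group = g, n = length(idx), n_used = sum(use),
                        mean_cdi = mean(cdis[use]), ci_low = NA_real_,
                        ci_high = NA_real_, mean_ami = mean(mamis))
    }
    out[[g]] <- row
  }
  list(summary = do.call(rbind, out), ami_curves = curves)
}
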