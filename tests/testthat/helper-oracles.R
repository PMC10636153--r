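## Shared fixtures and independent oracles used across the test files.
##
## Frozen dip-statistic reference values: computed once with an exact
## linear-programming oracle (dip = min over unimodal CDFs G of
## sup|F_n - G|, G piecewise linear with a jump allowed only at the mode,
## minimised by an LP per mode placement).  The samples are regenerated
## below from the recorded seed; the expected dips are frozen here.
dip_reference_samples <- function() {
  laminattn:::with_seed(31, {
    lapply(1:25, function(i) {
      n <- sample(4:12, 1)
      if (i %% 2 == 0) sample(1:5, n, replace = TRUE) + 0 else rnorm(n)
    })
  })
}
dip_reference_values <- c(
  0.125000, 0.125000, 0.113737, 0.100000, 0.070730, 0.125000, 0.125101,
  0.150000, 0.110848, 0.166667, 0.089171, 0.222222, 0.077948, 0.125000,
  0.101791, 0.071429, 0.117014, 0.166667, 0.125000, 0.111111, 0.122680,
  0.125000, 0.125000, 0.166667, 0.147377)

## ---- shared spike-train fixtures -------------------------------------------

## step-rate trials: baseline before `onset`, `high` after, Poisson
step_trials <- function(n_trials, base, high, onset = 50,
                        span = c(-200, 400)) {
  lapply(seq_len(n_trials), function(i) {
    pre <- laminattn:::rpois_segment(base, span[1], onset)
    post <- laminattn:::rpois_segment(high, onset, span[2])
    c(pre, post)
  })
}

## chop a long spike train into fixed-length pseudo-trials
chop_train <- function(x, width = 1000, n = NULL) {
  if (is.null(n)) n <- floor(max(x) / width)
  lapply(seq_len(n), function(k)
    x[x >= (k - 1) * width & x < k * width] - (k - 1) * width)
}

## minimal hand-built trial set: one unit; the attend-in trains default to
## the attend-away ones but can be supplied independently
manual_trial_set <- function(spike_times_by_trial, contrast = 40,
                             trains_in = spike_times_by_trial) {
  structure(list(contrasts = contrast, span = c(-200, 400),
                 n_trials = length(spike_times_by_trial), seed = 0,
                 spikes = list(list("in" = list(trains_in),
                                    away = list(spike_times_by_trial)))),
            class = "trial_set")
}

## brute-force grid-search CRF oracle: best SSE over a dense parameter grid,
## using the closed-form SSE expansion in (r_max, m) for speed.  The grid is
## 50 x 50 x 20 x 20 over (r_max, c50, n, m).
crf_grid_best_sse <- function(contrasts, y) {
  r_grid <- seq(0, 2 * max(y), length.out = 50)
  c50_grid <- exp(seq(log(0.5), log(100), length.out = 50))
  n_grid <- seq(0.3, 6, length.out = 20)
  m_grid <- seq(0, max(y), length.out = 20)
  yty <- sum(y * y); sy <- sum(y); nn <- length(y)
  best <- Inf
  rm_outer <- outer(r_grid^2, rep(1, length(m_grid)))
  for (c50 in c50_grid) for (en in n_grid) {
    cn <- contrasts^en
    s <- cn / (cn + c50^en)
    ss <- sum(s * s); s1 <- sum(s); sy_ <- sum(s * y)
    ## SSE(r, m) = yty - 2 r sy_ - 2 m sy + r^2 ss + 2 r m s1 + m^2 nn
    sse <- yty - 2 * outer(r_grid * sy_, rep(1, length(m_grid))) -
      2 * outer(rep(1, length(r_grid)), m_grid * sy) +
      rm_outer * ss +
      2 * outer(r_grid, m_grid) * s1 +
      outer(rep(1, length(r_grid)), m_grid^2) * nn
    b <- min(sse)
    if (b < best) best <- b
  }
  best
}
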