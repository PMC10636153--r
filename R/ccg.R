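## Pooled spike-train cross-correlograms with shift-predictor or jitter
## correction, window means and layer-wise class-pair summaries.

#' Cross-correlogram between two pooled spike trains
#'
#' Counts spike pairs at each lag within trials, normalises by the geometric
#' mean of the two spike counts (coincidences per spike per bin) and, when
#' requested, subtracts a correction for stimulus-locked covariation: the
#' shift predictor (pair counts with the target train rotated by one trial)
#' or a jitter predictor (target spikes re-drawn uniformly within
#' \code{jitter_ms} windows, averaged over repeats).
#'
#' @param train_ref,train_tgt Lists of per-trial spike-time vectors on a
#'   common time base (ms); or bare numeric vectors for a single trial.
#' @param max_lag Maximum lag, ms (>= 25).
#' @param bin Lag bin width, ms.
#' @param correction One of "shift", "jitter", "none".
#' @param jitter_ms Jitter window for the jitter predictor.
#' @param n_jitter Jitter repeats.
#' @param seed RNG seed (jitter only).
#' @return List of class \code{"correlogram"}: lags, value (corrected when
#'   requested), raw, predictor, corrected, n_spikes_ref, n_spikes_tgt,
#'   flagged (empty train).
#' @export
pooled_ccg <- function(train_ref, train_tgt, max_lag = 100, bin = 1,
                       correction = c("shift", "jitter", "none"),
                       jitter_ms = 25, n_jitter = 10, seed = 1) {
  correction <- match.arg(correction)
  if (max_lag < 25) stop_config("max_lag must be >= 25 ms")
  if (is.numeric(train_ref)) train_ref <- list(train_ref)
  if (is.numeric(train_tgt)) train_tgt <- list(train_tgt)
  stopifnot(length(train_ref) == length(train_tgt))
  n_trials <- length(train_ref)
  lags <- seq(-max_lag, max_lag, by = bin)
  n_ref <- sum(lengths(train_ref)); n_tgt <- sum(lengths(train_tgt))
  if (n_ref == 0 || n_tgt == 0) {
    return(structure(list(lags = lags, value = rep(0, length(lags)),
                          raw = rep(0, length(lags)), predictor = NULL,
                          corrected = correction != "none",
                          n_spikes_ref = n_ref, n_spikes_tgt = n_tgt,
                          flagged = TRUE),
                     class = "correlogram"))
  }
  count_all <- function(ref_list, tgt_list) {
    tot <- integer(length(lags))
    for (tr in seq_along(ref_list)) {
      tot <- tot + .ccg_count(sort(ref_list[[tr]]), sort(tgt_list[[tr]]),
                              max_lag, bin)
    }
    tot
  }
  norm <- sqrt(n_ref * n_tgt)
  raw_counts <- count_all(train_ref, train_tgt)
  raw <- raw_counts / norm
  predictor <- NULL
  value <- raw
  if (correction == "shift" && n_trials > 1) {
    shifted <- train_tgt[c(2:n_trials, 1)]
    predictor <- count_all(train_ref, shifted) / norm
    value <- raw - predictor
  } else if (correction == "jitter") {
    acc <- numeric(length(lags))
    with_seed(seed, {
      for (r in seq_len(n_jitter)) {
        jit <- lapply(train_tgt, function(t)
          floor(t / jitter_ms) * jitter_ms + runif(length(t), 0, jitter_ms))
        acc <- acc + count_all(train_ref, jit)
      }
    })
    predictor <- acc / n_jitter / norm
    value <- raw - predictor
  } else if (correction == "shift") {
    warning("shift predictor needs > 1 trial; returning uncorrected CCG")
    correction <- "none"
  }
  structure(list(lags = lags, value = value, raw = raw,
                 raw_counts = raw_counts, predictor = predictor,
                 corrected = correction != "none",
                 n_spikes_ref = n_ref, n_spikes_tgt = n_tgt,
                 flagged = FALSE),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  pk <- which.max(abs(x$value))
  cat(sprintf(
    "CCG: %d lags (%g..%g ms), %s; peak %.4g at %g ms (%d x %d spikes)\n",
    length(x$lags), min(x$lags), max(x$lags),
    if (x$corrected) "corrected" else "raw",
    x$value[pk], x$lags[pk], x$n_spikes_ref, x$n_spikes_tgt))
  invisible(x)
}

#' Mean correlogram value in a symmetric window around zero lag
#'
#' @param correlogram A \code{\link{pooled_ccg}} result.
#' @param window_halfwidth Half-width in ms (default 25, i.e. a 50-ms
#'   window).
#' @return Scalar mean of the (corrected) values over |lag| <= halfwidth.
#' @export
window_mean <- function(correlogram, window_halfwidth = 25) {
  if (window_halfwidth > max(correlogram$lags))
    stop_config("window exceeds the lag range")
  sel <- abs(correlogram$lags) <= window_halfwidth
  mean(correlogram$value[sel])
}

#' Layer-wise class-pair correlograms from pooled unit trains
#'
#' Pools the spikes of all units of each class within a layer (per session),
#' computes the corrected CCG of each class pair per session and averages
#' across sessions.
#'
#' @param unit_trains List (one element per unit) of per-trial spike-time
#'   vectors.
#' @param class_labels,layer_labels Per-unit labels.
#' @param session Per-unit session id (default: a single session).
#' @param pairs List of 2-vectors c(ref_class, tgt_class) to evaluate.
#' @param ... Passed to \code{\link{pooled_ccg}}.
#' @return Nested list \code{result[[layer]][[pair_name]]}: averaged
#'   correlogram (list with lags, value, n_sessions, window_mean).
#' @export
group_ccg_by_layer <- function(unit_trains, class_labels, layer_labels,
                               session = rep(1L, length(unit_trains)),
                               pairs = list(c("narrow", "broad"),
                                            c("medium", "broad")), ...) {
  stopifnot(length(unit_trains) == length(class_labels),
            length(unit_trains) == length(layer_labels))
  pool <- function(idx) {
    if (length(idx) == 0) return(NULL)
    n_tr <- length(unit_trains[[idx[1]]])
    lapply(seq_len(n_tr), function(tr)
      sort(unlist(lapply(unit_trains[idx], `[[`, tr), use.names = FALSE)))
  }
  out <- list()
  for (lay in unique(layer_labels)) {
    lay_res <- list()
    for (pr in pairs) {
      per_session <- list()
      for (ses in unique(session)) {
        i_ref <- which(layer_labels == lay & class_labels == pr[1] &
                         session == ses)
        i_tgt <- which(layer_labels == lay & class_labels == pr[2] &
                         session == ses)
        if (length(i_ref) == 0 || length(i_tgt) == 0) next
        cg <- pooled_ccg(pool(i_ref), pool(i_tgt), ...)
        if (!cg$flagged) per_session[[length(per_session) + 1]] <- cg
      }
      if (length(per_session) == 0) {
        warning(sprintf("no %s/%s pair in layer %s; skipped",
                        pr[1], pr[2], lay))
        next
      }
      vals <- rowMeans(do.call(cbind, lapply(per_session, `[[`, "value")))
      avg <- list(lags = per_session[[1]]$lags, value = vals,
                  n_sessions = length(per_session))
      avg$window_mean <- mean(vals[abs(avg$lags) <= 25])
      lay_res[[paste(pr, collapse = "_")]] <- avg
    }
    out[[lay]] <- lay_res
  }
  out
}
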