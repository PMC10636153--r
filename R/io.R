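## Plain-text serialization of trial sets: a long-format CSV of spike times
## plus a JSON sidecar with the trial structure and generator seed.

#' Write a trial set to disk
#'
#' Spike times go to \code{<path>.csv} in long format (unit, condition,
#' contrast_index, trial, time_ms); contrasts, span, trial counts and seed
#' go to \code{<path>.json}.
#'
#' @param trial_set A \code{\link{simulate_trials}} result.
#' @param path Output path stem (without extension).
#' @return \code{path}, invisibly.
#' @export
write_trialset <- function(trial_set, path) {
  stopifnot(inherits(trial_set, "trial_set"))
  rows <- list()
  for (u in seq_along(trial_set$spikes)) {
    for (cond in names(trial_set$spikes[[u]])) {
      per_contrast <- trial_set$spikes[[u]][[cond]]
      for (ci in seq_along(per_contrast)) {
        for (tr in seq_along(per_contrast[[ci]])) {
          t <- per_contrast[[ci]][[tr]]
          if (length(t) == 0) next
          rows[[length(rows) + 1]] <- data.frame(
            unit = u, condition = cond, contrast_index = ci, trial = tr,
            time_ms = t)
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  write_json(list(contrasts = trial_set$contrasts, span = trial_set$span,
                  n_trials = trial_set$n_trials, seed = trial_set$seed,
                  n_units = length(trial_set$spikes)),
             paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trial set written by \code{\link{write_trialset}}
#'
#' @param path Path stem used when writing.
#' @return A \code{"trial_set"} object.
#' @export
read_trialset <- function(path) {
  meta <- read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read.csv(paste0(path, ".csv"))
  spikes <- vector("list", meta$n_units)
  empty <- lapply(seq_along(meta$contrasts), function(i)
    lapply(seq_len(meta$n_trials), function(j) numeric(0)))
  for (u in seq_len(meta$n_units))
    spikes[[u]] <- list("in" = empty, away = empty)
  for (key in split(df, list(df$unit, df$condition, df$contrast_index,
                             df$trial), drop = TRUE)) {
    spikes[[key$unit[1]]][[key$condition[1]]][[key$contrast_index[1]]][[
      key$trial[1]]] <- key$time_ms
  }
  structure(list(contrasts = meta$contrasts, span = meta$span,
                 n_trials = meta$n_trials, seed = meta$seed,
                 spikes = spikes),
            class = "trial_set")
}
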