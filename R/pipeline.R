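## End-to-end pipeline: simulate a laminar population, classify waveforms,
## fit CRFs, compute AMI/CDI by class and layer, estimate latencies, and run
## the two mechanistic models.

#' Pipeline run configuration
#'
#' @param preset \code{"paper_like"} (class-by-layer attention scenario with
#'   contrast gain for broad units in superficial/input layers) or
#'   \code{"null"} (no attention effect, unimodal waveform widths).
#' @param seed Master seed; every stage derives its own seed from it.
#' @param n_units Population size.
#' @param n_trials Trials per contrast per condition.
#' @param n_boot Bootstrap resamples for CIs.
#' @param k_max Largest cluster count scanned for the elbow.
#' @param n_restarts Consensus k-means restarts.
#' @param run_models Also run the normalization-model sweep and the E-I
#'   network sweep (slower).
#' @param out_dir Optional output directory for CSV/JSON reports.
#' @return List of class \code{"run_config"}.
#' @export
run_config <- function(preset = c("paper_like", "null"), seed = 7,
                       n_units = 240, n_trials = 48, n_boot = 10000,
                       k_max = 6, n_restarts = 200, run_models = FALSE,
                       out_dir = NULL) {
  preset <- match.arg(preset)
  structure(list(preset = preset, seed = seed, n_units = n_units,
                 n_trials = n_trials, n_boot = n_boot, k_max = k_max,
                 n_restarts = n_restarts, run_models = run_models,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (1) synthetic population and trials; (2) PTD measurement,
#' consensus k-means over k = 1..k_max, AIC/BIC elbows, dip test,
#' ground-truth label agreement, PCA cross-check; (3) visual-responsiveness
#' screen, per-unit CRF fits and AMI/CDI, aggregation by detected class x
#' true layer; (4) per-unit latency and class summaries; (5) optionally the
#' normalization-model field sweep and the E-I network sigma_I sweep.
#' When \code{out_dir} is set, per-unit tables and group summaries are
#' written as CSV/JSON (deterministic content for a fixed config and seed).
#'
#' @param config A \code{\link{run_config}}.
#' @return List of class \code{"run_report"}.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  ## --- stage 1: synthetic data ------------------------------------------
  pop_cfg <- if (config$preset == "null") {
    population_config(n_units = config$n_units,
                      ptd_modes = c(narrow = 0.35, medium = 0.35,
                                    broad = 0.35),
                      ptd_sd = 0.05, scenario = "null")
  } else {
    population_config(n_units = config$n_units)
  }
  pop <- make_population(pop_cfg, seed = child_seed(seed, 1))
  trials <- simulate_trials(pop, n_trials = config$n_trials,
                            seed = child_seed(seed, 2))
  truth <- as.data.frame(pop)
  ## --- stage 2: waveform classification ---------------------------------
  ptd <- vapply(pop$units, function(u) measure_ptd(u$waveform), numeric(1))
  ks <- seq_len(config$k_max)
  sols <- lapply(ks, function(k)
    meta_kmeans(ptd, k, n_restarts = config$n_restarts,
                seed = child_seed(seed, 10 + k)))
  aic <- vapply(sols, `[[`, numeric(1), "aic")
  bic <- vapply(sols, `[[`, numeric(1), "bic")
  k_aic <- kneedle_elbow(ks, aic)
  k_bic <- kneedle_elbow(ks, bic)
  k_sel <- if (!is.na(k_aic)) k_aic else k_bic
  sol <- sols[[k_sel]]
  classes <- name_classes_by_width(sol$labels, ptd)
  agreement <- label_agreement(truth$cls, classes)$agreement
  dip <- dip_test(ptd, n_boot = 2000, seed = child_seed(seed, 3))
  wf_mat <- normalize_waveforms(lapply(pop$units, `[[`, "waveform"))
  pca <- pca_crosscheck(wf_mat, sol$labels, k = k_sel,
                        seed = child_seed(seed, 4))
  ## --- stage 3: CRF, AMI, CDI -------------------------------------------
  responsive <- vapply(seq_along(pop$units), function(u)
    screen_visual_responsiveness(trials, u), logical(1))
  idx <- which(responsive)
  profiles <- lapply(idx, function(u) unit_crf_profile(trials, u))
  groups_cl <- classes[idx]
  groups_cl_layer <- paste(classes[idx], truth$layer[idx], sep = ".")
  agg_class <- aggregate_by_group(profiles, groups_cl,
                                  n_boot = config$n_boot,
                                  seed = child_seed(seed, 5))
  agg_cl_layer <- aggregate_by_group(profiles, groups_cl_layer,
                                     n_boot = config$n_boot,
                                     seed = child_seed(seed, 6))
  ## --- stage 4: latency --------------------------------------------------
  grid <- seq(trials$span[1], trials$span[2] - 1, by = 1)
  latencies <- vapply(seq_along(pop$units), function(u) {
    ## pool trials of the top two contrasts, both conditions
    top <- order(trials$contrasts, decreasing = TRUE)[1:2]
    trains <- c(unlist(lapply(top, function(ci)
      trials$spikes[[u]][["in"]][[ci]]), recursive = FALSE),
      unlist(lapply(top, function(ci)
        trials$spikes[[u]][["away"]][[ci]]), recursive = FALSE))
    est <- adaptive_rate(trains, grid)
    response_time(est, trains, n_boot = 500,
                  seed = child_seed(seed, 100 + u))
  }, numeric(1))
  lat_summary <- class_latency_summary(latencies, classes,
                                       n_boot = config$n_boot,
                                       seed = child_seed(seed, 7))
  ## --- stage 5: mechanistic models (optional) ---------------------------
  nm <- NULL; ei <- NULL
  if (config$run_models) {
    nm <- sweep_fields(nm_config())
    ei <- ei_correlation_vs_sigma(net_config(), sigma_I_values = c(1, 2, 4),
                                  n_seeds = 3, seed = child_seed(seed, 8))
  }
  report <- structure(list(
    preset = config$preset, seed = seed,
    n_units = config$n_units, n_responsive = length(idx),
    ptd = ptd, truth = truth,
    k_aic = k_aic, k_bic = k_bic, k_selected = k_sel,
    aic = aic, bic = bic,
    classes = classes, class_agreement = agreement,
    dip = dip, pca_agreement = pca$agreement_fraction,
    class_summary = agg_class, class_layer_summary = agg_cl_layer,
    latencies = latencies, latency_summary = lat_summary,
    nm_cdi = nm, ei_sweep = ei,
    config = config), class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

## write the tabular parts of a report as CSV/JSON (stable ordering)
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  units <- data.frame(report$truth,
                      ptd_measured = report$ptd,
                      class_detected = report$classes,
                      latency_ms = report$latencies)
  write.csv(units, file.path(out_dir, "units.csv"), row.names = FALSE)
  write.csv(report$class_layer_summary$summary,
            file.path(out_dir, "cdi_by_class_layer.csv"), row.names = FALSE)
  write.csv(report$latency_summary$per_class,
            file.path(out_dir, "latency_by_class.csv"), row.names = FALSE)
  meta <- list(preset = report$preset, seed = report$seed,
               k_selected = report$k_selected, k_aic = report$k_aic,
               k_bic = report$k_bic,
               class_agreement = report$class_agreement,
               dip_p = report$dip$p_value,
               pca_agreement = report$pca_agreement)
  write_json(meta, file.path(out_dir, "report.json"), auto_unbox = TRUE,
             digits = NA)
  if (!is.null(report$nm_cdi))
    write.csv(as.data.frame(report$nm_cdi),
              file.path(out_dir, "nm_cdi_matrix.csv"))
  if (!is.null(report$ei_sweep))
    write.csv(report$ei_sweep, file.path(out_dir, "ei_sweep.csv"),
              row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline report (preset %s, seed %d)\n", x$preset, x$seed))
  cat(sprintf("  units: %d (%d visually responsive)\n", x$n_units,
              x$n_responsive))
  cat(sprintf("  k (AIC/BIC elbows): %s / %s; selected %d\n",
              x$k_aic, x$k_bic, x$k_selected))
  cat(sprintf("  class agreement with ground truth: %.1f%%\n",
              100 * x$class_agreement))
  cat(sprintf("  dip test p = %.4g; PCA cross-check agreement %.1f%%\n",
              x$dip$p_value, 100 * x$pca_agreement))
  cat("  CDI by class x layer:\n")
  print(x$class_layer_summary$summary, row.names = FALSE)
  invisible(x)
}
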