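## Columnar conductance-based E-I spiking network: Gaussian cross-column
## connectivity, step-input simulations and spike-time-correlation sweeps.

#' Configuration for the columnar E-I spiking network
#'
#' A line of cortical columns, each holding excitatory (E) and inhibitory
#' (I) leaky integrate-and-fire neurons at a fixed 4:1 ratio.  Only E
#' neurons project across columns; the weight of a connection from column
#' d1 onto a neuron in column d2 decays as a Gaussian of the column distance
#' with SD \code{sigma_E} (targets E) or \code{sigma_I} (targets I).
#' Cross-column weights are normalised so the summed input onto a neuron is
#' independent of the pooling width; inhibition stays within-column.
#'
#' @param n_columns Number of columns in a line (open ends, no wraparound).
#' @param n_E,n_I Neurons per column (must satisfy n_E = 4 n_I).
#' @param sigma_E,sigma_I Gaussian SDs of cross-column excitation onto E and
#'   I targets, in column units.
#' @param w_EE,w_EI,w_IE,w_II Total synaptic weight (conductance, units of
#'   the leak) a neuron receives from each source population: E onto E,
#'   E onto I, I onto E, I onto I.
#' @param tau_m_E,tau_m_I Membrane time constants, ms.
#' @param v_rest,v_th,v_reset Resting, threshold and reset potentials, mV.
#' @param e_exc,e_inh Synaptic reversal potentials, mV.
#' @param tau_syn_e,tau_syn_i Synaptic decay time constants, ms.
#' @param refractory Absolute refractory period, ms.
#' @param dt Euler step, ms.
#' @param ext_rate_base,ext_rate_step Per-neuron external Poisson rate (Hz)
#'   before/during the step input.
#' @param step_start,step_end Step-input interval, ms.
#' @param w_ext Conductance increment per external event.
#' @param duration Simulation length, ms.
#' @param rate_ceiling Abort threshold on the population rate, spikes/s.
#' @return List of class \code{"net_config"}.
#' @export
net_config <- function(n_columns = 9, n_E = 80, n_I = 20,
                       sigma_E = 2, sigma_I = 2,
                       w_EE = 0.5, w_EI = 8, w_IE = 4, w_II = 8,
                       tau_m_E = 20, tau_m_I = 10,
                       v_rest = -70, v_th = -50, v_reset = -60,
                       e_exc = 0, e_inh = -80,
                       tau_syn_e = 5, tau_syn_i = 10,
                       refractory = 2, dt = 0.1,
                       ext_rate_base = 1100, ext_rate_step = 2200,
                       step_start = 500, step_end = Inf,
                       w_ext = 0.075, duration = 4000,
                       rate_ceiling = 250) {
  if (n_E != 4 * n_I)
    stop_config("E:I ratio must be 4:1 (got %d:%d)", n_E, n_I)
  if (sigma_E <= 0 || sigma_I <= 0)
    stop_config("sigma_E and sigma_I must be > 0")
  if (duration <= step_start)
    stop_config("duration must exceed the step onset")
  structure(as.list(environment()), class = "net_config")
}

#' Build the network connectivity
#'
#' Returns dense target-major weight matrices: entry (i, j) is the
#' conductance increment delivered to neuron i when neuron j fires.
#' Cross-column Gaussian factors are normalised per target so each neuron's
#' total weight from a source population equals the configured scalar.
#'
#' @param config A \code{\link{net_config}}.
#' @return List of class \code{"ei_network"}: w_exc, w_inh (N x N), is_e,
#'   column (per-neuron), config.
#' @export
build_network <- function(config = net_config()) {
  stopifnot(inherits(config, "net_config"))
  nc <- config$n_columns
  per_col <- config$n_E + config$n_I
  N <- nc * per_col
  column <- rep(seq_len(nc), each = per_col)
  is_e <- rep(c(rep(TRUE, config$n_E), rep(FALSE, config$n_I)), nc)
  gauss_w <- function(sigma) {
    k <- outer(seq_len(nc), seq_len(nc),
               function(a, b) exp(-(a - b)^2 / (2 * sigma^2)))
    sweep(k, 1, rowSums(k), "/")  # normalise over source columns per target
  }
  k_e <- gauss_w(config$sigma_E)  # E sources -> E targets
  k_i <- gauss_w(config$sigma_I)  # E sources -> I targets
  w_exc <- matrix(0, N, N)
  w_inh <- matrix(0, N, N)
  e_idx <- which(is_e); i_idx <- which(!is_e)
  for (ct in seq_len(nc)) {
    tgt_e <- e_idx[column[e_idx] == ct]
    tgt_i <- i_idx[column[i_idx] == ct]
    for (cs in seq_len(nc)) {
      src_e <- e_idx[column[e_idx] == cs]
      w_exc[tgt_e, src_e] <- config$w_EE * k_e[ct, cs] / config$n_E
      w_exc[tgt_i, src_e] <- config$w_EI * k_i[ct, cs] / config$n_E
    }
    src_i <- i_idx[column[i_idx] == ct]  # inhibition is within-column
    w_inh[tgt_e, src_i] <- config$w_IE / config$n_I
    w_inh[tgt_i, src_i] <- config$w_II / config$n_I
  }
  structure(list(w_exc = w_exc, w_inh = w_inh, is_e = is_e,
                 column = column, config = config),
            class = "ei_network")
}

#' Simulate the spiking network
#'
#' Conductance-based LIF dynamics integrated with a fixed Euler step under
#' independent external Poisson drive that steps up during the configured
#' interval.  Deterministic given the seed.
#'
#' @param config A \code{\link{net_config}}, or an already-built
#'   \code{\link{build_network}} result.
#' @param seed RNG seed.
#' @return List of class \code{"spike_raster"}: data.frame \code{spikes}
#'   (time_ms, neuron, column, type), n_neurons, duration, aborted.
#' @export
run_simulation <- function(config = net_config(), seed = 1) {
  net <- if (inherits(config, "ei_network")) config else
    build_network(config)
  cfg <- net$config
  res <- with_seed(seed, .lif_simulate(
    net$w_exc, net$w_inh, net$is_e,
    duration_ms = cfg$duration, dt = cfg$dt,
    tau_m_e = cfg$tau_m_E, tau_m_i = cfg$tau_m_I,
    v_rest = cfg$v_rest, v_th = cfg$v_th, v_reset = cfg$v_reset,
    e_exc = cfg$e_exc, e_inh = cfg$e_inh,
    tau_syn_e = cfg$tau_syn_e, tau_syn_i = cfg$tau_syn_i,
    refractory_ms = cfg$refractory,
    ext_rate_base = cfg$ext_rate_base, ext_rate_step = cfg$ext_rate_step,
    step_start = cfg$step_start,
    step_end = min(cfg$step_end, cfg$duration),
    w_ext = cfg$w_ext, rate_ceiling = cfg$rate_ceiling))
  if (res$aborted)
    warning("runaway activity: population rate exceeded the ceiling; raster truncated")
  spikes <- data.frame(time_ms = res$times, neuron = res$ids,
                       column = net$column[res$ids],
                       type = ifelse(net$is_e[res$ids], "E", "I"))
  structure(list(spikes = spikes, n_neurons = length(net$is_e),
                 column = net$column, is_e = net$is_e,
                 duration = cfg$duration, aborted = res$aborted,
                 config = cfg),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  rate <- nrow(x$spikes) / x$n_neurons / (x$duration / 1000)
  cat(sprintf("Spike raster: %d spikes, %d neurons, %.0f ms (%.1f sp/s)%s\n",
              nrow(x$spikes), x$n_neurons, x$duration, rate,
              if (x$aborted) " [ABORTED]" else ""))
  invisible(x)
}

## mean rate (spikes/s per neuron) of a subset in a time window
raster_rate <- function(raster, type = c("E", "I"), window) {
  type <- match.arg(type)
  sel <- raster$spikes$type == type &
    raster$spikes$time_ms >= window[1] & raster$spikes$time_ms < window[2]
  n_type <- sum((raster$is_e & type == "E") | (!raster$is_e & type == "I"))
  sum(sel) / n_type / (diff(window) / 1000)
}

## pooled per-"trial" trains of one population in the centre column:
## steady-state activity chopped into equal pseudo-trials for the shift
## predictor
center_pool_trains <- function(raster, type, chunk_ms = 500,
                               t_start = NULL) {
  cols <- raster$column
  center <- ceiling(max(cols) / 2)
  if (is.null(t_start)) t_start <- raster$config$step_start + 250
  sp <- raster$spikes
  sel <- sp$column == center & sp$type == type & sp$time_ms >= t_start
  tt <- sp$time_ms[sel] - t_start
  n_chunks <- floor((raster$duration - t_start) / chunk_ms)
  lapply(seq_len(n_chunks), function(k)
    sort(tt[tt >= (k - 1) * chunk_ms & tt < k * chunk_ms]) -
      (k - 1) * chunk_ms)
}

#' E-I spike-time correlation as a function of pooling widths
#'
#' For each value of \code{sigma_I} (and, in a second sweep, each
#' \code{sigma_E}) the network is simulated across seeds; centre-column E
#' and I spikes are pooled, the shift-predictor-corrected CCG computed, and
#' its peak amplitude (maximum within +/- 10 ms of zero lag) and +/- 25-ms
#' window mean recorded.
#'
#' @param config A \code{\link{net_config}} used as the base.
#' @param sigma_I_values,sigma_E_values Sweep grids (column units); when one
#'   grid is swept the other parameter stays at its base value.
#' @param n_seeds Simulation seeds per grid value.
#' @param seed Base seed.
#' @param max_lag,chunk_ms CCG parameters.
#' @return data.frame: sweep ("sigma_I"/"sigma_E"), sigma, seed, peak,
#'   win_mean, rate_E, rate_I.
#' @export
ei_correlation_vs_sigma <- function(config = net_config(),
                                    sigma_I_values = c(1, 2, 4),
                                    sigma_E_values = NULL,
                                    n_seeds = 10, seed = 1,
                                    max_lag = 100, chunk_ms = 500) {
  run_one <- function(sweep, sigma, s) {
    cfg <- config
    if (sweep == "sigma_I") cfg$sigma_I <- sigma else cfg$sigma_E <- sigma
    cfg <- do.call(net_config, unclass(cfg))
    ras <- run_simulation(cfg, seed = child_seed(seed, s + 997L *
                                                   round(100 * sigma)))
    e_tr <- center_pool_trains(ras, "E", chunk_ms)
    i_tr <- center_pool_trains(ras, "I", chunk_ms)
    cg <- pooled_ccg(e_tr, i_tr, max_lag = max_lag, correction = "shift")
    steady <- c(ras$config$step_start + 250, ras$duration)
    data.frame(sweep = sweep, sigma = sigma, seed = s,
               peak = max(cg$value[abs(cg$lags) <= 10]),
               win_mean = window_mean(cg, 25),
               rate_E = raster_rate(ras, "E", steady),
               rate_I = raster_rate(ras, "I", steady))
  }
  rows <- list()
  for (sig in sigma_I_values) for (s in seq_len(n_seeds))
    rows[[length(rows) + 1]] <- run_one("sigma_I", sig, s)
  if (!is.null(sigma_E_values))
    for (sig in sigma_E_values) for (s in seq_len(n_seeds))
      rows[[length(rows) + 1]] <- run_one("sigma_E", sig, s)
  do.call(rbind, rows)
}
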