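## Normalization model of attention: stimulation, suppressive and attention
## fields on a 1-D space x orientation grid, with field-size sweeps.

#' Configuration for the normalization model of attention
#'
#' One-dimensional visual space (two mirror-symmetric stimulus locations)
#' crossed with an orientation axis.  Stimulus drive is a Gaussian patch in
#' space and orientation scaled by contrast, passed through a pointwise
#' nonlinearity and pooled by the stimulation field; attentional gain
#' multiplies the excitatory drive before divisive normalization by the
#' suppressive-field pool plus a semisaturation constant.
#'
#' @param space_halfwidth Half-extent of the spatial grid, degrees.
#' @param n_space,n_ori Grid sizes (space, orientation).
#' @param stim_pos Eccentricity of the two stimuli, degrees (at +/- this).
#' @param stim_size Stimulus patch SD, degrees.
#' @param stim_ori_sd Stimulus orientation tuning SD, degrees.
#' @param stimfield_size Stimulation-field SD, degrees.
#' @param stimfield_ori_sd Stimulation-field orientation pooling SD, degrees.
#' @param suppfield_size Suppressive-field SD, degrees (pools all
#'   orientations).
#' @param attnfield_size Attention-field SD, degrees.
#' @param attn_gain Peak multiplicative attentional gain (>= 1).
#' @param sigma_norm Semisaturation constant, drive units.
#' @param io_exponent Pointwise input-output exponent applied to the
#'   stimulus drive before stimulation-field pooling.
#' @return List of class \code{"nm_config"}.
#' @export
nm_config <- function(space_halfwidth = 16, n_space = 128, n_ori = 64,
                      stim_pos = 4, stim_size = 1, stim_ori_sd = 20,
                      stimfield_size = 1, stimfield_ori_sd = 30,
                      suppfield_size = 3, attnfield_size = 4,
                      attn_gain = 2, sigma_norm = 1e-2, io_exponent = 2) {
  cfg <- list(space_halfwidth = space_halfwidth, n_space = n_space,
              n_ori = n_ori, stim_pos = stim_pos, stim_size = stim_size,
              stim_ori_sd = stim_ori_sd, stimfield_size = stimfield_size,
              stimfield_ori_sd = stimfield_ori_sd,
              suppfield_size = suppfield_size,
              attnfield_size = attnfield_size, attn_gain = attn_gain,
              sigma_norm = sigma_norm, io_exponent = io_exponent)
  step <- 2 * space_halfwidth / n_space
  for (nm in c("stim_size", "stimfield_size", "suppfield_size",
               "attnfield_size")) {
    if (cfg[[nm]] <= 0) stop_config("%s must be > 0", nm)
    if (cfg[[nm]] < 2 * step)
      stop_config("%s = %g deg is below 2 grid steps (%g deg); refine grid",
                  nm, cfg[[nm]], 2 * step)
  }
  if (attn_gain < 1) stop_config("attn_gain must be >= 1")
  if (sigma_norm <= 0) stop_config("sigma_norm must be > 0")
  structure(cfg, class = "nm_config")
}

## Gaussian spatial convolution along rows (space dim) of a space x ori
## matrix, kernel normalised to unit sum; truncated (open) boundaries
nm_conv_space <- function(mat, sigma_deg, step) {
  k <- gauss_kernel(sigma_deg, step) * step  # unit-sum weights
  apply(mat, 2, function(col) conv_same(col, k / step, step,
                                        edge_correct = FALSE))
}

## circular Gaussian convolution along the orientation dim (180 deg period)
nm_conv_ori <- function(mat, sigma_deg, ori_step) {
  n <- ncol(mat)
  d <- ori_step * pmin(0:(n - 1), n - (0:(n - 1)))  # circular distances
  k <- exp(-0.5 * (d / sigma_deg)^2)
  k <- k / sum(k)
  t(apply(mat, 1, function(row) Re(fft(fft(row) * fft(k), inverse = TRUE)) /
            n))
}

#' Default contrast grid for normalization-model simulations
#'
#' 16 log-spaced contrast levels in [1, 100] percent; a dense grid keeps the
#' low/high AMI averages entering the CDI smooth in the model parameters.
#'
#' @return Numeric vector of contrasts (percent).
#' @export
nm_default_contrasts <- function()
  round(exp(seq(log(1), log(100), length.out = 16)), 3)

#' Simulate the normalization model of attention
#'
#' Computes the probed neuron's contrast response with attention directed to
#' the stimulus in its receptive field (attend-in) and to the mirror
#' location in the opposite hemifield (attend-away), plus the resulting AMI
#' curve and CDI (low/high split at the attend-away half-maximum contrast).
#'
#' @param config An \code{\link{nm_config}}.
#' @param contrasts Contrast levels in percent.
#' @return List of class \code{"nm_result"}: contrasts, crf_attended,
#'   crf_unattended, ami, cdi (list from \code{\link{compute_cdi}}),
#'   c_half (split contrast).
#' @export
simulate_nm <- function(config = nm_config(),
                        contrasts = nm_default_contrasts()) {
  stopifnot(inherits(config, "nm_config"))
  x <- seq(-config$space_halfwidth, config$space_halfwidth,
           length.out = config$n_space)
  step <- x[2] - x[1]
  ori_step <- 180 / config$n_ori
  th <- seq(0, 180 - ori_step, by = ori_step)
  ## two stimuli: probe at +stim_pos with orientation 0, the other at
  ## -stim_pos with the orthogonal orientation
  gauss_sp <- function(center, sd) exp(-0.5 * ((x - center) / sd)^2)
  dcirc <- function(a, b) {
    d <- abs(a - b) %% 180
    pmin(d, 180 - d)
  }
  gauss_or <- function(center, sd) exp(-0.5 * (dcirc(th, center) / sd)^2)
  stim_shape <- outer(gauss_sp(config$stim_pos, config$stim_size),
                      gauss_or(0, config$stim_ori_sd)) +
    outer(gauss_sp(-config$stim_pos, config$stim_size),
          gauss_or(90, config$stim_ori_sd))
  attn_field <- function(x_att)
    1 + (config$attn_gain - 1) * gauss_sp(x_att, config$attnfield_size)
  probe_ix <- which.min(abs(x - config$stim_pos))
  probe_io <- which.min(dcirc(th, 0))
  respond <- function(c_pct, x_att) {
    drive <- (c_pct / 100 * stim_shape)^config$io_exponent
    e0 <- nm_conv_space(drive, config$stimfield_size, step)
    e0 <- nm_conv_ori(e0, config$stimfield_ori_sd, ori_step)
    e <- attn_field(x_att) * e0
    s_sp <- nm_conv_space(e, config$suppfield_size, step)
    s <- matrix(rowMeans(s_sp), nrow(s_sp), ncol(s_sp))  # full ori pooling
    r <- e / (s + config$sigma_norm)
    r[probe_ix, probe_io]
  }
  crf_att <- vapply(contrasts, respond, numeric(1), x_att = config$stim_pos)
  crf_un <- vapply(contrasts, respond, numeric(1), x_att = -config$stim_pos)
  s <- crf_att + crf_un
  ami <- ifelse(s == 0, NA_real_, (crf_att - crf_un) / s)
  ## low/high split at the attend-away half-maximum contrast
  half <- max(crf_un) / 2
  above <- which(crf_un >= half)
  c_half <- if (length(above) == 0 || max(crf_un) == 0) NA_real_ else {
    i <- above[1]
    if (i == 1) contrasts[1] else
      approx(crf_un[(i - 1):i], contrasts[(i - 1):i], xout = half)$y
  }
  cdi <- if (is.finite(c_half))
    compute_cdi(ami, contrasts, c_half) else
    list(cdi = NA_real_, valid = FALSE, unstable = TRUE,
         ami_low = NA_real_, ami_high = NA_real_,
         ami_mean = mean(ami, na.rm = TRUE))
  structure(list(contrasts = contrasts, crf_attended = crf_att,
                 crf_unattended = crf_un, ami = ami, cdi = cdi,
                 c_half = c_half, config = config),
            class = "nm_result")
}

#' Sweep stimulation- and suppressive-field sizes
#'
#' Re-simulates the model for every pair of field sizes, all other
#' parameters fixed, and records the CDI.
#'
#' @param base_config An \code{\link{nm_config}}.
#' @param stimfield_sizes,suppfield_sizes Ascending size grids, degrees.
#' @param contrasts Contrast levels in percent.
#' @return Matrix of CDI values (rows = stimulation-field sizes, cols =
#'   suppressive-field sizes), with sizes in dimnames.
#' @export
sweep_fields <- function(base_config = nm_config(),
                         stimfield_sizes = c(0.75, 1.5, 3),
                         suppfield_sizes = c(2, 4, 8),
                         contrasts = nm_default_contrasts()) {
  if (is.unsorted(stimfield_sizes) || is.unsorted(suppfield_sizes))
    stop_config("size grids must be ascending")
  out <- matrix(NA_real_, length(stimfield_sizes), length(suppfield_sizes),
                dimnames = list(stimfield = stimfield_sizes,
                                suppfield = suppfield_sizes))
  for (i in seq_along(stimfield_sizes)) for (j in seq_along(suppfield_sizes)) {
    cfg <- base_config
    cfg$stimfield_size <- stimfield_sizes[i]
    cfg$suppfield_size <- suppfield_sizes[j]
    cfg <- do.call(nm_config, unclass(cfg))
    out[i, j] <- simulate_nm(cfg, contrasts)$cdi$cdi
  }
  out
}

## is a CDI matrix nonincreasing along both axes (within tolerance)?
cdi_monotone <- function(cdi_mat, tol = 1e-6) {
  rows_ok <- all(apply(cdi_mat, 1, function(v) all(diff(v) <= tol)))
  cols_ok <- all(apply(cdi_mat, 2, function(v) all(diff(v) <= tol)))
  rows_ok && cols_ok
}

#' Robustness of the field-size/CDI pattern
#'
#' Re-runs the stimulation x suppressive field sweep across attention-field
#' sizes, stimulus sizes and input-output exponents, and reports whether the
#' CDI is nonincreasing along both field-size axes in every slice.
#'
#' @param base_config An \code{\link{nm_config}}.
#' @param attnfield_sizes,stim_sizes,io_exponents Slice grids.
#' @param stimfield_sizes,suppfield_sizes Sweep grids.
#' @param contrasts Contrast levels.
#' @return List: slices (data.frame with one row per slice: parameters,
#'   monotone flag, cdi range), all_hold (logical).
#' @export
robustness_suite <- function(base_config = nm_config(),
                             attnfield_sizes = c(3, 4, 6),
                             stim_sizes = c(0.75, 1, 1.5),
                             io_exponents = c(1, 2),
                             stimfield_sizes = c(0.75, 1.5, 3),
                             suppfield_sizes = c(2, 4, 8),
                             contrasts = nm_default_contrasts()) {
  rows <- list()
  for (af in attnfield_sizes) for (ss in stim_sizes) for (io in io_exponents) {
    cfg <- base_config
    cfg$attnfield_size <- af; cfg$stim_size <- ss; cfg$io_exponent <- io
    cfg <- do.call(nm_config, unclass(cfg))
    m <- sweep_fields(cfg, stimfield_sizes, suppfield_sizes, contrasts)
    rows[[length(rows) + 1]] <- data.frame(
      attnfield_size = af, stim_size = ss, io_exponent = io,
      monotone = cdi_monotone(m), cdi_min = min(m), cdi_max = max(m))
  }
  slices <- do.call(rbind, rows)
  list(slices = slices, all_hold = all(slices$monotone))
}
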