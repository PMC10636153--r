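test_that("connectivity obeys the 4:1 ratio and Gaussian distance decay", {
  expect_error(net_config(n_E = 80, n_I = 25), "4:1")
  expect_error(net_config(sigma_I = 0), "sigma")

  ## near-zero sigma: cross-column weights vanish relative to within-column
  net0 <- build_network(net_config(sigma_E = 0.01, sigma_I = 0.01,
                                   duration = 600))
  e1 <- which(net0$is_e & net0$column == 1)[1]
  within <- net0$w_exc[which(net0$is_e & net0$column == 5)[1],
                       which(net0$is_e & net0$column == 5)[2]]
  cross <- net0$w_exc[which(net0$is_e & net0$column == 5)[1], e1]
  expect_lt(cross, 1e-6 * within)

  ## flat limit: cross-column equals within-column weight
  netf <- build_network(net_config(sigma_E = 1000, sigma_I = 1000,
                                   duration = 600))
  tgt <- which(netf$is_e & netf$column == 5)[1]
  w_within <- netf$w_exc[tgt, which(netf$is_e & netf$column == 5)[2]]
  w_cross <- netf$w_exc[tgt, which(netf$is_e & netf$column == 1)[1]]
  expect_lt(abs(w_cross / w_within - 1), 1e-4)

  ## row sums against the closed-form Gaussian sums over column distances
  cfg <- net_config()
  net <- build_network(cfg)
  for (col in c(1, 5, 9)) {
    tgt <- which(net$is_e & net$column == col)[1]
    expect_lt(abs(sum(net$w_exc[tgt, net$is_e]) - cfg$w_EE), 1e-12)
    k <- exp(-(col - 1:9)^2 / (2 * cfg$sigma_E^2))
    manual <- sum(cfg$w_EE * (k / sum(k)))  # closed-form normalised sum
    expect_lt(abs(sum(net$w_exc[tgt, net$is_e]) - manual), 1e-12)
    tgt_i <- which(!net$is_e & net$column == col)[1]
    expect_lt(abs(sum(net$w_exc[tgt_i, net$is_e]) - cfg$w_EI), 1e-12)
    ## inhibition stays within the column
    src_i_other <- which(!net$is_e & net$column != col)
    expect_true(all(net$w_inh[tgt, src_i_other] == 0))
  }
})

test_that("simulation is deterministic per seed and silent without drive", {
  cfg <- net_config(duration = 800)
  r1 <- run_simulation(cfg, seed = 4)
  r2 <- run_simulation(cfg, seed = 4)
  expect_identical(r1$spikes, r2$spikes)
  r3 <- run_simulation(cfg, seed = 5)
  expect_false(identical(r1$spikes, r3$spikes))

  quiet <- net_config(ext_rate_base = 1e-9, ext_rate_step = 1e-9,
                      duration = 600)
  expect_equal(nrow(run_simulation(quiet, seed = 1)$spikes), 0)
})

test_that("uncoupled neurons match an isolated-neuron oracle", {
  base <- net_config(w_EE = 0, w_EI = 0, w_IE = 0, w_II = 0,
                     duration = 4000)
  full <- run_simulation(base, seed = 2)
  solo_cfg <- net_config(n_columns = 1, n_E = 4, n_I = 1,
                         w_EE = 0, w_EI = 0, w_IE = 0, w_II = 0,
                         duration = 60000)
  solo <- run_simulation(solo_cfg, seed = 3)
  win_full <- c(1000, 4000); win_solo <- c(1000, 60000)
  for (ty in c("E", "I")) {
    rf <- laminattn:::raster_rate(full, ty, win_full)
    rs <- laminattn:::raster_rate(solo, ty, win_solo)
    expect_lt(abs(rf - rs) / rs, 0.05)
  }
})

test_that("default network is stationary with exchangeable columns", {
  ras <- run_simulation(net_config(duration = 4000), seed = 6)
  expect_false(ras$aborted)
  st <- ras$spikes[ras$spikes$time_ms >= 1000, ]
  ## Mann-Kendall style trend test on 100-ms binned population counts
  bins <- cut(st$time_ms, seq(1000, 4000, by = 100))
  counts <- as.numeric(table(bins))
  mk <- suppressWarnings(cor.test(seq_along(counts), counts,
                                  method = "kendall"))
  expect_gt(mk$p.value, 0.05)
  ## E rate in a plausible cortical range
  rate_e <- laminattn:::raster_rate(ras, "E", c(1000, 4000))
  expect_gt(rate_e, 5); expect_lt(rate_e, 30)
  ## near-flat sigma: column rates are exchangeable
  rasf <- run_simulation(net_config(sigma_E = 100, sigma_I = 100,
                                    duration = 3000), seed = 7)
  stf <- rasf$spikes[rasf$spikes$time_ms >= 1000 & rasf$spikes$type == "E", ]
  col_rates <- as.numeric(table(factor(stf$column, levels = 1:9)))
  expect_lt(sd(col_rates) / mean(col_rates), 0.15)
})

test_that("runaway activity aborts with a warning", {
  bad <- net_config(w_EE = 80, w_EI = 0.01, w_IE = 0.01, w_II = 0.01,
                    ext_rate_base = 4000, ext_rate_step = 8000,
                    duration = 2000, rate_ceiling = 100)
  expect_warning(ras <- run_simulation(bad, seed = 1), "runaway")
  expect_true(ras$aborted)
})

test_that("sigma_I lowers the local E-I correlation; sigma_E has little effect", {
  sw <- ei_correlation_vs_sigma(net_config(duration = 3500),
                                sigma_I_values = c(1, 4),
                                sigma_E_values = c(1, 4), n_seeds = 3,
                                seed = 88)
  ag <- aggregate(peak ~ sweep + sigma, sw, mean)
  p_i <- ag$peak[ag$sweep == "sigma_I"]
  expect_gt(p_i[1], p_i[2])
  ## sigma_E difference is small relative to the sigma_I difference
  p_e <- ag$peak[ag$sweep == "sigma_E"]
  expect_lt(abs(p_e[1] - p_e[2]), (p_i[1] - p_i[2]))
})
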