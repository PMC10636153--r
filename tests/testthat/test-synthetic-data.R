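test_that("population generation is deterministic and honours proportions", {
  cfg <- population_config(n_units = 60)
  p1 <- make_population(cfg, seed = 11)
  p2 <- make_population(cfg, seed = 11)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_identical(p1$units[[7]]$waveform$amplitude,
                   p2$units[[7]]$waveform$amplitude)

  cfg1 <- population_config(n_units = 40,
                            class_props = c(narrow = 0, medium = 1,
                                            broad = 0))
  pop <- make_population(cfg1, seed = 3)
  expect_true(all(as.data.frame(pop)$cls == "medium"))

  expect_error(population_config(class_props = c(narrow = 0.5,
                                                 medium = 0.5,
                                                 broad = 0.5)),
               "sum to 1")
})

test_that("pooled PTD distribution of the default population is multimodal", {
  pop <- make_population(population_config(n_units = 250), seed = 5)
  ptd <- vapply(pop$units, function(u) measure_ptd(u$waveform), numeric(1))
  dt <- dip_test(ptd, n_boot = 1000, seed = 6)
  expect_lt(dt$p_value, 0.01)
})

test_that("waveform templates reproduce the requested PTD", {
  for (ptd in c(0.2, 0.35, 0.4, 0.55)) {
    w <- make_waveform("broad", ptd)
    expect_lt(abs(measure_ptd(w) - ptd), w$dt / 2 + 1e-9)
  }
  ## amplitude scaling leaves the measurement unchanged
  w <- make_waveform("narrow", 0.4)
  w10 <- w; w10$amplitude <- 10 * w$amplitude
  expect_equal(measure_ptd(w10), measure_ptd(w))
  expect_error(make_waveform("narrow", 0.01), "resolution")
})

test_that("averaging noisy waveforms recovers the PTD within 0.02 ms", {
  ptd_true <- 0.35
  reps <- lapply(1:200, function(i)
    make_waveform("medium", ptd_true, noise_sd = 0.05, seed = i)$amplitude)
  avg <- make_waveform("medium", ptd_true)
  avg$amplitude <- Reduce(`+`, reps) / length(reps)
  expect_lt(abs(measure_ptd(avg) - ptd_true), 0.02)
})

test_that("identity attention effect leaves the two conditions exchangeable", {
  cfg <- population_config(n_units = 40, scenario = "null")
  pop <- make_population(cfg, seed = 2)
  tr <- simulate_trials(pop, n_trials = 30, seed = 3)
  ci <- which.max(tr$contrasts)
  pass <- vapply(seq_len(40), function(u) {
    a <- vapply(tr$spikes[[u]][["in"]][[ci]], length, numeric(1))
    b <- vapply(tr$spikes[[u]][["away"]][[ci]], length, numeric(1))
    suppressWarnings(wilcox.test(a, b)$p.value) > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("response gain 1.15 yields the analytic per-contrast AMI", {
  cfg <- population_config(
    n_units = 1, class_props = c(narrow = 0, medium = 1, broad = 0),
    scenario = "null")
  pop <- make_population(cfg, seed = 4)
  pop$units[[1]]$attention_effect <- attention_effect(response_gain = 1.15,
                                                      baseline_gain = 1.15)
  tr <- simulate_trials(pop, contrasts = c(10, 40), n_trials = 4000, seed = 5)
  expected <- 0.15 / 2.15
  for (ci in 1:2) {
    a <- mean(vapply(tr$spikes[[1]][["in"]][[ci]], function(t)
      sum(t >= 60 & t < 260), numeric(1)))
    b <- mean(vapply(tr$spikes[[1]][["away"]][[ci]], function(t)
      sum(t >= 60 & t < 260), numeric(1)))
    ami <- (a - b) / (a + b)
    ## 3 SE of the empirical AMI at these counts
    expect_lt(abs(ami - expected), 3 * sqrt(1 / (a * 4000) + 1 / (b * 4000)))
  }
})

test_that("zero contrast fires at baseline and rates converge to the CRF", {
  cfg <- population_config(n_units = 1,
                           class_props = c(narrow = 0, medium = 0,
                                           broad = 1),
                           latency_means = c(narrow = 40, medium = 40,
                                             broad = 40),
                           latency_sd = 1e-6)
  pop <- make_population(cfg, seed = 9)
  u <- pop$units[[1]]
  tr <- simulate_trials(pop, contrasts = c(0, 40), n_trials = 4000, seed = 10)
  r <- spike_counts_to_rates(tr, 1, "away")
  ## blank trials: baseline m only
  expect_lt(abs(r$rate[1] - u$crf_away[["m"]]) / u$crf_away[["m"]], 0.1)
  ## rate conservation at 40% contrast: < 3% relative error at this size
  expect_lt(abs(r$rate[2] - crf_response(40, u$crf_away)) /
              crf_response(40, u$crf_away), 0.03)
})

test_that("correlated pools: shared fraction controls the zero-lag peak", {
  ## independence: corrected CCG consistent with zero
  p0 <- make_correlated_pools(40, 10, 10, 20, 0, 40000, seed = 21)
  cg0 <- pooled_ccg(chop_train(p0$e, 1000, 40), chop_train(p0$i, 1000, 40),
                    max_lag = 50)
  expect_lt(max(abs(cg0$value)), 6 * sd(cg0$value[abs(cg0$lags) > 10]))
  ## identical drive: maximal at lag 0
  p1 <- make_correlated_pools(40, 10, 10, 20, 1, 40000, seed = 22)
  cg1 <- pooled_ccg(chop_train(p1$e, 1000, 40), chop_train(p1$i, 1000, 40),
                    max_lag = 50)
  expect_equal(cg1$lags[which.max(cg1$value)], 0)
  ## monotone mean peak over the shared fraction, several seeds
  fracs <- c(0, 0.25, 0.5, 0.75, 1)
  peaks <- sapply(fracs, function(f) {
    mean(vapply(1:8, function(s) {
      p <- make_correlated_pools(40, 10, 10, 20, f, 20000, seed = 100 + s)
      cg <- pooled_ccg(chop_train(p$e, 1000, 20), chop_train(p$i, 1000, 20),
                       max_lag = 50)
      cg$value[cg$lags == 0]
    }, numeric(1)))
  })
  expect_true(all(diff(peaks) > 0))
  expect_error(make_correlated_pools(10, 5, 10, 10, 1.5, 1000),
               "common_fraction")
})

test_that("trial sets round-trip through the text serialization", {
  pop <- make_population(population_config(n_units = 3), seed = 1)
  tr <- simulate_trials(pop, n_trials = 4, seed = 2)
  path <- file.path(tempdir(), "ts_roundtrip")
  write_trialset(tr, path)
  tr2 <- read_trialset(path)
  expect_equal(tr2$contrasts, tr$contrasts)
  for (u in 1:3) for (cond in c("in", "away"))
    for (ci in seq_along(tr$contrasts)) for (k in 1:4)
      expect_equal(tr2$spikes[[u]][[cond]][[ci]][[k]],
                   tr$spikes[[u]][[cond]][[ci]][[k]], tolerance = 1e-6)
  unlink(paste0(path, c(".csv", ".json")))
})
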