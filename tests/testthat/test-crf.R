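test_that("spike counts convert to rates with the half-open window", {
  ## 10 spikes uniformly inside the window in each of 3 trials -> 50 sp/s
  tr <- manual_trial_set(lapply(1:3, function(i) seq(60, 250, length.out = 10)))
  r <- spike_counts_to_rates(tr, 1, "away")
  expect_equal(r$rate, 50)
  ## boundary convention: 60 in, 260 out
  tr2 <- manual_trial_set(list(c(60, 260)))
  expect_equal(spike_counts_to_rates(tr2, 1, "away")$rate, 5)
})

test_that("trial-mean rates are unbiased for Poisson spiking", {
  ok <- vapply(1:30, function(s) {
    lambda <- 25
    trains <- laminattn:::with_seed(s, lapply(1:500, function(i)
      laminattn:::rpois_segment(lambda, -200, 400)))
    r <- spike_counts_to_rates(manual_trial_set(trains), 1, "away")
    abs(r$rate - lambda) <= 3 * r$sem
  }, logical(1))
  expect_gte(sum(ok), 28)
})

test_that("fit_crf recovers noiseless parameters and flags flat input", {
  p <- crf_params(50, 20, 2, 5)
  cc <- c(2.5, 5, 10, 20, 40, 80)
  fit <- fit_crf(cc, crf_response(cc, p))
  expect_lt(max(abs(fit$params - p) / p), 1e-4)
  expect_false(fit$flat)

  flat <- fit_crf(cc, rep(7, 6))
  expect_true(flat$flat)
  expect_lt(flat$params[["r_max"]], 1e-3)
  expect_lt(abs(flat$params[["m"]] - 7), 0.01)

  expect_error(fit_crf(c(10, 20, 40), c(1, 2, 3)), "5 contrast")
})

test_that("fit_crf never loses to the brute-force grid oracle", {
  cc <- c(2.5, 5, 10, 20, 40, 80)
  for (s in 1:10) {
    truth <- laminattn:::with_seed(s, crf_params(
      rlnorm(1, log(30), 0.3), rlnorm(1, log(15), 0.3),
      min(4, rlnorm(1, log(2), 0.2)), rlnorm(1, log(5), 0.3)))
    y <- laminattn:::with_seed(100 + s,
      rpois(6, crf_response(cc, truth) * 0.2 * 100) / (0.2 * 100))
    fit <- fit_crf(cc, y)
    expect_lte(fit$sse, crf_grid_best_sse(cc, y) + 1e-9)
  }
})

test_that("AMI has the analytic gain forms and is antisymmetric", {
  p <- crf_params(50, 20, 2, 5)
  cc <- c(2.5, 5, 10, 20, 40, 80)
  expect_equal(ami_curve(p, p, cc), rep(0, 6))
  g <- crf_params(50 * 1.15, 20, 2, 5 * 1.15)
  expect_equal(ami_curve(g, p, cc), rep(0.15 / 2.15, 6), tolerance = 1e-12)
  ## antisymmetry over random parameter pairs
  for (s in 1:10) {
    a <- laminattn:::with_seed(s, crf_params(rlnorm(1, 3), rlnorm(1, 2.5),
                                             runif(1, 0.5, 4), rlnorm(1, 1)))
    b <- laminattn:::with_seed(s + 50, crf_params(rlnorm(1, 3),
                                                  rlnorm(1, 2.5),
                                                  runif(1, 0.5, 4),
                                                  rlnorm(1, 1)))
    expect_equal(ami_curve(a, b, cc), -ami_curve(b, a, cc))
  }
  ## contrast gain: R_in(c) = R_away(2c) gives strictly decreasing AMI
  away <- crf_params(50, 20, 2, 0)
  inn <- crf_params(50, 10, 2, 0)
  dense <- seq(1, 100, by = 0.5)
  expect_true(all(diff(ami_curve(inn, away, dense)) < 0))
})

test_that("parameter AMIs isolate the modulated parameter", {
  p <- crf_params(50, 20, 2, 5)
  expect_equal(unname(ami_params(p, p)), rep(0, 4))
  g <- crf_params(50 * 1.15, 20, 2, 5)
  ap <- ami_params(g, p)
  expect_equal(unname(ap[["ami_r_max"]]), 0.15 / 2.15, tolerance = 1e-12)
  expect_equal(unname(ap[c("ami_c50", "ami_n", "ami_m")]),
               rep(0, 3), ignore_attr = TRUE)
})

test_that("CDI follows its definition, with exact zero under response gain", {
  ## constant AMI curve -> CDI 0
  expect_equal(compute_cdi(rep(0.07, 6), c(2.5, 5, 10, 20, 40, 80), 20)$cdi,
               0)
  ## worked arithmetic
  expect_equal(compute_cdi(c(0.2, 0.2, 0.1, 0.1), c(5, 10, 40, 80), 20)$cdi,
               (0.2 - 0.1) / 0.15, tolerance = 1e-12)
  ## positive scaling of the AMI curve leaves the CDI unchanged
  a <- c(0.3, 0.25, 0.12, 0.05)
  c1 <- compute_cdi(a, c(5, 10, 40, 80), 20)$cdi
  c2 <- compute_cdi(5 * a, c(5, 10, 40, 80), 20)$cdi
  expect_equal(c1, c2)
  ## pure response gain through the full pipeline: AMI constant, CDI 0
  away <- crf_params(40, 15, 2, 4)
  inn <- crf_params(40 * 1.2, 15, 2, 4 * 1.2)
  cc <- c(2.5, 5, 10, 20, 40, 80)
  ami <- ami_curve(inn, away, cc)
  expect_equal(compute_cdi(ami, cc, 15)$cdi, 0, tolerance = 1e-12)
  ## instability flag
  expect_true(compute_cdi(c(0.001, -0.001, 0.002, -0.002),
                          c(5, 10, 40, 80), 20)$unstable)
  ## need both sides of the split
  expect_false(compute_cdi(c(0.1, 0.2), c(30, 40), 20)$valid)
})

test_that("responsiveness screen is calibrated and powered", {
  ## null: baseline everywhere -> ~5% flagged
  null_flags <- vapply(1:200, function(s) {
    trains <- laminattn:::with_seed(s, lapply(1:40, function(i)
      laminattn:::rpois_segment(10, -200, 400)))
    trains_in <- laminattn:::with_seed(9000 + s, lapply(1:40, function(i)
      laminattn:::rpois_segment(10, -200, 400)))
    screen_visual_responsiveness(manual_trial_set(trains,
                                                  trains_in = trains_in), 1)
  }, logical(1))
  expect_gte(mean(null_flags), 0.005)
  expect_lte(mean(null_flags), 0.12)
  ## power: 3x baseline in the evoked window, 50 trials
  power_flags <- vapply(1:50, function(s) {
    trains <- laminattn:::with_seed(1000 + s, lapply(1:50, function(i) {
      c(laminattn:::rpois_segment(10, -200, 60),
        laminattn:::rpois_segment(30, 60, 260),
        laminattn:::rpois_segment(10, 260, 400))
    }))
    screen_visual_responsiveness(manual_trial_set(trains), 1)
  }, logical(1))
  expect_gte(mean(power_flags), 0.98)
  ## zero spikes -> not responsive
  empty <- manual_trial_set(lapply(1:10, function(i) numeric(0)))
  expect_false(screen_visual_responsiveness(empty, 1))
})

test_that("group aggregation is permutation invariant and exact for clones", {
  prof <- function(cdi, ami) {
    list(contrasts = c(5, 10, 40, 80), ami = rep(ami, 4), mean_ami = ami,
         cdi = list(cdi = cdi, valid = TRUE, unstable = FALSE),
         ami_params = rep(0, 4))
  }
  profiles <- c(lapply(1:5, function(i) prof(0.4, 0.1)),
                lapply(1:5, function(i) prof(-0.2, 0.1)))
  groups <- rep(c("a", "b"), each = 5)
  agg <- aggregate_by_group(profiles, groups, n_boot = 200, seed = 1)
  expect_equal(agg$summary$mean_cdi, c(0.4, -0.2))
  expect_equal(agg$summary$ci_low, c(0.4, -0.2))
  expect_equal(agg$summary$ci_high, c(0.4, -0.2))
  ## permuting unit order leaves the summary unchanged
  o <- c(7, 2, 9, 4, 1, 10, 3, 6, 5, 8)
  agg2 <- aggregate_by_group(profiles[o], groups[o], n_boot = 200, seed = 1)
  expect_equal(agg2$summary, agg$summary)
})
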