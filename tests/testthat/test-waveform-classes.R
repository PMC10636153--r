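test_that("measure_ptd matches construction and rejects non-biphasic input", {
  w <- make_waveform("medium", 0.35)
  expect_lt(abs(measure_ptd(w) - 0.35), w$dt / 2 + 1e-9)
  flipped <- w; flipped$amplitude <- -w$amplitude
  expect_error(measure_ptd(flipped), "polarity")
  expect_error(measure_ptd(rep(1, 50), dt = 0.025), "biphasic")
  expect_error(measure_ptd(seq(0, 1, length.out = 50), dt = 0.025),
               "biphasic")
})

test_that("measure_ptd agrees with a parabolic-interpolation extremum oracle", {
  ## independent oracle: quadratic interpolation through the three samples
  ## around each discrete extremum
  para_extremum <- function(t, y, idx) {
    if (idx <= 1 || idx >= length(y)) return(t[idx])
    a <- y[idx - 1]; b <- y[idx]; cc <- y[idx + 1]
    denom <- a - 2 * b + cc
    if (denom == 0) return(t[idx])
    t[idx] + 0.5 * (a - cc) / denom * (t[2] - t[1])
  }
  deltas <- vapply(1:100, function(i) {
    ptd <- runif(1, 0.2, 0.6)
    w <- make_waveform("broad", ptd, noise_sd = 0.02, seed = 7000 + i)
    i_tr <- which.min(w$amplitude)
    post <- w$amplitude[i_tr:length(w$amplitude)]
    i_pk <- i_tr + which.max(post) - 1L
    oracle <- para_extremum(w$time, w$amplitude, i_pk) -
      para_extremum(w$time, w$amplitude, i_tr)
    abs(measure_ptd(w) - oracle)
  }, numeric(1))
  expect_lt(median(deltas), 0.01)
})

test_that("consensus k-means recovers separable and mixture structure", {
  x <- rep(c(0.2, 0.35, 0.55), times = c(20, 20, 20))
  sol <- meta_kmeans(x, k = 3, n_restarts = 25, seed = 1)
  expect_true(all(sol$consensus %in% c(0, 1)))
  truth <- rep(1:3, times = c(20, 20, 20))
  expect_equal(label_agreement(truth, sol$labels)$agreement, 1)

  sol1 <- meta_kmeans(x, k = 1, n_restarts = 5, seed = 1)
  expect_true(all(sol1$labels == 1L))
  expect_true(all(sol1$consensus == 1))

  expect_error(meta_kmeans(1:3, k = 5), "exceeds")

  ## Gaussian 3-mixture: high agreement after optimal matching
  set.seed(42)
  g <- sample(1:3, 200, replace = TRUE)
  xg <- rnorm(200, c(0.2, 0.35, 0.55)[g], 0.03)
  solg <- suppressWarnings(meta_kmeans(xg, k = 3, n_restarts = 100,
                                       seed = 2))
  expect_gte(label_agreement(g, solg$labels)$agreement, 0.95)
})

test_that("one consensus restart reproduces plain k-means", {
  set.seed(5)
  x <- rnorm(60)
  sol <- meta_kmeans(x, k = 2, n_restarts = 1, seed = 99)
  km <- laminattn:::with_seed(99, kmeans(matrix(x, ncol = 1), centers = 2,
                                         iter.max = 100))
  expect_equal(label_agreement(km$cluster, sol$labels)$agreement, 1)
})

test_that("information criteria prefer the generating number of clusters", {
  wins2 <- 0; wins4 <- 0; bic_wins <- 0
  for (s in 1:20) {
    set.seed(s)
    g <- rep(1:3, each = 40)
    x <- rnorm(120, c(0, 1, 2)[g], 0.08)
    crit <- function(k) suppressWarnings(
      information_criteria(x, meta_kmeans(x, k, n_restarts = 10,
                                          seed = s)$labels, k))
    a2 <- crit(2); a3 <- crit(3); a4 <- crit(4)
    wins2 <- wins2 + (a3[["aic"]] < a2[["aic"]])
    wins4 <- wins4 + (a3[["aic"]] < a4[["aic"]])
  }
  expect_gte(wins2, 17)
  expect_gte(wins4, 17)
  ## unimodal data: BIC(1) < BIC(2) most of the time
  for (s in 1:50) {
    set.seed(100 + s)
    x <- rnorm(100)
    b1 <- information_criteria(x, rep(1L, 100), 1)[["bic"]]
    l2 <- suppressWarnings(meta_kmeans(x, 2, n_restarts = 10,
                                       seed = s))$labels
    b2 <- information_criteria(x, l2, 2)[["bic"]]
    bic_wins <- bic_wins + (b1 < b2)
  }
  expect_gte(bic_wins, 45)
  ## degenerate data stays finite via the variance floor
  expect_warning(ic <- information_criteria(rep(1, 20), rep(1L, 20), 1),
                 "floor")
  expect_true(all(is.finite(ic)))
  ## label-permutation invariance
  set.seed(1); x <- rnorm(30); lab <- sample(1:3, 30, replace = TRUE)
  perm <- c(3L, 1L, 2L)[lab]
  expect_equal(suppressWarnings(information_criteria(x, lab, 3)),
               suppressWarnings(information_criteria(x, perm, 3)))
})

test_that("kneedle finds constructed elbows and flags linear curves", {
  expect_equal(kneedle_elbow(1:6, c(10, 4, 1, 0.9, 0.85, 0.84)), 3)
  expect_true(is.na(kneedle_elbow(1:5, seq(10, 2, length.out = 5))))
  ## pipeline composition: AIC curve of the separable 3-mixture has elbow 3
  x <- rep(c(0.2, 0.35, 0.55), times = c(25, 25, 25)) +
    rnorm(75, 0, 0.005)
  aic <- vapply(1:6, function(k) suppressWarnings(
    meta_kmeans(x, k, n_restarts = 20, seed = k)$aic), numeric(1))
  expect_equal(kneedle_elbow(1:6, aic), 3)
})

test_that("dip statistic matches analytic values and the exact slow oracle", {
  expect_equal(dip_stat(c(0, 1, 2)), 1 / 6)
  expect_equal(dip_stat(c(0, 0.2, 2)), 1 / 6)
  expect_equal(dip_stat(c(0, 0, 1)), 1 / 6)
  expect_equal(dip_stat(seq(0, 1, length.out = 100)), 1 / 200)
  expect_lt(abs(dip_stat(rep(c(0, 1), 500)) - 0.25), 0.01)
  expect_equal(dip_stat(rep(3, 25)), 0)
  ## frozen exact-oracle values on random small samples (with ties)
  samples <- dip_reference_samples()
  for (i in seq_along(samples))
    expect_lt(abs(dip_stat(samples[[i]]) - dip_reference_values[i]), 1e-5)
  ## bounds hold for arbitrary samples
  for (i in 1:20) {
    set.seed(200 + i)
    x <- rnorm(sample(10:200, 1))^sample(1:3, 1)
    d <- dip_stat(x)
    expect_gte(d, 0); expect_lte(d, 0.25)
  }
})

test_that("dip test is calibrated on unimodal data and flags point masses", {
  null_tab <- dip_null_table(500, n_boot = 500, seed = 1)
  ok <- vapply(1:50, function(s) {
    x <- laminattn:::with_seed(1000 + s, runif(500))
    dip_test(x, null_dips = null_tab)$p_value > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.9)
  ct <- dip_test(rep(2, 50))
  expect_equal(ct$statistic, 0)
  expect_equal(ct$p_value, 1)
})

test_that("PCA cross-check agrees with PTD labels on structured waveforms", {
  pop <- make_population(population_config(n_units = 150), seed = 8)
  ptd <- vapply(pop$units, function(u) measure_ptd(u$waveform), numeric(1))
  sol <- suppressWarnings(meta_kmeans(ptd, 3, n_restarts = 60, seed = 9))
  wf <- normalize_waveforms(lapply(pop$units, `[[`, "waveform"))
  expect_true(all(abs(apply(abs(wf), 1, max) - 1) < 1e-9))
  pc <- pca_crosscheck(wf, sol$labels, k = 3, seed = 10)
  expect_gte(pc$agreement_fraction, 0.8)
  expect_true(all(pc$explained_variance_fractions <= 1))
  expect_error(pca_crosscheck(wf, sol$labels, k = 4), "clusters")
  ## random balanced labels agree at chance level
  set.seed(11)
  agr <- replicate(30, label_agreement(sample(1:3, 300, replace = TRUE),
                                       sample(1:3, 300,
                                              replace = TRUE))$agreement)
  expect_gt(mean(agr), 0.28)
  expect_lt(mean(agr), 0.40)
})

test_that("classes are named by ascending waveform width", {
  lab <- c(1, 1, 2, 2, 3, 3)
  ptd <- c(0.5, 0.6, 0.2, 0.2, 0.35, 0.36)
  expect_equal(name_classes_by_width(lab, ptd),
               c("broad", "broad", "narrow", "narrow", "medium", "medium"))
})
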