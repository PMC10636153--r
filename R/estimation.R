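## Bootstrap estimation statistics and rank tests.

#' Bootstrap sampling distribution of the mean
#'
#' Resamples the data with replacement \code{n_boot} times and returns the
#' sampling distribution of the mean with a 95% percentile confidence
#' interval.  CI endpoints are order statistics of the bootstrap sample
#' (quantile type 1), so the interval is exactly reproducible.
#'
#' @param values Numeric vector (n >= 2).
#' @param n_boot Number of bootstrap resamples.
#' @param seed RNG seed (resampling is deterministic given the seed).
#' @param conf Confidence level (default 0.95).
#' @return A list of class \code{"boot_result"}: point, samples, ci_low,
#'   ci_high, n_boot, seed.
#' @export
boot_mean <- function(values, n_boot = 10000, seed = 1, conf = 0.95) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop_config("boot_mean needs at least 2 finite values (got %d)", n)
  samples <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    colMeans(matrix(values[idx], nrow = n))
  })
  alpha <- round((1 - conf) / 2, 10)  # guard the order-statistic index
  ci <- quantile(samples, c(alpha, 1 - alpha), type = 1, names = FALSE)
  structure(list(point = mean(values), samples = samples,
                 ci_low = ci[1], ci_high = ci[2],
                 n_boot = n_boot, seed = seed, conf = conf),
            class = "boot_result")
}

#' @export
print.boot_result <- function(x, ...) {
  cat(sprintf("mean = %.4g, %g%% CI [%.4g, %.4g] (%d bootstrap resamples)\n",
              x$point, 100 * x$conf, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

#' Two-sided Wilcoxon signed rank test against zero
#'
#' @param values Numeric vector; zeros are dropped per the signed-rank
#'   convention.  All-zero input returns p = 1.
#' @return p-value.
#' @export
signed_rank_vs_zero <- function(values) {
  values <- values[is.finite(values)]
  if (all(values == 0)) return(1)
  wilcox.test(values, mu = 0, exact = FALSE, correct = TRUE)$p.value
}

#' Two-sided Wilcoxon rank sum test
#'
#' @param a,b Numeric samples.
#' @return p-value.
#' @export
rank_sum <- function(a, b) {
  wilcox.test(a[is.finite(a)], b[is.finite(b)], exact = FALSE,
              correct = TRUE)$p.value
}

#' Bonferroni correction over a family of tests
#'
#' @param p_list Raw p-values.
#' @param n Family size (default \code{length(p_list)}).
#' @param alpha Family-wise level (default 0.05; with n = 3 the per-test
#'   threshold is 0.0167).
#' @return A list: p_adjusted, significant (raw p < alpha/n), threshold.
#' @export
bonferroni_adjust <- function(p_list, n = length(p_list), alpha = 0.05) {
  p <- as.numeric(p_list)
  list(p_adjusted = pmin(1, p * n),
       significant = p < alpha / n,
       threshold = alpha / n)
}
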