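## Waveform-based unit classification: peak-to-trough duration, consensus
## k-means meta-clustering, information criteria, kneedle elbow detection,
## Hartigan's dip statistic and a PCA cross-check.

#' Measure the peak-to-trough duration of a spike waveform
#'
#' The waveform is upsampled with a cubic spline; the trough is the global
#' minimum and the peak the global maximum after the trough.  Waveforms whose
#' global maximum precedes the trough (inverted polarity) or that have no
#' biphasic shape raise an error.
#'
#' @param waveform A \code{\link{make_waveform}} object, or a numeric
#'   amplitude vector (then \code{dt} must be given).
#' @param upsample_factor Spline upsampling factor (default 10).
#' @param dt Sampling step in ms when \code{waveform} is a bare vector.
#' @return Peak-to-trough duration in ms.
#' @export
measure_ptd <- function(waveform, upsample_factor = 10, dt = NULL) {
  if (inherits(waveform, "spike_waveform")) {
    t <- waveform$time; a <- waveform$amplitude
  } else {
    if (is.null(dt)) stop_config("dt required for a bare amplitude vector")
    a <- as.numeric(waveform); t <- (seq_along(a) - 1) * dt
  }
  if (length(a) < 8) stop_config("waveform needs >= 8 samples")
  if (diff(range(a)) == 0 || all(diff(a) >= 0) || all(diff(a) <= 0))
    stop_config("no biphasic shape: waveform is constant or monotone")
  sp <- spline(t, a, n = length(a) * upsample_factor)
  i_tr <- which.min(sp$y)
  i_pk_global <- which.max(sp$y)
  if (i_pk_global <= i_tr)
    stop_config("no biphasic shape: peak precedes trough (check polarity)")
  post <- sp$y[i_tr:length(sp$y)]
  i_pk <- i_tr + which.max(post) - 1L
  sp$x[i_pk] - sp$x[i_tr]
}

#' Normalise and trough-align spike waveforms
#'
#' Spline-upsamples each waveform, scales it so the largest absolute
#' amplitude is 1, and shifts it so the trough sits at a common index,
#' yielding a matrix suitable for PCA.
#'
#' @param waveforms List of \code{\link{make_waveform}} objects (or numeric
#'   vectors sharing \code{dt}).
#' @param dt Sampling step in ms for bare vectors.
#' @param upsample_factor Spline upsampling factor.
#' @param pre_ms,post_ms Window around the trough to keep.
#' @return Matrix (units x time); attribute \code{"dt"} gives the upsampled
#'   step.
#' @export
normalize_waveforms <- function(waveforms, dt = NULL, upsample_factor = 4,
                                pre_ms = 0.5, post_ms = 1.6) {
  rows <- lapply(waveforms, function(w) {
    if (inherits(w, "spike_waveform")) {
      t <- w$time; a <- w$amplitude
    } else {
      if (is.null(dt)) stop_config("dt required for bare amplitude vectors")
      a <- as.numeric(w); t <- (seq_along(a) - 1) * dt
    }
    step <- (t[2] - t[1]) / upsample_factor
    sp <- spline(t, a, n = length(a) * upsample_factor)
    y <- sp$y / max(abs(sp$y))
    i_tr <- which.min(y)
    idx <- i_tr + seq(round(-pre_ms / step), round(post_ms / step))
    idx <- pmin(pmax(idx, 1L), length(y))
    list(y = y[idx], step = step)
  })
  out <- do.call(rbind, lapply(rows, `[[`, "y"))
  attr(out, "dt") <- rows[[1]]$step
  out
}

#' Consensus (meta) k-means clustering
#'
#' Runs k-means \code{n_restarts} times with random initialisations, builds
#' the co-assignment (consensus) matrix, and extracts the final partition by
#' cutting an average-linkage agglomerative tree of (1 - consensus) at k
#' clusters.  Deterministic given the seed.
#'
#' @param features Numeric vector (e.g. per-unit PTD) or matrix (rows =
#'   units).
#' @param k Number of clusters.
#' @param n_restarts Number of k-means restarts (default 500).
#' @param seed RNG seed.
#' @return List of class \code{"cluster_solution"}: k, labels (1..k),
#'   centers (per-cluster feature means), sizes, consensus, aic, bic
#'   (Gaussian mixture criteria, 1-D features only).
#' @export
meta_kmeans <- function(features, k, n_restarts = 500, seed = 1) {
  x <- if (is.matrix(features)) features else matrix(features, ncol = 1)
  n <- nrow(x)
  if (k > n) stop_config("k = %d exceeds number of units (%d)", k, n)
  if (nrow(unique(x)) < k)
    stop_config("need at least k distinct feature values")
  if (n_restarts < 1) stop_config("n_restarts must be >= 1")
  with_seed(seed, {
    consensus <- matrix(0, n, n)
    for (r in seq_len(n_restarts)) {
      km <- NULL
      for (try in 1:100) {
        km <- tryCatch(kmeans(x, centers = k, iter.max = 100),
                       error = function(e) NULL)
        if (!is.null(km)) break
      }
      if (is.null(km)) stop_config("k-means failed repeatedly (k = %d)", k)
      consensus <- consensus + outer(km$cluster, km$cluster, "==")
    }
    consensus <- consensus / n_restarts
    labels <- if (k == 1L) rep(1L, n) else {
      hc <- hclust(as.dist(1 - consensus), method = "average")
      cutree(hc, k = k)
    }
    centers <- do.call(rbind, lapply(seq_len(k), function(g)
      colMeans(x[labels == g, , drop = FALSE])))
    crit <- if (ncol(x) == 1L)
      information_criteria(x[, 1], labels, k) else c(aic = NA_real_,
                                                     bic = NA_real_)
    structure(list(k = k, labels = labels, centers = centers,
                   sizes = tabulate(labels, k), consensus = consensus,
                   aic = crit[["aic"]], bic = crit[["bic"]]),
              class = "cluster_solution")
  })
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("k = %d clusters, sizes: %s; AIC = %.4g, BIC = %.4g\n",
              x$k, paste(x$sizes, collapse = "/"), x$aic, x$bic))
  invisible(x)
}

#' Gaussian-mixture information criteria for a hard partition
#'
#' Log-likelihood of a 1-D Gaussian mixture with per-cluster mean, variance
#' and mixing weight evaluated at the hard assignment; parameter count
#' p = 3k - 1.  AIC = 2p - 2 lnL, BIC = p ln(n) - 2 lnL.  Singleton or
#' zero-variance clusters have their variance floored at \code{var_floor}
#' (default: squared waveform sampling step) with a warning.
#'
#' @param features 1-D numeric features (e.g. PTD in ms).
#' @param labels Cluster labels (1..k).
#' @param k Number of clusters.
#' @param var_floor Variance floor.
#' @return Named vector c(aic, bic).
#' @export
information_criteria <- function(features, labels, k, var_floor = 0.025^2) {
  x <- as.numeric(features); n <- length(x)
  stopifnot(length(labels) == n, all(labels %in% seq_len(k)))
  loglik <- 0
  floored <- FALSE
  for (g in seq_len(k)) {
    xg <- x[labels == g]
    if (length(xg) == 0L) next
    v <- if (length(xg) > 1) var(xg) else 0
    if (!is.finite(v) || v < var_floor) { v <- var_floor; floored <- TRUE }
    w <- length(xg) / n
    loglik <- loglik + sum(dnorm(xg, mean(xg), sqrt(v), log = TRUE) + log(w))
  }
  if (floored) warning("variance floor applied to a degenerate cluster")
  p <- 3 * k - 1
  c(aic = 2 * p - 2 * loglik, bic = p * log(n) - 2 * loglik)
}

#' Kneedle elbow detection on an information-criterion curve
#'
#' Both axes are min-max normalised; for a decreasing convex criterion the
#' difference curve is d_i = (1 - x_i) - y_i and the elbow is the k at its
#' global maximum (ties resolved to the smallest k).  An exactly linear
#' criterion has no elbow and returns NA.
#'
#' @param k_values Candidate cluster counts (ascending).
#' @param criterion_values AIC or BIC values at those k.
#' @param tol Tolerance for flatness of the difference curve.
#' @return The elbow k, or NA when the curve is linear.
#' @export
kneedle_elbow <- function(k_values, criterion_values, tol = 1e-10) {
  stopifnot(length(k_values) == length(criterion_values),
            length(k_values) >= 3)
  o <- order(k_values)
  kv <- k_values[o]; y <- criterion_values[o]
  xs <- (kv - min(kv)) / (max(kv) - min(kv))
  ys <- (y - min(y)) / if (diff(range(y)) > 0) diff(range(y)) else 1
  d <- (1 - xs) - ys
  if (max(d) - min(d) < tol) return(NA_integer_)
  kv[which.max(d)]
}

#' Hartigan's dip statistic
#'
#' Maximum deviation between the empirical CDF and the closest unimodal CDF,
#' computed by the iterative greatest-convex-minorant / least-concave-
#' majorant construction.  The dip of any sample lies in [0, 0.25]; a sample
#' of n distinct values has dip >= 1/(2n).
#'
#' @param x Numeric sample (n >= 2 for a nontrivial value).
#' @return The dip statistic.
#' @export
dip_stat <- function(x) {
  x <- sort(as.numeric(x[is.finite(x)]))
  n <- length(x)
  if (n < 2 || x[n] == x[1]) return(0)
  if (n == 2) return(0.25)
  ## convexity pointer chains for the minorant (mn) and majorant (mj)
  mn <- integer(n); mj <- integer(n)
  mn[1] <- 1L
  for (j in 2:n) {
    mn[j] <- j - 1L
    repeat {
      mnj <- mn[j]
      if (mnj == 1L) break
      mnmnj <- mn[mnj]
      if ((x[j] - x[mnj]) * (mnj - mnmnj) <
          (x[mnj] - x[mnmnj]) * (j - mnj)) break
      mn[j] <- mnmnj
    }
  }
  mj[n] <- n
  for (kk in (n - 1):1) {
    mj[kk] <- kk + 1L
    repeat {
      mjk <- mj[kk]
      if (mjk == n) break
      mjmjk <- mj[mjk]
      if ((x[kk] - x[mjk]) * (mjk - mjmjk) <
          (x[mjk] - x[mjmjk]) * (kk - mjk)) break
      mj[kk] <- mjmjk
    }
  }
  low <- 1L; high <- n; dip <- 0
  gcm <- integer(n + 1L); lcm <- integer(n + 1L)
  for (iter in 1:(2L * n)) {
    gcm[1] <- high; l_gcm <- 1L
    while (gcm[l_gcm] > low) {
      gcm[l_gcm + 1L] <- mn[gcm[l_gcm]]; l_gcm <- l_gcm + 1L
    }
    lcm[1] <- low; l_lcm <- 1L
    while (lcm[l_lcm] < high) {
      lcm[l_lcm + 1L] <- mj[lcm[l_lcm]]; l_lcm <- l_lcm + 1L
    }
    ig <- l_gcm; ih <- l_lcm
    d <- 0
    if (l_gcm != 2L || l_lcm != 2L) {
      ## largest gap between the minorant (lower step corners, counts i-1)
      ## and the majorant (upper corners, counts i)
      ix <- l_gcm - 1L; iv <- 2L
      repeat {
        gcmix <- gcm[ix]; lcmiv <- lcm[iv]
        if (gcmix > lcmiv) {
          gcmi1 <- gcm[ix + 1L]
          interp <- if (x[gcmix] == x[gcmi1]) 0 else
            (x[lcmiv] - x[gcmi1]) * (gcmix - gcmi1) / (x[gcmix] - x[gcmi1])
          dx <- (lcmiv - gcmi1 + 1) - interp
          iv <- iv + 1L
          if (dx >= d) { d <- dx; ig <- ix + 1L; ih <- iv - 1L }
        } else {
          lcmiv1 <- lcm[iv - 1L]
          interp <- if (x[lcmiv] == x[lcmiv1]) (lcmiv - lcmiv1) else
            (x[gcmix] - x[lcmiv1]) * (lcmiv - lcmiv1) / (x[lcmiv] - x[lcmiv1])
          dx <- interp - (gcmix - lcmiv1 - 1)
          ix <- ix - 1L
          if (dx >= d) { d <- dx; ig <- ix + 1L; ih <- iv }
        }
        if (ix < 1L) ix <- 1L
        if (iv > l_lcm) iv <- l_lcm
        if (gcm[ix] == lcm[iv]) break
      }
    } else d <- 1
    if (d <= dip) break
    ## deviations of the ECDF from the two fits outside the modal interval
    dip_l <- 1
    if (ig <= l_gcm - 1L) for (j in ig:(l_gcm - 1L)) {
      jb <- gcm[j + 1L]; je <- gcm[j]
      if (je - jb > 1L && x[je] != x[jb]) {
        C <- (je - jb) / (x[je] - x[jb])
        for (jj in jb:je) {
          tt <- (jj - jb + 1) - (x[jj] - x[jb]) * C
          if (tt > dip_l) dip_l <- tt
        }
      }
    }
    dip_u <- 1
    if (ih <= l_lcm - 1L) for (j in ih:(l_lcm - 1L)) {
      jb <- lcm[j]; je <- lcm[j + 1L]
      if (je - jb > 1L && x[je] != x[jb]) {
        C <- (je - jb) / (x[je] - x[jb])
        for (jj in jb:je) {
          tt <- (je - jj + 1) - (x[je] - x[jj]) * C
          if (tt > dip_u) dip_u <- tt
        }
      }
    }
    dipnew <- max(dip_l, dip_u)
    if (dipnew > dip) dip <- dipnew
    if (gcm[ig] == low && lcm[ih] == high) break
    low <- gcm[ig]; high <- lcm[ih]
  }
  dip / (2 * n)
}

#' Hartigan's dip test of unimodality
#'
#' The null distribution of the dip is simulated from uniform(0, 1) samples
#' of the same size; the p-value is the fraction of null dips at least as
#' large as the observed one (add-one correction).
#'
#' @param sample Numeric sample (n >= 10 recommended).
#' @param n_boot Number of null samples (default 2000).
#' @param seed RNG seed.
#' @param null_dips Optional precomputed null dip values for samples of the
#'   same size (reused across calls, e.g. in calibration studies).
#' @return List: statistic, p_value, n_boot.
#' @export
dip_test <- function(sample, n_boot = 2000, seed = 1, null_dips = NULL) {
  sample <- sample[is.finite(sample)]
  n <- length(sample)
  stat <- dip_stat(sample)
  if (stat == 0) return(list(statistic = 0, p_value = 1, n_boot = 0L))
  if (is.null(null_dips))
    null_dips <- with_seed(seed,
      vapply(seq_len(n_boot), function(i) dip_stat(runif(n)), numeric(1)))
  p <- (1 + sum(null_dips >= stat)) / (length(null_dips) + 1)
  list(statistic = stat, p_value = p, n_boot = length(null_dips))
}

#' Simulate null dip values for samples of size n
#'
#' @param n Sample size.
#' @param n_boot Number of uniform(0,1) null samples.
#' @param seed RNG seed.
#' @return Numeric vector of dip statistics under the unimodal null.
#' @export
dip_null_table <- function(n, n_boot = 2000, seed = 1) {
  with_seed(seed,
    vapply(seq_len(n_boot), function(i) dip_stat(runif(n)), numeric(1)))
}

#' Best label agreement over cluster relabellings
#'
#' Fraction of units assigned to the same cluster, maximised over all
#' permutations of the labels of \code{b} (exact for small k).
#'
#' @param a,b Two label vectors of equal length.
#' @return List: agreement (fraction), permutation (named mapping applied to
#'   b's labels).
#' @export
label_agreement <- function(a, b) {
  stopifnot(length(a) == length(b))
  ua <- sort(unique(a)); ub <- sort(unique(b))
  if (length(ub) > 8) stop_config("too many labels for exact matching")
  perms <- all_perms(length(ub))
  best <- -1; best_perm <- NULL
  bi <- match(b, ub)
  for (r in seq_len(nrow(perms))) {
    mapped <- ua[perms[r, ]][bi]
    agr <- mean(mapped == a)
    if (agr > best) { best <- agr; best_perm <- perms[r, ] }
  }
  list(agreement = best,
       permutation = stats::setNames(ua[best_perm], ub))
}

## all permutations of 1..k as a matrix (k! rows)
all_perms <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(k - 1L)
  out <- NULL
  for (i in seq_len(k)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

#' PCA cross-check of a PTD-based classification
#'
#' Runs PCA on the (trough-aligned, amplitude-normalised) waveform matrix,
#' clusters the first two principal-component scores with consensus k-means
#' and reports the best-matching agreement with the PTD-based labels.
#'
#' @param norm_waveforms Matrix from \code{\link{normalize_waveforms}}.
#' @param ptd_labels Cluster labels from the PTD classification.
#' @param k Number of clusters (must match the PTD solution).
#' @param seed RNG seed.
#' @param n_restarts Consensus restarts for the PC-space k-means.
#' @return List: pc_labels, agreement_fraction, explained_variance_fractions
#'   (per-component fractions for PC1 and PC2), scores.
#' @export
pca_crosscheck <- function(norm_waveforms, ptd_labels, k, seed = 1,
                           n_restarts = 100) {
  if (length(unique(ptd_labels)) != k)
    stop_config("ptd_labels has %d clusters but k = %d",
                length(unique(ptd_labels)), k)
  pc <- prcomp(norm_waveforms, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, 1:2, drop = FALSE]
  sol <- meta_kmeans(scores, k = k, n_restarts = n_restarts, seed = seed)
  agr <- label_agreement(ptd_labels, sol$labels)
  list(pc_labels = sol$labels, agreement_fraction = agr$agreement,
       explained_variance_fractions = ev[1:2], scores = scores)
}

#' Name PTD clusters by ascending mean width
#'
#' Maps cluster ids to narrow/medium/broad (k = 3), narrow/broad (k = 2) or
#' generic names, ordered by the cluster-mean PTD.
#'
#' @param labels Cluster labels.
#' @param ptd Per-unit PTD values.
#' @return Character vector of class names.
#' @export
name_classes_by_width <- function(labels, ptd) {
  k <- length(unique(labels))
  means <- tapply(ptd, labels, mean)
  ord <- order(means)
  nm <- if (k == 3) c("narrow", "medium", "broad")
        else if (k == 2) c("narrow", "broad")
        else paste0("class", seq_len(k))
  mapping <- stats::setNames(nm, names(means)[ord])
  unname(mapping[as.character(labels)])
}
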