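#' Type II (major-axis) linear regression
#'
#' Model-II regression appropriate when both variables carry error: the
#' fitted line is the major axis of the sample covariance matrix. The slope
#' has the closed form
#' `(s_yy - s_xx + sqrt((s_yy - s_xx)^2 + 4 s_xy^2)) / (2 s_xy)`.
#' A 95% confidence interval is obtained by bootstrap percentile over pairs,
#' and `r`/`p` come from the Pearson correlation.
#'
#' @param x,y numeric vectors (n >= 3; `x` not constant).
#' @param n_boot bootstrap resamples for the CI.
#' @param seed seed for the bootstrap.
#' @return a `type2_fit`: slope, intercept, ci95, r, p.
#' @export
type2_regression <- function(x, y, n_boot = 200, seed = 1) {
  abort_if(length(x) != length(y), "x and y must have equal length")
  abort_if(length(x) < 3, "need at least 3 points")
  abort_if(stats::sd(x) == 0, "x must not be constant")
  sl <- major_axis_slope(x, y)
  ev <- eigen(stats::cov(cbind(x, y)), symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] / ev[1] > 0.95)
    rlang::warn("near-isotropic point cloud: major axis is ambiguous")
  set.seed(as.integer(seed))
  boot <- replicate(n_boot, {
    i <- sample.int(length(x), replace = TRUE)
    if (stats::sd(x[i]) == 0) NA_real_ else major_axis_slope(x[i], y[i])
  })
  ci <- unname(stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  ct <- stats::cor.test(x, y)
  structure(list(slope = sl, intercept = mean(y) - sl * mean(x),
                 ci95 = ci, r = unname(ct$estimate), p = ct$p.value,
                 n = length(x)),
            class = "type2_fit")
}

major_axis_slope <- function(x, y) {
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxy == 0) {
    rlang::warn("zero covariance: major axis aligned with a coordinate axis")
    return(if (syy > sxx) Inf else 0)
  }
  (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
}

#' @export
print.type2_fit <- function(x, ...) {
  cat("<type2_fit> slope = ", signif(x$slope, 4), " [",
      signif(x$ci95[1], 4), ", ", signif(x$ci95[2], 4), "], R = ",
      signif(x$r, 3), ", p = ", format.pval(x$p), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.type2_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 conf.low = c(NA, x$ci95[1]), conf.high = c(NA, x$ci95[2]))
}

#' @export
glance.type2_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r = x$r,
                 p.value = x$p, n = x$n)
}

#' Sequential F-test between nested noise-correlation structures
#'
#' Compares a reduced model in which noise correlation depends only on
#' vestibular signal correlation (`r_noise = a * r_sv`) against the full
#' model with both modalities (`r_noise = a * r_sv + b * r_si`), both fitted
#' by least squares without intercepts (matching the model forms). The test
#' statistic is `F = (RSS_red - RSS_full) / (RSS_full / (n - 2))` on
#' (1, n - 2) degrees of freedom.
#'
#' @param pairs tibble with columns `r_signal_vest`, `r_signal_vis`,
#'   `r_noise` (e.g. from [generate_synthetic_pairs()]).
#' @return list: `F`, `p`, `coef_reduced`, `coef_full`, `rss_reduced`,
#'   `rss_full`, `n`.
#' @export
sequential_f_test <- function(pairs) {
  n <- nrow(pairs)
  abort_if(n < 4, "need at least 4 pairs")
  x1 <- pairs$r_signal_vest
  x2 <- pairs$r_signal_vis
  y <- pairs$r_noise
  X <- cbind(vestibular = x1, visual = x2)
  abort_if(qr(X)$rank < 2, "collinear predictors: the two signal correlations are not distinguishable")
  red <- stats::lm.fit(X[, 1, drop = FALSE], y)
  full <- stats::lm.fit(X, y)
  rss_r <- sum(red$residuals^2)
  rss_f <- sum(full$residuals^2)
  Fstat <- (rss_r - rss_f) / (rss_f / (n - 2))
  list(F = Fstat, p = stats::pf(Fstat, 1, n - 2, lower.tail = FALSE),
       coef_reduced = stats::coef(red), coef_full = stats::coef(full),
       rss_reduced = rss_r, rss_full = rss_f, n = n)
}

#' Ansari-Bradley rank test of equal dispersion
#'
#' Two-sided test that two samples share a scale parameter, via
#' [stats::ansari.test()] (exact enumeration for small samples without ties,
#' normal approximation otherwise). Degenerate input (all values identical
#' across both samples) returns p = 1.
#'
#' @param x,y numeric samples (each n >= 3).
#' @return two-sided p-value.
#' @export
ansari_bradley <- function(x, y) {
  abort_if(length(x) < 3 || length(y) < 3, "both samples need n >= 3")
  if (stats::sd(c(x, y)) == 0) return(1)
  suppressWarnings(stats::ansari.test(x, y)$p.value)
}

# count density modes at a given bandwidth
count_modes <- function(x, bw) {
  d <- stats::density(x, bw = bw, n = 512)
  sum(diff(sign(diff(d$y))) == -2)
}

# smallest bandwidth at which the kernel density has at most k modes
critical_bandwidth <- function(x, k, iter = 32) {
  hi <- stats::sd(x)
  while (count_modes(x, hi) > k) hi <- hi * 2
  lo <- hi / 1024
  if (count_modes(x, lo) <= k) return(lo)
  for (i in seq_len(iter)) {
    mid <- sqrt(lo * hi)
    if (count_modes(x, mid) <= k) hi <- mid else lo <- mid
  }
  hi
}

# Watson U2 goodness-of-fit statistic of a sample against a fitted CDF
watson_u2 <- function(x, cdf) {
  n <- length(x)
  u <- sort(cdf(x))
  w2 <- sum((u - (2 * seq_len(n) - 1) / (2 * n))^2) + 1 / (12 * n)
  w2 - n * (mean(u) - 0.5)^2
}

# CDF of the variance-rescaled Gaussian-kernel smooth of x at bandwidth h
kde_cdf <- function(x, h) {
  xb <- mean(x)
  s2 <- stats::var(x)
  shrink <- 1 / sqrt(1 + h^2 / s2)
  centers <- xb + (x - xb) * shrink
  hh <- h * shrink
  function(q) vapply(q, function(t) mean(stats::pnorm((t - centers) / hh)),
                     numeric(1))
}

# draw one bootstrap sample from the rescaled smooth density
kde_resample <- function(x, h) {
  xb <- mean(x)
  s2 <- stats::var(x)
  n <- length(x)
  y <- x[sample.int(n, replace = TRUE)] + h * stats::rnorm(n)
  xb + (y - xb) / sqrt(1 + h^2 / s2)
}

#' Kernel-density multimodality test
#'
#' Tests whether a sample is unimodal or bimodal using critical smoothing
#' bandwidths: `h_k` is the smallest Gaussian-kernel bandwidth at which the
#' density estimate has at most k modes (found by bisection). The
#' goodness of fit of the sample to the critically smoothed k-modal density
#' is measured with Watson's U2 statistic on the fitted CDF; its null
#' distribution is obtained by bootstrapping samples from that
#' (variance-rescaled) density. Decision rule: `p_uni > 0.05` is unimodal;
#' `p_uni < 0.05` together with `p_bi > 0.05` is bimodal. The decision is
#' invariant under affine rescaling of the data.
#'
#' @param values numeric sample (n >= 20).
#' @param n_boot bootstrap resamples per hypothesis.
#' @param seed seed for the bootstrap.
#' @return list: `p_uni`, `p_bi`, `h_uni`, `h_bi`, `decision`
#'   (`"unimodal"`, `"bimodal"` or `"multimodal"`).
#' @export
modality_test <- function(values, n_boot = 200, seed = 1) {
  abort_if(length(values) < 20, "need at least 20 values")
  set.seed(as.integer(seed))
  p_of <- function(k) {
    h <- critical_bandwidth(values, k)
    t_obs <- watson_u2(values, kde_cdf(values, h))
    t_boot <- replicate(n_boot, {
      y <- kde_resample(values, h)
      watson_u2(y, kde_cdf(values, h))
    })
    list(p = (1 + sum(t_boot >= t_obs)) / (n_boot + 1), h = h)
  }
  uni <- p_of(1)
  bi <- p_of(2)
  decision <- if (uni$p > 0.05) "unimodal"
              else if (bi$p > 0.05) "bimodal" else "multimodal"
  list(p_uni = uni$p, p_bi = bi$p, h_uni = uni$h, h_bi = bi$h,
       decision = decision)
}

#' Separation of two K-means clusters of scalar CP values
#'
#' Two-cluster K-means (best of several seeded restarts) applied to a
#' vector of CP values; the separation index d is the absolute distance
#' between the two centroids. Returns 0 when the values do not support two
#' distinct clusters.
#'
#' @param cp_values numeric vector (n >= 4).
#' @param nstart K-means restarts.
#' @return centroid separation d >= 0.
#' @export
kmeans_separation <- function(cp_values, nstart = 10) {
  abort_if(length(cp_values) < 4, "need at least 4 values")
  if (length(unique(cp_values)) < 2) return(0)
  km <- stats::kmeans(cp_values, centers = 2, nstart = nstart)
  abs(diff(as.vector(km$centers)))
}

#' Spearman rank correlation with tie-corrected p-value
#'
#' @param x,y numeric vectors (n >= 3).
#' @return list: `rho`, `p`.
#' @export
rank_correlation <- function(x, y) {
  abort_if(length(x) != length(y), "x and y must have equal length")
  abort_if(length(x) < 3, "need at least 3 points")
  abort_if(stats::sd(x) == 0 || stats::sd(y) == 0,
           "rank correlation undefined for constant input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
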