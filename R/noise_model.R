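#' Specification of the tuning-similarity noise-correlation rule
#'
#' Pairwise noise correlations are assigned from signal correlations as
#' `r_noise = a_vestibular * r_signal_vestibular + a_visual * r_signal_visual`,
#' optionally restricted by a mask. Defaults are the coefficients fitted to
#' MSTd pair recordings (0.12 and 0.09); hypothetical simulations typically
#' use 0.1 for both. `variance_factor` scales trial-to-trial response
#' variance relative to the mean rate (Fano-like factor, default 1.5).
#'
#' Masks: `all_pairs` applies the full rule; `within_pool_only` zeroes
#' cross-pool entries; `vestibular_only` / `visual_only` keep a single term
#' (the pure-correlation model structures).
#'
#' @param a_vestibular,a_visual slope coefficients on the two signal
#'   correlations.
#' @param mask which pairs receive structured correlations.
#' @param variance_factor response variance / mean rate (> 0).
#' @return a `correlation_spec` list.
#' @export
correlation_spec <- function(a_vestibular = 0.12, a_visual = 0.09,
                             mask = c("all_pairs", "within_pool_only",
                                      "vestibular_only", "visual_only"),
                             variance_factor = 1.5) {
  mask <- match.arg(mask)
  abort_if(!is.finite(a_vestibular) || !is.finite(a_visual),
           "correlation coefficients must be finite")
  abort_if(variance_factor <= 0, "variance_factor must be > 0")
  structure(list(a_vestibular = a_vestibular, a_visual = a_visual,
                 mask = mask, variance_factor = variance_factor),
            class = "correlation_spec")
}

#' Signal correlation between two tuning curves
#'
#' Pearson correlation between the mean firing rates of two neurons over a
#' shared heading grid.
#'
#' @param rates_a,rates_b mean-rate vectors on the same grid.
#' @return correlation in \[-1, 1\].
#' @export
signal_correlation <- function(rates_a, rates_b) {
  abort_if(length(rates_a) != length(rates_b), "curves must share a grid")
  abort_if(stats::sd(rates_a) == 0 || stats::sd(rates_b) == 0,
           "signal correlation undefined for a flat tuning curve")
  stats::cor(rates_a, rates_b)
}

# pairwise signal-correlation matrix for one condition
signal_correlation_matrix <- function(pop, condition) {
  m <- tuning_matrix(pop, condition)
  abort_if(any(apply(m, 1, stats::sd) == 0),
           "flat tuning curve: signal correlations undefined")
  stats::cor(t(m))
}

#' Build a pairwise noise-correlation matrix from tuning similarity
#'
#' Off-diagonal entries follow the masked linear rule of
#' [correlation_spec()]; the diagonal is set to 1. Entries falling outside
#' \[-1, 1\] are clipped with a warning. The assigned matrix is not
#' guaranteed positive semidefinite, so it is passed through [nearest_psd()]
#' when needed; any eigenvalue adjustment is recorded in `repair_log`. The
#' symmetric matrix square root `Q` (with `Q %*% t(Q) = R`) used for trial
#' generation is computed by eigendecomposition.
#'
#' @param pop a `neural_population` with the conditions the mask requires.
#' @param spec a [correlation_spec()].
#' @return a `correlation_matrix`: list with `R`, `Q`, `repair_log`, `spec`.
#' @export
build_correlation_matrix <- function(pop, spec) {
  n <- nrow(pop$neurons)
  has <- function(k) k %in% pop$conditions
  need_vest <- spec$mask %in% c("all_pairs", "within_pool_only", "vestibular_only") &&
    spec$a_vestibular != 0
  need_vis <- spec$mask %in% c("all_pairs", "within_pool_only", "visual_only") &&
    spec$a_visual != 0
  abort_if(spec$mask == "vestibular_only" && !has("vestibular"),
           "mask requires vestibular tuning")
  abort_if(spec$mask == "visual_only" && !has("visual"),
           "mask requires visual tuning")

  R <- matrix(0, n, n)
  if (need_vest && has("vestibular"))
    R <- R + spec$a_vestibular * signal_correlation_matrix(pop, "vestibular")
  if (need_vis && has("visual"))
    R <- R + spec$a_visual * signal_correlation_matrix(pop, "visual")
  if (spec$mask == "within_pool_only") {
    abort_if(!"pool" %in% names(pop$neurons),
             "within_pool_only mask needs pool labels")
    same_pool <- outer(pop$neurons$pool, pop$neurons$pool, "==")
    R[!same_pool] <- 0
  }
  abort_if(any(!is.finite(R)), "non-finite noise correlation produced")
  if (any(R > 1 + 1e-12 | R < -1 - 1e-12)) {
    rlang::warn("noise correlations outside [-1, 1] were clipped")
    R <- clip(R, -1, 1)
  }
  diag(R) <- 1
  R <- (R + t(R)) / 2

  repair_log <- list(repaired = FALSE)
  ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-10) {
    R_fixed <- nearest_psd(R)
    repair_log <- list(repaired = TRUE, min_eigenvalue_before = ev_min,
                       max_abs_change = max(abs(R_fixed - R)))
    R <- R_fixed
  }
  structure(list(R = R, Q = matrix_sqrt(R), repair_log = repair_log, spec = spec),
            class = "correlation_matrix")
}

#' Nearest positive-semidefinite repair by eigenvalue clipping
#'
#' Negative eigenvalues are clipped at zero, the matrix is reassembled, and
#' the diagonal is renormalized to 1 (so the result is again a correlation
#' matrix). Idempotent on PSD inputs.
#'
#' @param R symmetric matrix.
#' @return symmetric PSD matrix with unit diagonal.
#' @export
nearest_psd <- function(R) {
  abort_if(!isSymmetric(R, tol = 1e-8), "nearest_psd expects a symmetric matrix")
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (min(e$values) >= 0) return(R)
  v <- pmax(e$values, 0)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(out))
  d[d == 0] <- 1
  out <- out / tcrossprod(d)
  diag(out) <- 1
  (out + t(out)) / 2
}

#' Symmetric square root of a PSD correlation matrix
#'
#' Returns `Q` with `Q %*% t(Q) = R`, computed by eigendecomposition. Unlike
#' a Cholesky factor, the symmetric root exists for singular PSD matrices.
#' Inputs with an eigenvalue below `-tol` are rejected (repair first with
#' [nearest_psd()]).
#'
#' @param R symmetric PSD matrix.
#' @param tol tolerance on negative eigenvalues.
#' @return symmetric matrix `Q`.
#' @export
matrix_sqrt <- function(R, tol = 1e-8) {
  abort_if(!isSymmetric(R, tol = 1e-8), "matrix_sqrt expects a symmetric matrix")
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  abort_if(min(e$values) < -tol,
           "matrix has a negative eigenvalue beyond tolerance; repair with nearest_psd() first")
  v <- sqrt(pmax(e$values, 0))
  e$vectors %*% (v * t(e$vectors))
}

#' Simulate correlated single-trial population responses
#'
#' For each condition and heading, single-trial rates are drawn as
#' `response = mean + sqrt(variance_factor * mean) * (Q %*% z)` with `z` a
#' standard-normal vector, i.e. proportional Gaussian noise whose variance is
#' `variance_factor` times the mean rate, correlated across neurons through
#' the matrix square root `Q`. Negative draws are retained by default (this
#' preserves the assigned correlation structure exactly); set
#' `rectify = TRUE` to clamp rates at 0 for sensitivity analyses.
#'
#' @param pop a `neural_population`.
#' @param corr a `correlation_matrix` from [build_correlation_matrix()].
#' @param conditions conditions to simulate (default: all in `pop`).
#' @param n_trials trials per heading (>= 2); 200 is the conventional choice.
#' @param seed integer seed; regeneration with the same seed is
#'   bit-identical.
#' @param rectify clamp negative rates at 0.
#' @return a `trial_set`: responses indexed \[neuron, heading, trial\] per
#'   condition.
#' @export
simulate_trials <- function(pop, corr, conditions = NULL, n_trials = 200,
                            seed = 1, rectify = FALSE) {
  conditions <- conditions %||% pop$conditions
  abort_if(n_trials < 2, "n_trials must be >= 2")
  n <- nrow(pop$neurons)
  abort_if(nrow(corr$R) != n, "correlation matrix dimension must match population size")
  vf <- corr$spec$variance_factor
  set.seed(as.integer(seed))
  responses <- lapply(conditions, function(k) {
    m <- tuning_matrix(pop, k)
    arr <- array(NA_real_, dim = c(n, length(pop$grid), n_trials),
                 dimnames = list(rownames(m), pop$grid, NULL))
    for (h in seq_along(pop$grid)) {
      mu <- m[, h]
      z <- matrix(stats::rnorm(n * n_trials), n, n_trials)
      resp <- mu + sqrt(vf * mu) * (corr$Q %*% z)
      if (rectify) resp <- pmax(resp, 0)
      arr[, h, ] <- resp
    }
    arr
  })
  names(responses) <- conditions
  structure(list(responses = responses, grid = pop$grid, n_trials = n_trials,
                 conditions = conditions, seed = as.integer(seed),
                 rectify = rectify, variance_factor = vf),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat("<trial_set> ", dim(x$responses[[1]])[1], " neurons x ",
      length(x$grid), " headings x ", x$n_trials, " trials; conditions: ",
      paste(x$conditions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Long table of simulated trials
#'
#' @param x a `trial_set`.
#' @param ... unused.
#' @return tibble with `neuron_id`, `condition`, `heading_deg`, `trial`,
#'   `rate_hz`.
#' @export
tidy.trial_set <- function(x, ...) {
  purrr::map_dfr(x$conditions, function(k) {
    arr <- x$responses[[k]]
    d <- dim(arr)
    tibble::tibble(
      neuron_id = rep(as.integer(dimnames(arr)[[1]]), times = d[2] * d[3]),
      condition = k,
      heading_deg = rep(rep(x$grid, each = d[1]), times = d[3]),
      trial = rep(seq_len(d[3]), each = d[1] * d[2]),
      rate_hz = as.vector(arr)
    )
  })
}

#' Empirical noise-correlation matrix from simulated trials
#'
#' Responses are standardized within each heading (per neuron: subtract the
#' across-trial mean, divide by the across-trial SD) to remove
#' stimulus-driven covariance, then pooled across headings; the Pearson
#' correlation of the pooled standardized responses estimates r_noise.
#' Headings where any neuron has zero variance are excluded with a warning.
#'
#' @param trials a `trial_set`.
#' @param condition which condition to estimate from.
#' @return symmetric matrix of pairwise noise-correlation estimates.
#' @export
empirical_noise_correlation <- function(trials, condition = trials$conditions[1]) {
  arr <- trials$responses[[condition]]
  abort_if(is.null(arr), "condition not present in trial set")
  abort_if(dim(arr)[3] < 2, "need at least 2 trials per heading")
  pooled <- list()
  dropped <- 0
  for (h in seq_len(dim(arr)[2])) {
    x <- arr[, h, ]
    s <- apply(x, 1, stats::sd)
    if (any(s == 0)) {
      dropped <- dropped + 1
      next
    }
    pooled[[length(pooled) + 1]] <- (x - rowMeans(x)) / s
  }
  if (dropped > 0)
    rlang::warn(paste(dropped, "heading(s) with zero variance excluded"))
  abort_if(length(pooled) == 0, "no usable headings")
  stats::cor(t(do.call(cbind, pooled)))
}
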