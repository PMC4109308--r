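#' Area under the ROC curve between two response distributions
#'
#' Pairwise-comparison estimator: the fraction of (pref, null) response
#' pairs in which the preferred-group response exceeds the null-group
#' response, ties counted 0.5. Equivalent to the area under the ROC curve,
#' and invariant under any strictly increasing transform of the responses.
#'
#' @param pref_group,null_group numeric response vectors (nonempty).
#' @return value in \[0, 1\].
#' @examples
#' roc_area(c(3, 4), c(1, 2))  # 1
#' roc_area(c(2, 4), c(3, 5))  # 0.25
#' @export
roc_area <- function(pref_group, null_group) {
  abort_if(length(pref_group) == 0 || length(null_group) == 0,
           "both response groups must be nonempty")
  n1 <- length(pref_group)
  n2 <- length(null_group)
  r <- rank(c(pref_group, null_group))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Choice probability of one neuron at the ambiguous heading
#'
#' Trials at 0 deg are split by whether the decoder's choice matches the
#' neuron's preferred direction in the analyzed condition (`pref_sign`:
#' +1 = rightward). CP is the ROC area of preferred-choice responses against
#' opposite-choice responses, so CP > 0.5 means stronger firing precedes
#' preferred-direction choices. CP is undefined (NA) when either choice
#' group has fewer than `min_trials` trials. An optional permutation p-value
#' is computed by shuffling choice labels.
#'
#' @param responses rates per trial at 0 deg.
#' @param choices character vector (`"left"`/`"right"`), aligned by trial.
#' @param pref_sign -1 (leftward) or +1 (rightward).
#' @param min_trials minimum trials per choice group (default 5).
#' @param n_perm permutation count for the p-value (0 = skip).
#' @return one-row tibble: `cp`, `n_pref`, `n_null`, `p_perm`.
#' @export
choice_probability <- function(responses, choices, pref_sign, min_trials = 5,
                               n_perm = 0) {
  abort_if(length(responses) != length(choices),
           "responses and choices must align by trial")
  abort_if(!pref_sign %in% c(-1, 1), "pref_sign must be -1 or +1")
  pref_dir <- if (pref_sign > 0) "right" else "left"
  is_pref <- choices == pref_dir
  n_pref <- sum(is_pref)
  n_null <- sum(!is_pref)
  if (n_pref < min_trials || n_null < min_trials) {
    return(tibble::tibble(cp = NA_real_, n_pref = n_pref, n_null = n_null,
                          p_perm = NA_real_))
  }
  cp <- roc_area(responses[is_pref], responses[!is_pref])
  p_perm <- NA_real_
  if (n_perm > 0) {
    null_cp <- replicate(n_perm, {
      lab <- sample(is_pref)
      roc_area(responses[lab], responses[!lab])
    })
    p_perm <- (1 + sum(abs(null_cp - 0.5) >= abs(cp - 0.5))) / (n_perm + 1)
  }
  tibble::tibble(cp = cp, n_pref = n_pref, n_null = n_null, p_perm = p_perm)
}

#' Choice probabilities for every neuron in a decoded simulation
#'
#' Combines a `trial_set` with the choice records produced by [run_task()]
#' and computes each neuron's CP at the 0 deg heading, per condition. The
#' reference sign for the combined condition is the sign of the combined
#' tuning slope; for single-cue conditions it is the neuron's preference in
#' that condition.
#'
#' @param trials a `trial_set`.
#' @param pop the generating `neural_population`.
#' @param records choice records from [run_task()].
#' @param conditions conditions to analyze (default: those in `records`).
#' @param min_trials minimum trials per choice group.
#' @return tibble: `neuron_id`, `condition`, `congruency_index`, `class`,
#'   `cp`, `n_pref`, `n_null`.
#' @export
choice_probability_table <- function(trials, pop, records, conditions = NULL,
                                     min_trials = 5) {
  conditions <- conditions %||% unique(records$condition)
  h0 <- which(trials$grid == 0)
  nn <- pop$neurons
  purrr::map_dfr(conditions, function(k) {
    arr <- trials$responses[[k]]
    rec <- dplyr::filter(records, .data$condition == k, .data$heading_deg == 0)
    rec <- dplyr::arrange(rec, .data$trial)
    sign_col <- paste0("pref_sign_", k)
    abort_if(!sign_col %in% names(nn), paste("no preference sign for", k))
    purrr::map_dfr(seq_len(nrow(nn)), function(i) {
      ps <- nn[[sign_col]][i]
      if (is.na(ps) || ps == 0) {
        res <- tibble::tibble(cp = NA_real_, n_pref = NA_integer_,
                              n_null = NA_integer_, p_perm = NA_real_)
      } else {
        res <- choice_probability(arr[i, h0, ], rec$choice, ps, min_trials)
      }
      tibble::tibble(
        neuron_id = nn$neuron_id[i], condition = k,
        congruency_index = if ("congruency_index" %in% names(nn))
          nn$congruency_index[i] else NA_real_,
        class = if ("class" %in% names(nn)) nn$class[i] else NA_character_,
        cp = res$cp, n_pref = res$n_pref, n_null = res$n_null
      )
    })
  })
}

new_threshold_fit <- function(mu, sigma, converged, n_points, scope) {
  structure(list(mu = mu, sigma = sigma, converged = converged,
                 n_points = n_points, scope = scope),
            class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat("<threshold_fit> (", x$scope, ") mu = ", signif(x$mu, 4),
      " deg, sigma = ", signif(x$sigma, 4), " deg, converged = ",
      x$converged, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.threshold_fit <- function(x, ...) {
  tibble::tibble(term = c("mu", "sigma"), estimate = c(x$mu, x$sigma))
}

#' @export
glance.threshold_fit <- function(x, ...) {
  tibble::tibble(mu = x$mu, sigma = x$sigma, converged = x$converged,
                 n_points = x$n_points, scope = x$scope)
}

# probit GLM fit of proportion-rightward vs heading; cumulative-Gaussian MLE
fit_cumulative_gaussian <- function(heading, n_right, n_total, span,
                                    force_zero_mu = FALSE) {
  ok <- n_total > 0
  heading <- heading[ok]; n_right <- n_right[ok]; n_total <- n_total[ok]
  fml <- if (force_zero_mu) cbind(n_right, n_total - n_right) ~ heading + 0
         else cbind(n_right, n_total - n_right) ~ heading
  fit <- tryCatch(
    suppressWarnings(stats::glm(fml, family = stats::quasibinomial("probit"))),
    error = function(e) NULL)
  if (is.null(fit)) return(list(mu = NA_real_, sigma = span, converged = FALSE))
  cf <- stats::coef(fit)
  slope <- cf[["heading"]]
  intercept <- if ("(Intercept)" %in% names(cf)) cf[["(Intercept)"]] else 0
  bad <- !fit$converged || !is.finite(slope) || slope <= 0
  sigma <- if (is.finite(slope) && slope > 0) 1 / slope else Inf
  mu <- if (is.finite(slope) && slope != 0) -intercept / slope else NA_real_
  flagged <- bad || sigma > 2 * span || sigma < span / 1e4
  list(mu = mu, sigma = min(max(sigma, span / 1e4), 100 * span),
       converged = !flagged)
}

#' Psychometric threshold from decoded choice records
#'
#' Maximum-likelihood fit of the proportion of rightward choices versus
#' heading to a cumulative Gaussian `Phi((theta - mu) / sigma)` with no
#' lapse terms (a probit GLM). The threshold is the fitted `sigma`
#' (~84%-correct point). Uninformative or perfectly separated data are
#' returned with a bounded `sigma` and `converged = FALSE`.
#'
#' @param records choice records from [run_task()], a single condition (or
#'   pass `condition` to filter).
#' @param condition optional condition filter.
#' @return a `threshold_fit`.
#' @export
psychometric_threshold <- function(records, condition = NULL) {
  if (!is.null(condition))
    records <- dplyr::filter(records, .data$condition == !!condition)
  agg <- records |>
    dplyr::group_by(.data$heading_deg) |>
    dplyr::summarise(n_right = sum(.data$choice == "right"), n = dplyr::n(),
                     .groups = "drop")
  abort_if(nrow(agg) < 5, "need at least 5 headings spanning 0")
  abort_if(min(agg$heading_deg) >= 0 || max(agg$heading_deg) <= 0,
           "headings must span 0")
  span <- max(abs(agg$heading_deg))
  res <- fit_cumulative_gaussian(agg$heading_deg, agg$n_right, agg$n, span)
  new_threshold_fit(res$mu, res$sigma, res$converged, nrow(agg),
                    "psychometric")
}

#' Neurometric threshold of a single neuron
#'
#' For each symmetric heading pair +/-theta, the discriminability of the
#' neuron's responses is the ROC area between the +theta and -theta response
#' distributions, oriented by the neuron's heading preference in the
#' condition (the ideal-observer / anti-neuron convention). These
#' proportions are fitted versus signed heading with a cumulative Gaussian
#' through 0.5 at 0 deg (probit ML with trial-count weights); the threshold
#' is the fitted sigma.
#'
#' @param trials a `trial_set`.
#' @param neuron_id neuron to analyze.
#' @param condition condition to analyze.
#' @param pref_sign optional preference sign override (-1/+1); otherwise
#'   inferred from the sign of the response-heading correlation of the
#'   trial means.
#' @return a `threshold_fit`.
#' @export
neurometric_threshold <- function(trials, neuron_id, condition,
                                  pref_sign = NULL) {
  arr <- trials$responses[[condition]]
  abort_if(is.null(arr), "condition not present in trial set")
  i <- match(as.character(neuron_id), dimnames(arr)[[1]])
  abort_if(is.na(i), "neuron not found")
  grid <- trials$grid
  pos <- grid[grid > 0]
  abort_if(length(pos) < 3, "need at least 3 symmetric heading pairs")
  if (is.null(pref_sign)) {
    mr <- apply(arr[i, , ], 1, mean)
    pref_sign <- sign(stats::cor(mr, grid))
    if (!pref_sign %in% c(-1, 1)) pref_sign <- 1
  }
  p <- vapply(pos, function(th) {
    rp <- arr[i, which(grid == th), ]
    rn <- arr[i, which(grid == -th), ]
    if (pref_sign > 0) roc_area(rp, rn) else roc_area(rn, rp)
  }, numeric(1))
  n_tr <- dim(arr)[3]
  heading <- c(pos, -pos)
  n_right <- round(c(p, 1 - p) * n_tr)
  span <- max(pos)
  res <- fit_cumulative_gaussian(heading, n_right, rep(n_tr, length(heading)),
                                 span, force_zero_mu = TRUE)
  new_threshold_fit(0, res$sigma, res$converged, length(pos), "neurometric")
}

#' Neurometric thresholds for all neurons
#'
#' @param trials a `trial_set`.
#' @param pop the generating population (supplies preference signs).
#' @param conditions conditions to analyze.
#' @return tibble: `neuron_id`, `condition`, `sigma`, `converged`.
#' @export
neurometric_table <- function(trials, pop, conditions = NULL) {
  conditions <- conditions %||% trials$conditions
  nn <- pop$neurons
  purrr::map_dfr(conditions, function(k) {
    sign_col <- paste0("pref_sign_", k)
    purrr::map_dfr(nn$neuron_id, function(id) {
      ps <- if (sign_col %in% names(nn)) nn[[sign_col]][nn$neuron_id == id] else NULL
      if (!is.null(ps) && (is.na(ps) || ps == 0)) ps <- NULL
      fit <- neurometric_threshold(trials, id, k, pref_sign = ps)
      tibble::tibble(neuron_id = id, condition = k, sigma = fit$sigma,
                     converged = fit$converged)
    })
  })
}

#' Optimal cue-integration prediction for the combined threshold
#'
#' Under optimal (maximum-likelihood) integration of two independent cues
#' with single-cue thresholds `sigma_vest` and `sigma_vis`, the predicted
#' combined threshold is
#' `sigma_vest * sigma_vis / sqrt(sigma_vest^2 + sigma_vis^2)`. Always at
#' most the smaller single-cue threshold, and symmetric in its arguments.
#'
#' @param sigma_vest,sigma_vis single-cue thresholds in degrees (> 0).
#' @return predicted combined threshold in degrees.
#' @examples
#' optimal_combined_threshold(2.16, 1.24)  # ~1.07
#' @export
optimal_combined_threshold <- function(sigma_vest, sigma_vis) {
  abort_if(any(sigma_vest <= 0) || any(sigma_vis <= 0),
           "thresholds must be > 0")
  sigma_vest * sigma_vis / sqrt(sigma_vest^2 + sigma_vis^2)
}
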