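#' Configuration of the weighted maximum-likelihood readout
#'
#' The decoder computes, for each trial, a log-likelihood profile over
#' headings under independent-Poisson assumptions, using a reference tuning
#' curve per neuron, and reports left/right by comparing likelihood mass on
#' the two sides of straight ahead.
#'
#' `reference` selects which tuning curve plays the mean-rate template: the
#' vestibular curve for every condition (the default, matching the
#' hypothesis that all cells are decoded according to their vestibular
#' preference), the visual curve, or the curve of the condition being
#' decoded (`condition_matched`).
#'
#' Weight rules: `uniform` (all 1), `pool` (a constant per pool), two
#' congruency-dependent Readout-Index profiles (`ri_power`, the default, and
#' `ri_additive`; see Details), and `ri_verbatim` (the exponential profile
#' `(1 - exp(-(c/2) * RI)) / (1 - exp(-1))` exactly as printed in the source
#' formulation, kept available even though it goes negative for opposite
#' cells).
#'
#' @details Both RI profiles are built on the congruency sigmoid
#' `g(c) = clip[(1 - exp(-(c/2 + 1/2))) / (1 - exp(-1)), 0, 1]`, which rises
#' from 0 at congruency -1 to 1 at +1. The additive profile is
#' `w = RI + (1 - RI) * g(c)`: every neuron gets at least RI. The power
#' profile is `w = g(c)^(4 * (1 - RI))`: congruent cells keep near-full
#' weight at every RI while opposite cells receive little weight at
#' intermediate RI. Both satisfy the qualitative
#' contract -- weight 1 for every congruency at RI = 1, opposite-cell weight
#' falling to 0 as RI falls to 0, monotone in congruency and RI, confined to
#' \[0, 1\] -- but only the power profile also produces roughly matched
#' vestibular and visual decoder thresholds at mid-range RI, so it is the
#' default.
#'
#' `polarity` maps pool labels to `"preferred"` or `"anti_preferred"`; an
#' anti-preferred pool is decoded relative to each neuron's anti-preferred
#' stimulus, implemented by mirroring its reference tuning about 0 deg
#' (keeping the Poisson likelihood well-formed).
#'
#' @param reference reference-tuning convention.
#' @param weight_rule readout-weight rule.
#' @param ri Readout Index in \[0, 1\] (RI profiles only).
#' @param pool_weights named weights per pool (`pool` rule only).
#' @param polarity named character vector pool -> polarity; pools not named
#'   default to `"preferred"`.
#' @param rate_floor small positive rate (spikes/s) guarding `log(0)` at
#'   tuning nulls.
#' @return a `readout_spec`.
#' @export
readout_spec <- function(reference = c("vestibular", "visual", "condition_matched"),
                         weight_rule = c("ri_power", "ri_additive",
                                         "ri_verbatim", "pool", "uniform"),
                         ri = 0.5,
                         pool_weights = c(pool1 = 1, pool2 = 0),
                         polarity = NULL,
                         rate_floor = 0.1) {
  reference <- match.arg(reference)
  weight_rule <- match.arg(weight_rule)
  abort_if(ri < 0 || ri > 1, "Readout Index must lie in [0, 1]")
  abort_if(rate_floor <= 0, "rate_floor must be > 0")
  structure(list(reference = reference, weight_rule = weight_rule, ri = ri,
                 pool_weights = pool_weights, polarity = polarity,
                 rate_floor = rate_floor),
            class = "readout_spec")
}

# verbatim printed RI profile; negative for negative congruency
ri_weight_verbatim <- function(ci, ri) {
  (1 - exp(-(ci / 2) * ri)) / (1 - exp(-1))
}

# shared congruency sigmoid, 0 at c = -1, 1 at c = +1
ri_weight_base <- function(ci) {
  clip((1 - exp(-(ci / 2 + 0.5))) / (1 - exp(-1)), 0, 1)
}

# additive profile: w = RI + (1 - RI) g(c); every cell gets at least RI
ri_weight_additive <- function(ci, ri) {
  ri + (1 - ri) * ri_weight_base(ci)
}

# power profile (default): w = g(c)^(4 (1 - RI)). Same boundary behavior
# (w = 1 for all c at RI = 1; opposite-cell weight -> 0 as RI -> 0; monotone
# in congruency and RI; congruent cells keep near-full weight at every RI)
# but opposite and intermediate cells receive little weight at mid RI, which
# is what lets a mid-range RI produce roughly matched single-cue thresholds.
ri_weight_power <- function(ci, ri) {
  ri_weight_base(ci)^(4 * (1 - ri))
}

#' Readout weight of each neuron
#'
#' @param pop a `neural_population`.
#' @param spec a [readout_spec()].
#' @return tibble with `neuron_id` and `weight`.
#' @export
readout_weights <- function(pop, spec) {
  nn <- pop$neurons
  w <- switch(spec$weight_rule,
    uniform = rep(1, nrow(nn)),
    pool = {
      abort_if(!"pool" %in% names(nn), "pool weight rule needs pool labels")
      unname(spec$pool_weights[nn$pool])
    },
    ri_verbatim = ,
    ri_additive = ,
    ri_power = {
      abort_if(!"congruency_index" %in% names(nn) || anyNA(nn$congruency_index),
               "RI profiles need a congruency index for every neuron")
      fn <- switch(spec$weight_rule, ri_verbatim = ri_weight_verbatim,
                   ri_additive = ri_weight_additive, ri_power = ri_weight_power)
      fn(nn$congruency_index, spec$ri)
    }
  )
  tibble::tibble(neuron_id = nn$neuron_id, weight = w)
}

# reference tuning matrix (neurons x headings) with anti-preferred pools
# mirrored about 0 deg; grid symmetry makes mirroring a column reversal
reference_tuning <- function(pop, spec, condition) {
  ref_cond <- if (spec$reference == "condition_matched") condition else spec$reference
  f <- tuning_matrix(pop, ref_cond)
  if (!is.null(spec$polarity)) {
    anti <- names(spec$polarity)[spec$polarity == "anti_preferred"]
    if (length(anti) > 0) {
      abort_if(!"pool" %in% names(pop$neurons), "polarity map needs pool labels")
      rows <- pop$neurons$pool %in% anti
      f[rows, ] <- f[rows, rev(seq_len(ncol(f))), drop = FALSE]
    }
  }
  f
}

#' Log-likelihood profile over headings for one trial
#'
#' Under independent Poisson spiking (rates read in a 1 s window), the
#' weighted log likelihood of heading theta is
#' `sum_i w_i * r_i * log(max(f_i(theta), rate_floor)) - sum_i f_i(theta)`,
#' where `f_i` is neuron i's reference tuning curve. The second
#' (bias-correction) term is unweighted. Constant factors independent of
#' theta are dropped.
#'
#' @param response_vec observed rates, one per neuron.
#' @param pop a `neural_population`.
#' @param weights readout weights (tibble from [readout_weights()] or a
#'   plain numeric vector in neuron order).
#' @param spec a [readout_spec()].
#' @param condition condition of the trial being decoded.
#' @return a `likelihood_profile`: list with `angles` and `log_values`.
#' @export
log_likelihood <- function(response_vec, pop, weights, spec, condition) {
  n <- nrow(pop$neurons)
  abort_if(length(response_vec) != n,
           "response vector length must equal population size")
  w <- if (is.data.frame(weights)) weights$weight else weights
  abort_if(length(w) != n, "weights length must equal population size")
  f <- reference_tuning(pop, spec, condition)
  logf <- log(pmax(f, spec$rate_floor))
  lv <- unname(as.vector(crossprod(logf, w * response_vec)) - colSums(f))
  structure(list(angles = pop$grid, log_values = lv),
            class = "likelihood_profile")
}

#' Left/right decision from a likelihood profile
#'
#' The log profile is exponentiated after subtracting its maximum (overflow
#' guard), then likelihood mass is summed over leftward (theta < 0) and
#' rightward (theta > 0) headings, excluding 0 deg. The greater side wins;
#' an exact tie is broken by a fair coin (drawn from the current RNG stream)
#' and flagged.
#'
#' @param profile a `likelihood_profile` (symmetric grid about 0).
#' @return list with `choice` (`"left"`/`"right"`) and `tie` flag.
#' @export
decide <- function(profile) {
  lv <- profile$log_values
  abort_if(all(!is.finite(lv)), "likelihood profile is degenerate (all -Inf)")
  p <- exp(lv - max(lv))
  s_left <- sum(p[profile$angles < 0])
  s_right <- sum(p[profile$angles > 0])
  if (s_right > s_left) {
    list(choice = "right", tie = FALSE)
  } else if (s_left > s_right) {
    list(choice = "left", tie = FALSE)
  } else {
    list(choice = if (stats::runif(1) < 0.5) "left" else "right", tie = TRUE)
  }
}

#' Decode every simulated trial into a left/right choice
#'
#' Applies the weighted maximum-likelihood readout to each trial of a
#' `trial_set` and records one choice per trial. Deterministic given the
#' seed (which feeds only the tie-breaking coin).
#'
#' @param trials a `trial_set`.
#' @param pop the `neural_population` that generated the trials.
#' @param spec a [readout_spec()].
#' @param conditions conditions to decode (default: all in `trials`).
#' @param seed integer seed for tie breaking.
#' @return tibble of choice records: `condition`, `heading_deg`, `trial`,
#'   `choice`, `tie`.
#' @export
run_task <- function(trials, pop, spec, conditions = NULL, seed = 1) {
  conditions <- conditions %||% trials$conditions
  n <- nrow(pop$neurons)
  abort_if(dim(trials$responses[[1]])[1] != n,
           "trial set and population sizes differ")
  w <- readout_weights(pop, spec)$weight
  set.seed(as.integer(seed))
  purrr::map_dfr(conditions, function(k) {
    f <- reference_tuning(pop, spec, k)
    logf <- log(pmax(f, spec$rate_floor))
    bias <- colSums(f)
    arr <- trials$responses[[k]]
    is_left <- trials$grid < 0
    is_right <- trials$grid > 0
    purrr::map_dfr(seq_along(trials$grid), function(h) {
      resp <- arr[, h, ]                      # neurons x trials
      ll <- crossprod(w * resp, logf)         # trials x headings
      ll <- sweep(ll, 2, bias)
      p <- exp(ll - apply(ll, 1, max))
      s_left <- rowSums(p[, is_left, drop = FALSE])
      s_right <- rowSums(p[, is_right, drop = FALSE])
      tie <- s_left == s_right
      choice <- ifelse(s_right > s_left, "right", "left")
      if (any(tie)) choice[tie] <- ifelse(stats::runif(sum(tie)) < 0.5, "left", "right")
      tibble::tibble(condition = k, heading_deg = trials$grid[h],
                     trial = seq_len(ncol(resp)), choice = choice, tie = tie)
    })
  })
}
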