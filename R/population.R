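#' Fine heading grids for the discrimination task
#'
#' Logarithmically spaced headings around straight ahead (0 deg), symmetric
#' about zero. Two presets are provided: the grid used for fully hypothetical
#' cosine-tuned populations (`"hypothetical"`, with +/-0.25 deg) and the grid
#' onto which recorded tuning curves are interpolated (`"mstd"`, with
#' +/-0.2 deg). Both contain 0 and every +theta together with -theta.
#'
#' @param preset `"hypothetical"` or `"mstd"`.
#' @return numeric vector of headings in degrees, strictly increasing.
#' @examples
#' heading_grid("hypothetical")
#' @export
heading_grid <- function(preset = c("hypothetical", "mstd")) {
  preset <- match.arg(preset)
  half <- switch(preset,
    hypothetical = c(8, 4, 2, 1, 0.5, 0.25, 0.1),
    mstd         = c(8, 4, 2, 1, 0.5, 0.2, 0.1)
  )
  sort(c(-half, 0, half))
}

#' Validate a heading grid
#'
#' A valid grid is strictly increasing, contains 0, and contains -theta for
#' every +theta.
#'
#' @param angles numeric vector of headings in degrees.
#' @return the grid, invisibly, or an error.
#' @export
validate_heading_grid <- function(angles) {
  abort_if(!is.numeric(angles) || anyNA(angles) || any(!is.finite(angles)),
           "heading grid must be finite numeric")
  abort_if(any(diff(angles) <= 0), "heading grid must be strictly increasing")
  abort_if(!0 %in% angles, "heading grid must contain 0")
  abort_if(!isTRUE(all.equal(sort(angles), sort(-angles))),
           "heading grid must be symmetric about 0 (every +theta needs a -theta)")
  invisible(angles)
}

new_population <- function(tuning, neurons, grid, conditions, provenance, seed = NA_integer_) {
  structure(
    list(tuning = tuning, neurons = neurons, grid = grid,
         conditions = conditions, provenance = provenance, seed = seed),
    class = "neural_population"
  )
}

#' @export
print.neural_population <- function(x, ...) {
  cat("<neural_population> ", x$provenance, ": ", nrow(x$neurons), " neurons, ",
      length(x$grid), " headings, conditions: ",
      paste(x$conditions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Long tuning table of a population
#'
#' @param x a `neural_population`.
#' @param ... unused.
#' @return tibble with columns `neuron_id`, `condition`, `heading_deg`,
#'   `mean_rate_hz`.
#' @export
tidy.neural_population <- function(x, ...) x$tuning

#' Mean-rate matrix for one stimulus condition
#'
#' @param pop a `neural_population`.
#' @param condition condition name present in `pop`.
#' @return numeric matrix, neurons x headings, rows named by neuron id.
#' @export
tuning_matrix <- function(pop, condition) {
  abort_if(!condition %in% pop$conditions,
           paste0("condition '", condition, "' not present in population"))
  tb <- dplyr::filter(pop$tuning, .data$condition == !!condition)
  wide <- tidyr::pivot_wider(tb, id_cols = "neuron_id",
                             names_from = "heading_deg",
                             values_from = "mean_rate_hz")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$neuron_id
  # columns in grid order
  m[, order(as.numeric(colnames(m))), drop = FALSE]
}

cosine_rate <- function(theta, pref, amplitude) {
  amplitude * (cos((theta - pref) * pi / 180) + 1)
}

#' Generate a cosine-tuned hypothetical population
#'
#' Each neuron's mean rate is `amplitude * (cos((theta - P) * pi/180) + 1)`,
#' peaking at its preferred heading P with peak rate `2 * amplitude` and
#' minimum 0. For fine heading discrimination, preferences are +/-90 deg
#' (rightward/leftward), giving monotone tuning over the grid. The population
#' is split into two pools; each pool holds equal numbers of leftward- and
#' rightward-preferring units. With two stimulus conditions, pool 1 neurons
#' are congruent (same preference in both conditions) and pool 2 neurons are
#' either congruent too or opposite (preferences 180 deg apart,
#' `pool2_opposite = TRUE`).
#'
#' @param n number of neurons (each pool must come out even so that
#'   leftward/rightward counts balance).
#' @param amplitude rate scale in spikes/s (> 0); peak response is
#'   `2 * amplitude`.
#' @param preferences the two candidate preferred headings, degrees.
#' @param conditions character vector of stimulus conditions, subset of
#'   `c("vestibular", "visual")`.
#' @param grid heading grid (validated; must be symmetric about 0).
#' @param pool_split fraction of neurons in pool 1.
#' @param pool2_opposite if `TRUE` (two-condition case), pool 2 neurons have
#'   visual preference 180 deg from their vestibular preference.
#' @return a `neural_population`.
#' @examples
#' pop <- make_cosine_population(8, conditions = "vestibular")
#' range(pop$tuning$mean_rate_hz)
#' @export
make_cosine_population <- function(n, amplitude = 100,
                                   preferences = c(-90, 90),
                                   conditions = "vestibular",
                                   grid = heading_grid("hypothetical"),
                                   pool_split = 0.5,
                                   pool2_opposite = FALSE) {
  validate_heading_grid(grid)
  abort_if(amplitude <= 0, "amplitude must be > 0")
  abort_if(length(preferences) != 2, "exactly two candidate preferences expected")
  abort_if(!all(conditions %in% c("vestibular", "visual")),
           "conditions must be a subset of c('vestibular', 'visual')")
  n1 <- round(n * pool_split)
  n2 <- n - n1
  abort_if(n1 %% 2 != 0 || n2 %% 2 != 0,
           "each pool must contain an even number of neurons (equal left/right split)")

  pool <- rep(c("pool1", "pool2"), c(n1, n2))
  # alternate left/right within each pool
  pref_vest <- c(rep(preferences, n1 / 2), rep(preferences, n2 / 2))
  pref_vis <- pref_vest
  if (pool2_opposite && length(conditions) > 1) {
    flip <- pool == "pool2"
    pref_vis[flip] <- ifelse(pref_vest[flip] > 0, pref_vest[flip] - 180,
                             pref_vest[flip] + 180)
  }
  pref_by_cond <- list(vestibular = pref_vest, visual = pref_vis)

  tuning <- purrr::map_dfr(conditions, function(k) {
    p <- pref_by_cond[[k]]
    tibble::tibble(
      neuron_id = rep(seq_len(n), each = length(grid)),
      condition = k,
      heading_deg = rep(grid, times = n),
      mean_rate_hz = as.vector(vapply(seq_len(n), function(i)
        cosine_rate(grid, p[i], amplitude), numeric(length(grid))))
    )
  })

  neurons <- tibble::tibble(neuron_id = seq_len(n), pool = pool)
  pop <- new_population(tuning, neurons, grid, conditions, "hypothetical")
  pop$neurons <- annotate_neurons(pop)
  pop
}

# per-neuron rate-heading correlation signs, congruency index and class labels
annotate_neurons <- function(pop, class_band = 0.5) {
  out <- pop$neurons
  for (k in pop$conditions) {
    m <- tuning_matrix(pop, k)
    r <- unname(apply(m, 1, function(f) {
      if (stats::sd(f) == 0) return(NA_real_)
      stats::cor(f, pop$grid)
    }))
    out[[paste0("r_", k)]] <- r
    out[[paste0("pref_sign_", k)]] <- sign(r)
  }
  if (all(c("vestibular", "visual") %in% pop$conditions)) {
    out$congruency_index <- out$r_vestibular * out$r_visual
    out$class <- classify_congruency(out$congruency_index, class_band)
  }
  if ("combined" %in% pop$conditions && !"pref_sign_combined" %in% names(out)) {
    m <- tuning_matrix(pop, "combined")
    out$pref_sign_combined <- unname(sign(apply(m, 1, stats::cor, y = pop$grid)))
  }
  out
}

#' Label cells by visual-vestibular congruency
#'
#' Reporting convention: congruent if the congruency index is at least
#' `+band`, opposite if at most `-band`, otherwise intermediate. The default
#' band of 0.5 matches the \[-1, -0.5\] range used to select opposite cells
#' in the bimodality analyses.
#'
#' @param ci congruency index values in \[-1, 1\].
#' @param band classification band (default 0.5).
#' @return character vector: `"congruent"`, `"intermediate"` or `"opposite"`.
#' @export
classify_congruency <- function(ci, band = 0.5) {
  dplyr::case_when(
    is.na(ci) ~ NA_character_,
    ci >= band ~ "congruent",
    ci <= -band ~ "opposite",
    TRUE ~ "intermediate"
  )
}

#' Default calibration for the MSTd-like population generator
#'
#' Geometric-mean single-neuron neurometric thresholds (degrees) per
#' single-cue condition, with a log-normal spread, plus baseline firing-rate
#' scale. Slope magnitudes are derived analytically from these targets: with
#' response variance `variance_factor * mean rate`, a locally linear tuning
#' curve with baseline B and slope b has neurometric sigma
#' `sqrt(2 * variance_factor * B) / (2 * |b|)`.
#'
#' @param threshold_gm named geometric means of the target single-neuron
#'   thresholds (deg) for `vestibular` and `visual`.
#' @param threshold_sdlog log-scale SD of the per-neuron threshold draw.
#' @param baseline_gm geometric-mean baseline rate, spikes/s.
#' @param baseline_sdlog log-scale SD of the baseline draw.
#' @param variance_factor trial-to-trial variance / mean rate.
#' @param ripple_freq range of spatial frequencies (rad/deg) of the smooth
#'   ripple added to each tuning curve to de-linearize it.
#' @param ripple_dim number of shared ripple basis functions per condition.
#'   Small values bound the dimensionality of tuning diversity, which makes
#'   the tuning-similarity noise correlations information-limiting (decoder
#'   thresholds plateau with population size).
#' @param shape_coherence named correlations (`congruent`, `intermediate`,
#'   `opposite`) between a cell's visual ripple shape and its vestibular
#'   shape (the mirror image when the two heading preferences disagree).
#'   1 makes the visual curve a perfect (mirrored) affine transform; lower
#'   values add idiosyncratic visual curvature. The defaults are calibrated
#'   so that a Readout Index near 0.5 yields roughly matched vestibular and
#'   visual decoder thresholds.
#' @param combined_gain gain applied to the centered reliability-weighted
#'   blend that forms the combined-condition tuning curve. Calibrated so
#'   that the decoder's combined-condition threshold sits at the optimal
#'   cue-integration prediction from the measured single-cue thresholds,
#'   the empirical signature of near-optimal integration.
#' @return list of calibration parameters.
#' @export
mstd_sensitivity_params <- function(threshold_gm = c(vestibular = 7.1, visual = 5.5),
                                    threshold_sdlog = 0.45,
                                    baseline_gm = 30,
                                    baseline_sdlog = 0.4,
                                    variance_factor = 1.5,
                                    ripple_freq = c(0.15, 0.6),
                                    ripple_dim = 2,
                                    shape_coherence = c(congruent = 0.9,
                                                        intermediate = 0.7,
                                                        opposite = 0.5),
                                    combined_gain = 1.1) {
  list(threshold_gm = threshold_gm, threshold_sdlog = threshold_sdlog,
       baseline_gm = baseline_gm, baseline_sdlog = baseline_sdlog,
       variance_factor = variance_factor, ripple_freq = ripple_freq,
       ripple_dim = ripple_dim, shape_coherence = shape_coherence,
       combined_gain = combined_gain)
}

# shared ripple dictionary: K smooth basis functions over the grid,
# residualized against (1, theta) and scaled to unit SD. Drawing every
# neuron's curvature from a small shared dictionary bounds the dimensionality
# of tuning diversity, which makes the tuning-similarity noise correlations
# information-limiting at the population level (decoder thresholds plateau
# with population size instead of shrinking indefinitely).
ripple_dictionary <- function(grid, k, ripple_freq) {
  vapply(seq_len(k), function(j) {
    repeat {
      raw <- sin(grid * stats::runif(1, ripple_freq[1], ripple_freq[2]) +
                   stats::runif(1, 0, 2 * pi))
      res <- stats::lm.fit(cbind(1, grid), raw)$residuals
      if (stats::sd(res) > 1e-3) return(res / stats::sd(res))
    }
  }, numeric(length(grid)))
}

# one smooth tuning curve: baseline + signed slope + ripple of given
# amplitude, rectified at 0. With the ripple orthogonal to (1, theta), the
# rate-heading correlation is |b| sd(theta) / sqrt(b^2 sd(theta)^2 + amp^2)
# before rectification.
mstd_curve <- function(grid, baseline, slope, amp, ripple) {
  pmax(baseline + slope * grid + amp * ripple, 0)
}

# ripple amplitude that yields rate-heading correlation m at slope b
amp_for_correlation <- function(b, m, grid) {
  if (abs(m) >= 0.999) return(0)
  abs(b) * stats::sd(grid) * sqrt(1 / m^2 - 1)
}

#' Generate an MSTd-like multisensory population
#'
#' Synthetic stand-in for a sample of multisensory heading-selective neurons
#' with heterogeneous visual/vestibular congruency. Each neuron gets, per
#' single-cue condition, a tuning curve over the fine grid of the form
#' baseline + signed slope + smooth ripple, rectified at 0 spikes/s. Signed
#' slopes define the heading preference; the ripple amplitude is solved so
#' the rate-heading Pearson correlation hits a drawn target, which makes the
#' realized congruency-index distribution span \[-1, 1\]. Congruent cells get
#' same-sign slopes in the two conditions, opposite cells opposite-sign, and
#' intermediate cells a weak correlation in one randomly chosen condition.
#' Combined-condition tuning is the sum of the two single-cue curves, which
#' combines single-neuron sensitivities in near-quadrature (congruent cells
#' gain sensitivity; opposite cells largely cancel). Slope magnitudes are
#' calibrated from `sensitivity` so that congruent-cell neurometric
#' thresholds have geometric means near the targets (visual more sensitive
#' than vestibular by default). Drawing is fully seeded and reproducible.
#'
#' Cells are assigned `pool1` (congruent class, congruency index >= 0.5) or
#' `pool2` (all others) so that pool-based readouts can emulate a
#' congruent-cells-only decoder.
#'
#' @param n number of neurons (>= 2).
#' @param congruency_mix fractions of congruent / intermediate / opposite
#'   cells (nonnegative, summing to 1).
#' @param grid heading grid.
#' @param sensitivity calibration list from [mstd_sensitivity_params()].
#' @param seed integer seed.
#' @return a `neural_population` with conditions vestibular, visual and
#'   combined.
#' @export
make_mstd_like_population <- function(n = 200,
                                      congruency_mix = c(congruent = 0.40,
                                                         intermediate = 0.30,
                                                         opposite = 0.30),
                                      grid = heading_grid("mstd"),
                                      sensitivity = mstd_sensitivity_params(),
                                      seed = 1) {
  validate_heading_grid(grid)
  abort_if(n < 2, "n must be >= 2")
  abort_if(any(congruency_mix < 0), "congruency_mix fractions must be nonnegative")
  abort_if(abs(sum(congruency_mix) - 1) > 1e-8, "congruency_mix must sum to 1")
  abort_if(n %% 2 != 0, "n must be even (neurons are generated in mirror pairs)")
  set.seed(as.integer(seed))

  # neurons are drawn in mirror pairs: each drawn cell is accompanied by its
  # left/right mirror image (tuning reversed about 0 deg in every condition),
  # so the population is exactly balanced and the decoder unbiased at 0 deg
  n_draw <- n %/% 2
  classes <- sample(rep(c("congruent", "intermediate", "opposite"),
                        round_mix(congruency_mix, n_draw)))
  sp <- sensitivity
  conds <- c("vestibular", "visual")
  dict <- ripple_dictionary(grid, sp$ripple_dim, sp$ripple_freq)

  draw_ripple <- function() {
    repeat {
      r <- as.vector(dict %*% stats::rnorm(ncol(dict)))
      if (stats::sd(r) > 1e-3) return(r / stats::sd(r))
    }
  }

  curves <- vector("list", n_draw)
  for (i in seq_len(n_draw)) {
    d_vest <- sample(c(-1, 1), 1)
    d <- c(vestibular = d_vest,
           visual = switch(classes[i],
                           congruent = d_vest,
                           opposite = -d_vest,
                           intermediate = sample(c(-1, 1), 1)))
    # congruent and opposite cells share one tuning-linearity value across
    # modalities, so a congruent cell's visual curve is an affine transform
    # of its vestibular curve (and an opposite cell's its mirror image) --
    # the shape similarity that lets a vestibular-referenced decoder read
    # visual-condition responses coherently. Intermediate cells are weakly
    # tuned in one randomly chosen modality: weak correlation is realized by
    # shrinking the slope at normal ripple size, never by inflating the
    # ripple.
    weak <- if (classes[i] == "intermediate") sample(conds, 1) else NA
    m_shape <- stats::runif(1, 0.75, 0.98)
    m <- stats::setNames(rep(m_shape, 2), conds)
    if (classes[i] == "intermediate") {
      m[setdiff(conds, weak)] <- stats::runif(1, 0.55, 0.9)
      m[weak] <- stats::runif(1, 0.02, 0.35)
    }
    # tuning shape is shared across modalities in the way congruency
    # dictates: congruent cells reuse the vestibular ripple in the visual
    # curve, opposite cells get its mirror image (their visual tuning is the
    # reversed shape), intermediates draw an independent shape
    rip_vest <- draw_ripple()
    mix_shape <- function(base, rho) {
      r <- rho * base + sqrt(1 - rho^2) * draw_ripple()
      r / stats::sd(r)
    }
    vis_base <- if (d[["visual"]] == d[["vestibular"]]) rip_vest else rev(rip_vest)
    rip_vis <- mix_shape(vis_base, sp$shape_coherence[[classes[i]]])
    ripples <- list(vestibular = rip_vest, visual = rip_vis)
    # the threshold calibration (visual more sensitive than vestibular) was
    # measured on congruent cells; opposite cells get the symmetric
    # geometric-mean target in both modalities, so neither cue dominates
    # their combined-condition preference on average
    gm_k <- sp$threshold_gm
    if (classes[i] == "opposite")
      gm_k[] <- exp(mean(log(sp$threshold_gm)))
    per_cond <- lapply(conds, function(k) {
      B <- stats::rlnorm(1, log(sp$baseline_gm), sp$baseline_sdlog)
      sig <- stats::rlnorm(1, log(gm_k[[k]]), sp$threshold_sdlog)
      b_cal <- d[[k]] * sqrt(2 * sp$variance_factor * B) / (2 * sig)
      if (!is.na(weak) && k == weak) {
        # ripple sized as for a strongly tuned cell, slope shrunk to hit
        # the weak target correlation
        amp <- amp_for_correlation(b_cal, m_shape, grid)
        b <- d[[k]] * amp / (stats::sd(grid) * sqrt(1 / m[[k]]^2 - 1))
      } else {
        b <- b_cal
        amp <- amp_for_correlation(b, m[[k]], grid)
      }
      list(curve = mstd_curve(grid, B, b, amp, ripples[[k]]), B = B, b = b)
    })
    names(per_cond) <- conds
    # combined condition: reliability-weighted blend of the centered
    # single-cue curves at single-cue rate scale (sub-additive multisensory
    # response); congruent cells gain sensitivity from the more reliable
    # cue, opposite cells partially cancel
    s2 <- vapply(per_cond, function(p) p$b^2 / p$B, numeric(1))
    w <- s2 / sum(s2)
    B_c <- mean(vapply(per_cond, `[[`, numeric(1), "B"))
    comb <- B_c + sp$combined_gain *
      (w[["vestibular"]] * (per_cond$vestibular$curve - per_cond$vestibular$B) +
       w[["visual"]] * (per_cond$visual$curve - per_cond$visual$B))
    curves[[i]] <- list(vestibular = per_cond$vestibular$curve,
                        visual = per_cond$visual$curve,
                        combined = pmax(comb, 0))
  }
  mirrored <- lapply(curves, function(cc) lapply(cc, rev))
  all_curves <- vector("list", n)
  all_curves[seq(1, n, by = 2)] <- curves
  all_curves[seq(2, n, by = 2)] <- mirrored

  tuning <- purrr::map_dfr(c(conds, "combined"), function(k) {
    tibble::tibble(
      neuron_id = rep(seq_len(n), each = length(grid)),
      condition = k,
      heading_deg = rep(grid, times = n),
      mean_rate_hz = unlist(lapply(all_curves, `[[`, k), use.names = FALSE)
    )
  })

  neurons <- tibble::tibble(neuron_id = seq_len(n),
                            target_class = rep(classes, each = 2))
  pop <- new_population(tuning, neurons, grid,
                        c(conds, "combined"), "mstd_like", as.integer(seed))
  pop$neurons <- annotate_neurons(pop)
  pop$neurons$pool <- ifelse(pop$neurons$class == "congruent", "pool1", "pool2")
  pop
}

# largest-remainder rounding of class counts to total n
round_mix <- function(mix, n) {
  raw <- mix[c("congruent", "intermediate", "opposite")] * n
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    add <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[add] <- k[add] + 1
  }
  as.integer(k)
}

#' Linearly interpolate a tuning curve onto a new heading grid
#'
#' Works on a long tuning table; interpolation is done independently within
#' each `neuron_id` x `condition` group. Values at shared headings are
#' preserved exactly; extrapolation beyond the span of the source grid is
#' rejected.
#'
#' @param tuning tibble with columns `heading_deg`, `mean_rate_hz`, and
#'   optionally `neuron_id`, `condition`.
#' @param target_grid headings (degrees) to interpolate onto.
#' @return tibble in the same long format on the target grid.
#' @examples
#' tc <- tibble::tibble(heading_deg = c(0, 1), mean_rate_hz = c(10, 20))
#' interpolate_tuning(tc, 0.5)$mean_rate_hz  # 15
#' @export
interpolate_tuning <- function(tuning, target_grid) {
  abort_if(min(target_grid) < min(tuning$heading_deg) ||
             max(target_grid) > max(tuning$heading_deg),
           "target grid extends beyond the span of the source grid (extrapolation refused)")
  keys <- intersect(c("neuron_id", "condition"), names(tuning))
  grouped <- dplyr::group_by(tuning, dplyr::across(dplyr::all_of(keys)))
  out <- dplyr::reframe(grouped, {
    y <- stats::approx(.data$heading_deg, .data$mean_rate_hz,
                       xout = target_grid, method = "linear")$y
    tibble::tibble(heading_deg = target_grid, mean_rate_hz = y)
  })
  tibble::as_tibble(out)
}

#' Congruency index of visual vs vestibular tuning
#'
#' For each neuron, the Pearson correlation between mean rate and heading is
#' computed separately for the vestibular and visual tuning curves over the
#' fine grid; the congruency index is the product of the two coefficients.
#' Positive for congruent cells, negative for opposite cells.
#'
#' @param pop a `neural_population` containing both single-cue conditions.
#' @return tibble with `neuron_id`, `r_vestibular`, `r_visual`,
#'   `congruency_index`.
#' @export
congruency_index <- function(pop) {
  abort_if(!all(c("vestibular", "visual") %in% pop$conditions),
           "population must contain vestibular and visual conditions")
  mv <- tuning_matrix(pop, "vestibular")
  mi <- tuning_matrix(pop, "visual")
  flat <- apply(mv, 1, stats::sd) == 0 | apply(mi, 1, stats::sd) == 0
  abort_if(any(flat),
           "flat tuning in at least one condition: congruency index undefined")
  tibble::tibble(
    neuron_id = as.integer(rownames(mv)),
    r_vestibular = unname(apply(mv, 1, stats::cor, y = pop$grid)),
    r_visual = unname(apply(mi, 1, stats::cor, y = pop$grid))
  ) |>
    dplyr::mutate(congruency_index = .data$r_vestibular * .data$r_visual)
}

#' Classify a pair of neurons by congruency match
#'
#' The product of the two congruency indices decides the label: > 0.2 is
#' `matched` (congruent-congruent or opposite-opposite), < -0.2 is
#' `mismatched` (congruent-opposite), anything in between is `undefined`.
#'
#' @param ci_a,ci_b congruency indices in \[-1, 1\] (vectorized).
#' @return character vector of labels.
#' @examples
#' classify_pair_congruency(0.8, 0.9)   # matched
#' classify_pair_congruency(0.8, -0.9)  # mismatched
#' @export
classify_pair_congruency <- function(ci_a, ci_b) {
  abort_if(any(abs(ci_a) > 1, na.rm = TRUE) || any(abs(ci_b) > 1, na.rm = TRUE),
           "congruency indices must lie in [-1, 1]")
  prod <- ci_a * ci_b
  dplyr::case_when(
    prod > 0.2 ~ "matched",
    prod < -0.2 ~ "mismatched",
    TRUE ~ "undefined"
  )
}
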