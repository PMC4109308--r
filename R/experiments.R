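#' Simulation profiles
#'
#' Problem sizes for the packaged experiments. The `desk` profile (200
#' neurons, 100 trials per heading, 200 resamples) preserves every
#' sign/ordering property of the full-scale setting and runs in minutes;
#' the `paper` profile uses the full-scale sizes (1000 neurons, 200 trials
#' per heading).
#'
#' @param profile `"desk"` or `"paper"`.
#' @return list with `n_neurons`, `n_trials`, `n_boot`.
#' @export
cp_profile <- function(profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  switch(profile,
    desk = list(n_neurons = 200, n_trials = 100, n_boot = 200),
    paper = list(n_neurons = 1000, n_trials = 200, n_boot = 1000))
}

experiment_result <- function(name, config, ...) {
  cfg <- config
  structure(c(list(name = name, config = cfg,
                   config_hash = rlang::hash(c(list(name = name), cfg))),
              list(...)),
            class = "cp_experiment")
}

#' @export
print.cp_experiment <- function(x, ...) {
  cat("<cp_experiment> ", x$name, " (config hash ", x$config_hash, ")\n",
      sep = "")
  invisible(x)
}

#' Single-modality model comparison: correlated noise vs selective readout
#'
#' Two pools of cosine-tuned neurons, one stimulus condition. In the
#' pure-correlation variant all pairs are correlated in proportion to their
#' signal correlation, but only pool 1 is decoded (pool 2 weight 0); the
#' r_noise-vs-r_signal slope is swept and the mean CP of the non-decoded
#' pool is reported. In the selective-decoding variant noise is correlated
#' within each pool only; the pool-2 decoding weight is swept in \[0, 1\]
#' under both readout polarities (preferred and anti-preferred).
#'
#' @param slopes r_noise/r_signal slopes for the pure-correlation sweep.
#' @param weights pool-2 decoding weights for the selective sweep.
#' @param selective_slope within-pool correlation slope of the selective
#'   variant (0.1, the conventional hypothetical value).
#' @param n_neurons,n_trials,amplitude simulation sizes.
#' @param seed master seed.
#' @return a `cp_experiment` with tibbles `pure` (slope, pool-2 mean CP) and
#'   `selective` (weight, polarity, pool-2 mean CP).
#' @export
run_single_modality_models <- function(slopes = seq(0, 0.2, by = 0.05),
                                       weights = c(0, 0.25, 0.5, 0.75, 1),
                                       selective_slope = 0.1,
                                       n_neurons = 200, n_trials = 100,
                                       amplitude = 100, seed = 1) {
  cfg <- list(slopes = slopes, weights = weights,
              selective_slope = selective_slope, n_neurons = n_neurons,
              n_trials = n_trials, amplitude = amplitude, seed = seed)
  seeds <- derive_seeds(seed, 2 + length(slopes))
  pop <- make_cosine_population(n_neurons, amplitude,
                                conditions = "vestibular")
  pool2 <- pop$neurons$pool == "pool2"

  pure <- purrr::map_dfr(seq_along(slopes), function(j) {
    s <- slopes[j]
    corr <- build_correlation_matrix(
      pop, correlation_spec(a_vestibular = s, a_visual = 0, mask = "all_pairs"))
    trials <- simulate_trials(pop, corr, n_trials = n_trials, seed = seeds[2 + j])
    rs <- readout_spec(reference = "condition_matched", weight_rule = "pool",
                       pool_weights = c(pool1 = 1, pool2 = 0))
    rec <- run_task(trials, pop, rs, seed = seeds[2 + j])
    cp <- choice_probability_table(trials, pop, rec)
    tibble::tibble(slope = s,
                   pool2_mean_cp = mean(cp$cp[pool2], na.rm = TRUE),
                   pool1_mean_cp = mean(cp$cp[!pool2], na.rm = TRUE))
  })

  corr_sel <- build_correlation_matrix(
    pop, correlation_spec(a_vestibular = selective_slope, a_visual = 0,
                          mask = "within_pool_only"))
  trials_sel <- simulate_trials(pop, corr_sel, n_trials = n_trials,
                                seed = seeds[1])
  selective <- purrr::map_dfr(c("preferred", "anti_preferred"), function(pol) {
    purrr::map_dfr(weights, function(wt) {
      rs <- readout_spec(reference = "condition_matched", weight_rule = "pool",
                         pool_weights = c(pool1 = 1, pool2 = wt),
                         polarity = c(pool2 = pol))
      rec <- run_task(trials_sel, pop, rs, seed = seeds[2])
      cp <- choice_probability_table(trials_sel, pop, rec)
      tibble::tibble(weight = wt, polarity = pol,
                     pool2_mean_cp = mean(cp$cp[pool2], na.rm = TRUE))
    })
  })

  experiment_result("single_modality_models", cfg,
                    pure = pure, selective = selective)
}

#' Multisensory hypothetical model variants
#'
#' Two pools of cosine-tuned neurons with two stimulus conditions: pool 1
#' congruent cells, pool 2 opposite cells (visual preference 180 deg from
#' vestibular). Four variants are run: the pure-correlation model with
#' correlations tied to vestibular tuning similarity only or to visual
#' similarity only (pool 2 not decoded), the selective-decoding model
#' (both-modality correlation rule, which cancels across pools when the two
#' coefficients are equal) decoded against vestibular or against visual
#' reference tuning, and a hybrid with vestibular-only correlations plus a
#' nonzero pool-2 weight. Reported per variant and condition: mean CP of
#' opposite (pool 2) and congruent (pool 1) cells.
#'
#' @param n_neurons,n_trials,amplitude simulation sizes.
#' @param a correlation slope for the hypothetical rules.
#' @param weight_pool2 pool-2 decoding weight in the selective and hybrid
#'   variants.
#' @param seed master seed.
#' @return a `cp_experiment` with a `summary` tibble and per-variant CP
#'   tables in `cp_tables`.
#' @export
run_multisensory_hypothetical <- function(n_neurons = 200, n_trials = 100,
                                          amplitude = 100, a = 0.1,
                                          weight_pool2 = 0.5, seed = 1) {
  cfg <- list(n_neurons = n_neurons, n_trials = n_trials,
              amplitude = amplitude, a = a, weight_pool2 = weight_pool2,
              seed = seed)
  pop <- make_cosine_population(n_neurons, amplitude,
                                conditions = c("vestibular", "visual"),
                                pool2_opposite = TRUE)
  variants <- list(
    pure_vestibular = list(mask = "vestibular_only", w2 = 0, ref = "vestibular"),
    pure_visual = list(mask = "visual_only", w2 = 0, ref = "vestibular"),
    selective_vestibular = list(mask = "all_pairs", w2 = weight_pool2,
                                ref = "vestibular"),
    selective_visual = list(mask = "all_pairs", w2 = weight_pool2,
                            ref = "visual"),
    hybrid = list(mask = "vestibular_only", w2 = weight_pool2,
                  ref = "vestibular")
  )
  seeds <- derive_seeds(seed, length(variants))
  cp_tables <- list()
  summary <- purrr::imap_dfr(variants, function(v, nm) {
    corr <- build_correlation_matrix(
      pop, correlation_spec(a_vestibular = a, a_visual = a, mask = v$mask))
    sd_i <- seeds[match(nm, names(variants))]
    trials <- simulate_trials(pop, corr, conditions = c("vestibular", "visual"),
                              n_trials = n_trials, seed = sd_i)
    rs <- readout_spec(reference = v$ref, weight_rule = "pool",
                       pool_weights = c(pool1 = 1, pool2 = v$w2))
    rec <- run_task(trials, pop, rs, seed = sd_i)
    cp <- choice_probability_table(trials, pop, rec)
    cp_tables[[nm]] <<- cp
    cp |>
      dplyr::left_join(pop$neurons[, c("neuron_id", "pool")], by = "neuron_id") |>
      dplyr::group_by(.data$condition, .data$pool) |>
      dplyr::summarise(mean_cp = mean(.data$cp, na.rm = TRUE), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "pool", values_from = "mean_cp") |>
      dplyr::transmute(variant = nm, condition = .data$condition,
                       congruent_mean_cp = .data$pool1,
                       opposite_mean_cp = .data$pool2)
  })
  experiment_result("multisensory_hypothetical", cfg,
                    summary = summary, cp_tables = cp_tables)
}

#' Model contrasts on an MSTd-like population
#'
#' Runs both readout models on one MSTd-like population across the
#' vestibular, visual and combined conditions. The selective-decoding model
#' uses the both-modality correlation rule (coefficients 0.12/0.09) and the
#' congruency-dependent Readout-Index weight profile; the pure-correlation
#' model uses vestibular-only correlations and decodes congruent-class
#' cells only. On the combined-condition CPs of opposite cells (congruency
#' index <= -0.5) it runs the multimodality test, the Ansari-Bradley
#' dispersion comparison between models, and the K-means separation index;
#' it also fits the CP-vs-neurometric-threshold correlation per model.
#'
#' @param n_neurons,n_trials simulation sizes; the conventional 200 trials
#'   per heading keep single-neuron CP noise small enough for the shape
#'   analyses.
#' @param ri Readout Index of the selective model.
#' @param a_vestibular,a_visual correlation-rule coefficients.
#' @param congruency_mix class mix of the generated population.
#' @param n_boot resamples for the modality test.
#' @param n_reps independent population replicates; CP tables are pooled
#'   across replicates before the distribution-shape battery (one desk-scale
#'   population yields ~60 opposite cells, which underpowers the
#'   multimodality test).
#' @param seed master seed.
#' @return a `cp_experiment` with `cp` (per-model CP tables, pooled),
#'   `combined_opposite` (the test battery) and `threshold_regressions`.
#' @export
run_mstd_constrained_models <- function(n_neurons = 200, n_trials = 200,
                                        ri = 0.5, a_vestibular = 0.12,
                                        a_visual = 0.09,
                                        congruency_mix = c(congruent = 0.40,
                                                           intermediate = 0.30,
                                                           opposite = 0.30),
                                        n_boot = 200, n_reps = 1, seed = 1) {
  cfg <- list(n_neurons = n_neurons, n_trials = n_trials, ri = ri,
              a_vestibular = a_vestibular, a_visual = a_visual,
              congruency_mix = congruency_mix, n_boot = n_boot,
              n_reps = n_reps, seed = seed)
  seeds <- derive_seeds(seed, 1 + 3 * n_reps)
  conds <- c("vestibular", "visual", "combined")
  rs_sel <- readout_spec(reference = "vestibular",
                         weight_rule = "ri_power", ri = ri)
  rs_pure <- readout_spec(reference = "vestibular", weight_rule = "pool",
                          pool_weights = c(pool1 = 1, pool2 = 0))

  reps <- purrr::map(seq_len(n_reps), function(r) {
    sd_pop <- seeds[1 + r]
    sd_sel <- seeds[1 + n_reps + r]
    sd_pure <- seeds[1 + 2 * n_reps + r]
    pop <- make_mstd_like_population(n_neurons, congruency_mix, seed = sd_pop)
    corr_sel <- build_correlation_matrix(
      pop, correlation_spec(a_vestibular, a_visual, mask = "all_pairs"))
    corr_pure <- build_correlation_matrix(
      pop, correlation_spec(a_vestibular, 0, mask = "vestibular_only"))
    trials_sel <- simulate_trials(pop, corr_sel, conds, n_trials, seed = sd_sel)
    trials_pure <- simulate_trials(pop, corr_pure, conds, n_trials,
                                   seed = sd_pure)
    rec_sel <- run_task(trials_sel, pop, rs_sel, conds, seed = sd_sel)
    rec_pure <- run_task(trials_pure, pop, rs_pure, conds, seed = sd_pure)
    cp <- dplyr::bind_rows(
      dplyr::mutate(choice_probability_table(trials_sel, pop, rec_sel),
                    model = "selective"),
      dplyr::mutate(choice_probability_table(trials_pure, pop, rec_pure),
                    model = "pure_correlation"))
    nt <- dplyr::bind_rows(
      dplyr::mutate(neurometric_table(trials_sel, pop, "combined"),
                    model = "selective"),
      dplyr::mutate(neurometric_table(trials_pure, pop, "combined"),
                    model = "pure_correlation"))
    list(pop = pop, cp = dplyr::mutate(cp, rep = r),
         nt = dplyr::mutate(nt, rep = r))
  })

  cp <- purrr::map_dfr(reps, "cp")
  nt <- purrr::map_dfr(reps, "nt")

  opp_of <- function(model) {
    dplyr::filter(cp, .data$model == !!model, .data$condition == "combined",
                  .data$congruency_index <= -0.5, !is.na(.data$cp))$cp
  }
  opp_sel <- opp_of("selective")
  opp_pure <- opp_of("pure_correlation")

  combined_opposite <- list(
    cp_pure = opp_pure,
    cp_selective = opp_sel,
    modality_pure = modality_test(opp_pure, n_boot, seed = seeds[1]),
    modality_selective = modality_test(opp_sel, n_boot, seed = seeds[1]),
    ansari_p = ansari_bradley(opp_pure, opp_sel),
    d_pure = kmeans_separation(opp_pure),
    d_selective = kmeans_separation(opp_sel),
    sd_pure = stats::sd(opp_pure),
    sd_selective = stats::sd(opp_sel)
  )

  reg_of <- function(model) {
    d <- cp |>
      dplyr::filter(.data$model == !!model, .data$condition == "combined",
                    !is.na(.data$cp)) |>
      dplyr::inner_join(dplyr::filter(nt, .data$model == !!model,
                                      .data$converged),
                        by = c("neuron_id", "condition", "model", "rep"))
    ct <- stats::cor.test(d$cp, d$sigma)
    tibble::tibble(r = unname(ct$estimate), ci_low = ct$conf.int[1],
                   ci_high = ct$conf.int[2], p = ct$p.value, n = nrow(d))
  }
  threshold_regressions <- dplyr::bind_rows(
    dplyr::mutate(reg_of("selective"), model = "selective"),
    dplyr::mutate(reg_of("pure_correlation"), model = "pure_correlation"))

  experiment_result("mstd_constrained_models", cfg,
                    pop = reps[[1]]$pop, cp = cp,
                    combined_opposite = combined_opposite,
                    threshold_regressions = threshold_regressions,
                    neurometric = nt)
}

#' Decoder threshold sweeps over Readout Index and population size
#'
#' On an MSTd-like population with the both-modality correlation structure,
#' decodes all three conditions with the congruency-dependent weight
#' profile over a grid of Readout-Index values and fits a psychometric
#' threshold per condition; the optimal cue-integration prediction is
#' computed from the two single-cue fits at each RI. A second sweep varies
#' population size at fixed RI.
#'
#' @param n_neurons population size for the RI sweep.
#' @param n_trials trials per heading.
#' @param ri_grid Readout-Index grid (0 to 1 in steps of 0.1 by default).
#' @param pop_sizes population sizes for the size sweep.
#' @param ri_for_sizes RI used in the size sweep.
#' @param n_reps_sizes independent replicates per population size in the
#'   size sweep (threshold estimates at desk scale are noisy enough that a
#'   single draw can mask the plateau).
#' @param a_vestibular,a_visual correlation-rule coefficients.
#' @param congruency_mix class mix of the generated populations.
#' @param seed master seed.
#' @return a `cp_experiment` with tibbles `ri_sweep` (ri, condition, sigma,
#'   optimal prediction) and `size_sweep`.
#' @export
run_threshold_sweeps <- function(n_neurons = 200, n_trials = 200,
                                 ri_grid = seq(0, 1, by = 0.1),
                                 pop_sizes = c(24, 50, 100, 200, 400),
                                 ri_for_sizes = 0.5, n_reps_sizes = 3,
                                 a_vestibular = 0.12, a_visual = 0.09,
                                 congruency_mix = c(congruent = 0.40,
                                                    intermediate = 0.30,
                                                    opposite = 0.30),
                                 seed = 1) {
  cfg <- list(n_neurons = n_neurons, n_trials = n_trials, ri_grid = ri_grid,
              pop_sizes = pop_sizes, ri_for_sizes = ri_for_sizes,
              n_reps_sizes = n_reps_sizes,
              a_vestibular = a_vestibular, a_visual = a_visual,
              congruency_mix = congruency_mix, seed = seed)
  seeds <- derive_seeds(seed, 2 + 2 * length(pop_sizes) * n_reps_sizes)
  conds <- c("vestibular", "visual", "combined")

  sweep_one <- function(pop, trials, ri, seed_dec) {
    rs <- readout_spec(reference = "vestibular",
                       weight_rule = "ri_power", ri = ri)
    rec <- run_task(trials, pop, rs, conds, seed = seed_dec)
    purrr::map_dfr(conds, function(k) {
      fit <- psychometric_threshold(rec, k)
      tibble::tibble(condition = k, sigma = fit$sigma, mu = fit$mu,
                     converged = fit$converged)
    })
  }

  pop <- make_mstd_like_population(n_neurons, congruency_mix, seed = seeds[1])
  corr <- build_correlation_matrix(
    pop, correlation_spec(a_vestibular, a_visual, mask = "all_pairs"))
  trials <- simulate_trials(pop, corr, conds, n_trials, seed = seeds[2])

  ri_sweep <- purrr::map_dfr(ri_grid, function(ri) {
    dplyr::mutate(sweep_one(pop, trials, ri, seeds[2]), ri = ri,
                  .before = 1)
  })
  ri_optimal <- ri_sweep |>
    tidyr::pivot_wider(id_cols = "ri", names_from = "condition",
                       values_from = "sigma") |>
    dplyr::mutate(optimal = optimal_combined_threshold(.data$vestibular,
                                                       .data$visual))

  size_grid <- tidyr::expand_grid(rep = seq_len(n_reps_sizes),
                                  n_set = pop_sizes)
  size_sweep <- purrr::map_dfr(seq_len(nrow(size_grid)), function(j) {
    nset <- size_grid$n_set[j]
    p <- make_mstd_like_population(nset, congruency_mix,
                                   seed = seeds[2 + j])
    co <- build_correlation_matrix(
      p, correlation_spec(a_vestibular, a_visual, mask = "all_pairs"))
    sd_tr <- seeds[2 + nrow(size_grid) + j]
    tr <- simulate_trials(p, co, conds, n_trials, seed = sd_tr)
    dplyr::mutate(sweep_one(p, tr, ri_for_sizes, sd_tr),
                  n_neurons = nset, rep = size_grid$rep[j], .before = 1)
  })

  experiment_result("threshold_sweeps", cfg, ri_sweep = ri_sweep,
                    ri_optimal = ri_optimal, size_sweep = size_sweep)
}
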