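test_that("RI weight profiles match their closed forms", {
  # verbatim printed formula
  expect_equal(cpdecode:::ri_weight_verbatim(2, 1), 1)
  expect_equal(cpdecode:::ri_weight_verbatim(0, 0.3), 0)
  expect_equal(cpdecode:::ri_weight_verbatim(0, 1), 0)
  expect_equal(cpdecode:::ri_weight_verbatim(-2, 1),
               (1 - exp(1)) / (1 - exp(-1)))
  expect_lt(cpdecode:::ri_weight_verbatim(-2, 1), -2.7)  # negative weights

  cgrid <- seq(-1, 1, by = 0.1)
  for (fn in list(cpdecode:::ri_weight_additive, cpdecode:::ri_weight_power)) {
    expect_equal(fn(cgrid, 1), rep(1, length(cgrid)))    # all equal at RI = 1
    expect_true(all(diff(fn(cgrid, 0.4)) >= 0))          # monotone in c
    expect_true(all(fn(cgrid, 0.3) >= 0 & fn(cgrid, 0.3) <= 1))
    expect_lte(fn(-1, 0.05), 0.05)                       # opposite -> 0
  }
  expect_error(readout_spec(ri = 1.5), "\\[0, 1\\]")
})

test_that("log-likelihood matches the hand-computed two-heading case", {
  grid <- c(-1, 0, 1)
  pop <- pop_from_curves(list(vestibular = matrix(c(10, 15, 20), 1)), grid)
  spec <- readout_spec(reference = "condition_matched", weight_rule = "uniform")
  prof <- log_likelihood(15, pop, 1, spec, "vestibular")
  d <- prof$log_values[1] - prof$log_values[3]
  expect_equal(d, 15 * log(10 / 20) - (10 - 20), tolerance = 1e-12)
  expect_equal(d, -0.39720, tolerance = 1e-4)
  expect_gt(prof$log_values[3], prof$log_values[1])  # theta = +1 favored

  # zero weights leave only the response-independent bias term
  prof0 <- log_likelihood(15, pop, 0, spec, "vestibular")
  expect_equal(prof0$log_values, -c(10, 15, 20))

  # flat reference tuning gives a flat profile
  popf <- pop_from_curves(list(vestibular = rbind(c(10, 15, 20),
                                                  c(12, 12, 12))), grid)
  proff <- log_likelihood(c(0, 7), popf, c(0, 1), spec, "vestibular")
  expect_equal(diff(proff$log_values + c(22, 27, 32)), c(0, 0))
  expect_error(log_likelihood(1:3, pop, 1, spec, "vestibular"), "length")
})

test_that("decisions follow likelihood mass and flag exact ties", {
  prof <- structure(list(angles = c(-8, -4, 0, 4, 8),
                         log_values = c(0, -50, -50, -50, -50)),
                    class = "likelihood_profile")
  set.seed(1)
  expect_equal(decide(prof)$choice, "left")
  sym <- structure(list(angles = c(-8, -4, 0, 4, 8),
                        log_values = c(-1, -2, 0, -2, -1)),
                   class = "likelihood_profile")
  set.seed(1)
  out <- decide(sym)
  expect_true(out$tie)
  expect_true(out$choice %in% c("left", "right"))
  degen <- structure(list(angles = c(-1, 0, 1),
                          log_values = rep(-Inf, 3)),
                     class = "likelihood_profile")
  expect_error(decide(degen), "degenerate")
})

test_that("the decoder agrees with a brute-force likelihood enumeration", {
  grid <- c(-2, 0, 2)
  f <- rbind(c(12, 20, 30), c(25, 18, 8))
  pop <- pop_from_curves(list(vestibular = f), grid)
  spec <- readout_spec(reference = "condition_matched",
                       weight_rule = "uniform", rate_floor = 0.1)
  w <- c(1, 1)
  set.seed(3)
  for (i in 1:25) {
    r <- stats::runif(2, 0, 40)
    prof <- log_likelihood(r, pop, w, spec, "vestibular")
    # independent explicit computation
    ll <- vapply(seq_along(grid), function(h)
      sum(w * r * log(pmax(f[, h], 0.1))) - sum(f[, h]), numeric(1))
    expect_equal(prof$log_values, ll, tolerance = 1e-12)
    lik <- exp(ll - max(ll))
    expected <- if (lik[3] > lik[1]) "right" else if (lik[1] > lik[3]) "left" else NA
    if (!is.na(expected)) expect_equal(decide(prof)$choice, expected)
  }
})

test_that("run_task produces one seeded record per trial", {
  pop <- make_cosine_population(8, conditions = "vestibular")
  cm <- build_correlation_matrix(pop, correlation_spec(0.1, 0))
  tr <- simulate_trials(pop, cm, "vestibular", n_trials = 20, seed = 2)
  spec <- readout_spec(reference = "condition_matched", weight_rule = "uniform")
  rec <- run_task(tr, pop, spec, seed = 4)
  expect_equal(nrow(rec), 20 * length(pop$grid))
  expect_identical(rec, run_task(tr, pop, spec, seed = 4))
  # high-sensitivity population called correctly at the largest heading
  expect_gt(mean(rec$choice[rec$heading_deg == 8] == "right"), 0.95)
  expect_gt(mean(rec$choice[rec$heading_deg == -8] == "left"), 0.95)
})

test_that("zero decoding weights yield chance performance through tie coins", {
  pop <- make_cosine_population(8, conditions = "vestibular")
  cm <- build_correlation_matrix(pop, correlation_spec(0.1, 0))
  tr <- simulate_trials(pop, cm, "vestibular", n_trials = 60, seed = 2)
  spec <- readout_spec(reference = "condition_matched", weight_rule = "pool",
                       pool_weights = c(pool1 = 0, pool2 = 0))
  rec <- run_task(tr, pop, spec, seed = 4)
  expect_true(all(rec$tie))
  expect_lt(abs(mean(rec$choice == "right") - 0.5), 3 / sqrt(nrow(rec)) / 2 + 0.02)
})

test_that("anti-preferred polarity on every neuron mirrors the choices", {
  pop <- make_cosine_population(8, conditions = "vestibular")
  cm <- build_correlation_matrix(pop, correlation_spec(0.1, 0,
                                                       mask = "within_pool_only"))
  tr <- simulate_trials(pop, cm, "vestibular", n_trials = 40, seed = 6)
  sp_pref <- readout_spec(reference = "condition_matched", weight_rule = "uniform")
  sp_anti <- readout_spec(reference = "condition_matched", weight_rule = "uniform",
                          polarity = c(pool1 = "anti_preferred",
                                       pool2 = "anti_preferred"))
  r1 <- run_task(tr, pop, sp_pref, seed = 1)
  r2 <- run_task(tr, pop, sp_anti, seed = 1)
  keep <- !r1$tie & !r2$tie
  expect_true(all(r1$choice[keep] != r2$choice[keep]))
})

test_that("rescaling all weights preserves decisions on a mirror pair", {
  grid <- c(-2, -1, 0, 1, 2)
  up <- c(10, 14, 18, 22, 26)
  pop <- pop_from_curves(list(vestibular = rbind(up, rev(up))), grid)
  spec1 <- readout_spec(reference = "condition_matched", weight_rule = "uniform")
  set.seed(8)
  for (i in 1:20) {
    r <- stats::runif(2, 5, 30)
    p1 <- log_likelihood(r, pop, c(1, 1), spec1, "vestibular")
    p2 <- log_likelihood(r, pop, c(3, 3), spec1, "vestibular")
    set.seed(1); c1 <- decide(p1)
    set.seed(1); c2 <- decide(p2)
    if (!c1$tie && !c2$tie) expect_equal(c1$choice, c2$choice)
  }
})

test_that("proportion correct grows with heading under matched decoding", {
  pop <- make_cosine_population(16, conditions = "vestibular")
  cm <- build_correlation_matrix(pop, correlation_spec(0, 0))
  tr <- simulate_trials(pop, cm, "vestibular", n_trials = 80, seed = 3)
  spec <- readout_spec(reference = "condition_matched", weight_rule = "uniform")
  rec <- run_task(tr, pop, spec, seed = 5)
  pc <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(rec, heading_deg != 0), ah = abs(heading_deg)),
    correct = mean((choice == "right") == (heading_deg > 0)))
  expect_gt(stats::cor(pc$ah, pc$correct, method = "spearman"), 0.5)
  expect_gt(pc$correct[pc$ah == 8], pc$correct[pc$ah == 0.1])
})
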