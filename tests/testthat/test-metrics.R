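test_that("ROC area matches brute-force pair counting", {
  expect_equal(roc_area(c(3, 4), c(1, 2)), 1)
  expect_equal(roc_area(1, 1), 0.5)
  expect_equal(roc_area(c(2, 4), c(3, 5)), 0.25)
  set.seed(11)
  for (i in 1:30) {
    a <- sample(0:20, sample(2:12, 1), replace = TRUE)
    b <- sample(0:20, sample(2:12, 1), replace = TRUE)
    expect_equal(roc_area(a, b), roc_brute(a, b))
    expect_equal(roc_area(a, b) + roc_area(b, a), 1)
    # invariant under strictly increasing transforms
    expect_equal(roc_area(exp(a / 5), exp(b / 5)), roc_area(a, b))
  }
  expect_error(roc_area(numeric(0), 1), "nonempty")
})

test_that("choice probability splits trials by preferred-direction choices", {
  resp <- c(10, 12, 9, 8, 30, 31, 29, 33, 28, 11)
  ch <- rep(c("left", "right"), each = 5)
  out <- choice_probability(resp, ch, pref_sign = 1)
  expect_equal(out$cp, roc_brute(resp[6:10], resp[1:5]))
  flip <- choice_probability(resp, ch, pref_sign = -1)
  expect_equal(flip$cp, 1 - out$cp)   # ROC symmetry under preference flip
  # perfectly ordered responses
  perfect <- choice_probability(c(1, 2, 3, 11, 12, 13),
                                c("left", "left", "left", "right", "right", "right"),
                                1, min_trials = 3)
  expect_equal(perfect$cp, 1)
  # group smaller than min_trials is undefined
  und <- choice_probability(resp, c(rep("left", 9), "right"), 1)
  expect_true(is.na(und$cp))
  # choice-independent responses stay near 0.5 across seeded replicates
  set.seed(21)
  cps <- replicate(200, {
    r <- rnorm(60)
    ch <- sample(c("left", "right"), 60, replace = TRUE, prob = c(0.5, 0.5))
    choice_probability(r, ch, 1)$cp
  })
  expect_lt(abs(mean(cps, na.rm = TRUE) - 0.5), 0.02)
})

test_that("neurometric threshold recovers the generative sigma", {
  grid <- heading_grid("mstd")
  pos <- grid[grid > 0]
  n_tr <- 200
  arr <- array(NA_real_, c(1, length(grid), n_tr),
               dimnames = list("1", grid, NULL))
  set.seed(5)
  for (h in seq_along(grid)) arr[1, h, ] <- rnorm(n_tr, grid[h] / 2, 1)
  tr <- structure(list(responses = list(vestibular = arr), grid = grid,
                       n_trials = n_tr, conditions = "vestibular",
                       seed = 1L), class = "trial_set")
  fit <- neurometric_threshold(tr, 1, "vestibular")
  # ROC(+t vs -t) = Phi(t / sqrt(2)) so sigma = sqrt(2)
  expect_true(fit$converged)
  expect_lt(abs(fit$sigma - sqrt(2)) / sqrt(2), 0.15)

  # doubling response noise doubles the threshold
  arr2 <- arr
  set.seed(5)
  for (h in seq_along(grid)) arr2[1, h, ] <- rnorm(n_tr, grid[h] / 2, 2)
  tr2 <- tr; tr2$responses$vestibular <- arr2
  fit2 <- neurometric_threshold(tr2, 1, "vestibular")
  expect_lt(abs(fit2$sigma / fit$sigma - 2), 0.4)

  # heading-independent responses: threshold beyond the grid, flagged
  arr3 <- arr
  set.seed(6)
  for (h in seq_along(grid)) arr3[1, h, ] <- rnorm(n_tr, 5, 1)
  tr3 <- tr; tr3$responses$vestibular <- arr3
  fit3 <- neurometric_threshold(tr3, 1, "vestibular", pref_sign = 1)
  expect_false(fit3$converged)
  expect_gt(fit3$sigma, max(grid))
})

test_that("psychometric threshold recovers the generative parameters", {
  grid <- heading_grid("mstd")
  set.seed(7)
  mk <- function(p_fun) {
    purrr::map_dfr(grid, function(h) {
      ch <- stats::rbinom(200, 1, p_fun(h))
      tibble::tibble(condition = "vestibular", heading_deg = h,
                     trial = 1:200,
                     choice = ifelse(ch == 1, "right", "left"), tie = FALSE)
    })
  }
  rec <- mk(function(h) pnorm(h / 2))
  fit <- psychometric_threshold(rec)
  expect_true(fit$converged)
  expect_lt(abs(fit$sigma - 2), 0.2)
  expect_lt(abs(fit$mu), 0.3)

  # mirror-flipping the choices negates mu, keeps sigma
  rec2 <- mk(function(h) pnorm((h - 0.5) / 2))
  f2 <- psychometric_threshold(rec2)
  rec2m <- rec2
  rec2m$heading_deg <- -rec2m$heading_deg
  rec2m$choice <- ifelse(rec2m$choice == "right", "left", "right")
  f2m <- psychometric_threshold(rec2m)
  expect_equal(f2m$sigma, f2$sigma, tolerance = 1e-6)
  expect_equal(f2m$mu, -f2$mu, tolerance = 1e-6)

  # uninformative choices: sigma above the grid span, flagged
  rec3 <- mk(function(h) 0.5)
  f3 <- psychometric_threshold(rec3)
  expect_false(f3$converged)
  expect_gt(f3$sigma, max(grid))

  # broom-style accessors
  expect_named(glance(fit), c("mu", "sigma", "converged", "n_points", "scope"))
  expect_equal(tidy(fit)$estimate[2], fit$sigma)
})

test_that("optimal cue integration follows the closed form", {
  expect_equal(optimal_combined_threshold(3, 3), 3 / sqrt(2))
  expect_lt(abs(optimal_combined_threshold(2.16, 1.24) - 1.07), 0.01)
  expect_equal(optimal_combined_threshold(2, 1e9), 2, tolerance = 1e-12)
  # bounded by the better cue and symmetric
  expect_lte(optimal_combined_threshold(2.3, 1.1), 1.1)
  expect_equal(optimal_combined_threshold(2.3, 1.1),
               optimal_combined_threshold(1.1, 2.3))
  expect_error(optimal_combined_threshold(-1, 2), "> 0")
})

test_that("a zero-weight uncorrelated neuron has chance-level CP", {
  pop <- make_cosine_population(10, conditions = "vestibular",
                                pool_split = 0.8)
  # pool 2 (2 neurons) uncorrelated with decoded pool 1 and unweighted
  cm <- build_correlation_matrix(
    pop, correlation_spec(0.1, 0, mask = "within_pool_only"))
  tr <- simulate_trials(pop, cm, "vestibular", n_trials = 500, seed = 12)
  spec <- readout_spec(reference = "condition_matched", weight_rule = "pool",
                       pool_weights = c(pool1 = 1, pool2 = 0))
  rec <- run_task(tr, pop, spec, seed = 12)
  cp <- choice_probability_table(tr, pop, rec)
  p2 <- cp$cp[pop$neurons$pool == "pool2"]
  expect_lt(max(abs(p2 - 0.5)), 3 / sqrt(250) + 0.03)
})
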