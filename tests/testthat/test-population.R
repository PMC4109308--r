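test_that("heading grids are symmetric, ordered and contain zero", {
  for (p in c("hypothetical", "mstd")) {
    g <- heading_grid(p)
    expect_silent(validate_heading_grid(g))
    expect_true(0 %in% g)
    expect_setequal(g, -g)
  }
  expect_error(validate_heading_grid(c(-1, 0, 2)), "symmetric")
  expect_error(validate_heading_grid(c(-1, 1)), "contain 0")
  expect_error(validate_heading_grid(c(1, 0, -1)), "increasing")
})

test_that("cosine tuning hits the stated peak, null and quadrature rates", {
  g <- c(-180, -90, 0, 90, 180)
  pop <- make_cosine_population(4, amplitude = 100, conditions = "vestibular",
                                grid = g)
  m <- tuning_matrix(pop, "vestibular")
  right <- m[pop$neurons$pref_sign_vestibular == 1, , drop = FALSE]
  expect_equal(unname(right[, g == 90]), rep(200, nrow(right)))
  expect_equal(unname(right[, g == -90]), rep(0, nrow(right)))
  expect_equal(unname(right[, g == 0]), rep(100, nrow(right)))
  # per-neuron extrema over the full heading circle
  expect_true(all(abs(apply(m, 1, max) - 200) < 1e-12))
  expect_true(all(abs(apply(m, 1, min)) < 1e-12))
  expect_error(make_cosine_population(4, amplitude = -1), "amplitude")
  expect_error(make_cosine_population(4, grid = c(-1, 0, 2)), "symmetric")
})

test_that("opposite-pool cosine populations have congruency -1 in pool 2", {
  pop <- make_cosine_population(8, conditions = c("vestibular", "visual"),
                                pool2_opposite = TRUE)
  ci <- congruency_index(pop)
  p2 <- pop$neurons$pool == "pool2"
  expect_true(all(ci$congruency_index[p2] < -0.9))
  expect_true(all(ci$congruency_index[!p2] > 0.9))
})

test_that("linear interpolation is exact at nodes, midpoints and round trips", {
  tc <- tibble::tibble(heading_deg = c(0, 1), mean_rate_hz = c(10, 20))
  expect_equal(interpolate_tuning(tc, 0.5)$mean_rate_hz, 15)
  expect_equal(interpolate_tuning(tc, c(0, 1))$mean_rate_hz, c(10, 20))
  expect_error(interpolate_tuning(tc, 2), "extrapolation")
  # piecewise-linear curve resampled to a finer grid and back is unchanged
  src <- tibble::tibble(heading_deg = -2:2,
                        mean_rate_hz = c(3, 7, 4, 9, 1))
  fine <- interpolate_tuning(src, seq(-2, 2, by = 0.1))
  back <- interpolate_tuning(fine, -2:2)
  expect_equal(back$mean_rate_hz, src$mean_rate_hz, tolerance = 1e-12)
})

test_that("congruency index is the product of per-condition Pearson correlations", {
  grid <- c(-1, 0, 1)
  pop <- pop_from_curves(list(
    vestibular = matrix(c(1, 2, 3), 1),
    visual = matrix(c(3, 1, 2), 1)), grid)
  ci <- congruency_index(pop)
  r1 <- stats::cor(c(1, 2, 3), grid)
  r2 <- stats::cor(c(3, 1, 2), grid)
  expect_equal(ci$congruency_index, r1 * r2)
  expect_equal(ci$congruency_index, 1 * -0.5)

  # identical increasing curves -> +1; mirrored visual -> -1
  up <- matrix(c(1, 2, 3), 1)
  expect_equal(congruency_index(pop_from_curves(
    list(vestibular = up, visual = up), grid))$congruency_index, 1)
  expect_equal(congruency_index(pop_from_curves(
    list(vestibular = up, visual = up[, 3:1, drop = FALSE]),
    grid))$congruency_index, -1)

  flat <- matrix(c(2, 2, 2), 1)
  expect_error(congruency_index(pop_from_curves(
    list(vestibular = flat, visual = up), grid)), "flat")
})

test_that("congruency index flips sign with exactly one mirrored condition", {
  grid <- heading_grid("mstd")
  set.seed(4)
  v <- 30 + 0.8 * grid + 0.3 * sin(grid)
  w <- 25 + 0.5 * grid + 0.2 * cos(grid * 0.4)
  ci <- function(a, b) congruency_index(pop_from_curves(
    list(vestibular = matrix(a, 1), visual = matrix(b, 1)),
    grid))$congruency_index
  base <- ci(v, w)
  expect_equal(ci(rev(v), rev(w)), base, tolerance = 1e-12)   # both flipped
  expect_equal(ci(rev(v), w), -base, tolerance = 1e-12)       # one flipped
})

test_that("pair congruency classification follows the 0.2 product rule", {
  expect_equal(classify_pair_congruency(0.8, 0.9), "matched")
  expect_equal(classify_pair_congruency(0.8, -0.9), "mismatched")
  expect_equal(classify_pair_congruency(0.4, 0.4), "undefined")
  expect_equal(classify_pair_congruency(c(1, -1, 0.1), c(1, 1, 0.1)),
               c("matched", "mismatched", "undefined"))
  expect_error(classify_pair_congruency(1.2, 0.5), "\\[-1, 1\\]")
})

test_that("MSTd-like generation is seeded, class-faithful and nonnegative", {
  pop1 <- make_mstd_like_population(60, seed = 7)
  pop2 <- make_mstd_like_population(60, seed = 7)
  expect_identical(pop1$tuning, pop2$tuning)
  pop3 <- make_mstd_like_population(60, seed = 8)
  expect_false(identical(pop3$tuning, pop1$tuning))
  expect_true(all(pop1$tuning$mean_rate_hz >= 0))
  expect_true(min(pop1$neurons$congruency_index) < -0.5)
  expect_true(max(pop1$neurons$congruency_index) > 0.5)

  all_cong <- make_mstd_like_population(
    40, c(congruent = 1, intermediate = 0, opposite = 0), seed = 1)
  expect_true(all(all_cong$neurons$congruency_index > 0))
  all_opp <- make_mstd_like_population(
    40, c(congruent = 0, intermediate = 0, opposite = 1), seed = 1)
  expect_true(all(all_opp$neurons$congruency_index < 0))
  expect_error(make_mstd_like_population(40, c(congruent = -0.5,
                                               intermediate = 0.5,
                                               opposite = 1)), "nonnegative")
})

test_that("congruency distributions agree across seeds within sampling error", {
  h <- function(seed) {
    ci <- make_mstd_like_population(200, seed = seed)$neurons$congruency_index
    table(cut(ci, breaks = c(-1, -0.5, 0, 0.5, 1), include.lowest = TRUE))
  }
  h1 <- h(1)
  h2 <- h(2)
  expect_gt(suppressWarnings(stats::chisq.test(rbind(h1, h2)))$p.value, 0.001)
})

test_that("congruent-cell neurometric thresholds match the calibration targets", {
  pop <- make_mstd_like_population(200, seed = 3)
  corr <- build_correlation_matrix(pop, correlation_spec())
  tr <- simulate_trials(pop, corr, c("vestibular", "visual"), 200, seed = 4)
  nt <- neurometric_table(tr, pop, c("vestibular", "visual"))
  cong <- pop$neurons$neuron_id[pop$neurons$class == "congruent"]
  nt <- nt[nt$neuron_id %in% cong & nt$converged, ]
  gm <- dplyr::summarise(dplyr::group_by(nt, condition),
                         gm = exp(mean(log(sigma))))
  gm_vest <- gm$gm[gm$condition == "vestibular"]
  gm_vis <- gm$gm[gm$condition == "visual"]
  expect_lt(gm_vis, gm_vest)      # visual more sensitive, as calibrated
  expect_gt(gm_vest, 7.1 * 0.6)
  expect_lt(gm_vest, 7.1 * 1.4)
  expect_gt(gm_vis, 5.5 * 0.6)
  expect_lt(gm_vis, 5.5 * 1.4)
})
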