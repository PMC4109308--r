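# independent brute-force oracles used across the suite

# ROC area by explicit pairwise comparison
roc_brute <- function(pref, null) {
  cmp <- outer(pref, null, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# optimal two-cluster split of scalar data by exhaustive search over sorted
# split points; returns centroid distance of the best split
kmeans_brute <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best <- Inf
  d <- 0
  for (k in 1:(n - 1)) {
    a <- xs[1:k]
    b <- xs[(k + 1):n]
    ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (ss < best) {
      best <- ss
      d <- abs(mean(a) - mean(b))
    }
  }
  d
}

# exact Ansari-Bradley permutation p-value by enumeration of group
# assignments (small n, no ties)
ansari_brute <- function(x, y) {
  m <- length(x)
  ab_score <- function(v) {
    n <- length(v)
    r <- rank(v)
    pmin(r, n + 1 - r)
  }
  pooled <- c(x, y)
  sc <- ab_score(pooled)
  t_obs <- sum(sc[seq_len(m)])
  idx <- utils::combn(length(pooled), m)
  t_all <- apply(idx, 2, function(i) sum(sc[i]))
  # two-sided by tail doubling, the convention of the exact distribution
  p_lo <- mean(t_all <= t_obs + 1e-12)
  p_hi <- mean(t_all >= t_obs - 1e-12)
  min(1, 2 * min(p_lo, p_hi))
}

# build a small population directly from curves (list: condition -> matrix
# neurons x headings)
pop_from_curves <- function(curves, grid) {
  tuning <- purrr::map_dfr(names(curves), function(k) {
    m <- curves[[k]]
    tibble::tibble(
      neuron_id = rep(seq_len(nrow(m)), each = ncol(m)),
      condition = k,
      heading_deg = rep(grid, times = nrow(m)),
      mean_rate_hz = as.vector(t(m))
    )
  })
  pop <- cpdecode:::new_population(
    tuning, tibble::tibble(neuron_id = seq_len(nrow(curves[[1]]))),
    grid, names(curves), "test")
  pop$neurons <- cpdecode:::annotate_neurons(pop)
  pop
}
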