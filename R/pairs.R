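#' Generate synthetic neuron-pair correlation records
#'
#' Stand-in for a sample of simultaneously recorded multisensory neuron
#' pairs (synthetic; no recorded data enter the package). Each member of a
#' pair draws a congruency class and per-modality rate-heading correlations
#' `c_vestibular`, `c_visual` (same-sign for congruent cells, opposite-sign
#' for opposite cells, one weak modality for intermediates). For locally
#' monotone tuning, the signal correlation between two neurons in modality k
#' is approximately the product of their rate-heading correlations, so
#' `r_signal_k = c_a,k * c_b,k` plus measurement noise. Noise correlations
#' then follow the linear tuning-similarity rule
#' `r_noise = a_vestibular * r_sv + a_visual * r_si` plus observation noise.
#' The congruent-heavy default class mix makes the two signal correlations
#' weakly positively dependent (Spearman rho near 0.29), and pairs are
#' classified matched/mismatched/undefined by the product-of-congruency
#' rule.
#'
#' @param n_pairs number of pairs (>= 10); 127 emulates the reference
#'   sample size.
#' @param coeffs named coefficients `a_vestibular`, `a_visual` of the
#'   noise-correlation rule.
#' @param noise_sd SD of the observation noise added to r_noise (>= 0).
#' @param sig_noise_sd SD of the measurement noise on each signal
#'   correlation.
#' @param congruency_mix class fractions for the drawn neurons.
#' @param seed integer seed.
#' @return tibble: `pair_id`, `r_signal_vest`, `r_signal_vis`, `r_noise`,
#'   `ci_a`, `ci_b`, `congruency_class`.
#' @export
generate_synthetic_pairs <- function(n_pairs = 127,
                                     coeffs = c(a_vestibular = 0.12,
                                                a_visual = 0.09),
                                     noise_sd = 0.1,
                                     sig_noise_sd = 0.08,
                                     congruency_mix = c(congruent = 0.70,
                                                        intermediate = 0.12,
                                                        opposite = 0.18),
                                     seed = 1) {
  abort_if(n_pairs < 10, "need at least 10 pairs")
  abort_if(noise_sd < 0, "noise_sd must be >= 0")
  abort_if(any(congruency_mix < 0) || abs(sum(congruency_mix) - 1) > 1e-8,
           "congruency_mix must be nonnegative and sum to 1")
  set.seed(as.integer(seed))

  draw_neuron <- function() {
    cls <- sample(names(congruency_mix), 1, prob = congruency_mix)
    d <- sample(c(-1, 1), 1)
    c_vest <- d * stats::runif(1, 0.6, 0.98)
    c_vis <- switch(cls,
      congruent = d * stats::runif(1, 0.6, 0.98),
      opposite = -d * stats::runif(1, 0.6, 0.98),
      intermediate = sample(c(-1, 1), 1) * stats::runif(1, 0.02, 0.45))
    c(c_vest, c_vis)
  }

  out <- purrr::map_dfr(seq_len(n_pairs), function(pid) {
    a <- draw_neuron()
    b <- draw_neuron()
    r_sv <- clip(a[1] * b[1] + stats::rnorm(1, 0, sig_noise_sd), -1, 1)
    r_si <- clip(a[2] * b[2] + stats::rnorm(1, 0, sig_noise_sd), -1, 1)
    tibble::tibble(
      pair_id = pid,
      r_signal_vest = r_sv,
      r_signal_vis = r_si,
      ci_a = a[1] * a[2],
      ci_b = b[1] * b[2]
    )
  })
  out$r_noise <- clip(coeffs[["a_vestibular"]] * out$r_signal_vest +
                        coeffs[["a_visual"]] * out$r_signal_vis +
                        stats::rnorm(n_pairs, 0, noise_sd), -1, 1)
  out$congruency_class <- classify_pair_congruency(out$ci_a, out$ci_b)
  out[, c("pair_id", "r_signal_vest", "r_signal_vis", "r_noise",
          "ci_a", "ci_b", "congruency_class")]
}
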