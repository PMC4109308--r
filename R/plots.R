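#' Plot choice probability against congruency index
#'
#' Scatter of per-neuron CPs versus congruency index, faceted by condition
#' (and model when present), with the chance line at 0.5.
#'
#' @param cp_tbl CP table from [choice_probability_table()].
#' @return a ggplot object.
#' @export
plot_cp_by_congruency <- function(cp_tbl) {
  p <- ggplot2::ggplot(dplyr::filter(cp_tbl, !is.na(.data$cp)),
                       ggplot2::aes(x = .data$congruency_index, y = .data$cp,
                                    colour = .data$class)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = "Congruency index", y = "Choice probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if ("model" %in% names(cp_tbl)) {
    p + ggplot2::facet_grid(model ~ condition)
  } else {
    p + ggplot2::facet_wrap(~condition)
  }
}

#' Plot the congruency-dependent readout weight profiles
#'
#' @param ri_values Readout-Index values to draw.
#' @param rule `"ri_reconstructed"` (default) or `"ri_verbatim"`.
#' @return a ggplot object.
#' @export
plot_weight_profiles <- function(ri_values = seq(0, 1, by = 0.2),
                                 rule = c("ri_reconstructed", "ri_verbatim")) {
  rule <- match.arg(rule)
  fn <- if (rule == "ri_reconstructed") ri_weight_reconstructed else ri_weight_verbatim
  grid <- tidyr::expand_grid(congruency = seq(-1, 1, by = 0.02),
                             ri = ri_values)
  grid$weight <- fn(grid$congruency, grid$ri)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$congruency, y = .data$weight,
                                     colour = factor(.data$ri),
                                     group = .data$ri)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Congruency index", y = "Decoding weight",
                  colour = "RI") +
    ggplot2::theme_minimal()
}

#' Plot psychometric thresholds across a Readout-Index sweep
#'
#' @param x a `cp_experiment` from [run_threshold_sweeps()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cp_experiment <- function(x, ...) {
  if (!is.null(x$ri_sweep)) {
    d <- x$ri_sweep
    opt <- dplyr::transmute(x$ri_optimal, ri = .data$ri,
                            condition = "optimal prediction",
                            sigma = .data$optimal)
    ggplot2::ggplot(dplyr::bind_rows(d[, c("ri", "condition", "sigma")], opt),
                    ggplot2::aes(x = .data$ri, y = .data$sigma,
                                 colour = .data$condition)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "Readout Index", y = "Threshold (deg)",
                    colour = NULL) +
      ggplot2::theme_minimal()
  } else if (!is.null(x$cp)) {
    plot_cp_by_congruency(x$cp)
  } else if (!is.null(x$summary)) {
    ggplot2::ggplot(x$summary,
                    ggplot2::aes(x = .data$condition, y = .data$opposite_mean_cp,
                                 fill = .data$variant)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
      ggplot2::labs(y = "Mean CP, opposite cells") +
      ggplot2::theme_minimal()
  } else {
    rlang::abort("no autoplot method for this experiment result")
  }
}
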