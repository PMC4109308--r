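#' Write and read tuning tables
#'
#' Tuning tables are persisted as plain CSV with columns `neuron_id`,
#' `condition`, `heading_deg`, `mean_rate_hz`; population metadata (seed,
#' provenance) goes to a JSON sidecar. The round trip is lossless to at
#' least 6 significant digits.
#'
#' @param pop a `neural_population`.
#' @param path CSV path; metadata is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_tuning_csv <- function(pop, path) {
  readr::write_csv(pop$tuning, path)
  meta <- list(provenance = pop$provenance, seed = pop$seed,
               conditions = pop$conditions, grid = pop$grid)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_tuning_csv
#' @return `read_tuning_csv()` reconstructs a `neural_population` from the
#'   CSV (and JSON sidecar when present).
#' @export
read_tuning_csv <- function(path) {
  tuning <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              neuron_id = readr::col_integer(),
                              condition = readr::col_character(),
                              heading_deg = readr::col_double(),
                              mean_rate_hz = readr::col_double()))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path,
                                                          simplifyVector = TRUE)
          else list(provenance = "file", seed = NA_integer_)
  grid <- sort(unique(tuning$heading_deg))
  validate_heading_grid(grid)
  pop <- new_population(tuning,
                        tibble::tibble(neuron_id = sort(unique(tuning$neuron_id))),
                        grid, unique(tuning$condition),
                        meta$provenance %||% "file", meta$seed %||% NA_integer_)
  pop$neurons <- annotate_neurons(pop)
  if ("class" %in% names(pop$neurons))
    pop$neurons$pool <- ifelse(pop$neurons$class == "congruent", "pool1", "pool2")
  pop
}

#' Write and read pair-statistics tables
#'
#' CSV with columns `pair_id`, `r_signal_vest`, `r_signal_vis`, `r_noise`,
#' `congruency_class` (plus per-neuron congruency indices when present).
#'
#' @param pairs tibble from [generate_synthetic_pairs()].
#' @param path CSV path.
#' @return `path` invisibly; `read_pair_stats_csv()` returns the tibble.
#' @export
write_pair_stats_csv <- function(pairs, path) {
  readr::write_csv(pairs, path)
  invisible(path)
}

#' @rdname write_pair_stats_csv
#' @export
read_pair_stats_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write and read decoded choice records
#'
#' CSV with columns `condition`, `heading_deg`, `trial`, `choice`, `tie`.
#'
#' @param records tibble from [run_task()].
#' @param path CSV path.
#' @return `path` invisibly; the reader returns the tibble.
#' @export
write_choice_records_csv <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_choice_records_csv
#' @export
read_choice_records_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    condition = readr::col_character(),
                    heading_deg = readr::col_double(),
                    trial = readr::col_integer(),
                    choice = readr::col_character(),
                    tie = readr::col_logical()))
}
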