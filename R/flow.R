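# Flow-cytometry quantification: gated event counts to cells per gram.

#' Convert gated flow-cytometry events to cells per gram
#'
#' Each replicate's gated event count is divided by the analyzed volume
#' and scaled back through the dilution chain:
#' `events / analyzed_volume * dilution_factor * suspension_ml_per_g * 1000`.
#' The three gates map onto the method labels `Flow.live`, `Flow.dead` and
#' `Flow.total`; because the total gate is the sum of the live and dead
#' gates, the converted concentrations are additive replicate by
#' replicate.
#'
#' @param data A tibble of flow records with columns `batch_id`,
#'   `replicate`, `live_events`, `dead_events`, `total_events`,
#'   `analyzed_volume` (uL), `dilution_factor`.
#' @param gates Which gates to convert (subset of `live`, `dead`,
#'   `total`).
#' @param suspension_ml_per_g Rehydration volume per gram of powder (mL).
#'
#' @return A long tibble: `batch_id`, `replicate`, `method`
#'   (`Flow.live` / `Flow.dead` / `Flow.total`), `count_per_g`.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   batch_id = "B01", replicate = 1, live_events = 900, dead_events = 100,
#'   total_events = 1000, analyzed_volume = 1, dilution_factor = 1e3
#' )
#' flow_cells_per_g(rec)
flow_cells_per_g <- function(data,
                             gates = c("live", "dead", "total"),
                             suspension_ml_per_g = 10) {
  needed <- c("batch_id", "replicate", "live_events", "dead_events",
              "total_events", "analyzed_volume", "dilution_factor")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Flow records lack column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(data$analyzed_volume <= 0)) {
    abort("`analyzed_volume` must be positive.")
  }
  gates <- match.arg(gates, several.ok = TRUE)
  scale <- data$dilution_factor * suspension_ml_per_g * 1000 /
    data$analyzed_volume
  purrr::map_dfr(gates, function(g) {
    tibble(
      batch_id = data$batch_id,
      replicate = data$replicate,
      method = paste0("Flow.", g),
      count_per_g = data[[paste0(g, "_events")]] * scale
    )
  }) %>%
    arrange(.data$batch_id, .data$replicate, .data$method)
}
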