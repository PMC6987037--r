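# Colony-count quantification: countable-window filtering and CFU/g.

#' Keep plates inside the countable window
#'
#' Standard pour-plate practice only trusts plates carrying between 25 and
#' 250 colonies; sparser plates are statistically unreliable and denser
#' ones undercount through colony merging. Boundaries are inclusive.
#'
#' When nothing survives the window the result is an empty tibble carrying
#' a `diagnostic` attribute ("too numerous to count" when every plate is
#' overgrown, "too few colonies to count" when every plate is sparse,
#' "no plates within the countable window" otherwise), and a warning of
#' class `dropcount_uncountable` is emitted. An empty result is a flagged
#' outcome, not an error.
#'
#' @param data A plate series tibble with columns `batch_id`,
#'   `dilution_level`, `plated_volume`, `plate_index`, `colonies`.
#' @param window Length-2 numeric, inclusive countable range
#'   (default `c(25, 250)`).
#'
#' @return The rows of `data` whose `colonies` fall inside the window;
#'   attribute `diagnostic` is `NULL` when at least one plate is countable.
#' @export
#' @examples
#' series <- tibble::tibble(
#'   batch_id = "B01", dilution_level = 1e-6, plated_volume = 1,
#'   plate_index = 1:4, colonies = c(24, 25, 250, 251)
#' )
#' select_countable(series) # keeps the plates with 25 and 250 colonies
select_countable <- function(data, window = c(25, 250)) {
  if (nrow(data) == 0) abort("Plate series is empty.")
  if (length(window) != 2 || window[1] > window[2]) {
    abort("`window` must be (low, high) with low <= high.")
  }
  keep <- data$colonies >= window[1] & data$colonies <= window[2]
  out <- data[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    diag <- if (all(data$colonies > window[2])) {
      "too numerous to count"
    } else if (all(data$colonies < window[1])) {
      "too few colonies to count"
    } else {
      "no plates within the countable window"
    }
    attr(out, "diagnostic") <- diag
    warn(paste0("No countable plates: ", diag), class = "dropcount_uncountable")
  }
  out
}

#' Per-plate viable counts per gram
#'
#' Each countable plate contributes
#' `colonies / (plated_volume * dilution_level) * suspension_ml_per_g`
#' CFU per gram of powder. These per-plate replicate values feed the
#' coefficient-of-variation stage; [cfu_per_g()] combines them into a
#' per-batch point estimate.
#'
#' @inheritParams select_countable
#' @param suspension_ml_per_g Rehydration volume per gram of powder (mL).
#'
#' @return `data` with an added `count_per_g` column.
#' @export
plate_counts_per_g <- function(data, suspension_ml_per_g = 10) {
  if (any(data$plated_volume <= 0)) abort("`plated_volume` must be positive.")
  if (any(data$dilution_level <= 0 | data$dilution_level > 1)) {
    abort("`dilution_level` must lie in (0, 1].")
  }
  data %>%
    mutate(count_per_g = .data$colonies /
             (.data$plated_volume * .data$dilution_level) *
             suspension_ml_per_g)
}

#' Batch CFU per gram from countable plates
#'
#' Combines countable plates into one estimate per batch as the weighted
#' mean `sum(colonies) / sum(plated_volume * dilution_level)` scaled to
#' grams — i.e. total colonies over total sample mass examined, the
#' ISO-7218-style pooling across dilution levels. Plates at the same
#' dilution get equal weight, so there the weighted mean reduces to the
#' simple mean of per-plate values.
#'
#' @inheritParams plate_counts_per_g
#' @return A tibble with one row per batch: `batch_id`, `cfu_per_g`,
#'   `n_plates`.
#' @export
#' @examples
#' series <- tibble::tibble(
#'   batch_id = "B01", dilution_level = 1e-6, plated_volume = 1,
#'   plate_index = 1, colonies = 100
#' )
#' cfu_per_g(series) # 1e9 CFU/g under the default 1:10 rehydration
cfu_per_g <- function(data, suspension_ml_per_g = 10) {
  if (nrow(data) == 0) {
    abort("No countable plates: CFU/g is a flagged missing value for this batch.")
  }
  plate_counts_per_g(data, suspension_ml_per_g) %>%
    group_by(.data$batch_id) %>%
    summarise(
      cfu_per_g = sum(.data$colonies) /
        sum(.data$plated_volume * .data$dilution_level) *
        suspension_ml_per_g,
      n_plates = n(),
      .groups = "drop"
    )
}
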