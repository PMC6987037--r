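# Shared fixtures: all built in code at test time.

one_batch <- function(live = 1e11, dead = 0, id = "B01", strain = "NCFM") {
  tibble::tibble(batch_id = id, strain = strain,
                 live_conc = live, dead_conc = dead)
}

# a tiny deterministic measurement table: 3 batches x 2 methods x 3 reps
toy_table <- function() {
  tidyr::expand_grid(
    batch_id = c("B01", "B02", "B03"),
    method = c("Plate", "PCR.live"),
    replicate = 1:3
  ) |>
    dplyr::mutate(
      strain = "NCFM",
      count_per_g = 1e9 * (1 + 0.1 * replicate) *
        ifelse(method == "PCR.live", 1.2, 1) *
        match(batch_id, c("B01", "B02", "B03"))
    ) |>
    dplyr::select(batch_id, strain, method, replicate, count_per_g)
}

quiet_compare <- function(...) {
  suppressMessages(compare_methods(...))
}
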