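# Simulators for the three measurement processes: pour-plate counting,
# droplet digital PCR (with a viability-treated arm) and flow cytometry.
#
# Unit conventions used throughout:
#   * true concentrations are cells per gram of powder;
#   * powder is rehydrated 1:10 w/v (11 g into 110 mL), so one gram of
#     powder corresponds to `suspension_ml_per_g` mL (default 10) of
#     primary suspension, i.e. 10,000 uL per gram;
#   * `dilution_factor` is a fold >= 1 applied to the primary suspension;
#   * plate `dilution_level` is the complementary convention, a fraction
#     <= 1 (a 10^-6 dilution has dilution_level 1e-6).

as_truth <- function(truth) {
  if (is.data.frame(truth)) {
    if (nrow(truth) != 1) abort("`truth` must describe exactly one batch.")
    truth <- as.list(truth)
  }
  if (is.null(truth$batch_id)) truth$batch_id <- "B01"
  if (is.null(truth$dead_conc)) truth$dead_conc <- 0
  if (is.null(truth$live_conc) || truth$live_conc < 0) {
    abort("`truth` must carry a non-negative `live_conc`.")
  }
  truth
}

#' Simulate a serial-dilution pour-plate series for one batch
#'
#' Each plate receives `plated_volume` mL of suspension diluted to
#' `dilution_level`, so the expected colony count is
#' `live_conc * plated_volume * dilution_level / suspension_ml_per_g`
#' multiplied by a lognormal replicate error with relative SD
#' `plate_rel_sd`. Colonies are Poisson about that mean. Counts are
#' reported for every requested dilution level; applying the countable
#' window (25-250) is the quantification stage's job, not the simulator's.
#'
#' @param truth One-row data frame or list with `batch_id` and `live_conc`
#'   (cells per gram).
#' @param dilution_levels Numeric vector of dilution fractions in (0, 1].
#' @param n_plates Plates poured per dilution level.
#' @param plated_volume Volume plated per plate, in mL of diluted sample.
#' @param plate_rel_sd Relative SD of the lognormal replicate error.
#' @param suspension_ml_per_g Rehydration volume per gram of powder (mL).
#' @param seed Optional integer seed.
#'
#' @return Tibble with columns `batch_id`, `dilution_level`,
#'   `plated_volume`, `plate_index`, `colonies`.
#' @export
simulate_plate_series <- function(truth,
                                  dilution_levels,
                                  n_plates = 17,
                                  plated_volume = 1,
                                  plate_rel_sd = 0.15,
                                  suspension_ml_per_g = 10,
                                  seed = NULL) {
  truth <- as_truth(truth)
  if (any(dilution_levels <= 0 | dilution_levels > 1)) {
    abort("`dilution_levels` must lie in (0, 1].")
  }
  if (n_plates < 1) abort("`n_plates` must be >= 1.")
  draw <- function() {
    purrr::map_dfr(dilution_levels, function(d) {
      mu <- truth$live_conc * plated_volume * d / suspension_ml_per_g
      noise <- rlnorm_relsd(n_plates, plate_rel_sd)
      tibble(
        batch_id = truth$batch_id,
        dilution_level = d,
        plated_volume = plated_volume,
        plate_index = seq_len(n_plates),
        colonies = rpois(n_plates, mu * noise)
      )
    })
  }
  with_optional_seed(seed, draw())
}

# lognormal multipliers with unit mean and given relative sd
rlnorm_relsd <- function(n, rel_sd) {
  if (rel_sd <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + rel_sd^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Simulate droplet digital PCR wells for one batch and treatment arm
#'
#' The effective template concentration is `live_conc` plus, for the
#' untreated arm, the full dead-cell concentration, or, for the
#' viability-dye treated arm, only the fraction `pemax_dead_carryover` of
#' it. That concentration is carried through the dilution chain to a mean
#' copies-per-droplet occupancy `m`; each well then reports a binomial
#' number of positive droplets with success probability `1 - exp(-m)`,
#' with an extra lognormal well-to-well error on `m`.
#'
#' @param truth One-row data frame or list with `batch_id`, `live_conc`,
#'   `dead_conc`.
#' @param arm `"treated"` (viability-dye, PCR.live) or `"untreated"`
#'   (PCR.total).
#' @param dilution_factor Fold dilution (>= 1) of the primary suspension
#'   into the PCR reaction.
#' @param n_wells Number of replicate wells.
#' @param droplets_per_well Accepted droplets per well.
#' @param droplet_volume Droplet volume in microliters (QX200 nominal
#'   8.5e-4).
#' @param noise A [noise_model()].
#' @param suspension_ml_per_g Rehydration volume per gram (mL).
#' @param copies_per_cell Genomic target copies per cell (single-copy
#'   assays: 1).
#' @param seed Optional integer seed.
#'
#' @return Tibble with columns `batch_id`, `well_id`, `arm`,
#'   `accepted_droplets`, `positive_droplets`, `dilution_factor`,
#'   `droplet_volume`.
#' @export
simulate_ddpcr_wells <- function(truth,
                                 arm = c("treated", "untreated"),
                                 dilution_factor = 1e4,
                                 n_wells = 3,
                                 droplets_per_well = 20000,
                                 droplet_volume = 8.5e-4,
                                 noise = noise_model(),
                                 suspension_ml_per_g = 10,
                                 copies_per_cell = 1,
                                 seed = NULL) {
  truth <- as_truth(truth)
  arm <- match.arg(arm)
  if (droplets_per_well < 1) abort("`droplets_per_well` must be >= 1.")
  if (droplet_volume <= 0) abort("`droplet_volume` must be positive.")
  if (dilution_factor < 1) abort("`dilution_factor` must be >= 1.")

  conc_eff <- truth$live_conc +
    if (arm == "treated") noise$pemax_dead_carryover * truth$dead_conc
    else truth$dead_conc
  copies_per_ul <- conc_eff * copies_per_cell /
    (suspension_ml_per_g * 1000) / dilution_factor
  m <- copies_per_ul * droplet_volume

  draw <- function() {
    m_well <- m * rlnorm_relsd(n_wells, noise$ddpcr_extra_rel_sd)
    tibble(
      batch_id = truth$batch_id,
      well_id = sprintf("%s-%s-W%d", truth$batch_id,
                        ifelse(arm == "treated", "L", "T"), seq_len(n_wells)),
      arm = arm,
      accepted_droplets = as.integer(droplets_per_well),
      positive_droplets = rbinom(n_wells, droplets_per_well,
                                 1 - exp(-m_well)),
      dilution_factor = dilution_factor,
      droplet_volume = droplet_volume
    )
  }
  with_optional_seed(seed, draw())
}

#' Simulate gated flow-cytometry replicates for one batch
#'
#' The live gate collects `(1 - flow_live_misgate)` of the live cells plus
#' `flow_live_misgate` of the dead cells; the dead gate is complementary;
#' the total gate is their sum, exactly. Independent lognormal replicate
#' errors with relative SD `flow_rel_sd` multiply each gate. Event
#' counts are the gated concentrations carried through the dilution chain
#' into the analyzed volume and rounded to whole events.
#'
#' @param truth One-row data frame or list with `batch_id`, `live_conc`,
#'   `dead_conc`.
#' @param dilution_factor Fold dilution (>= 1) of the primary suspension.
#' @param n_replicates Number of replicates.
#' @param analyzed_volume Analyzed volume per replicate, in microliters.
#' @param noise A [noise_model()].
#' @param suspension_ml_per_g Rehydration volume per gram (mL).
#' @param seed Optional integer seed.
#'
#' @return Tibble with columns `batch_id`, `replicate`, `live_events`,
#'   `dead_events`, `total_events`, `analyzed_volume`, `dilution_factor`.
#' @export
simulate_flow <- function(truth,
                          dilution_factor = 1e3,
                          n_replicates = 3,
                          analyzed_volume = 5,
                          noise = noise_model(),
                          suspension_ml_per_g = 10,
                          seed = NULL) {
  truth <- as_truth(truth)
  if (dilution_factor < 1) abort("`dilution_factor` must be >= 1.")
  if (analyzed_volume <= 0) abort("`analyzed_volume` must be positive.")

  mis <- noise$flow_live_misgate
  live_gate <- truth$live_conc * (1 - mis) + mis * truth$dead_conc
  dead_gate <- truth$dead_conc * (1 - mis) + mis * truth$live_conc
  per_ul <- analyzed_volume / (suspension_ml_per_g * 1000) / dilution_factor

  draw <- function() {
    # independent replicate errors per gate; the total gate is still the
    # exact sum of the live and dead gates
    live_events <- round(live_gate * per_ul *
                           rlnorm_relsd(n_replicates, noise$flow_rel_sd))
    dead_events <- round(dead_gate * per_ul *
                           rlnorm_relsd(n_replicates, noise$flow_rel_sd))
    tibble(
      batch_id = truth$batch_id,
      replicate = seq_len(n_replicates),
      live_events = live_events,
      dead_events = dead_events,
      total_events = live_events + dead_events,
      analyzed_volume = analyzed_volume,
      dilution_factor = dilution_factor
    )
  }
  with_optional_seed(seed, draw())
}

# Decade-dilution choices emulating how an analyst targets each
# instrument's working range from an approximate expected potency.

# plate: pick the decade level whose expected count is nearest (on the log
# scale) to the geometric centre of the 25-250 countable window (~79)
choose_plate_dilution <- function(live_conc, plated_volume = 1,
                                  suspension_ml_per_g = 10,
                                  window = c(25, 250)) {
  target <- sqrt(prod(window))
  per_unit <- live_conc * plated_volume / suspension_ml_per_g
  10^min(round(log10(target / per_unit)), 0)
}

# ddPCR: target a mid-range droplet occupancy m ~ 0.8 copies per droplet
choose_ddpcr_dilution <- function(conc_eff, droplet_volume = 8.5e-4,
                                  suspension_ml_per_g = 10,
                                  target_m = 0.8) {
  per_ul <- conc_eff / (suspension_ml_per_g * 1000)
  10^max(round(log10(per_ul * droplet_volume / target_m)), 0)
}

# flow: target ~1e4 events per uL in the analyzed sample
choose_flow_dilution <- function(total_conc, suspension_ml_per_g = 10,
                                 target_events_per_ul = 1e4) {
  per_ul <- total_conc / (suspension_ml_per_g * 1000)
  10^max(round(log10(per_ul / target_events_per_ul)), 0)
}

#' Simulate a complete enumeration study
#'
#' Generates ground-truth batches and pushes each through the three
#' measurement processes with the replicate structure of the design:
#' `plate_replicates` plates at each of three decade dilution levels
#' bracketing the countable window, `well_replicates` ddPCR wells per
#' treatment arm, and `flow_replicates` flow-cytometry replicates. Each
#' batch and measurement stage draws from its own RNG sub-stream (derived
#' by hashing the batch id), so results do not depend on batch order.
#'
#' @inheritParams generate_study
#' @param droplets_per_well Accepted droplets per ddPCR well.
#' @param droplet_volume Droplet volume in microliters.
#' @param plated_volume Volume plated per plate (mL).
#' @param analyzed_volume Flow-cytometry analyzed volume (uL).
#' @param suspension_ml_per_g Rehydration volume per gram of powder (mL).
#'
#' @return A list of class `dropcount_sim` with tibbles `truth`, `plate`,
#'   `ddpcr`, `flow`, and the `design`, `noise` and `seed` used.
#' @export
#' @examples
#' sim <- simulate_study(seed = 1)
#' head(sim$ddpcr)
simulate_study <- function(design = study_design(),
                           noise = noise_model(),
                           conc_range = c(1e10, 1e12),
                           seed = 1L,
                           droplets_per_well = 20000,
                           droplet_volume = 8.5e-4,
                           plated_volume = 1,
                           analyzed_volume = 5,
                           suspension_ml_per_g = 10) {
  truth <- generate_study(design, noise, conc_range, seed)

  plate <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    centre <- choose_plate_dilution(tr$live_conc, plated_volume,
                                    suspension_ml_per_g)
    levels <- pmin(centre * c(10, 1, 0.1), 1)
    simulate_plate_series(
      tr, unique(levels), n_plates = design$plate_replicates,
      plated_volume = plated_volume, plate_rel_sd = noise$plate_rel_sd,
      suspension_ml_per_g = suspension_ml_per_g,
      seed = subseed(seed, tr$batch_id, "plate")
    )
  })

  ddpcr <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    purrr::map_dfr(c("treated", "untreated"), function(arm) {
      conc_eff <- tr$live_conc +
        if (arm == "treated") noise$pemax_dead_carryover * tr$dead_conc
        else tr$dead_conc
      dil <- choose_ddpcr_dilution(conc_eff, droplet_volume,
                                   suspension_ml_per_g)
      simulate_ddpcr_wells(
        tr, arm, dilution_factor = dil,
        n_wells = design$well_replicates,
        droplets_per_well = droplets_per_well,
        droplet_volume = droplet_volume, noise = noise,
        suspension_ml_per_g = suspension_ml_per_g,
        seed = subseed(seed, tr$batch_id, paste0("ddpcr-", arm))
      )
    })
  })

  flow <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    dil <- choose_flow_dilution(tr$live_conc + tr$dead_conc,
                                suspension_ml_per_g)
    simulate_flow(
      tr, dilution_factor = dil, n_replicates = design$flow_replicates,
      analyzed_volume = analyzed_volume, noise = noise,
      suspension_ml_per_g = suspension_ml_per_g,
      seed = subseed(seed, tr$batch_id, "flow")
    )
  })

  structure(
    list(truth = truth, plate = plate, ddpcr = ddpcr, flow = flow,
         design = design, noise = noise, seed = as.integer(seed),
         suspension_ml_per_g = suspension_ml_per_g),
    class = "dropcount_sim"
  )
}
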