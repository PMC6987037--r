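# Study design and noise configuration for the measurement-process simulator.

#' Describe the replicate structure of an enumeration study
#'
#' A study enumerates a set of production batches, each assigned to one
#' strain, with every batch measured by plate count, droplet digital PCR
#' (both a viability-dye treated arm and an untreated arm) and flow
#' cytometry. The default design mirrors a 50-batch production study:
#' 20 NCFM, 9 Bi-07, 8 Lp-115, 8 HN019, 3 Bl-04 and 2 La-14 batches, with
#' 17 plates per batch and triplicate wells/replicates for the other
#' methods.
#'
#' @param n_batches_per_strain Named integer vector mapping strain label to
#'   number of batches. Names must be drawn from the six study strains.
#' @param plate_replicates Plates poured per batch at each dilution level.
#' @param well_replicates ddPCR wells per treatment arm per batch.
#' @param flow_replicates Flow-cytometry replicates per batch.
#'
#' @return A list of class `study_design`.
#' @export
#' @examples
#' study_design()
study_design <- function(n_batches_per_strain = c(
                           "NCFM" = 20, "Bi-07" = 9, "Lp-115" = 8,
                           "HN019" = 8, "Bl-04" = 3, "La-14" = 2
                         ),
                         plate_replicates = 17,
                         well_replicates = 3,
                         flow_replicates = 3) {
  if (length(n_batches_per_strain) == 0 || sum(n_batches_per_strain) == 0) {
    abort("Study design must contain at least one batch.")
  }
  if (is.null(names(n_batches_per_strain)) ||
      !all(nzchar(names(n_batches_per_strain)))) {
    abort("`n_batches_per_strain` must be a named vector (strain -> count).")
  }
  unknown <- setdiff(names(n_batches_per_strain), DROPCOUNT_STRAINS)
  if (length(unknown) > 0) {
    abort(paste0("Unknown strain label(s): ", paste(unknown, collapse = ", ")))
  }
  if (any(n_batches_per_strain < 0)) {
    abort("Batch counts must be non-negative.")
  }
  reps <- c(plate_replicates, well_replicates, flow_replicates)
  if (any(reps < 1)) {
    abort("All replicate counts must be >= 1.")
  }
  structure(
    list(
      n_batches_per_strain = n_batches_per_strain,
      plate_replicates = as.integer(plate_replicates),
      well_replicates = as.integer(well_replicates),
      flow_replicates = as.integer(flow_replicates)
    ),
    class = "study_design"
  )
}

#' Configure the noise regimes of the simulated measurement processes
#'
#' The relative standard deviations are multiplicative lognormal replicate
#' errors, one per plate/well/replicate. Plate counting is by far the
#' noisiest process, flow cytometry intermediate, and ddPCR adds only a
#' small extra error on top of the intrinsic droplet partition sampling
#' noise. `pemax_dead_carryover` is the fraction of dead-cell template that
#' survives viability-dye (PEMAX) treatment and still amplifies in the
#' treated arm; it creates the systematic positive offset of viable ddPCR
#' relative to plate counts. `flow_live_misgate` is the fraction of each
#' population assigned to the wrong live/dead gate. `dead_fraction_mean`
#' controls the mean dead:live ratio drawn per batch.
#'
#' @param plate_rel_sd Relative SD of plate replicate error (default 0.15).
#' @param flow_rel_sd Relative SD of flow replicate error (default 0.03).
#' @param ddpcr_extra_rel_sd Relative SD of well-to-well error added on top
#'   of partition sampling noise (default 0.01).
#' @param pemax_dead_carryover Fraction in \[0, 1\] (default 0.2).
#' @param flow_live_misgate Fraction in \[0, 1\] (default 0.02).
#' @param dead_fraction_mean Mean per-batch dead-cell fraction relative to
#'   live cells (default 0.15).
#'
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(plate_rel_sd = 0.15,
                        flow_rel_sd = 0.03,
                        ddpcr_extra_rel_sd = 0.01,
                        pemax_dead_carryover = 0.2,
                        flow_live_misgate = 0.02,
                        dead_fraction_mean = 0.15) {
  fracs <- c(pemax_dead_carryover, flow_live_misgate, dead_fraction_mean)
  if (any(fracs < 0 | fracs > 1)) {
    abort("Carryover, misgating and dead fractions must lie in [0, 1].")
  }
  sds <- c(plate_rel_sd, flow_rel_sd, ddpcr_extra_rel_sd)
  if (any(sds < 0)) {
    abort("Relative standard deviations must be non-negative.")
  }
  structure(
    list(
      plate_rel_sd = plate_rel_sd,
      flow_rel_sd = flow_rel_sd,
      ddpcr_extra_rel_sd = ddpcr_extra_rel_sd,
      pemax_dead_carryover = pemax_dead_carryover,
      flow_live_misgate = flow_live_misgate,
      dead_fraction_mean = dead_fraction_mean
    ),
    class = "noise_model"
  )
}

# Stable 31-bit polynomial string hash; used to derive per-batch,
# per-measurement-stage RNG sub-seeds so batch simulation order never
# matters. Modulus 2^31 - 1 keeps results inside R's integer range.
hash_string <- function(x) {
  mod <- 2147483647
  h <- 0
  for (code in utf8ToInt(x)) {
    h <- (h * 31 + code) %% mod
  }
  h
}

subseed <- function(seed, batch_id, stage) {
  as.integer((seed + hash_string(paste(stage, batch_id, sep = "/"))) %%
               2147483647L)
}

#' Generate ground-truth batches for a simulated study
#'
#' Draws one true live-cell and dead-cell concentration (cells per gram of
#' freeze-dried powder) per batch. Live concentrations are log-uniform over
#' `conc_range`; the dead-cell concentration is the live concentration
#' times a per-batch dead fraction drawn from a Beta distribution with mean
#' `noise$dead_fraction_mean` (concentration parameter 20).
#'
#' @param design A [study_design()].
#' @param noise A [noise_model()].
#' @param conc_range Length-2 positive numeric: range of true live
#'   concentrations in cells per gram. The default, `c(1e10, 1e12)`,
#'   spans typical freeze-dried probiotic concentrate potencies.
#' @param seed Integer seed; the same seed reproduces the same batch list.
#'
#' @return A tibble with columns `batch_id`, `strain`, `live_conc`,
#'   `dead_conc`, one row per batch.
#' @export
#' @examples
#' generate_study(study_design(), noise_model(), seed = 1)
generate_study <- function(design = study_design(),
                           noise = noise_model(),
                           conc_range = c(1e10, 1e12),
                           seed = 1L) {
  stopifnot(inherits(design, "study_design"), inherits(noise, "noise_model"))
  if (length(conc_range) != 2 || any(conc_range <= 0)) {
    abort("`conc_range` must be two positive concentrations.")
  }
  counts <- design$n_batches_per_strain
  counts <- counts[counts > 0]
  n_total <- sum(counts)
  strains <- rep(names(counts), counts)
  ids <- sprintf("B%02d", seq_len(n_total))

  # Beta(mean * k, (1 - mean) * k) with k = 20 gives a realistic spread of
  # dead fractions across batches without ever leaving [0, 1].
  k <- 20
  a <- noise$dead_fraction_mean * k
  b <- (1 - noise$dead_fraction_mean) * k

  withr::with_seed(as.integer(seed), {
    log_lo <- log10(min(conc_range))
    log_hi <- log10(max(conc_range))
    live <- 10^runif(n_total, log_lo, log_hi)
    dead_frac <- if (a > 0) rbeta(n_total, a, b) else rep(0, n_total)
    tibble(
      batch_id = ids,
      strain = strains,
      live_conc = live,
      dead_conc = live * dead_frac
    )
  })
}
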