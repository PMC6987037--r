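# Pipeline orchestration: simulate -> quantify -> compare.

#' Assemble a pipeline configuration
#'
#' Bundles the study design, noise model and all quantification settings
#' into one validated object consumed by [run_simulate()],
#' [run_quantify()], [run_compare()] and [run_study()]. Settings given on
#' a call override those read from a YAML file
#' ([read_pipeline_config()]), which override these defaults.
#'
#' @param design A [study_design()].
#' @param noise A [noise_model()].
#' @param conc_range True live-concentration range (cells/g) for the
#'   simulator.
#' @param seed Integer seed governing every random draw of a run.
#' @param droplet_volume Droplet volume (uL).
#' @param droplets_per_well Accepted droplets per simulated well.
#' @param min_droplets Accepted-droplet threshold for the
#'   under-partitioned flag.
#' @param countable_window Inclusive colony-count window, default
#'   `c(25, 250)`.
#' @param conf_level Confidence level for ddPCR interval estimates.
#' @param loa_multiplier Limits-of-agreement multiplier (1.96 = 95%).
#' @param suspension_ml_per_g Rehydration volume per gram of powder (mL).
#' @param copies_per_cell Assay target copies per cell.
#' @param plated_volume Volume plated per plate (mL).
#' @param analyzed_volume Flow-cytometry analyzed volume (uL).
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = study_design(),
                            noise = noise_model(),
                            conc_range = c(1e10, 1e12),
                            seed = 1L,
                            droplet_volume = 8.5e-4,
                            droplets_per_well = 20000,
                            min_droplets = 10000,
                            countable_window = c(25, 250),
                            conf_level = 0.95,
                            loa_multiplier = 1.96,
                            suspension_ml_per_g = 10,
                            copies_per_cell = 1,
                            plated_volume = 1,
                            analyzed_volume = 5) {
  stopifnot(inherits(design, "study_design"), inherits(noise, "noise_model"))
  if (conf_level <= 0 || conf_level >= 1) abort("`conf_level` must be in (0, 1).")
  if (loa_multiplier <= 0) abort("`loa_multiplier` must be positive.")
  if (suspension_ml_per_g <= 0) abort("`suspension_ml_per_g` must be positive.")
  if (droplet_volume <= 0) abort("`droplet_volume` must be positive.")
  structure(
    list(
      design = design, noise = noise,
      conc_range = as.numeric(conc_range), seed = as.integer(seed),
      droplet_volume = droplet_volume,
      droplets_per_well = as.integer(droplets_per_well),
      min_droplets = as.integer(min_droplets),
      countable_window = as.numeric(countable_window),
      conf_level = conf_level, loa_multiplier = loa_multiplier,
      suspension_ml_per_g = suspension_ml_per_g,
      copies_per_cell = copies_per_cell,
      plated_volume = plated_volume, analyzed_volume = analyzed_volume
    ),
    class = "pipeline_config"
  )
}

config_hash <- function(config) {
  rlang::hash(unclass(config))
}

#' Simulate a study under a pipeline configuration
#'
#' Runs [simulate_study()] with the configuration's design, noise and
#' seed. When `out_dir` is given, writes `truth.csv`,
#' `plate_series.csv`, `ddpcr_wells.csv`, `flow_records.csv` and a
#' `manifest.json` recording the seed and a configuration hash, so a
#' rerun with the same manifest seed reproduces the files byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return The `dropcount_sim` object, invisibly carrying the manifest as
#'   attribute `manifest` when files were written.
#' @export
run_simulate <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- simulate_study(
    design = config$design, noise = config$noise,
    conc_range = config$conc_range, seed = config$seed,
    droplets_per_well = config$droplets_per_well,
    droplet_volume = config$droplet_volume,
    plated_volume = config$plated_volume,
    analyzed_volume = config$analyzed_volume,
    suspension_ml_per_g = config$suspension_ml_per_g
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(sim$truth, file.path(out_dir, "truth.csv"))
    write_plate_series(sim$plate, file.path(out_dir, "plate_series.csv"))
    write_droplet_wells(sim$ddpcr, file.path(out_dir, "ddpcr_wells.csv"))
    write_flow_records(sim$flow, file.path(out_dir, "flow_records.csv"))
    manifest <- list(
      seed = config$seed,
      config_hash = config_hash(config),
      n_batches = nrow(sim$truth),
      files = c("truth.csv", "plate_series.csv", "ddpcr_wells.csv",
                "flow_records.csv")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    attr(sim, "manifest") <- manifest
  }
  sim
}

drop_invalid_droplet_rows <- function(wells) {
  bad <- wells$positive_droplets < 0 |
    wells$positive_droplets > wells$accepted_droplets |
    wells$accepted_droplets <= 0 |
    wells$dilution_factor < 1
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    warn(sprintf("Rejecting %d droplet well record(s) violating schema invariants.",
                 sum(bad)), class = "dropcount_rejected_rows")
  }
  wells[!bad, , drop = FALSE]
}

#' Quantify raw observations into a measurement table
#'
#' Converts raw plate series, droplet well records and flow records into
#' one long measurement table (`batch_id, strain, method, replicate,
#' count_per_g`). Plate counts pass through the countable window first;
#' batches with no countable plate are flagged missing (one `NA` row).
#' Each ddPCR well yields one replicate (`PCR.live` for the
#' viability-treated arm, `PCR.total` for the untreated arm); droplet
#' records violating their invariants are rejected with a warning. Flow
#' gates map to `Flow.live`, `Flow.dead` and `Flow.total`.
#'
#' @param config A [pipeline_config()].
#' @param plate,ddpcr,flow Raw observation tibbles (or a `dropcount_sim`
#'   passed as `sim`).
#' @param sim Optional `dropcount_sim`; its components override `plate`,
#'   `ddpcr`, `flow`.
#' @param strains Optional tibble `batch_id`, `strain` to annotate rows;
#'   defaults to the simulation truth when `sim` is given, otherwise
#'   strain is `NA`.
#' @return A measurement-table tibble.
#' @export
run_quantify <- function(config = pipeline_config(),
                         plate = NULL, ddpcr = NULL, flow = NULL,
                         sim = NULL, strains = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "dropcount_sim"))
    plate <- plate %||% sim$plate
    ddpcr <- ddpcr %||% sim$ddpcr
    flow <- flow %||% sim$flow
    strains <- strains %||% sim$truth[c("batch_id", "strain")]
  }
  out <- list()

  if (!is.null(plate) && nrow(plate) > 0) {
    keep <- plate$colonies >= config$countable_window[1] &
      plate$colonies <= config$countable_window[2]
    countable <- plate[keep, , drop = FALSE]
    plate_rows <- if (nrow(countable) > 0) {
      plate_counts_per_g(countable, config$suspension_ml_per_g) %>%
        group_by(.data$batch_id) %>%
        mutate(replicate = row_number()) %>%
        ungroup() %>%
        mutate(method = "Plate") %>%
        select("batch_id", "method", "replicate", "count_per_g")
    } else {
      tibble(batch_id = character(), method = character(),
             replicate = integer(), count_per_g = double())
    }
    uncountable <- setdiff(unique(plate$batch_id), plate_rows$batch_id)
    if (length(uncountable) > 0) {
      warn(sprintf("%d batch(es) had no countable plates; Plate flagged missing.",
                   length(uncountable)), class = "dropcount_uncountable")
      plate_rows <- bind_rows(
        plate_rows,
        tibble(batch_id = uncountable, method = "Plate", replicate = 1L,
               count_per_g = NA_real_)
      )
    }
    out <- c(out, list(plate_rows))
  }

  if (!is.null(ddpcr) && nrow(ddpcr) > 0) {
    wells <- drop_invalid_droplet_rows(ddpcr)
    if (nrow(wells) > 0) {
      est <- quantify_wells(
        wells,
        suspension_ml_per_g = config$suspension_ml_per_g,
        copies_per_cell = config$copies_per_cell,
        conf_level = config$conf_level,
        min_droplets = config$min_droplets
      )
      ddpcr_rows <- est %>%
        mutate(method = ifelse(.data$arm == "treated",
                               "PCR.live", "PCR.total")) %>%
        group_by(.data$batch_id, .data$method) %>%
        mutate(replicate = row_number()) %>%
        ungroup() %>%
        select("batch_id", "method", "replicate", "count_per_g")
      out <- c(out, list(ddpcr_rows))
    }
  }

  if (!is.null(flow) && nrow(flow) > 0) {
    flow_rows <- flow_cells_per_g(flow,
                                  suspension_ml_per_g =
                                    config$suspension_ml_per_g) %>%
      mutate(replicate = as.integer(.data$replicate)) %>%
      select("batch_id", "method", "replicate", "count_per_g")
    out <- c(out, list(flow_rows))
  }

  if (length(out) == 0) abort("No raw observations supplied.")
  table <- bind_rows(out)
  if (!is.null(strains)) {
    table <- left_join(table, strains, by = "batch_id")
  } else {
    table$strain <- NA_character_
  }
  table <- table %>%
    select("batch_id", "strain", "method", "replicate", "count_per_g") %>%
    arrange(match(.data$method, DROPCOUNT_METHODS), .data$batch_id,
            .data$replicate)
  validate_measurement_table(table)
  table
}

#' Compare methods and write the study report
#'
#' Runs the consistency (CV) and agreement (Pearson, regression,
#' Bland-Altman) analyses over a measurement table. With fewer than two
#' methods the agreement stage is skipped with a warning and only the CV
#' summary is produced. When `out_dir` is given, writes
#' `cv_summary.tsv`, `pair_agreement.tsv`, a machine-readable
#' `report.json` (stamped with the configuration hash), and figures:
#' per-method boxplots, pairwise scatter plots with the y = x reference,
#' and Bland-Altman plots.
#'
#' @param config A [pipeline_config()].
#' @param table A measurement table.
#' @param out_dir Optional output directory.
#' @param figure_methods Methods drawn in the figures (default the three
#'   viable-count methods).
#' @return A list of class `dropcount_report` with elements `cv_summary`
#'   and `agreement` (`NULL` when skipped).
#' @export
run_compare <- function(config = pipeline_config(), table,
                        out_dir = NULL,
                        figure_methods = c("Plate", "PCR.live", "Flow.live")) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_measurement_table(table)
  methods_present <- intersect(DROPCOUNT_METHODS, unique(table$method))

  cv_summary <- method_cv_summary(table)
  agreement <- NULL
  if (length(methods_present) >= 2) {
    agreement <- compare_methods(table,
                                 loa_multiplier = config$loa_multiplier)
  } else {
    warn("Only one method present: agreement analysis skipped.",
         class = "dropcount_single_method")
  }

  report <- structure(
    list(cv_summary = cv_summary, agreement = agreement),
    class = "dropcount_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(cv_summary, file.path(out_dir, "cv_summary.tsv"))
    if (!is.null(agreement)) {
      readr::write_tsv(agreement, file.path(out_dir, "pair_agreement.tsv"))
    }
    jsonlite::write_json(
      list(
        config_hash = config_hash(config),
        seed = config$seed,
        cv_summary = cv_summary,
        pair_agreement = agreement
      ),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, pretty = TRUE, dataframe = "rows", digits = NA
    )
    fig_methods <- intersect(figure_methods, methods_present)
    if (length(fig_methods) >= 1) {
      ggplot2::ggsave(
        file.path(out_dir, "method_boxplot.png"),
        plot_method_boxplot(table, methods = fig_methods),
        width = 9, height = 4.5, dpi = 150
      )
    }
    if (length(fig_methods) >= 2) {
      prs <- utils::combn(fig_methods, 2, simplify = FALSE)
      for (pr in prs) {
        stem <- paste0(gsub("[^A-Za-z0-9]", "_", pr[1]), "_vs_",
                       gsub("[^A-Za-z0-9]", "_", pr[2]))
        ggplot2::ggsave(
          file.path(out_dir, paste0("scatter_", stem, ".png")),
          plot_method_scatter(table, pr[1], pr[2]),
          width = 5, height = 5, dpi = 150
        )
        ggplot2::ggsave(
          file.path(out_dir, paste0("bland_altman_", stem, ".png")),
          plot_bland_altman(table, pr[1], pr[2],
                            loa_multiplier = config$loa_multiplier),
          width = 5.5, height = 4.5, dpi = 150
        )
      }
    }
  }
  report
}

#' @export
print.dropcount_report <- function(x, ...) {
  cat("Enumeration method comparison report\n\n")
  cat("Consistency (mean per-batch CV %, by stratum):\n")
  print(as_tibble(unclass(x$cv_summary)), n = 12)
  if (!is.null(x$agreement)) {
    cat("\nPairwise agreement:\n")
    print(as_tibble(unclass(x$agreement)), n = 15)
  }
  invisible(x)
}

#' Run the full pipeline: simulate, quantify, compare
#'
#' @inheritParams run_simulate
#' @return A list with `sim`, `table` and `report`.
#' @export
#' @examples
#' \donttest{
#' res <- run_study(pipeline_config(seed = 7))
#' res$report$cv_summary
#' }
run_study <- function(config = pipeline_config(), out_dir = NULL) {
  sim <- run_simulate(config, out_dir = out_dir)
  table <- run_quantify(config, sim = sim)
  if (!is.null(out_dir)) {
    write_measurement_table(table,
                            file.path(out_dir, "measurement_table.csv"))
  }
  report <- run_compare(config, table, out_dir = out_dir)
  list(sim = sim, table = table, report = report)
}
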