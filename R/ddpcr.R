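# Poisson occupancy quantification for droplet digital PCR.
#
# With droplets of volume Vd uL and a fraction p of positive droplets, the
# mean occupancy is lambda = -ln(1 - p) copies per droplet, so the reaction
# holds lambda / Vd copies per uL. The dilution chain (fold dilution of the
# primary suspension times the rehydration volume per gram) converts that
# to copies -- and, through the copies-per-cell factor, cells -- per gram.

#' Quantify droplet digital PCR wells
#'
#' Converts positive/accepted droplet counts into occupancy, copies per
#' microliter of reaction, and cells per gram, with a Wilson score
#' confidence interval on the positive fraction mapped through the same
#' transform. Saturated wells (every droplet positive) have their point
#' estimate censored to `NA` and carry only a finite lower confidence
#' bound; wells with fewer accepted droplets than `min_droplets` are
#' flagged but not discarded.
#'
#' `quantify_well()` is the vectorised numeric interface;
#' `quantify_wells()` applies it to a tibble of well records (as produced
#' by [simulate_ddpcr_wells()] or [read_droplet_wells()]), one estimate
#' per well.
#'
#' @param positive_droplets,accepted_droplets Integer vectors,
#'   `0 <= positive <= accepted`, `accepted > 0`.
#' @param dilution_factor Fold dilution (>= 1) of the primary suspension
#'   into the reaction.
#' @param droplet_volume Droplet volume in microliters (QX200 nominal
#'   8.5e-4).
#' @param suspension_ml_per_g Rehydration volume per gram of powder (mL);
#'   with the 1:10 w/v default, one gram corresponds to 10,000 uL of
#'   primary suspension.
#' @param copies_per_cell Target copies per cell (single-copy assays: 1).
#' @param conf_level Confidence level for the Wilson interval.
#' @param min_droplets Accepted-droplet threshold below which a well is
#'   flagged as under-partitioned.
#' @param wells_used Number of wells behind each estimate (bookkeeping;
#'   set by [merge_wells()]).
#'
#' @return A tibble with columns `accepted_droplets`, `positive_droplets`,
#'   `p_hat`, `copies_per_droplet`, `copies_per_ul_reaction`,
#'   `count_per_g`, `ci_low`, `ci_high`, `wells_used`, `saturated`,
#'   `below_min_droplets`.
#' @export
#' @examples
#' quantify_well(5000, 10000) # lambda = ln 2, ~815.47 copies/uL
quantify_well <- function(positive_droplets,
                          accepted_droplets,
                          dilution_factor = 1,
                          droplet_volume = 8.5e-4,
                          suspension_ml_per_g = 10,
                          copies_per_cell = 1,
                          conf_level = 0.95,
                          min_droplets = 10000,
                          wells_used = 1L) {
  if (any(accepted_droplets <= 0)) {
    abort("`accepted_droplets` must be positive: a well with no partitions cannot be quantified.")
  }
  if (any(positive_droplets < 0 | positive_droplets > accepted_droplets)) {
    abort("`positive_droplets` must lie in [0, accepted_droplets].")
  }
  if (any(dilution_factor < 1)) abort("`dilution_factor` must be >= 1.")
  if (any(droplet_volume <= 0)) abort("`droplet_volume` must be positive.")

  p <- positive_droplets / accepted_droplets
  saturated <- p >= 1
  lambda <- ifelse(saturated, Inf, -log1p(-p))
  copies_ul <- lambda / droplet_volume
  chain <- dilution_factor * suspension_ml_per_g * 1000 / copies_per_cell
  count <- copies_ul * chain

  ci <- wilson_interval(positive_droplets, accepted_droplets, conf_level)
  to_count <- function(q) -log1p(-pmin(q, 1)) / droplet_volume * chain
  ci_low <- to_count(ci$low)
  ci_high <- to_count(ci$high)

  tibble(
    accepted_droplets = as.integer(accepted_droplets),
    positive_droplets = as.integer(positive_droplets),
    p_hat = p,
    copies_per_droplet = ifelse(saturated, NA_real_, lambda),
    copies_per_ul_reaction = ifelse(saturated, NA_real_, copies_ul),
    count_per_g = ifelse(saturated, NA_real_, count),
    ci_low = ci_low,
    ci_high = ci_high,
    wells_used = as.integer(wells_used),
    saturated = saturated,
    below_min_droplets = accepted_droplets < min_droplets
  )
}

# Wilson score interval for a binomial proportion; chosen over Wald for
# its behaviour at p near 0 and 1. At p = 1 the upper bound is 1 (and the
# mapped concentration bound infinite).
wilson_interval <- function(x, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(low = pmax(centre - half, 0), high = pmin(centre + half, 1))
}

#' @rdname quantify_well
#' @param data A tibble of droplet well records with columns `batch_id`,
#'   `arm`, `accepted_droplets`, `positive_droplets`, `dilution_factor`
#'   and optionally `droplet_volume`, `well_id`.
#' @param ... Passed on to [quantify_well()].
#' @export
quantify_wells <- function(data, ...) {
  validate_droplet_records(data)
  dv <- data$droplet_volume %||% NULL
  args <- list(
    positive_droplets = data$positive_droplets,
    accepted_droplets = data$accepted_droplets,
    dilution_factor = data$dilution_factor
  )
  if (!is.null(dv)) args$droplet_volume <- dv
  est <- do.call(quantify_well, c(args, list(...)))
  keep <- intersect(c("batch_id", "well_id", "arm", "dilution_factor"),
                    names(data))
  dplyr::bind_cols(data[keep], est)
}

#' Pool replicate ddPCR wells before quantification
#'
#' Merges wells by summing positive and accepted droplets within each
#' `batch_id` x `arm` group and quantifies the pooled counts ("merged
#' wells" convention). Pooling before the Poisson transform weights each
#' droplet equally and gives a lower-variance estimate than averaging
#' per-well concentrations. All wells in a group must share the same
#' dilution factor and droplet volume.
#'
#' @inheritParams quantify_wells
#' @return One estimate row per `batch_id` x `arm` group, with
#'   `wells_used` recording how many wells were pooled.
#' @export
#' @examples
#' wells <- tibble::tibble(
#'   batch_id = "B01", arm = "treated",
#'   accepted_droplets = c(10000, 10000, 10000),
#'   positive_droplets = c(100, 110, 90),
#'   dilution_factor = 1
#' )
#' merge_wells(wells) # same estimate as quantify_well(300, 30000)
merge_wells <- function(data, ...) {
  validate_droplet_records(data)
  grouped <- data %>%
    group_by(.data$batch_id, .data$arm)
  dils <- grouped %>%
    summarise(n_dil = n_distinct(.data$dilution_factor), .groups = "drop")
  if (any(dils$n_dil > 1)) {
    abort("Cannot merge wells with mixed dilution factors within a batch/arm group.")
  }
  if ("droplet_volume" %in% names(data)) {
    dvs <- grouped %>%
      summarise(n_dv = n_distinct(.data$droplet_volume), .groups = "drop")
    if (any(dvs$n_dv > 1)) {
      abort("Cannot merge wells with mixed droplet volumes within a batch/arm group.")
    }
  }
  pooled <- grouped %>%
    summarise(
      accepted_droplets = sum(.data$accepted_droplets),
      positive_droplets = sum(.data$positive_droplets),
      dilution_factor = .data$dilution_factor[1],
      droplet_volume = if ("droplet_volume" %in% names(data))
        .data$droplet_volume[1] else 8.5e-4,
      wells_used = n(),
      .groups = "drop"
    )
  est <- quantify_well(
    pooled$positive_droplets, pooled$accepted_droplets,
    dilution_factor = pooled$dilution_factor,
    droplet_volume = pooled$droplet_volume,
    wells_used = pooled$wells_used,
    ...
  )
  dplyr::bind_cols(pooled[c("batch_id", "arm", "dilution_factor")], est)
}

validate_droplet_records <- function(data, call = rlang::caller_env()) {
  needed <- c("accepted_droplets", "positive_droplets", "dilution_factor")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Droplet records lack column(s): ",
                 paste(missing_cols, collapse = ", ")), call = call)
  }
  if (!"batch_id" %in% names(data)) data$batch_id <- "B01"
  if (!"arm" %in% names(data)) data$arm <- "untreated"
  invisible(data)
}

#' Fit assay efficiency from a dilution series
#'
#' Given measured copy numbers at a set of dilution fractions of a
#' reference sample, computes the theoretical copies at each fraction
#' (`reference * fraction`, anchored at fraction 1), fits measured on
#' theoretical by ordinary least squares, and reports the slope as an
#' efficiency percentage together with the fit's R-squared. Efficiencies
#' within 90-105% are flagged as acceptable.
#'
#' @param data A data frame with columns `dilution_fraction` (in (0, 1])
#'   and `measured` (copies, same units as `reference`).
#' @param reference Copies measured at fraction 1, the anchor of the
#'   theoretical series.
#' @param intercept Include an intercept in the regression (default TRUE);
#'   set FALSE to force the line through the origin.
#'
#' @return An object of class `efficiency_fit`; see [tidy()] and
#'   [glance()] methods.
#' @export
#' @examples
#' series <- tibble::tibble(
#'   dilution_fraction = c(1, 0.5, 0.25, 0.1, 0.025),
#'   measured = 1e4 * c(1, 0.5, 0.25, 0.1, 0.025)
#' )
#' glance(fit_efficiency(series, reference = 1e4))
fit_efficiency <- function(data, reference, intercept = TRUE) {
  if (!all(c("dilution_fraction", "measured") %in% names(data))) {
    abort("`data` needs columns `dilution_fraction` and `measured`.")
  }
  if (nrow(data) < 3) abort("An efficiency fit needs at least 3 series points.")
  if (any(data$dilution_fraction <= 0 | data$dilution_fraction > 1)) {
    abort("`dilution_fraction` values must lie in (0, 1].")
  }
  if (reference <= 0) abort("`reference` must be positive.")
  theoretical <- reference * data$dilution_fraction
  if (length(unique(theoretical)) < 2) {
    abort("Degenerate dilution series: all theoretical values identical.")
  }
  df <- tibble(theoretical = theoretical, measured = data$measured)
  fit <- if (intercept) lm(measured ~ theoretical, data = df)
         else lm(measured ~ theoretical + 0, data = df)
  slope <- unname(coef(fit)[["theoretical"]])
  eff <- 100 * slope
  structure(
    list(
      fit = fit,
      data = df,
      slope = slope,
      intercept = if (intercept) unname(coef(fit)[["(Intercept)"]]) else 0,
      efficiency_pct = eff,
      r_squared = suppressWarnings(summary(fit)$r.squared),
      within_limits = eff >= 90 && eff <= 105
    ),
    class = "efficiency_fit"
  )
}

#' @export
print.efficiency_fit <- function(x, ...) {
  cat(sprintf(
    "ddPCR assay efficiency fit\n  efficiency: %.2f%% (%s 90-105%% window)\n  R-squared:  %.4f\n  points:     %d\n",
    x$efficiency_pct, if (x$within_limits) "within" else "OUTSIDE",
    x$r_squared, nrow(x$data)
  ))
  invisible(x)
}

#' @export
tidy.efficiency_fit <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @export
glance.efficiency_fit <- function(x, ...) {
  tibble(
    efficiency_pct = x$efficiency_pct,
    r_squared = x$r_squared,
    within_limits = x$within_limits,
    n_points = nrow(x$data)
  )
}

#' @export
autoplot.efficiency_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$theoretical, y = .data$measured)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Theoretical copies", y = "Measured copies",
      title = sprintf("Assay efficiency %.2f%% (R² = %.4f)",
                      object$efficiency_pct, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}
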