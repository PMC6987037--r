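# Method-comparison statistics: per-batch CVs, Pearson correlation,
# regression against the identity line, and Bland-Altman relative
# differences with 95% limits of agreement.
#
# All statistics operate on the linear (non-log) counts-per-gram scale:
# probiotic potencies are labelled in scientific notation, and log
# transformation would artificially shrink the reported CVs.

#' Coefficient of variation of one batch's replicates
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean,
#' times 100, on the linear scale. Fewer than two non-missing replicates,
#' or a zero mean, yield `NA` (a flagged missing value).
#'
#' @param x Numeric vector of replicate measurements.
#' @return CV as a percentage, or `NA_real_`.
#' @export
#' @examples
#' per_batch_cv(c(100, 110, 120)) # 9.0909...
per_batch_cv <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  m <- mean(x)
  if (m == 0) return(NA_real_)
  sd(x) / m * 100
}

#' Summarise method consistency across batches
#'
#' Computes the per-batch CV of each method's replicates and averages it
#' over the batches of each stratum. The default strata reproduce the
#' layout of a method-variability table: all batches, the NCFM batches,
#' the non-NCFM batches, and each strain with at least `min_strain_n`
#' batches.
#'
#' @param data A measurement table: columns `batch_id`, `strain`,
#'   `method`, `replicate`, `count_per_g`.
#' @param methods Methods to summarise (default: all present, in
#'   canonical order).
#' @param strata Character vector of strata to report: any of `"All"`,
#'   `"NCFM"`, `"Non-NCFM"`, `"strain"`.
#' @param min_strain_n Minimum batches for a per-strain row (default 4).
#'
#' @return A tibble of class `consistency_summary`: `stratum`, `method`,
#'   `n_batches`, `mean_cv_pct`, `sd_cv_pct`.
#' @export
method_cv_summary <- function(data,
                              methods = NULL,
                              strata = c("All", "NCFM", "Non-NCFM", "strain"),
                              min_strain_n = 4) {
  validate_measurement_table(data)
  strata <- match.arg(strata, several.ok = TRUE)
  methods <- methods %||%
    intersect(DROPCOUNT_METHODS, unique(data$method))

  cvs <- data %>%
    filter(.data$method %in% methods) %>%
    group_by(.data$batch_id, .data$strain, .data$method) %>%
    summarise(cv = per_batch_cv(.data$count_per_g), .groups = "drop")

  summarise_stratum <- function(d, label) {
    if (nrow(d) == 0) return(NULL)
    d %>%
      group_by(.data$method) %>%
      summarise(
        n_batches = dplyr::n_distinct(.data$batch_id),
        mean_cv_pct = mean(.data$cv, na.rm = TRUE),
        sd_cv_pct = sd(.data$cv, na.rm = TRUE),
        .groups = "drop"
      ) %>%
      mutate(stratum = label, .before = 1)
  }

  out <- list()
  if ("All" %in% strata) {
    out <- c(out, list(summarise_stratum(cvs, "All")))
  }
  if ("NCFM" %in% strata) {
    out <- c(out, list(summarise_stratum(filter(cvs, .data$strain == "NCFM"),
                                         "NCFM")))
  }
  if ("Non-NCFM" %in% strata) {
    out <- c(out, list(summarise_stratum(filter(cvs, .data$strain != "NCFM"),
                                         "Non-NCFM")))
  }
  if ("strain" %in% strata) {
    eligible <- cvs %>%
      distinct(.data$strain, .data$batch_id) %>%
      count(.data$strain) %>%
      filter(.data$n >= min_strain_n) %>%
      pull(.data$strain)
    for (s in intersect(DROPCOUNT_STRAINS, eligible)) {
      out <- c(out, list(summarise_stratum(filter(cvs, .data$strain == s), s)))
    }
  }
  res <- bind_rows(out) %>%
    mutate(method = factor(.data$method, levels = DROPCOUNT_METHODS)) %>%
    arrange(match(.data$stratum, c("All", "NCFM", "Non-NCFM",
                                   DROPCOUNT_STRAINS)), .data$method) %>%
    mutate(method = as.character(.data$method))
  class(res) <- c("consistency_summary", class(res))
  res
}

#' Per-batch mean counts for one method
#'
#' Arithmetic mean of a method's replicates within each batch; batches
#' where every replicate is missing propagate `NA`. These per-batch values
#' are the inputs to the correlation, regression and Bland-Altman stages,
#' which compare one value per batch and method.
#'
#' @inheritParams method_cv_summary
#' @param method A single method label.
#' @return Tibble: `batch_id`, `strain`, `mean_count`.
#' @export
batch_means <- function(data, method) {
  validate_measurement_table(data)
  data %>%
    filter(.data$method == !!method) %>%
    group_by(.data$batch_id, .data$strain) %>%
    summarise(
      mean_count = if (all(is.na(.data$count_per_g))) NA_real_
                   else mean(.data$count_per_g, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Pearson correlation between two methods' per-batch values
#'
#' @param x,y Paired numeric vectors (one value per batch). Pairs with a
#'   missing member are dropped.
#' @return The product-moment correlation, or `NA` (with a warning) when
#'   fewer than 3 complete pairs remain or either vector is constant.
#' @export
pearson_r <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    warn("Fewer than 3 complete pairs: correlation undefined.")
    return(NA_real_)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Constant measurements: correlation undefined.")
    return(NA_real_)
  }
  cor(x, y)
}

#' Least-squares line of one method on another
#'
#' Ordinary least squares of `y` on `x`, where `x` is the first-named
#' method (the abscissa of an agreement scatter plot with its y = x
#' reference line). A slope of 1 and intercept of 0 indicate perfect
#' average agreement.
#'
#' @inheritParams pearson_r
#' @return One-row tibble: `slope`, `intercept`, `n_pairs`.
#' @export
regress_identity <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("Regression needs at least 3 complete pairs.")
  if (sd(x) == 0) abort("`x` is constant: regression undefined.")
  fit <- lm(y ~ x)
  tibble(
    slope = unname(coef(fit)[["x"]]),
    intercept = unname(coef(fit)[["(Intercept)"]]),
    n_pairs = length(x)
  )
}

#' Bland-Altman agreement on the relative-difference scale
#'
#' For each paired measurement the relative difference is
#' `d = (x - y) / ((x + y) / 2) * 100` (in percent; `x` is "Method 1").
#' Agreement is summarised by the mean relative difference and the 95%
#' limits of agreement `mean(d) +/- 1.96 * sd(d)` (sample SD, n - 1).
#' Swapping the arguments negates the mean and swaps-and-negates the
#' limits. Pairs whose sum is zero have an undefined relative difference
#' and are excluded with a warning.
#'
#' @inheritParams pearson_r
#' @param loa_multiplier Multiplier for the limits of agreement
#'   (1.96 for the conventional 95% limits).
#' @return One-row tibble: `mean_rel_diff_pct`, `sd_rel_diff_pct`,
#'   `loa_low_pct`, `loa_high_pct`, `n_pairs`, `n_excluded`.
#' @export
#' @examples
#' bland_altman(c(100, 80, 90), c(120, 80, 110))
bland_altman <- function(x, y, loa_multiplier = 1.96) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  zero_sum <- (x + y) == 0
  if (any(zero_sum)) {
    warn(sprintf("Excluding %d pair(s) with zero sum: relative difference undefined.",
                 sum(zero_sum)))
    x <- x[!zero_sum]; y <- y[!zero_sum]
  }
  if (length(x) < 2) abort("Bland-Altman needs at least 2 usable pairs.")
  d <- (x - y) / ((x + y) / 2) * 100
  m <- mean(d)
  s <- sd(d)
  tibble(
    mean_rel_diff_pct = m,
    sd_rel_diff_pct = s,
    loa_low_pct = m - loa_multiplier * s,
    loa_high_pct = m + loa_multiplier * s,
    n_pairs = length(d),
    n_excluded = sum(zero_sum)
  )
}

#' Pairwise agreement between all methods of a measurement table
#'
#' For every pair of methods (ordered by the canonical method sequence,
#' so `Plate` is "Method 1" against any PCR or flow method) computes the
#' Pearson correlation of per-batch means, the least-squares line of the
#' second method on the first, and the Bland-Altman relative-difference
#' summary. Batches missing either method are dropped pairwise and
#' counted.
#'
#' @inheritParams method_cv_summary
#' @param loa_multiplier Passed to [bland_altman()].
#' @return A tibble of class `pair_agreement`, one row per method pair:
#'   `method_x`, `method_y`, `n_pairs`, `pearson_r`, `slope`,
#'   `intercept`, `mean_rel_diff_pct`, `sd_rel_diff_pct`, `loa_low_pct`,
#'   `loa_high_pct`, `n_dropped`.
#' @export
compare_methods <- function(data, methods = NULL, loa_multiplier = 1.96) {
  validate_measurement_table(data)
  methods <- methods %||%
    intersect(DROPCOUNT_METHODS, unique(data$method))
  if (length(methods) < 2) {
    abort("Agreement analysis needs at least two methods.")
  }
  means <- purrr::map(setNames(methods, methods),
                      function(m) batch_means(data, m))
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  res <- purrr::map_dfr(pairs, function(pr) {
    mx <- means[[pr[1]]]; my <- means[[pr[2]]]
    joined <- inner_join(mx, my, by = c("batch_id", "strain"),
                         suffix = c("_x", "_y"))
    ok <- stats::complete.cases(joined$mean_count_x, joined$mean_count_y)
    n_dropped <- nrow(joined) - sum(ok)
    if (n_dropped > 0) {
      inform(sprintf("%s vs %s: dropping %d batch(es) with missing values.",
                     pr[1], pr[2], n_dropped))
    }
    x <- joined$mean_count_x[ok]
    y <- joined$mean_count_y[ok]
    reg <- regress_identity(x, y)
    ba <- bland_altman(x, y, loa_multiplier)
    tibble(
      method_x = pr[1], method_y = pr[2],
      n_pairs = length(x),
      pearson_r = pearson_r(x, y),
      slope = reg$slope, intercept = reg$intercept,
      n_dropped = n_dropped
    ) %>%
      dplyr::bind_cols(ba[c("mean_rel_diff_pct", "sd_rel_diff_pct",
                            "loa_low_pct", "loa_high_pct")])
  })
  class(res) <- c("pair_agreement", class(res))
  res
}

#' @export
tidy.pair_agreement <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
glance.consistency_summary <- function(x, ...) {
  as_tibble(unclass(x)) %>%
    filter(.data$stratum == "All")
}

validate_measurement_table <- function(data, call = rlang::caller_env()) {
  needed <- c("batch_id", "strain", "method", "replicate", "count_per_g")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Measurement table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")), call = call)
  }
  dup <- data %>%
    count(.data$batch_id, .data$method, .data$replicate) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort("Measurement table has duplicated (batch, method, replicate) rows.",
          call = call)
  }
  invisible(data)
}
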