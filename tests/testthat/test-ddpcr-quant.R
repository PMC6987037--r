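# Poisson occupancy quantification, well merging, confidence intervals
# and the dilution-series efficiency fit.

test_that("quantify_well matches the closed-form occupancy transform", {
  # half the droplets positive: lambda = ln 2, 815.47 copies/uL at the
  # nominal 8.5e-4 uL droplet
  est <- quantify_well(5000, 10000, dilution_factor = 1)
  expect_equal(est$copies_per_droplet, log(2), tolerance = 1e-10)
  expect_equal(est$copies_per_ul_reaction, 815.4673, tolerance = 1e-4)
  expect_false(est$saturated)
  # no positives: zero everywhere, zero lower bound
  z <- quantify_well(0, 20000)
  expect_equal(z$copies_per_droplet, 0)
  expect_equal(z$count_per_g, 0)
  expect_equal(z$ci_low, 0)
  expect_false(z$below_min_droplets)
})

test_that("saturated wells are flagged and censored, empty wells error", {
  s <- quantify_well(10000, 10000)
  expect_true(s$saturated)
  expect_true(is.na(s$count_per_g))
  expect_true(is.finite(s$ci_low) && s$ci_low > 0) # one-sided lower bound
  expect_error(quantify_well(0, 0), "no partitions")
  expect_error(quantify_well(11, 10), "positive_droplets")
})

test_that("count_per_g is strictly increasing in positive droplets", {
  pos <- seq(0, 19999, by = 97)
  est <- quantify_well(pos, 20000)
  expect_true(all(diff(est$count_per_g) > 0))
})

test_that("the dilution chain scales estimates linearly", {
  e1 <- quantify_well(3000, 20000, dilution_factor = 1)
  e2 <- quantify_well(3000, 20000, dilution_factor = 1000)
  expect_equal(e2$count_per_g, 1000 * e1$count_per_g)
  # copies-per-cell divides through
  e3 <- quantify_well(3000, 20000, copies_per_cell = 2)
  expect_equal(e3$count_per_g, e1$count_per_g / 2)
})

test_that("merge_wells pools droplets and conserves totals", {
  wells <- tibble::tibble(
    batch_id = "B01", arm = "treated",
    accepted_droplets = c(10000L, 10000L, 10000L),
    positive_droplets = c(100L, 110L, 90L),
    dilution_factor = 1, droplet_volume = 8.5e-4
  )
  merged <- merge_wells(wells)
  expect_equal(merged$accepted_droplets, 30000L)
  expect_equal(merged$positive_droplets, 300L)
  expect_equal(merged$wells_used, 3L)
  expect_equal(merged$count_per_g, quantify_well(300, 30000)$count_per_g)
  # identical wells: pooling equals any single well
  same <- wells |> dplyr::mutate(positive_droplets = 100L)
  expect_equal(merge_wells(same)$count_per_g,
               quantify_well(100, 10000)$count_per_g)
  # mixed dilution factors are not poolable
  bad <- wells
  bad$dilution_factor <- c(1, 1, 10)
  expect_error(merge_wells(bad), "mixed dilution")
})

test_that("merging conserves sums across randomized well groups", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      n <- sample(2:6, 1)
      wells <- tibble::tibble(
        batch_id = "B01", arm = sample(c("treated", "untreated"), 1),
        accepted_droplets = sample(12000:20000, n, replace = TRUE),
        positive_droplets = 0L, dilution_factor = 10^sample(0:4, 1)
      )
      wells$positive_droplets <-
        as.integer(rbinom(n, wells$accepted_droplets, runif(1, 0.01, 0.95)))
      merged <- merge_wells(wells)
      expect_equal(merged$accepted_droplets, sum(wells$accepted_droplets))
      expect_equal(merged$positive_droplets, sum(wells$positive_droplets))
    }
  })
})

test_that("pooled and averaged estimates converge at small occupancy", {
  # linearisation oracle: for lambda -> 0, -ln(1-p) ~ p, so pooling and
  # averaging agree to first order; the gap shrinks with lambda
  gap <- sapply(c(1.5, 0.15, 0.015), function(lambda) {
    wells <- simulate_ddpcr_wells(
      one_batch(lambda / 8.5e-4 * 1e4), "untreated", dilution_factor = 1,
      n_wells = 3, droplets_per_well = 20000,
      noise = noise_model(ddpcr_extra_rel_sd = 0), seed = 7
    )
    pooled <- merge_wells(wells)$count_per_g
    averaged <- mean(quantify_wells(wells)$count_per_g)
    abs(pooled - averaged) / averaged
  })
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[3], 1e-4)
})

test_that("Wilson intervals narrow with droplet number and order with p", {
  wide <- quantify_well(500, 2000)
  narrow <- quantify_well(5000, 20000)
  expect_gt(wide$ci_high - wide$ci_low, narrow$ci_high - narrow$ci_low)
  expect_true(narrow$ci_low <= narrow$count_per_g &&
                narrow$count_per_g <= narrow$ci_high)
  expect_true(wide$below_min_droplets)
})

test_that("quantification inverts simulation with small bias", {
  # recovery across the working occupancy range: 3 pooled wells of
  # 20,000 droplets, 120 replicates per lambda
  dv <- 8.5e-4
  for (lambda in c(0.05, 0.7, 3)) {
    true_count <- lambda / dv * 1e4
    est <- withr::with_seed(100 + round(100 * lambda), {
      replicate(120, {
        pos <- rbinom(3, 20000, 1 - exp(-lambda))
        merge_wells(tibble::tibble(
          batch_id = "B", arm = "treated",
          accepted_droplets = rep(20000L, 3), positive_droplets = pos,
          dilution_factor = 1
        ))$count_per_g
      })
    })
    expect_lt(abs(mean(est) / true_count - 1), 0.02)
  }
})

test_that("efficiency fits recover exact and scaled series", {
  fr <- c(1, 0.5, 0.25, 0.1, 0.025)
  ref <- 1e4
  perfect <- fit_efficiency(
    tibble::tibble(dilution_fraction = fr, measured = ref * fr), ref
  )
  expect_equal(perfect$efficiency_pct, 100, tolerance = 1e-8)
  expect_equal(perfect$r_squared, 1, tolerance = 1e-10)
  expect_true(perfect$within_limits)

  half <- fit_efficiency(
    tibble::tibble(dilution_fraction = fr, measured = 0.5 * ref * fr), ref
  )
  expect_equal(half$efficiency_pct, 50, tolerance = 1e-8)
  expect_false(half$within_limits)

  g <- glance(half)
  expect_equal(g$efficiency_pct, 50, tolerance = 1e-8)
  td <- tidy(perfect)
  expect_equal(td$estimate[td$term == "slope"], 1, tolerance = 1e-8)
})

test_that("efficiency fit rejects degenerate input", {
  expect_error(
    fit_efficiency(tibble::tibble(dilution_fraction = c(1, 0.5),
                                  measured = c(1, 2)), 10),
    "at least 3"
  )
  expect_error(
    fit_efficiency(tibble::tibble(dilution_fraction = c(1, 1, 1),
                                  measured = c(1, 2, 3)), 10),
    "Degenerate"
  )
  expect_error(
    fit_efficiency(tibble::tibble(dilution_fraction = c(2, 1, 0.5),
                                  measured = c(1, 2, 3)), 10),
    "\\(0, 1\\]"
  )
})

test_that("efficiency is ~100% under pure partition sampling", {
  # simulate an unbiased dilution series, quantify, refit
  dv <- 8.5e-4
  fr <- c(1, 0.5, 0.25, 0.1, 0.05, 0.025)
  ref_lambda <- 2
  meas <- withr::with_seed(31, sapply(fr, function(f) {
    pos <- rbinom(1, 200000, 1 - exp(-ref_lambda * f))
    quantify_well(pos, 200000, droplet_volume = dv)$copies_per_ul_reaction
  }))
  fit <- fit_efficiency(
    tibble::tibble(dilution_fraction = fr, measured = meas),
    reference = ref_lambda / dv
  )
  expect_equal(fit$efficiency_pct, 100, tolerance = 0.02)
  expect_gt(fit$r_squared, 0.999)
})
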