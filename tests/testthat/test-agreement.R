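# Consistency (CV) and agreement (Pearson, regression, Bland-Altman).

test_that("per-batch CV matches hand computations and edge rules", {
  expect_equal(per_batch_cv(c(5, 5, 5)), 0)
  # sd = 10, mean = 110 -> 9.0909...%
  expect_equal(per_batch_cv(c(100, 110, 120)), 100 * 10 / 110,
               tolerance = 1e-10)
  expect_true(is.na(per_batch_cv(c(42))))
  expect_true(is.na(per_batch_cv(c(0, 0, 0))))
  expect_true(is.na(per_batch_cv(c(NA, 7))))
})

test_that("CV is invariant under positive rescaling", {
  withr::with_seed(19, {
    for (rep in 1:15) {
      x <- runif(5, 10, 1000)
      c1 <- per_batch_cv(x)
      for (k in c(1e-6, 3.7, 1e9)) {
        expect_equal(per_batch_cv(k * x), c1, tolerance = 1e-9)
      }
    }
  })
})

test_that("method_cv_summary averages batch CVs within strata", {
  # three batches with replicate sets engineered to CVs of 2, 3, 4%
  mk <- function(id, cv) {
    s <- cv / 100 * 100 # mean 100
    tibble::tibble(batch_id = id, strain = ifelse(id == "B03", "Bi-07",
                                                  "NCFM"),
                   method = "Plate", replicate = 1:2,
                   count_per_g = c(100 - s / sqrt(2), 100 + s / sqrt(2)))
  }
  tab <- dplyr::bind_rows(mk("B01", 2), mk("B02", 3), mk("B03", 4))
  out <- method_cv_summary(tab, strata = c("All", "NCFM", "Non-NCFM"))
  all_row <- out[out$stratum == "All", ]
  expect_equal(all_row$mean_cv_pct, 3, tolerance = 1e-6)
  expect_equal(all_row$sd_cv_pct, 1, tolerance = 1e-6)
  expect_equal(all_row$n_batches, 3L)
  expect_equal(out$mean_cv_pct[out$stratum == "NCFM"], 2.5, tolerance = 1e-6)
  expect_equal(out$mean_cv_pct[out$stratum == "Non-NCFM"], 4, tolerance = 1e-6)
})

test_that("batch_means averages replicates and propagates missingness", {
  tab <- tibble::tibble(
    batch_id = c("B01", "B01", "B02", "B03"), strain = "NCFM",
    method = "Plate", replicate = c(1L, 2L, 1L, 1L),
    count_per_g = c(100, 120, 80, NA)
  )
  m <- batch_means(tab, "Plate")
  expect_equal(m$mean_count[m$batch_id == "B01"], 110)
  expect_equal(m$mean_count[m$batch_id == "B02"], 80)
  expect_true(is.na(m$mean_count[m$batch_id == "B03"]))
})

test_that("pearson_r reproduces hand-computed correlations", {
  expect_equal(pearson_r(1:5, 2 * (1:5) + 1), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  # covariance 1, variances 5/3 each -> r = 0.6
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_warning(r <- pearson_r(c(1, 1, 1), c(1, 2, 3)), "Constant")
  expect_true(is.na(r))
})

test_that("pearson_r is invariant under positive affine transforms", {
  withr::with_seed(23, {
    x <- rnorm(20); y <- rnorm(20)
    base <- pearson_r(x, y)
    expect_equal(pearson_r(3 * x + 7, y), base, tolerance = 1e-12)
    expect_equal(pearson_r(x, 0.2 * y - 5), base, tolerance = 1e-12)
  })
})

test_that("regress_identity returns the least-squares line of y on x", {
  x <- c(1, 2, 3, 4, 5)
  fit <- regress_identity(x, x)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  half <- regress_identity(x, 0.5 * x)
  expect_equal(half$slope, 0.5, tolerance = 1e-12)
  expect_error(regress_identity(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("bland_altman matches the worked example", {
  ba <- bland_altman(c(100, 80, 90), c(120, 80, 110))
  expect_equal(ba$mean_rel_diff_pct, -12.727273, tolerance = 1e-6)
  expect_equal(ba$sd_rel_diff_pct, 11.059568, tolerance = 1e-6)
  expect_equal(ba$loa_low_pct, -34.404026, tolerance = 1e-6)
  expect_equal(ba$loa_high_pct, 8.949481, tolerance = 1e-6)
  # identical measurements agree perfectly
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mean_rel_diff_pct, 0)
  expect_equal(c(same$loa_low_pct, same$loa_high_pct), c(0, 0))
})

test_that("bland_altman is antisymmetric and bounded", {
  withr::with_seed(29, {
    for (rep in 1:10) {
      x <- runif(15, 1, 100); y <- runif(15, 1, 100)
      ab <- bland_altman(x, y)
      ba <- bland_altman(y, x)
      expect_equal(ab$mean_rel_diff_pct, -ba$mean_rel_diff_pct,
                   tolerance = 1e-12)
      expect_equal(ab$loa_low_pct, -ba$loa_high_pct, tolerance = 1e-12)
      expect_equal(ab$loa_high_pct, -ba$loa_low_pct, tolerance = 1e-12)
      # every relative difference lies in [-200, 200] by construction
      d <- (x - y) / ((x + y) / 2) * 100
      expect_true(all(abs(d) <= 200))
    }
  })
})

test_that("LOA contain ~95% of normal relative differences", {
  withr::with_seed(37, {
    base <- runif(4000, 50, 150)
    x <- base * (1 + rnorm(4000, 0, 0.02))
    y <- base * (1 + rnorm(4000, 0, 0.02))
    ba <- bland_altman(x, y)
    d <- (x - y) / ((x + y) / 2) * 100
    inside <- mean(d >= ba$loa_low_pct & d <= ba$loa_high_pct)
    expect_equal(inside, 0.95, tolerance = 0.01)
  })
})

test_that("zero-sum pairs are excluded with a warning", {
  expect_warning(
    ba <- bland_altman(c(0, 10, 20), c(0, 12, 18)),
    "zero sum"
  )
  expect_equal(ba$n_pairs, 2L)
  expect_equal(ba$n_excluded, 1L)
})

test_that("compare_methods orients pairs and matches its building blocks", {
  tab <- toy_table()
  agg <- quiet_compare(tab)
  expect_s3_class(agg, "pair_agreement")
  expect_equal(nrow(agg), 1) # one pair
  expect_equal(agg$method_x, "Plate") # Plate is Method 1
  mx <- batch_means(tab, "Plate")$mean_count
  my <- batch_means(tab, "PCR.live")$mean_count
  expect_equal(agg$pearson_r, pearson_r(mx, my))
  expect_equal(agg$slope, regress_identity(mx, my)$slope)
  expect_equal(agg$mean_rel_diff_pct,
               bland_altman(mx, my)$mean_rel_diff_pct)
  # PCR.live reads 20% high by construction: negative relative difference
  expect_lt(agg$mean_rel_diff_pct, 0)
})

test_that("all 15 pairs are reported for a six-method table", {
  sim <- simulate_study(seed = 2)
  tab <- run_quantify(pipeline_config(seed = 2), sim = sim)
  agg <- quiet_compare(tab)
  expect_equal(nrow(agg), choose(6, 2))
  expect_true(all(abs(agg$pearson_r) <= 1))
  expect_true(all(agg$loa_low_pct <= agg$mean_rel_diff_pct &
                    agg$mean_rel_diff_pct <= agg$loa_high_pct))
})
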