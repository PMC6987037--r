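# Ground-truth generation and the three measurement-process simulators.

test_that("generate_study reproduces the study's strain composition", {
  truth <- generate_study(seed = 1)
  expect_equal(nrow(truth), 50)
  comp <- table(truth$strain)
  expect_equal(unname(comp[["NCFM"]]), 20)
  expect_equal(unname(comp[["Bi-07"]]), 9)
  expect_equal(unname(comp[["Lp-115"]]), 8)
  expect_equal(unname(comp[["HN019"]]), 8)
  expect_equal(unname(comp[["Bl-04"]]), 3)
  expect_equal(unname(comp[["La-14"]]), 2)
  expect_true(all(truth$live_conc > 0))
  expect_true(all(truth$dead_conc >= 0))
})

test_that("generate_study handles minimal designs and rejects empty ones", {
  d <- study_design(n_batches_per_strain = c("Bl-04" = 1))
  truth <- generate_study(d, seed = 3)
  expect_equal(nrow(truth), 1)
  expect_equal(truth$strain, "Bl-04")
  expect_error(study_design(n_batches_per_strain = c("Bl-04" = 0)),
               "at least one batch")
  expect_error(study_design(n_batches_per_strain = c("EC-12" = 5)),
               "Unknown strain")
  expect_error(study_design(plate_replicates = 0), ">= 1")
})

test_that("identical seeds give identical outputs, different seeds differ", {
  expect_identical(generate_study(seed = 11), generate_study(seed = 11))
  expect_false(identical(generate_study(seed = 11)$live_conc,
                         generate_study(seed = 12)$live_conc))
  s1 <- simulate_study(seed = 5)
  s2 <- simulate_study(seed = 5)
  expect_identical(s1$plate, s2$plate)
  expect_identical(s1$ddpcr, s2$ddpcr)
  expect_identical(s1$flow, s2$flow)
})

test_that("plate simulator mean follows the configured Poisson mean", {
  # live 1e9/g, level 1e-7, 1 mL plated: mean 100 per plate when one gram
  # maps to one mL of suspension, and 10 under the default 1:10 chain
  s <- simulate_plate_series(one_batch(1e9), 1e-7, n_plates = 10000,
                             plate_rel_sd = 0, suspension_ml_per_g = 1,
                             seed = 2)
  expect_equal(mean(s$colonies), 100, tolerance = 0.01)
  s10 <- simulate_plate_series(one_batch(1e9), 1e-7, n_plates = 2000,
                               plate_rel_sd = 0, seed = 2)
  expect_equal(mean(s10$colonies), 10, tolerance = 0.05)
  # zero concentration -> all plates sterile
  s0 <- simulate_plate_series(one_batch(0), 1e-6, n_plates = 20, seed = 1)
  expect_true(all(s0$colonies == 0))
})

test_that("ddPCR simulator converges to the closed-form occupancy", {
  # m = 0.1 copies per droplet: expect 20000 * (1 - e^-0.1) ~ 1903.25
  # positives per well (oracle: closed-form occupancy probability)
  m <- 0.1
  dv <- 8.5e-4
  live <- m / dv * 1e4 # per gram, default chain, dilution 1
  wells <- simulate_ddpcr_wells(one_batch(live), "untreated",
                                dilution_factor = 1, n_wells = 1000,
                                droplets_per_well = 20000,
                                noise = noise_model(ddpcr_extra_rel_sd = 0),
                                seed = 4)
  expect_equal(mean(wells$positive_droplets), 20000 * (1 - exp(-0.1)),
               tolerance = 0.01)
  # m = 0 -> no positives
  z <- simulate_ddpcr_wells(one_batch(0), "untreated", dilution_factor = 1,
                            n_wells = 50, seed = 1)
  expect_true(all(z$positive_droplets == 0))
})

test_that("treatment arms coincide without dead cells and order with them", {
  tr <- one_batch(1e11, dead = 0)
  a <- simulate_ddpcr_wells(tr, "treated", 1e4, n_wells = 200, seed = 9)
  b <- simulate_ddpcr_wells(tr, "untreated", 1e4, n_wells = 200, seed = 9)
  # same seed, same effective concentration: identical draws
  expect_identical(a$positive_droplets, b$positive_droplets)

  trd <- one_batch(1e11, dead = 5e10)
  at <- simulate_ddpcr_wells(trd, "treated", 1e4, n_wells = 500, seed = 10)
  au <- simulate_ddpcr_wells(trd, "untreated", 1e4, n_wells = 500, seed = 11)
  expect_gt(mean(au$positive_droplets), mean(at$positive_droplets))
})

test_that("flow simulator respects gate additivity and the configured CV", {
  tr <- one_batch(1e11, dead = 2e10)
  f <- simulate_flow(tr, n_replicates = 1000, seed = 6)
  expect_identical(f$total_events, f$live_events + f$dead_events)
  cv <- sd(f$live_events) / mean(f$live_events) * 100
  expect_equal(cv, 3, tolerance = 0.12)
  # no dead cells and no misgating: dead gate empty
  f0 <- simulate_flow(one_batch(1e11, dead = 0),
                      noise = noise_model(flow_live_misgate = 0),
                      n_replicates = 10, seed = 2)
  expect_true(all(f0$dead_events == 0))
  expect_identical(f0$total_events, f0$live_events)
})

test_that("batch sub-streams make simulation order irrelevant", {
  truth <- generate_study(seed = 3)
  i <- 37
  centre <- dropcount:::choose_plate_dilution(truth$live_conc[i])
  solo <- simulate_plate_series(
    truth[i, ], unique(pmin(centre * c(10, 1, 0.1), 1)), n_plates = 17,
    seed = dropcount:::subseed(3, truth$batch_id[i], "plate")
  )
  full <- simulate_study(seed = 3)
  got <- full$plate[full$plate$batch_id == truth$batch_id[i], ]
  expect_equal(solo$colonies, got$colonies)
  expect_equal(solo$dilution_level, got$dilution_level)
})
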