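test_that("identical inputs and seed give bit-identical wells", {
  cfg <- sim_config()
  w1 <- simulate_well(235.4, cfg, seed = 11)
  w2 <- simulate_well(235.4, cfg, seed = 11)
  expect_identical(w1$amplitudes, w2$amplitudes)
  w3 <- simulate_well(235.4, cfg, seed = 12)
  expect_false(identical(w1$amplitudes, w3$amplitudes))
})

test_that("an empty reaction without false positives has no positive droplets", {
  cfg <- sim_config(false_positive_rate = 0)
  w <- simulate_well(0, cfg, seed = 5)
  expect_equal(sum(w$amplitudes > cfg$neg_mean + 5 * cfg$neg_sd), 0)
  expect_equal(w$accepted_count, round(cfg$n_droplets_generated * cfg$accepted_fraction))
})

test_that("positive fraction matches the closed-form occupancy probability", {
  cfg <- sim_config()
  w <- simulate_well(235.4, cfg, seed = 7)
  p_expected <- 1 - exp(-235.4 * 0.00085)   # 0.1813
  p_obs <- mean(w$amplitudes > 3400)
  expect_lt(abs(p_obs - p_expected),
            binom99_halfwidth(p_expected, w$accepted_count))
})

test_that("negative concentration is rejected", {
  expect_error(simulate_well(-1, sim_config(), seed = 1), "non-negative")
})

test_that("without rain and false positives every amplitude sits in a cluster", {
  cfg <- sim_config(rain_fraction = 0, false_positive_rate = 0)
  w <- simulate_well(500, cfg, seed = 3)
  near_neg <- abs(w$amplitudes - cfg$neg_mean) <= 5 * cfg$neg_sd
  near_pos <- abs(w$amplitudes - cfg$pos_mean) <= 5 * cfg$pos_sd
  expect_true(all(near_neg | near_pos))
})

test_that("positive fraction converges to 1 - exp(-cV) at large droplet counts", {
  cfg <- sim_config(n_droplets_generated = 1e6, accepted_fraction = 1,
                    rain_fraction = 0, false_positive_rate = 0)
  for (conc in c(50, 500)) {
    w <- simulate_well(conc, cfg, seed = 21 + conc)
    p_exp <- 1 - exp(-conc * 0.00085)
    expect_lt(abs(mean(w$amplitudes > 3400) - p_exp) / p_exp, 0.01)
  }
})

test_that("dilution series fixture matches its design", {
  ds <- simulate_dilution_series(120440, c(1, 5.5, 30.6, 170, 624), 3,
                                 sim_config(), seed = 2)
  expect_length(ds$wells, 15)
  expect_equal(nrow(ds$truth), 15)
  expect_equal(max(ds$truth$true_copies_per_reaction), 120440)
  expect_equal(min(round(ds$truth$true_copies_per_reaction)), 193)
  by_level <- unique(ds$truth[, c("dilution_factor", "true_copies_per_reaction")])
  by_level <- by_level[order(by_level$dilution_factor), ]
  expect_true(all(diff(by_level$true_copies_per_reaction) < 0))
  single <- simulate_dilution_series(100, 1, 1, sim_config(), seed = 2)
  expect_length(single$wells, 1)
  expect_equal(single$truth$true_copies_per_reaction, 100)
  expect_error(simulate_dilution_series(100, numeric(), 1, sim_config(), seed = 2),
               "non-empty")
  expect_error(simulate_dilution_series(100, c(1, 0.5), 1, sim_config(), seed = 2),
               ">= 1")
})

test_that("spike-in truth respects its generative arithmetic", {
  ex0 <- simulate_spikein_experiment(true_recovery = 0, background_acn = 300,
                                     replicates = 1, seed = 4)
  spike <- ex0$truth[ex0$truth$arm == "spike", ]
  buffer <- ex0$truth[ex0$truth$arm == "buffer", ]
  expect_equal(spike$true_copies_per_reaction, buffer$true_copies_per_reaction)
  ex1 <- simulate_spikein_experiment(true_recovery = 1, background_acn = 0,
                                     replicates = 1, seed = 4)
  spike1 <- ex1$truth[ex1$truth$arm == "spike", ]
  alone1 <- ex1$truth[ex1$truth$arm == "alone", ]
  expect_equal(spike1$true_copies_per_reaction, alone1$true_copies_per_reaction)
})

test_that("lossless spike-in yields ~100% recovery downstream", {
  ex <- simulate_spikein_experiment(spike_ge_levels = 232000,
                                    true_recovery = 1, background_acn = 0,
                                    replicates = 2,
                                    cfg = sim_config(rain_fraction = 0,
                                                     false_positive_rate = 0),
                                    seed = 9)
  acn <- function(arm) {
    w <- Filter(function(x) startsWith(x$sample_id, arm), ex$wells)
    mean(vapply(w, function(x) quantify_well(x, 3400)$copies_per_reaction,
                numeric(1)))
  }
  r <- spike_recovery(acn("spike"), acn("buffer"), acn("alone"))
  expect_lt(abs(r$recovery_pct - 100), 3)
})

test_that("longitudinal study emits the designed well and sheet layout", {
  des <- study_design(subjects = c("A", "B", "C"), timepoints = 1:10)
  sim <- simulate_longitudinal_study(des, sim_config(), seed = 6)
  expect_length(sim$wells, 3 * 10 * 2 + 4)
  expect_equal(sum(!sim$sample_sheet$is_ntc), 60)
  expect_equal(sum(sim$sample_sheet$is_ntc), 4)
  expect_equal(nrow(sim$truth), 30)
})

test_that("noise-free duplicate wells share the closed-form positive fraction", {
  des <- study_design(subjects = "A", timepoints = 1, log_variation_sd = 0,
                      extraction_cv = 0)
  cfg <- sim_config(rain_fraction = 0, false_positive_rate = 0)
  sim <- simulate_longitudinal_study(des, cfg, seed = 8)
  conc <- sim$truth$true_copies_per_ul_reaction[1]
  p_exp <- 1 - exp(-conc * 0.00085)
  for (w in sim$wells[1:2]) {
    expect_lt(abs(mean(w$amplitudes > 3400) - p_exp),
              binom99_halfwidth(p_exp, w$accepted_count))
  }
})

test_that("longitudinal sample sheet round-trips losslessly", {
  sim <- simulate_longitudinal_study(study_design(subjects = "A", timepoints = 1:2),
                                     sim_config(), seed = 13)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sample_sheet(sim$sample_sheet, path)
  back <- read_sample_sheet(path)
  expect_equal(back$sample_id, sim$sample_sheet$sample_id)
  expect_equal(back$stool_mass_mg, sim$sample_sheet$stool_mass_mg,
               tolerance = 1e-12)
  expect_equal(back$is_ntc, sim$sample_sheet$is_ntc)
})

test_that("preservation time course follows exponential decay truth", {
  tc <- simulate_preservation_timecourse(
    buffers = "EDTA", decay_rate_per_hour = c(EDTA = 0.01),
    baseline_copies_per_ul_extract = 1e5, seed = 10)
  t96 <- tc$truth$true_copies_per_ul_extract[tc$truth$time_h == 96]
  t0 <- tc$truth$true_copies_per_ul_extract[tc$truth$time_h == 0]
  expect_equal(t96 / t0, exp(-0.96), tolerance = 1e-12)

  growth <- simulate_preservation_timecourse(
    buffers = "EDTA", decay_rate_per_hour = c(EDTA = -0.005), seed = 10)
  ord <- order(growth$truth$time_h)
  expect_true(all(diff(growth$truth$true_copies_per_ul_extract[ord]) > 0))

  expect_error(simulate_preservation_timecourse(timepoints_hours = c(4, 24),
                                                seed = 1),
               "time 0")
})

test_that("OMNI buffer is simulated with single extractions", {
  tc <- simulate_preservation_timecourse(buffers = c("EDTA", "OMNI"),
                                         timepoints_hours = c(0, 4), seed = 1)
  ids <- vapply(tc$wells, `[[`, character(1), "sample_id")
  expect_equal(sum(startsWith(ids, "EDTA")), 4)  # duplicates
  expect_equal(sum(startsWith(ids, "OMNI")), 2)  # singles
})
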