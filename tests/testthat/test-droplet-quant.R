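test_that("QC partitions wells at the inclusive 10,000-droplet minimum", {
  w_low <- constant_well(1800, 9999, "A01")
  w_edge <- constant_well(1800, 10000, "A02")
  res <- qc_filter(list(w_low, w_edge))
  expect_length(res$accepted, 1)
  expect_equal(res$accepted[[1]]$well_id, "A02")
  expect_equal(res$rejected$well_id, "A01")
  expect_match(res$rejected$reason, "9999")
  empty <- qc_filter(list())
  expect_length(empty$accepted, 0)
  expect_equal(nrow(empty$rejected), 0)
})

test_that("droplets are positive only strictly above the threshold", {
  w <- droplet_well("A01", "S", "LINE1_60", c(2000, 3400, 5000))
  cts <- call_droplets(w, 3400)
  expect_equal(cts$positives, 1)
  expect_equal(cts$negatives, 2)
  expect_equal(cts$threshold_used, 3400)
  all_neg <- call_droplets(droplet_well("A02", "S", "LINE1_60", c(100, 200)), 3400)
  expect_equal(all_neg$positives, 0)
  expect_error(call_droplets(droplet_well("A03", "S", "LINE1_60", numeric()), 3400),
               "no droplets")
})

test_that("raising the threshold never increases the positive count", {
  set.seed(41)
  for (i in 1:20) {
    amps <- runif(500, 0, 8000)
    w <- droplet_well("W", "S", "A", amps)
    thresholds <- sort(runif(10, 500, 7500))
    pos <- vapply(thresholds, function(t) call_droplets(w, t)$positives,
                  numeric(1))
    expect_true(all(diff(pos) <= 0))
    # brute-force agreement
    expect_equal(pos, vapply(thresholds, function(t) sum(amps > t), numeric(1)))
  }
})

test_that("NTC-derived threshold is multiplier x 99.9th percentile, pooled", {
  ntc <- constant_well(1800, 100, "H01", "NTC")
  expect_equal(threshold_from_ntc(ntc), 2160)
  # pooling contract: two wells together equal one concatenated well
  a <- droplet_well("H01", "NTC", "A", c(rep(1500, 50), rep(1900, 50)))
  b <- droplet_well("H02", "NTC", "A", rep(1700, 100))
  pooled <- droplet_well("H03", "NTC", "A", c(a$amplitudes, b$amplitudes))
  expect_equal(threshold_from_ntc(list(a, b)), threshold_from_ntc(pooled))
  expect_error(threshold_from_ntc(droplet_well("H", "NTC", "A", numeric())),
               "fixed assay thresholds")
})

test_that("NTC-derived threshold separates simulated clusters", {
  cfg <- sim_config()
  ntcs <- lapply(1:4, function(i) simulate_well(0, cfg, seed = 100 + i,
                                                well_id = sprintf("N%d", i),
                                                sample_id = "NTC"))
  thr <- threshold_from_ntc(ntcs)
  w <- simulate_well(100, cfg, seed = 50)
  p_exp <- 1 - exp(-100 * 0.00085)
  expect_lt(abs(mean(w$amplitudes > thr) - p_exp),
            binom99_halfwidth(p_exp, w$accepted_count) +
              cfg$rain_fraction * p_exp)  # rain may fall below the NTC cut
})

test_that("Poisson inversion reproduces the closed form", {
  z <- poisson_concentration(make_counts(0, 15000))
  expect_equal(z$lambda_, 0)
  expect_equal(z$copies_per_ul_reaction, 0)
  expect_false(z$saturated_flag)

  x <- poisson_concentration(make_counts(1813, 8187), droplet_volume_nl = 0.85)
  expect_equal(x$lambda_, -log(0.8187), tolerance = 1e-12)
  expect_equal(x$copies_per_ul_reaction, -log(0.8187) / 0.00085,
               tolerance = 1e-12)
  expect_equal(round(x$copies_per_ul_reaction, 1), 235.3)
  expect_equal(x$copies_per_reaction, x$copies_per_ul_reaction * 20)
  expect_true(x$ci_low < x$copies_per_ul_reaction)
  expect_true(x$ci_high > x$copies_per_ul_reaction)

  sat <- poisson_concentration(make_counts(10000, 0))
  expect_true(sat$saturated_flag)
  expect_true(is.na(sat$copies_per_ul_reaction))

  expect_error(poisson_concentration(make_counts(0, 0)), "positive")
})

test_that("concentration is strictly increasing in positive count", {
  total <- 12000
  concs <- vapply(c(10, 100, 1000, 5000, 11000), function(p)
    poisson_concentration(make_counts(p, total - p))$copies_per_ul_reaction,
    numeric(1))
  expect_true(all(diff(concs) > 0))
})

test_that("estimator recovers simulated concentrations without bias", {
  cfg <- sim_config(rain_fraction = 0, false_positive_rate = 0)
  for (conc in c(20, 400)) {
    est <- vapply(1:60, function(i) {
      w <- simulate_well(conc, cfg, seed = 1000 * conc + i)
      quantify_well(w, 3400)$copies_per_ul_reaction
    }, numeric(1))
    expect_lt(abs(mean(est) - conc) / conc, 0.02)
  }
})

test_that("threshold call plus inversion equals brute-force occupancy inversion", {
  cfg <- sim_config(rain_fraction = 0, false_positive_rate = 0)
  w <- simulate_well(300, cfg, seed = 77)
  est <- quantify_well(w, 3400)
  # brute force: count droplets in the positive cluster directly
  occupied <- sum(abs(w$amplitudes - cfg$pos_mean) <= 5 * cfg$pos_sd)
  lambda_bf <- -log(1 - occupied / w$accepted_count)
  expect_equal(est$lambda_, lambda_bf, tolerance = 1e-12)
})
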