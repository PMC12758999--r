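test_that("replicate statistics match the reported count summaries", {
  # reconstructing replicates with the printed mean/sd reproduces the CVs
  # 0.020 and 0.080 when rounded to three decimals
  mk <- function(mean, sd) c(mean - sd, mean, mean + sd)  # sample sd = sd
  low <- replicate_stats(mk(114861742, 2351959))
  expect_equal(low$mean, 114861742)
  expect_equal(round(low$sd / low$mean, 3), 0.020)
  high <- replicate_stats(mk(243459547, 19356615))
  expect_equal(round(high$cv, 3), 0.080)
  # direct ratio check of the printed summaries
  expect_equal(round(2351959 / 114861742, 3), 0.020)
  expect_equal(round(19356615 / 243459547, 3), 0.080)
  # identical replicates have zero spread
  expect_equal(replicate_stats(c(5, 5, 5)), list(mean = 5, sd = 0, cv = 0))
  # single reading: sd defined as 0
  expect_equal(replicate_stats(7)$sd, 0)
  expect_error(replicate_stats(numeric()), "no replicate")
  expect_error(replicate_stats(c(1, -2)), "positive")
})

test_that("calibration factor is the mean of dose/count ratios", {
  # single point
  c1 <- build_calibration(calibration_point(100, 1e6), "planning_ct")
  expect_equal(c1$factor_cgy_per_count, 1e-4)
  expect_equal(c1$inverse_counts_per_cgy, 1e4)
  expect_equal(c1$factor_uncertainty, 0)
  # the two printed planning-CT points: ratio mean 2.702e-5 cGy/count
  pts <- list(calibration_point(2868, 114861742, 2351959, 5),
              calibration_point(7077, 243459547, 19356615, 5))
  c2 <- build_calibration(pts, "planning_ct")
  expect_equal(c2$factor_cgy_per_count,
               mean(c(2868 / 114861742, 7077 / 243459547)))
  expect_equal(round(c2$factor_cgy_per_count, 8), 2.702e-5, tolerance = 1e-4)
  # reciprocity invariant
  expect_equal(c2$factor_cgy_per_count * c2$inverse_counts_per_cgy, 1,
               tolerance = 1e-9)
  # a curve with inverse 20957.66 counts/cGy has factor 4.7715e-5
  c3 <- build_calibration(calibration_point(1, 20957.66), "cbct")
  expect_equal(c3$inverse_counts_per_cgy, 20957.66)
  expect_equal(c3$factor_cgy_per_count, 4.7715e-5, tolerance = 1e-4)
  # slope-through-origin option
  slope_pts <- list(calibration_point(10, 1e5), calibration_point(20, 2e5))
  cs <- build_calibration(slope_pts, "rt", method = "slope")
  expect_equal(cs$factor_cgy_per_count, 1e-4)
})

test_that("counts_to_dose applies background, factor and corrections linearly", {
  curve <- build_calibration(calibration_point(1, 20957.66), "cbct")
  # reciprocal identity: reading the inverse factor worth of counts = 1 cGy
  expect_equal(as.numeric(counts_to_dose(20957.66, curve)), 1,
               tolerance = 1e-12)
  # raw equal to background gives zero dose
  r0 <- osl_reading(500, 500, "cbct")
  expect_equal(as.numeric(counts_to_dose(r0, curve)), 0)
  # linear in net counts and in each correction factor
  base <- as.numeric(counts_to_dose(1000, curve))
  expect_equal(as.numeric(counts_to_dose(3000, curve)), 3 * base)
  for (nm in c("beam_quality", "linearity", "angle", "fading")) {
    co <- do.call(correction_factors, stats::setNames(list(1.25), nm))
    curve2 <- build_calibration(calibration_point(1, 20957.66), "cbct",
                                corrections = co)
    expect_equal(as.numeric(counts_to_dose(1000, curve2)), 1.25 * base)
  }
  # modality mismatch is a configuration error
  expect_error(counts_to_dose(osl_reading(10, 0, "rt"), curve),
               "modality")
  # dose -> counts -> dose round trip
  dose_cgy <- 3.7
  counts <- dose_cgy * curve$inverse_counts_per_cgy
  expect_equal(as.numeric(counts_to_dose(counts, curve)), dose_cgy,
               tolerance = 1e-9)
})

test_that("uncertainty propagation: quadrature and Monte-Carlo agree", {
  q <- propagate_uncertainty(c(a = 0.03, b = 0.04))
  expect_equal(q$combined_relative_sd, 0.05)
  # combined quadrature result dominates every component
  comp <- c(x = 0.02, y = 0.02, z = 0.01)
  q2 <- propagate_uncertainty(comp)
  expect_true(all(q2$combined_relative_sd >= comp))
  # single component: both methods return it (MC within sampling error)
  expect_equal(propagate_uncertainty(c(s = 0.08))$combined_relative_sd, 0.08)
  mc1 <- propagate_uncertainty(c(s = 0.08), "monte_carlo", n = 1e5, seed = 3)
  expect_equal(mc1$combined_relative_sd, 0.08, tolerance = 0.03)
  # MC vs quadrature within 3% relative for small components
  mc <- propagate_uncertainty(comp, "monte_carlo", n = 1e5, seed = 3)
  expect_equal(mc$combined_relative_sd, q2$combined_relative_sd,
               tolerance = 0.03)
  # MC is seeded and reproducible, and does not disturb the caller RNG
  set.seed(99); before <- stats::runif(1)
  set.seed(99)
  mc_a <- propagate_uncertainty(comp, "monte_carlo", seed = 7)
  after <- stats::runif(1)
  mc_b <- propagate_uncertainty(comp, "monte_carlo", seed = 7)
  expect_identical(mc_a$combined_relative_sd, mc_b$combined_relative_sd)
  expect_identical(before, after)
  expect_error(propagate_uncertainty(c(a = -0.1)), "nonnegative")
})

test_that("bleaching zero-check is inclusive at the threshold", {
  curve <- build_calibration(calibration_point(1, 20957.66), "cbct")
  thr <- zero_check_threshold(curve, sensitivity_mgy = 0.7)
  expect_equal(thr, 0.07 * 20957.66)
  expect_true(zero_check(0, thr))
  expect_true(zero_check(thr, thr))           # boundary passes
  expect_false(zero_check(thr * 1.01, thr))   # just above fails
  readings <- list(osl_reading(100, 100, "cbct"),
                   osl_reading(thr + 50, 0, "cbct"))
  expect_equal(zero_check(readings, thr), c(TRUE, FALSE))
  expect_error(zero_check(0, 0), "positive")
})

test_that("calibration recovers a known factor from synthetic counts", {
  k <- 2.937e-5; cv <- 0.05; n_points <- 6; n_rep <- 8
  set.seed(314)
  doses <- seq(200, 7000, length.out = n_points)
  pts <- lapply(doses, function(d) {
    st <- replicate_stats(generate_osl_counts(d, k, cv, n_rep))
    calibration_point(d, st$mean, st$sd, n_rep)
  })
  curve <- build_calibration(pts, "planning_ct")
  rel_bias <- abs(curve$factor_cgy_per_count - k) / k
  expect_lt(rel_bias, 3 * cv / sqrt(n_points * n_rep))
})

test_that("calibration CSV and JSON round-trips preserve the curve", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("modality,delivered_dose_cgy,count_mean,count_sd,n_replicates",
               "planning_ct,2868,114861742,2351959,5",
               "planning_ct,7077,243459547,19356615,5",
               "cbct,5,104788.3,2100,5"), csv)
  pts <- read_calibration_csv(csv)
  expect_named(pts, c("cbct", "planning_ct"))
  curve <- build_calibration(pts$planning_ct, "planning_ct")
  js <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(curve, js)
  back <- read_calibration_json(js)
  expect_equal(back$factor_cgy_per_count, curve$factor_cgy_per_count)
  expect_equal(back$modality, "planning_ct")
})
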