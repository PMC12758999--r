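test_that("cumulative imaging dose reproduces the measured-table arithmetic", {
  # brain: 15 CBCT at 5.720 mGy, CT excluded -> 85.8 mGy, reported 86
  brain <- cumulative_imaging_dose(4.92, 5.720, n_cbct = 15,
                                   include_ct = FALSE)
  expect_equal(brain$total_mgy, 85.8)
  expect_equal(round(brain$total_mgy), 86)
  # thyroid: CT 7.80 + 15 x 3.61 -> 61.95 mGy ~ 0.06 Gy
  thy <- cumulative_imaging_dose(7.80, 3.61, n_cbct = 15, include_ct = TRUE)
  expect_equal(thy$total_mgy, 61.95)
  expect_equal(round(dose_gy(thy$total_mgy, "mGy"), 2), 0.06)
  # n = 0 with CT included leaves the CT dose unchanged
  ct_only <- cumulative_imaging_dose(4.92, 5.720, n_cbct = 0,
                                     include_ct = TRUE, ct_u_mgy = 0.77)
  expect_equal(ct_only$total_mgy, 4.92)
  expect_equal(ct_only$uncertainty_mgy, 0.77)
  # quadrature of independent per-acquisition errors
  u <- cumulative_imaging_dose(4.92, 5.720, 15, TRUE, 0.77, 0.92)
  expect_equal(u$uncertainty_mgy, sqrt(0.77^2 + 15 * 0.92^2))
  expect_error(cumulative_imaging_dose(1, 1, -1), "nonnegative integer")
})

test_that("cumulative dose is additive in the number of acquisitions", {
  for (n1 in c(0, 3, 7)) {
    for (n2 in c(1, 5, 8)) {
      whole <- cumulative_imaging_dose(6.82, 4.373, n1 + n2, TRUE)
      split <- cumulative_imaging_dose(6.82, 4.373, n1, TRUE)$total_mgy +
        cumulative_imaging_dose(6.82, 4.373, n2, FALSE)$total_mgy
      expect_equal(whole$total_mgy, split, tolerance = 1e-12)
    }
  }
})

test_that("relative dose reconciles units exactly and matches quoted percents", {
  # 86 mGy of 36 Gy -> 0.24% at report rounding
  expect_equal(round(relative_dose(dose_value(85.8, "mGy"),
                                   dose_value(36, "Gy")), 2), 0.24)
  # same number vs 54 Gy total-with-boost -> 0.16%
  expect_equal(round(relative_dose(dose_value(85.8, "mGy"),
                                   dose_value(54, "Gy")), 2), 0.16)
  # thyroid imaging total 61.95 mGy vs 36 Gy -> 0.17%
  expect_equal(round(relative_dose(dose_value(61.95, "mGy"), 36), 2), 0.17)
  # thyroid treatment dose 8.7 Gy vs 36 Gy -> 24%
  expect_equal(round(relative_dose(8.7, 36)), 24)
  # dose equal to reference is 100%
  expect_equal(relative_dose(36, 36), 100)
  # identical result whether the dose arrives in mGy or Gy
  expect_equal(relative_dose(dose_value(85.8, "mGy"), 36),
               relative_dose(dose_value(0.0858, "Gy"), 36))
  expect_equal(relative_dose(85.8, 36, dose_unit = "mGy"),
               relative_dose(0.0858, 36))
  expect_error(relative_dose(1, 0), "positive")
})

test_that("exposure report ledgers the packaged phantom table correctly", {
  tab <- phantom_organ_doses()
  expect_equal(nrow(tab), 20)
  rep <- build_exposure_report(tab, prescription(), n_cbct = 15)
  s <- attr(rep, "summary")
  # CBCT-only totals span 48 (vertebrae) to 95 mGy (abdominal cavity)
  expect_equal(s$cbct_total_min$organ, "vertebrae")
  expect_equal(round(s$cbct_total_min$mgy), 48)
  expect_equal(s$cbct_total_max$organ, "abdominal_cavity")
  expect_equal(round(s$cbct_total_max$mgy), 95)
  # every organ's imaging total stays below 0.3% of the 36 Gy prescription
  expect_lt(s$max_pct_of_prescription, 0.3)
  expect_true(all(rep$pct_of_prescription > 0))
  # heart imaging total is 0.20% of prescription at report rounding
  heart <- rep[rep$organ == "heart", ]
  expect_equal(round(heart$pct_of_prescription, 2), 0.20)
  # brainstem CBCT-only total reported as 88 mGy
  expect_equal(round(rep$cbct_total_mgy[rep$organ == "brainstem"]), 88)
  # mandible CBCT-only total 0.092 Gy
  expect_equal(round(rep$cbct_total_mgy[rep$organ == "mandible"] / 1000, 3),
               0.092)
  # report-time rounding leaves the underlying report at full precision
  fmt <- format_exposure_report(rep)
  expect_equal(fmt$imaging_total_mgy, round(rep$imaging_total_mgy))
  expect_false(isTRUE(all.equal(rep$pct_of_prescription,
                                round(rep$pct_of_prescription, 2))))
})

test_that("exposure percents grow with the number of CBCT acquisitions", {
  tab <- phantom_organ_doses()
  reps <- lapply(c(0, 5, 10, 15, 25), function(n)
    build_exposure_report(tab, prescription(), n_cbct = n))
  pcts <- sapply(reps, function(r) r$pct_of_prescription)
  expect_true(all(apply(pcts, 1, function(x) all(diff(x) > 0))))
})

test_that("exposure report validates inputs and handles plan mappings", {
  tab <- phantom_organ_doses()
  dup <- rbind(tab, tab[1, ])
  expect_error(build_exposure_report(dup, prescription(), 15), "duplicate")
  # organs missing from a plan become NA, never zero
  plans <- list(vmat = data.frame(organ = c("heart", "thyroid"),
                                  eud_gy = c(6.6, 8.7)))
  rep <- build_exposure_report(tab, prescription(), 15, plans = plans)
  expect_equal(rep$eud_vmat_gy[rep$organ == "heart"], 6.6)
  expect_true(is.na(rep$eud_vmat_gy[rep$organ == "brain"]))
  expect_equal(round(rep$plan_pct_vmat[rep$organ == "thyroid"]), 24)
})

test_that("technique comparison produces EUD/NTCP matrices with deltas", {
  params <- list(
    heart = fit_ntcp_params(c(16, 6.6), c(0.30, 0.004), organ = "heart"),
    thyroid = fit_ntcp_params(c(27.1, 8.7), c(0.12, 0.005), organ = "thyroid")
  )
  long <- data.frame(
    organ = rep(c("heart", "thyroid"), each = 2),
    technique = rep(c("3dcrt", "vmat"), 2),
    eud_gy = c(16, 6.6, 27.1, 8.7)
  )
  cmp <- compare_techniques(long, params, reference = "3dcrt")
  # heart row: NTCP 30% and 0.4%
  expect_equal(unname(cmp$ntcp_pct["heart", ]), c(30, 0.4), tolerance = 1e-9)
  # thyroid row: ~12% and < 1%
  expect_equal(cmp$ntcp_pct["thyroid", "3dcrt"], 12, tolerance = 1e-9)
  expect_lt(cmp$ntcp_pct["thyroid", "vmat"], 1)
  # deltas vs the reference are zero for the reference itself
  expect_equal(unname(cmp$delta_eud_gy[, "3dcrt"]), c(0, 0))
  expect_equal(unname(cmp$ratio_eud[, "3dcrt"]), c(1, 1))
  expect_equal(cmp$delta_eud_gy["heart", "vmat"], 6.6 - 16)
  # single technique compares against itself with zero deltas
  single <- compare_techniques(long[long$technique == "vmat", ], params)
  expect_equal(unname(single$delta_eud_gy[, 1]), c(0, 0))
  # missing cells are NA and flagged
  holes <- long[-2, ]
  expect_message(cmp2 <- compare_techniques(holes, params), "missing")
  expect_true(is.na(cmp2$eud_gy["heart", "vmat"]))
  expect_error(compare_techniques(long[0, ], params), "empty")
})
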