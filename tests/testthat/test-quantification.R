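test_that("fit_calibration recovers every packaged response line exactly", {
  for (curve in default_calibration_curves()) {
    levels <- seq(curve$cal_low, curve$cal_high, length.out = 5)
    standards <- data.frame(ppb = levels,
                            response = curve$slope * levels + curve$intercept)
    fit <- fit_calibration(standards, curve$symbol)
    expect_equal(fit$slope, curve$slope, tolerance = 1e-9)
    expect_equal(fit$intercept, curve$intercept,
                 tolerance = 1e-9 * abs(curve$intercept))
    expect_equal(fit$r_squared, 1, tolerance = 1e-12)
    expect_equal(fit$cal_low, min(levels))
    expect_equal(fit$cal_high, max(levels))
  }
})

test_that("fit_calibration matches a closed-form least-squares oracle on noisy data", {
  # y = 2x + 1 with one perturbed point; oracle is the normal-equations
  # solution computed independently of lm
  x <- c(1, 2, 3, 4, 5)
  y <- 2 * x + 1
  y[3] <- y[3] + 0.5
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fit <- fit_calibration(data.frame(ppb = x, response = y))
  expect_equal(fit$intercept, unname(beta[1, 1]), tolerance = 1e-12)
  expect_equal(fit$slope, unname(beta[2, 1]), tolerance = 1e-12)
  expect_lt(fit$r_squared, 1)
})

test_that("fit_calibration rejects degenerate designs", {
  expect_error(fit_calibration(data.frame(ppb = c(1, 2), response = c(3, 5))),
               "at least 3")
  expect_error(
    fit_calibration(data.frame(ppb = c(1, 1, 1), response = c(1, 2, 3))),
    "zero concentration variance"
  )
})

test_that("invert_calibration is the exact inverse of the response line", {
  hg <- default_calibration_curves()$Hg
  expect_equal(invert_calibration(hg$intercept, hg)$ppb, 0)
  fwd <- hg$slope * 0.009 + hg$intercept
  expect_equal(invert_calibration(fwd, hg)$ppb, 0.009, tolerance = 1e-12)

  # round trip across the whole calibration range
  ppb <- seq(hg$cal_low, hg$cal_high, length.out = 20)
  back <- invert_calibration(hg$slope * ppb + hg$intercept, hg)
  expect_equal(back$ppb, ppb, tolerance = 1e-12)
  expect_true(all(back$in_range))

  zero <- invert_calibration(0, hg)
  expect_lt(zero$ppb, 0)
  expect_true(zero$censored_at_zero)
})

test_that("summarize_replicates aggregates, censors and range-checks", {
  refs <- default_reference_set()
  readings <- tibble::tibble(
    sample_id = "S1", element = "Hg", replicate = 1:3,
    value = c(0.010, 0.012, 0.011)
  )
  s <- summarize_replicates(readings, refs)
  expect_equal(s$mean_ppb, 0.011)
  expect_equal(s$sd_ppb, 0.001, tolerance = 1e-12)
  expect_equal(s$n_replicates, 3L)
  expect_false(s$censored)

  # mean exactly at the calibration floor counts as in range
  at_floor <- tibble::tibble(sample_id = "S1", element = "Hg",
                             replicate = 1:3, value = rep(0.005, 3))
  expect_true(summarize_replicates(at_floor, refs)$in_range)

  below_lod <- tibble::tibble(sample_id = "S1", element = "Hg",
                              replicate = 1:3, value = rep(0.0005, 3))
  s2 <- summarize_replicates(below_lod, refs)
  expect_true(s2$censored)

  expect_error(summarize_replicates(readings[0, ], refs), "empty")
  bad <- readings
  bad$element <- "Fe"
  expect_error(summarize_replicates(bad, refs), "unknown element.*Fe")
})

test_that("effective volume is the dilution-chain product", {
  expect_equal(effective_volume(sample_prep(0.4, 10, c(4, 100, 5))), 20000)
  expect_equal(effective_volume(sample_prep(0.4, 10, numeric(0))), 10)
  expect_equal(effective_volume(sample_prep(0.4, 10, c(2, 2))), 40)
  expect_error(sample_prep(tablet_mass_g = 0), "positive")
  expect_error(sample_prep(dilution_factors = c(4, -1)), "positive")
})

test_that("ppb to ug/g conversion reproduces every detected panel pair", {
  prep <- sample_prep()
  det <- study_detected_rows()
  s <- tibble::tibble(
    sample_id = det$sample_id, element = det$element, mean_ppb = det$ppb,
    sd_ppb = 0.001, n_replicates = 3, censored = FALSE, in_range = TRUE
  )
  conc <- ppb_to_ug_per_g(s, prep)
  expect_equal(round(conc$c_ug_per_g, 2), det$c_print)
  # and exactly, not only after rounding: a * 20000 / 0.4 * 1e-3 = a * 50
  expect_equal(conc$c_ug_per_g, det$ppb * 50, tolerance = 1e-12)
})

test_that("conversion is linear and absorbs censoring", {
  prep <- sample_prep()
  base <- tibble::tibble(sample_id = "S1", element = "Hg", mean_ppb = 0.007,
                         sd_ppb = 0.002, n_replicates = 3, censored = FALSE,
                         in_range = TRUE)
  for (k in c(0.5, 2, 10)) {
    scaled <- base
    scaled$mean_ppb <- base$mean_ppb * k
    expect_equal(ppb_to_ug_per_g(scaled, prep)$c_ug_per_g,
                 k * ppb_to_ug_per_g(base, prep)$c_ug_per_g,
                 tolerance = 1e-12)
  }
  zero <- base
  zero$mean_ppb <- 0
  expect_equal(ppb_to_ug_per_g(zero, prep)$c_ug_per_g, 0)

  censored <- base
  censored$censored <- TRUE
  out <- ppb_to_ug_per_g(censored, prep)
  expect_true(out$censored)
  expect_true(is.na(out$c_ug_per_g))
  # absorbing: no numeric metric downstream either
  risk <- assess_risk(out)
  expect_true(all(is.na(c(risk$edi, risk$hq, risk$cr, risk$daily_intake_ug))))
})

test_that("readings reader handles ppb and counts kinds and round-trips", {
  dir <- withr::local_tempdir()
  panel <- generate_panel(study_spike_plan(noise_rel_sd = 0))
  path <- file.path(dir, "readings.csv")
  write_readings(panel, path)
  back <- read_readings(path)
  expect_equal(back$value, panel$value, tolerance = 1e-12)

  # counts rows are back-calculated through the curve
  hg <- default_calibration_curves()$Hg
  counts <- tibble::tibble(
    sample_id = "S1", element = "Hg", replicate = 1:3,
    value = hg$slope * 0.009 + hg$intercept, value_kind = "counts"
  )
  cpath <- file.path(dir, "counts.csv")
  utils::write.csv(counts, cpath, row.names = FALSE)
  got <- read_readings(cpath)
  expect_equal(got$value, rep(0.009, 3), tolerance = 1e-9)

  utils::write.csv(counts[0, ], cpath, row.names = FALSE)
  expect_error(read_readings(cpath), "empty")
})
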