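make_conc <- function(element, c_ug_per_g, sample_id = "S1",
                      censored = FALSE) {
  tibble::tibble(sample_id = sample_id, element = element,
                 c_ug_per_g = ifelse(censored, NA_real_, c_ug_per_g),
                 sd_ug_per_g = NA_real_, censored = censored)
}

test_that("EDI follows the intake model and its reduced default form", {
  sc <- exposure_scenario() # IR 4.5 g, BW 70 kg, AT = EF*ED
  r <- compute_edi(make_conc("Hg", 0.25), sc)
  expect_equal(r$edi, 0.25 * 4.5 * 1e-3 / 70, tolerance = 1e-15)
  expect_equal(signif(r$edi, 2), 1.6e-5)

  r2 <- compute_edi(make_conc("Cr", 0.80), sc)
  expect_equal(signif(r2$edi, 2), 5.1e-5)

  expect_equal(compute_edi(make_conc("Hg", 0), sc)$edi, 0)

  # with AT = EF*ED the time factors cancel exactly, for any EF/ED
  sc2 <- exposure_scenario(ef_days_per_year = 200, ed_years = 7)
  r3 <- compute_edi(make_conc("Hg", 0.25), sc2)
  expect_identical(r3$edi, r$edi)
})

test_that("HQ divides by RfD and marks Pb as not computable", {
  sc <- exposure_scenario()
  hg <- compute_hq(compute_edi(make_conc("Hg", 0.25), sc))
  expect_equal(round(hg$hq, 3), 0.054)

  cr <- compute_hq(compute_edi(make_conc("Cr", 0.80), sc))
  expect_equal(round(cr$hq, 3), 0.017)

  pb <- compute_hq(compute_edi(make_conc("Pb", 0.5), sc))
  expect_false(is.na(pb$edi))
  expect_true(is.na(pb$hq))
  expect_equal(pb$hq_note, "RfD unavailable")
})

test_that("HI sums defined HQs and flags at one", {
  sc <- exposure_scenario()
  one <- compute_hq(compute_edi(make_conc("Hg", 0.25), sc))
  hi1 <- compute_hi(one)
  expect_equal(hi1$hi, one$hq) # single detected element: HI = HQ
  expect_false(hi1$hi_flag)

  all_cens <- compute_hq(compute_edi(
    make_conc(c("Hg", "Cr"), NA, censored = TRUE), sc))
  hi2 <- compute_hi(all_cens)
  expect_true(is.na(hi2$hi))
  expect_false(hi2$hi_flag)

  two <- tibble::tibble(sample_id = "S1", element = c("Hg", "Cr"),
                        hq = c(0.3, 0.8), censored = FALSE)
  hi3 <- compute_hi(two)
  expect_equal(hi3$hi, 1.1)
  expect_true(hi3$hi_flag)

  mixed <- two
  mixed$sample_id <- c("S1", "S2")
  expect_error(compute_hi(mixed), "single sample")
})

test_that("CR multiplies by CSF and classifies against the USEPA bounds", {
  sc <- exposure_scenario()
  cr <- compute_cr(compute_edi(make_conc("Cr", 0.55), sc))
  expect_equal(signif(cr$cr, 4), 1.768e-5)
  expect_equal(cr$cr_class, "acceptable")

  hg <- compute_cr(compute_edi(make_conc("Hg", 0.25), sc))
  expect_true(is.na(hg$cr))

  expect_equal(classify_cr(c(5e-4, 1e-4, 1e-6, 9.9e-7, NA)),
               c("unacceptable", "acceptable", "acceptable", "negligible",
                 NA))
})

test_that("PDE screen compares daily elemental intake on strict inequality", {
  sc <- exposure_scenario()
  hg <- pde_screen(make_conc("Hg", 0.45), sc)
  expect_equal(hg$daily_intake_ug, 2.025)
  expect_false(hg$pde_exceeded) # PDE(Hg) = 30 ug/day

  cr <- pde_screen(make_conc("Cr", 0.80), sc)
  expect_equal(cr$daily_intake_ug, 3.6)
  expect_false(cr$pde_exceeded) # PDE(Cr) = 11000 ug/day

  # exactly at the limit is not an exceedance
  at_limit <- pde_screen(make_conc("Hg", 30 / 4.5), sc)
  expect_equal(at_limit$daily_intake_ug, 30)
  expect_false(at_limit$pde_exceeded)
  just_over <- pde_screen(make_conc("Hg", 30.0001 / 4.5), sc)
  expect_true(just_over$pde_exceeded)
})

test_that("risk metrics scale with concentration and inversely with body weight", {
  base <- assess_risk(make_conc("Cr", 0.4))
  doubled_c <- assess_risk(make_conc("Cr", 0.8))
  expect_equal(doubled_c$edi, 2 * base$edi, tolerance = 1e-12)
  expect_equal(doubled_c$hq, 2 * base$hq, tolerance = 1e-12)
  expect_equal(doubled_c$cr, 2 * base$cr, tolerance = 1e-12)
  expect_equal(doubled_c$daily_intake_ug, 2 * base$daily_intake_ug,
               tolerance = 1e-12)

  heavy <- assess_risk(make_conc("Cr", 0.4), exposure_scenario(bw_kg = 140))
  expect_equal(heavy$edi, base$edi / 2, tolerance = 1e-12)
  expect_equal(heavy$hq, base$hq / 2, tolerance = 1e-12)
  expect_equal(heavy$cr, base$cr / 2, tolerance = 1e-12)
  # PDE intake is per product, independent of body weight
  expect_equal(heavy$daily_intake_ug, base$daily_intake_ug)
})

test_that("adding a detected element never decreases HI", {
  sc <- exposure_scenario()
  one <- assess_risk(make_conc("Hg", 0.3), sc)
  both <- assess_risk(dplyr::bind_rows(make_conc("Hg", 0.3),
                                       make_conc("As", 0.05)), sc)
  expect_gte(unique(both$hi), unique(one$hi))
  expect_gte(unique(both$hi), max(both$hq, na.rm = TRUE))
})

test_that("the full study panel risk table matches the printed report", {
  risk <- study_risk_table()
  det <- study_detected_rows()
  expect_equal(nrow(risk), 120)

  for (i in seq_len(nrow(det))) {
    row <- risk[risk$sample_id == det$sample_id[i] &
                  risk$element == det$element[i], ]
    expect_false(row$censored)
    expect_equal(round(row$c_ug_per_g, 2), det$c_print[i])
    expect_true(agrees_printed_signif(row$edi, det$edi_print[i], 2))
    expect_true(agrees_printed_decimal(row$hq, det$hq_print[i], 3))
    expect_true(agrees_printed_decimal(row$hi, det$hq_print[i], 3))
    if (is.na(det$cr_print[i])) {
      expect_true(is.na(row$cr))
    } else {
      expect_true(agrees_printed_signif(row$cr, det$cr_print[i], 4))
    }
  }

  clean <- c("S03", "S04", "S06", "S07", "S12")
  clean_rows <- risk[risk$sample_id %in% clean, ]
  expect_true(all(clean_rows$censored))
  expect_true(all(is.na(clean_rows$edi)))
  expect_true(all(is.na(clean_rows$hi)))
  fmt <- format_risk_table(clean_rows)
  expect_true(all(fmt$edi == "NC" & fmt$hq == "NC" & fmt$hi == "NC" &
                    fmt$cr == "NC"))
})
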