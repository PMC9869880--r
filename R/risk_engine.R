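#' Define an adult oral exposure scenario
#'
#' Parameters of the estimated-daily-intake model
#' `EDI = EF * ED * IR * C * 1e-3 / (BW * AT)` (mg/kg/day): intake rate IR
#' (grams of product per day), body weight BW (kg), exposure frequency EF
#' (days/year), exposure duration ED (years) and averaging time AT (days).
#' The default AT is `EF * ED`, which makes the time factors cancel so that
#' EDI reduces to `C * IR * 1e-3 / BW`. Defaults describe one 4.5 g tablet
#' per day taken by a 70 kg adult every day for 30 years.
#'
#' @param ir_g_per_day Daily product intake, g/day.
#' @param bw_kg Body weight, kg.
#' @param ef_days_per_year Exposure frequency, days/year.
#' @param ed_years Exposure duration, years.
#' @param at_days Averaging time, days; defaults to `EF * ED`.
#' @return An `exposure_scenario` object.
#' @export
exposure_scenario <- function(ir_g_per_day = 4.5, bw_kg = 70,
                              ef_days_per_year = 365, ed_years = 30,
                              at_days = ef_days_per_year * ed_years) {
  vals <- c(ir = ir_g_per_day, bw = bw_kg, ef = ef_days_per_year,
            ed = ed_years, at = at_days)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all exposure-scenario parameters must be positive", call. = FALSE)
  }
  structure(
    list(ir_g_per_day = ir_g_per_day, bw_kg = bw_kg,
         ef_days_per_year = ef_days_per_year, ed_years = ed_years,
         at_days = at_days, cf2 = 1e-3),
    class = "exposure_scenario"
  )
}

#' @export
print.exposure_scenario <- function(x, ...) {
  cat(sprintf("<exposure_scenario> IR = %g g/day, BW = %g kg, EF = %g d/y, ED = %g y, AT = %g d\n",
              x$ir_g_per_day, x$bw_kg, x$ef_days_per_year, x$ed_years,
              x$at_days))
  invisible(x)
}

# The EDI kernel shared by the deterministic table and the Monte Carlo
# engine. ir/bw may be vectors (simulation draws); c_ug_per_g in ug/g.
edi_kernel <- function(c_ug_per_g, ir, bw, ef = 365, ed = 30, at = ef * ed) {
  ef * ed * ir * c_ug_per_g * 1e-3 / (bw * at)
}

#' Estimated daily intake per concentration record
#'
#' @param conc Concentration tibble from [ppb_to_ug_per_g()].
#' @param scenario An [exposure_scenario()].
#' @return `conc` with an added `edi` column (mg/kg/day; `NA` for censored
#'   records, which carry all downstream metrics as not computable).
#' @export
compute_edi <- function(conc, scenario = exposure_scenario()) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  conc <- tibble::as_tibble(conc)
  conc$edi <- ifelse(
    conc$censored, NA_real_,
    edi_kernel(conc$c_ug_per_g, scenario$ir_g_per_day, scenario$bw_kg,
               scenario$ef_days_per_year, scenario$ed_years,
               scenario$at_days)
  )
  conc
}

#' Hazard quotient per record
#'
#' `HQ = EDI / RfD`. Elements without an established oral RfD (Pb in the
#' packaged set) yield `NA` with `hq_note = "RfD unavailable"`, so a
#' detected record for such an element cannot silently pass as harmless.
#'
#' @param records Output of [compute_edi()].
#' @param refs Element reference set.
#' @return `records` with added `hq` and `hq_note` columns.
#' @export
compute_hq <- function(records, refs = default_reference_set()) {
  records <- tibble::as_tibble(records)
  rfd <- refs$rfd[match(records$element, refs$symbol)]
  records$hq <- ifelse(is.na(records$edi) | is.na(rfd), NA_real_,
                       records$edi / rfd)
  records$hq_note <- dplyr::case_when(
    !is.na(records$hq) ~ NA_character_,
    is.na(records$edi) ~ "censored",
    is.na(rfd) ~ "RfD unavailable"
  )
  records
}

#' Lifetime cancer risk per record
#'
#' `CR = EDI * CSF` for the CSF-bearing carcinogens (Cd, Cr, Pb, Ni, As);
#' absent otherwise. The classification follows the USEPA convention:
#' below 1e-6 negligible, between 1e-6 and 1e-4 acceptable, above 1e-4
#' unacceptable.
#'
#' @param records Output of [compute_edi()].
#' @param refs Element reference set.
#' @return `records` with added `cr` and `cr_class` columns.
#' @export
compute_cr <- function(records, refs = default_reference_set()) {
  records <- tibble::as_tibble(records)
  csf <- refs$csf[match(records$element, refs$symbol)]
  records$cr <- ifelse(is.na(records$edi) | is.na(csf), NA_real_,
                       records$edi * csf)
  records$cr_class <- classify_cr(records$cr)
  records
}

#' Classify cancer-risk values against the USEPA bounds
#'
#' @param cr Numeric vector of cancer risks.
#' @return Character vector: `"negligible"` (< 1e-6), `"acceptable"`
#'   (1e-6 to 1e-4 inclusive), `"unacceptable"` (> 1e-4), `NA` for `NA`.
#' @export
classify_cr <- function(cr) {
  dplyr::case_when(
    is.na(cr) ~ NA_character_,
    cr > 1e-4 ~ "unacceptable",
    cr >= 1e-6 ~ "acceptable",
    TRUE ~ "negligible"
  )
}

#' Screen daily elemental intake against the permitted daily exposure
#'
#' The oral PDE (ICH Q3D / USP <232>) caps the absolute daily intake of an
#' element in ug/day: `daily_intake_ug = C * IR`, exceeded only on strict
#' inequality against the element PDE.
#'
#' @param records Concentration or risk tibble carrying `element`,
#'   `c_ug_per_g` and `censored`.
#' @param scenario An [exposure_scenario()].
#' @param refs Element reference set.
#' @return `records` with added `daily_intake_ug` and `pde_exceeded`
#'   columns (`NA` for censored records).
#' @export
pde_screen <- function(records, scenario = exposure_scenario(),
                       refs = default_reference_set()) {
  records <- tibble::as_tibble(records)
  pde <- refs$pde[match(records$element, refs$symbol)]
  records$daily_intake_ug <- ifelse(records$censored, NA_real_,
                                    records$c_ug_per_g * scenario$ir_g_per_day)
  records$pde_exceeded <- ifelse(is.na(records$daily_intake_ug), NA,
                                 records$daily_intake_ug > pde)
  records
}

#' Hazard index for one sample
#'
#' `HI` is the sum of the defined hazard quotients over the assessed
#' elements of one sample; censored or RfD-less records contribute
#' nothing. A sample with no defined HQ at all (everything censored)
#' reports `HI = NA` ("NC") with no flag.
#'
#' @param records Risk records for a single sample (same `sample_id`
#'   throughout), carrying an `hq` column.
#' @return One-row tibble: `sample_id`, `hi`, `hi_flag` (`hi >= 1`),
#'   `n_detected`.
#' @export
compute_hi <- function(records) {
  records <- tibble::as_tibble(records)
  ids <- unique(records$sample_id)
  if (length(ids) != 1) {
    stop("compute_hi expects records from a single sample; got: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  defined <- !is.na(records$hq)
  hi <- if (any(defined)) sum(records$hq[defined]) else NA_real_
  tibble::tibble(
    sample_id = ids,
    hi = hi,
    hi_flag = !is.na(hi) && hi >= 1,
    n_detected = sum(!records$censored)
  )
}

#' Full per-record risk table
#'
#' Runs EDI, HQ, CR and the PDE screen over a concentration table and
#' attaches the per-sample hazard index: the machine twin of a regulatory
#' screening report, one row per sample-by-element record.
#'
#' @param conc Concentration tibble from [ppb_to_ug_per_g()].
#' @param scenario An [exposure_scenario()].
#' @param refs Element reference set.
#' @return Tibble with columns `sample_id`, `element`, `c_ug_per_g`,
#'   `sd_ug_per_g`, `censored`, `ir_g_per_day`, `edi`, `hq`, `hq_note`,
#'   `hi`, `cr`, `cr_class`, `daily_intake_ug`, `pde_exceeded`.
#' @export
#' @examples
#' s <- tibble::tibble(sample_id = "S1", element = "Hg", mean_ppb = 0.005,
#'                     sd_ppb = 0.002, n_replicates = 3, censored = FALSE,
#'                     in_range = TRUE)
#' conc <- ppb_to_ug_per_g(s, sample_prep())
#' assess_risk(conc)
assess_risk <- function(conc, scenario = exposure_scenario(),
                        refs = default_reference_set()) {
  conc <- tibble::as_tibble(conc)
  unknown <- setdiff(unique(conc$element), refs$symbol)
  if (length(unknown) > 0) {
    stop("unknown element(s) in concentration table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  risk <- conc |>
    compute_edi(scenario) |>
    compute_hq(refs) |>
    compute_cr(refs) |>
    pde_screen(scenario, refs)
  risk$ir_g_per_day <- scenario$ir_g_per_day
  his <- dplyr::bind_rows(lapply(
    split(risk, risk$sample_id),
    compute_hi
  ))
  risk <- dplyr::left_join(risk, his[, c("sample_id", "hi", "hi_flag")],
                           by = "sample_id")
  dplyr::select(
    risk, "sample_id", "element", "c_ug_per_g", "sd_ug_per_g", "censored",
    "ir_g_per_day", "edi", "hq", "hq_note", "hi", "cr", "cr_class",
    "daily_intake_ug", "pde_exceeded"
  )
}

#' Per-sample risk summary
#'
#' @param risk A risk table from [assess_risk()].
#' @return Tibble with one row per sample: `hi`, `hi_flag`, `n_detected`,
#'   `max_cr`, `cr_class` (worst class among detected carcinogens),
#'   `any_pde_exceeded`.
#' @export
sample_summary <- function(risk) {
  risk <- tibble::as_tibble(risk)
  risk |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      hi = if (all(is.na(.data$hq))) NA_real_ else
        sum(.data$hq, na.rm = TRUE),
      hi_flag = !is.na(hi) && hi >= 1,
      n_detected = sum(!.data$censored),
      max_cr = if (all(is.na(.data$cr))) NA_real_ else
        max(.data$cr, na.rm = TRUE),
      cr_class = {
        cls <- .data$cr_class[!is.na(.data$cr_class)]
        if (length(cls) == 0) NA_character_ else
          c("unacceptable", "acceptable", "negligible")[
            min(match(cls, c("unacceptable", "acceptable", "negligible")))]
      },
      any_pde_exceeded = any(.data$pde_exceeded %in% TRUE),
      .groups = "drop"
    )
}

# Report-layer rounding mirroring the printing conventions of regulatory
# screening tables: C to 2 decimals, HQ/HI to 3 decimals, EDI to 2
# significant figures, CR to 4 significant figures. NA renders "NC".
.fmt_nc <- function(x, f) ifelse(is.na(x), "NC", f(x))

#' Render a risk table for reporting
#'
#' Rounds at the reporting layer only (comparisons for flags always use
#' full precision): concentrations to 2 decimals, EDI to 2 significant
#' figures, HQ and HI to 3 decimals, CR to 4 significant figures; absent
#' metrics render as `"NC"`.
#'
#' @param risk A risk table from [assess_risk()].
#' @return Tibble of character columns mirroring the screening-report
#'   column order: sample, element, ppb-level concentration columns, IR,
#'   EDI, HQ, HI, CR.
#' @export
format_risk_table <- function(risk) {
  risk <- tibble::as_tibble(risk)
  tibble::tibble(
    sample_id = risk$sample_id,
    element = risk$element,
    c_ug_per_g = .fmt_nc(risk$c_ug_per_g, function(x) sprintf("%.2f", x)),
    ir_g = sprintf("%g", risk$ir_g_per_day),
    edi = .fmt_nc(risk$edi, function(x) format(signif(x, 2))),
    hq = .fmt_nc(risk$hq, function(x) sprintf("%.3f", x)),
    hi = .fmt_nc(risk$hi, function(x) sprintf("%.3f", x)),
    cr = .fmt_nc(risk$cr, function(x) format(signif(x, 4)))
  )
}

#' Write a risk table
#'
#' Writes the formatted report to `path` and a full-precision
#' machine-readable companion with suffix `_full.csv`.
#'
#' @param risk A risk table from [assess_risk()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_risk_table <- function(risk, path) {
  full_path <- sub("\\.csv$", "_full.csv", path)
  if (identical(full_path, path)) full_path <- paste0(path, "_full.csv")
  utils::write.csv(tibble::as_tibble(risk), full_path, row.names = FALSE,
                   na = "")
  utils::write.csv(format_risk_table(risk), path, row.names = FALSE)
  invisible(path)
}
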