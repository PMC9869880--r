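# Frozen study values: the seven detected sample-by-element rows of the
# reference panel, as printed (ppb replicate mean, matrix concentration,
# EDI, HQ and CR at their printed precisions). The remaining five samples
# (S03, S04, S06, S07, S12) are fully censored.
study_detected_rows <- function() {
  tibble::tribble(
    ~sample_id, ~element, ~ppb,  ~c_print, ~edi_print, ~hq_print, ~cr_print,
    "S01",      "Hg",     0.005, 0.25,     1.6e-5,     0.054,     NA,
    "S02",      "Hg",     0.009, 0.45,     2.9e-5,     0.096,     NA,
    "S08",      "Hg",     0.006, 0.30,     1.9e-5,     0.064,     NA,
    "S09",      "Hg",     0.008, 0.40,     2.6e-5,     0.086,     NA,
    "S05",      "Cr",     0.011, 0.55,     3.5e-5,     0.011,     1.767e-5,
    "S10",      "Cr",     0.016, 0.80,     5.1e-5,     0.017,     2.571e-5,
    "S11",      "Cr",     0.013, 0.65,     4.2e-5,     0.014,     2.089e-5
  )
}

all_sample_ids <- function() sprintf("S%02d", 1:12)

# Build a replicate-readings table from per-cell mean ppb values: three
# identical replicates per detected cell, and deterministic sub-detection
# readings (LOD/4) for every other sample-by-element cell.
readings_from_means <- function(detected = study_detected_rows(),
                                refs = default_reference_set(),
                                sample_ids = all_sample_ids()) {
  grid <- expand.grid(sample_id = sample_ids, element = refs$symbol,
                      stringsAsFactors = FALSE)
  grid <- dplyr::left_join(grid, detected[, c("sample_id", "element", "ppb")],
                           by = c("sample_id", "element"))
  lod <- refs$lod[match(grid$element, refs$symbol)]
  grid$value <- ifelse(is.na(grid$ppb), lod / 4, grid$ppb)
  tibble::tibble(
    sample_id = rep(grid$sample_id, each = 3),
    element = rep(grid$element, each = 3),
    replicate = rep(1:3, times = nrow(grid)),
    value = rep(grid$value, each = 3)
  )
}

# Printed-precision agreement. Screening reports round, but a printed
# figure can also be a truncation of the computed value; agreement means
# the printed number equals the computed one either rounded or truncated
# at the printed precision.
trunc_decimal <- function(x, digits) trunc(x * 10^digits) / 10^digits

trunc_signif <- function(x, digits) {
  expo <- floor(log10(abs(x)))
  scale <- 10^(digits - 1 - expo)
  trunc(x * scale) / scale
}

agrees_printed_decimal <- function(computed, printed, digits) {
  abs(printed - round(computed, digits)) < 1e-9 |
    abs(printed - trunc_decimal(computed, digits)) < 1e-9
}

agrees_printed_signif <- function(computed, printed, digits) {
  tol <- abs(printed) * 1e-9 + 1e-15
  abs(printed - signif(computed, digits)) < tol |
    abs(printed - trunc_signif(computed, digits)) < tol
}

# Deterministic risk table for the study panel built from printed means.
study_risk_table <- function() {
  readings <- readings_from_means()
  conc <- ppb_to_ug_per_g(summarize_replicates(readings), sample_prep())
  assess_risk(conc)
}
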