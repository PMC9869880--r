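#' Construct a calibration curve
#'
#' A linear instrument response model `response = slope * ppb + intercept`,
#' valid on `[cal_low, cal_high]` ppb.
#'
#' @param symbol Element symbol.
#' @param slope Instrument response per ppb; must be positive.
#' @param intercept Response at zero concentration.
#' @param r_squared Coefficient of determination of the fit, in `[0, 1]`.
#' @param cal_low,cal_high Validity range, ppb.
#' @return A `calibration_curve` object.
#' @export
calibration_curve <- function(symbol, slope, intercept, r_squared,
                              cal_low, cal_high) {
  stopifnot(is.character(symbol), length(symbol) == 1)
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration slope must be positive (element ", symbol, ")",
         call. = FALSE)
  }
  if (!is.finite(r_squared) || r_squared < 0 || r_squared > 1) {
    stop("r_squared must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(cal_low) || !is.finite(cal_high) || cal_low >= cal_high) {
    stop("calibration range must satisfy cal_low < cal_high", call. = FALSE)
  }
  structure(
    list(symbol = symbol, slope = slope, intercept = intercept,
         r_squared = r_squared, cal_low = cal_low, cal_high = cal_high),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve %s> response = %.6g * ppb + %.6g (R2 = %.4f, range %g-%g ppb)\n",
              x$symbol, x$slope, x$intercept, x$r_squared, x$cal_low, x$cal_high))
  invisible(x)
}

#' Packaged ICP-MS calibration curves
#'
#' The daily-calibration response lines determined for the ten screened
#' elements on the quantification isotopes of [default_reference_set()],
#' with their reported coefficients of determination and validity ranges.
#'
#' @return Named list of [calibration_curve()] objects keyed by symbol.
#' @export
default_calibration_curves <- function() {
  refs <- default_reference_set()
  slopes <- c(Cd = 9628.7863, Pb = 156222.6825, As = 23185.9056,
              Hg = 9659.9875, Co = 178431.6850, V = 164792.2255,
              Ni = 38292.3170, Cr = 143526.7562, Sb = 95919.3327,
              Sn = 84295.4605)
  intercepts <- c(Cd = 120.0122, Pb = 340.0113, As = 360.0078,
                  Hg = 200.0025, Co = 680.0216, V = 3793.9275,
                  Ni = 5084.3934, Cr = 50184.4152, Sb = 1426.7563,
                  Sn = 450.0098)
  r2 <- c(Cd = 1.0000, Pb = 0.9975, As = 0.9989, Hg = 0.9939, Co = 0.9999,
          V = 0.9994, Ni = 0.9999, Cr = 0.9997, Sb = 1.0000, Sn = 0.9995)
  curves <- lapply(refs$symbol, function(sym) {
    row <- refs[refs$symbol == sym, ]
    calibration_curve(sym, slopes[[sym]], intercepts[[sym]], r2[[sym]],
                      row$cal_low, row$cal_high)
  })
  names(curves) <- refs$symbol
  curves
}

#' Fit a calibration curve by ordinary least squares
#'
#' @param standards Data frame with numeric columns `ppb` (standard
#'   concentration) and `response` (instrument counts); at least three
#'   standards spanning a positive range.
#' @param symbol Element symbol to attach to the curve.
#' @return A [calibration_curve()] with slope/intercept minimizing squared
#'   response residuals, `r_squared` computed on the same pairs, and range
#'   set to `[min(ppb), max(ppb)]`.
#' @export
#' @examples
#' std <- data.frame(ppb = c(0.005, 0.05, 0.5, 2),
#'                   response = 9659.9875 * c(0.005, 0.05, 0.5, 2) + 200.0025)
#' fit_calibration(std, "Hg")
fit_calibration <- function(standards, symbol = "X") {
  standards <- as.data.frame(standards)
  if (!all(c("ppb", "response") %in% names(standards))) {
    stop("standards must have columns 'ppb' and 'response'", call. = FALSE)
  }
  if (nrow(standards) < 3) {
    stop("calibration requires at least 3 standards", call. = FALSE)
  }
  if (any(standards$ppb < 0)) {
    stop("standard concentrations must be non-negative", call. = FALSE)
  }
  if (stats::var(standards$ppb) == 0) {
    stop("standards have zero concentration variance; cannot fit", call. = FALSE)
  }
  fit <- stats::lm(response ~ ppb, data = standards)
  coefs <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((standards$response - mean(standards$response))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  calibration_curve(symbol,
                    slope = unname(coefs["ppb"]),
                    intercept = unname(coefs["(Intercept)"]),
                    r_squared = min(max(r2, 0), 1),
                    cal_low = min(standards$ppb),
                    cal_high = max(standards$ppb))
}

#' Invert a calibration curve
#'
#' Maps raw instrument counts back to a concentration in ppb. Negative
#' back-calculated values (response below the intercept) are flagged
#' `censored_at_zero`; values outside the calibration range are flagged
#' out of range.
#'
#' @param response Numeric vector of instrument counts.
#' @param curve A [calibration_curve()].
#' @return Tibble with columns `response`, `ppb` (raw back-calculated
#'   value), `censored_at_zero`, `in_range`.
#' @export
invert_calibration <- function(response, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  ppb <- (response - curve$intercept) / curve$slope
  tibble::tibble(
    response = response,
    ppb = ppb,
    censored_at_zero = ppb < 0,
    in_range = ppb >= curve$cal_low & ppb <= curve$cal_high
  )
}

#' Describe the digestion and dilution of one tablet
#'
#' Records the digested tablet mass `m` and the dilution chain applied to
#' the digest before instrument intake. The effective diluted volume is
#' `V = digest_volume_ml * prod(dilution_factors)`; in the reference
#' preparation (0.4 g digested into 10 ml, diluted 1/4 then 1/100 then 1/5)
#' this gives V = 20000 ml, the volume that the ppb-to-ug/g conversion uses.
#'
#' @param tablet_mass_g Digested mass, g.
#' @param digest_volume_ml Initial digest volume, ml.
#' @param dilution_factors Ordered fold-dilutions applied downstream.
#' @return A `sample_prep` object with derived `effective_volume_ml`.
#' @export
#' @examples
#' prep <- sample_prep() # the reference preparation
#' effective_volume(prep) # 20000 ml
sample_prep <- function(tablet_mass_g = 0.4, digest_volume_ml = 10,
                        dilution_factors = c(4, 100, 5)) {
  if (!is.numeric(tablet_mass_g) || tablet_mass_g <= 0) {
    stop("tablet_mass_g must be positive", call. = FALSE)
  }
  if (!is.numeric(digest_volume_ml) || digest_volume_ml <= 0) {
    stop("digest_volume_ml must be positive", call. = FALSE)
  }
  if (length(dilution_factors) > 0 &&
      (!is.numeric(dilution_factors) || any(dilution_factors <= 0))) {
    stop("dilution_factors must all be positive", call. = FALSE)
  }
  structure(
    list(
      tablet_mass_g = tablet_mass_g,
      digest_volume_ml = digest_volume_ml,
      dilution_factors = as.numeric(dilution_factors),
      effective_volume_ml = digest_volume_ml * prod(as.numeric(dilution_factors))
    ),
    class = "sample_prep"
  )
}

#' @export
print.sample_prep <- function(x, ...) {
  cat(sprintf("<sample_prep> m = %g g, digest %g ml x (%s) -> V = %g ml\n",
              x$tablet_mass_g, x$digest_volume_ml,
              paste(x$dilution_factors, collapse = ", "),
              x$effective_volume_ml))
  invisible(x)
}

#' Effective diluted volume of a preparation
#'
#' @param prep A [sample_prep()].
#' @return Volume in ml.
#' @export
effective_volume <- function(prep) {
  stopifnot(inherits(prep, "sample_prep"))
  prep$effective_volume_ml
}

#' Aggregate replicate instrument readings
#'
#' Computes the per sample-by-element replicate mean and sample (n-1)
#' standard deviation in ppb, applies detection-limit censoring
#' (`censored` when the mean falls below the element LOD; sub-LOD
#' replicates are retained in the mean, no substitution rule is applied),
#' and flags whether the mean lies within the calibration range.
#'
#' @param readings Tibble with columns `sample_id`, `element`, `value`
#'   (ppb); one row per replicate.
#' @param refs Element reference set.
#' @return Tibble with columns `sample_id`, `element`, `mean_ppb`,
#'   `sd_ppb`, `n_replicates`, `censored`, `in_range`.
#' @export
summarize_replicates <- function(readings, refs = default_reference_set()) {
  readings <- tibble::as_tibble(readings)
  required <- c("sample_id", "element", "value")
  missing_cols <- setdiff(required, names(readings))
  if (length(missing_cols) > 0) {
    stop("readings are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(readings) == 0) {
    stop("readings table is empty", call. = FALSE)
  }
  unknown <- setdiff(unique(readings$element), refs$symbol)
  if (length(unknown) > 0) {
    stop("unknown element(s) in readings: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(readings$value)) || any(readings$value < 0)) {
    stop("replicate values must be finite and >= 0", call. = FALSE)
  }
  out <- readings |>
    dplyr::group_by(.data$sample_id, .data$element) |>
    dplyr::summarise(
      mean_ppb = mean(.data$value),
      sd_ppb = ifelse(dplyr::n() > 1, stats::sd(.data$value), 0),
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      refs[, c("symbol", "lod", "cal_low", "cal_high")],
      by = c(element = "symbol")
    ) |>
    dplyr::mutate(
      censored = .data$mean_ppb < .data$lod,
      in_range = .data$mean_ppb >= .data$cal_low &
        .data$mean_ppb <= .data$cal_high
    ) |>
    dplyr::select("sample_id", "element", "mean_ppb", "sd_ppb",
                  "n_replicates", "censored", "in_range")
  out
}

#' Convert censored ppb summaries to matrix concentrations
#'
#' Applies the dilution-chain conversion `C [ug/g] = a * V / m * 1e-3`,
#' where `a` is the replicate-mean instrument reading (ppb = ng/ml), `V`
#' the effective diluted volume (ml) and `m` the digested tablet mass (g);
#' the `1e-3` factor converts ng to ug. Standard deviations are propagated
#' by the same exact linear scaling. Censoring is absorbing: censored
#' summaries yield censored concentration records with no numeric value,
#' never an exception.
#'
#' @param summaries Output of [summarize_replicates()].
#' @param prep A [sample_prep()].
#' @return Tibble with columns `sample_id`, `element`, `c_ug_per_g`,
#'   `sd_ug_per_g`, `censored` (`NA` concentration when censored).
#' @export
#' @examples
#' s <- tibble::tibble(sample_id = "S1", element = "Hg", mean_ppb = 0.005,
#'                     sd_ppb = 0.002, n_replicates = 3, censored = FALSE,
#'                     in_range = TRUE)
#' ppb_to_ug_per_g(s, sample_prep()) # C = 0.25 ug/g
ppb_to_ug_per_g <- function(summaries, prep = sample_prep()) {
  stopifnot(inherits(prep, "sample_prep"))
  summaries <- tibble::as_tibble(summaries)
  factor <- effective_volume(prep) / prep$tablet_mass_g * 1e-3
  tibble::tibble(
    sample_id = summaries$sample_id,
    element = summaries$element,
    c_ug_per_g = ifelse(summaries$censored, NA_real_,
                        summaries$mean_ppb * factor),
    sd_ug_per_g = ifelse(summaries$censored, NA_real_,
                         summaries$sd_ppb * factor),
    censored = summaries$censored
  )
}

#' Read a delimited replicate-readings table
#'
#' Expected columns: `sample_id`, `element`, `replicate`, `value`, and
#' optionally `value_kind` (`"ppb"`, the default, or `"counts"`; counts
#' rows are back-calculated through the matching calibration curve).
#'
#' @param path CSV file path.
#' @param refs Element reference set used to validate symbols.
#' @param curves Named list of calibration curves, required when any row
#'   carries `value_kind == "counts"`.
#' @return Tibble with columns `sample_id`, `element`, `replicate`,
#'   `value` (ppb).
#' @export
read_readings <- function(path, refs = default_reference_set(),
                          curves = default_calibration_curves()) {
  if (!file.exists(path)) stop("readings file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("readings file is empty: ", path, call. = FALSE)
  required <- c("sample_id", "element", "replicate", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("readings file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(df$element), refs$symbol)
  if (length(unknown) > 0) {
    stop("unknown element(s) in readings: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!"value_kind" %in% names(df)) df$value_kind <- "ppb"
  bad_kind <- setdiff(unique(df$value_kind), c("ppb", "counts"))
  if (length(bad_kind) > 0) {
    stop("unknown value_kind: ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  }
  is_counts <- df$value_kind == "counts"
  if (any(is_counts)) {
    if (is.null(curves)) {
      stop("counts readings require calibration curves", call. = FALSE)
    }
    for (sym in unique(df$element[is_counts])) {
      curve <- curves[[sym]]
      if (is.null(curve)) {
        stop("no calibration curve for element '", sym, "'", call. = FALSE)
      }
      idx <- is_counts & df$element == sym
      ppb <- invert_calibration(df$value[idx], curve)$ppb
      df$value[idx] <- pmax(ppb, 0)
    }
  }
  tibble::as_tibble(df[, c("sample_id", "element", "replicate", "value")])
}

#' Write a measurement-summary or concentration table
#'
#' Human-readable rendering: censored cells print `"< LOD"` (summaries) or
#' `"NC"` (concentrations). A full-precision machine-readable companion is
#' written alongside with suffix `_full.csv` and is the file downstream
#' stages re-read.
#'
#' @param x Output of [summarize_replicates()] or [ppb_to_ug_per_g()].
#' @param path Output CSV path (the formatted file).
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(x, path) {
  x <- tibble::as_tibble(x)
  full_path <- sub("\\.csv$", "_full.csv", path)
  if (identical(full_path, path)) full_path <- paste0(path, "_full.csv")
  utils::write.csv(x, full_path, row.names = FALSE, na = "")
  fmt <- as.data.frame(x)
  if ("mean_ppb" %in% names(fmt)) {
    shown <- sprintf("%.3f ± %.3f", fmt$mean_ppb, fmt$sd_ppb)
    shown[fmt$censored] <- "< LOD"
    fmt$mean_ppb <- shown
    fmt$sd_ppb <- NULL
  }
  if ("c_ug_per_g" %in% names(fmt)) {
    shown <- sprintf("%.2f ± %.3f", fmt$c_ug_per_g, fmt$sd_ug_per_g)
    shown[fmt$censored] <- "NC"
    fmt$c_ug_per_g <- shown
    fmt$sd_ug_per_g <- NULL
  }
  utils::write.csv(fmt, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a full-precision concentration table
#'
#' @param path Path to a `*_full.csv` written by [write_quant_table()].
#' @return Concentration tibble as produced by [ppb_to_ug_per_g()].
#' @export
read_concentrations <- function(path) {
  if (!file.exists(path)) {
    stop("concentration file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "element", "c_ug_per_g", "censored")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("concentration file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$censored <- as.logical(df$censored)
  if (!"sd_ug_per_g" %in% names(df)) df$sd_ug_per_g <- NA_real_
  tibble::as_tibble(df[, c("sample_id", "element", "c_ug_per_g",
                           "sd_ug_per_g", "censored")])
}
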