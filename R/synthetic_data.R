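# Multiplicative replicate noise: normal truncated at zero, sampled by
# inverse CDF so a single seed yields a deterministic stream.
rtnorm_pos <- function(n, mean = 1, sd = 0.3) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

#' Generate calibration standards from a known response line
#'
#' Emits `(ppb, response)` pairs on the curve's line, optionally perturbed
#' by multiplicative truncated-normal noise on the response. Noise 0 gives
#' the exact line. Fewer than three levels are emitted but flagged as
#' insufficient for fitting.
#'
#' @param curve A [calibration_curve()] supplying the true line.
#' @param levels Standard concentrations, ppb (positive).
#' @param noise_rel_sd Relative SD of the multiplicative response noise.
#' @param seed Integer seed.
#' @return Tibble with columns `ppb`, `response`, and attribute
#'   `sufficient_for_fit`.
#' @export
generate_calibration_standards <- function(curve, levels,
                                           noise_rel_sd = 0, seed = 1L) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(levels <= 0)) stop("standard levels must be positive", call. = FALSE)
  if (noise_rel_sd < 0) stop("noise_rel_sd must be >= 0", call. = FALSE)
  truth <- curve$slope * levels + curve$intercept
  noise <- withr::with_seed(as.integer(seed),
                            rtnorm_pos(length(levels), 1, noise_rel_sd))
  out <- tibble::tibble(ppb = levels, response = truth * noise)
  attr(out, "sufficient_for_fit") <- length(levels) >= 3
  out
}

#' Define a spiked synthetic panel
#'
#' Emulates the structure of a screened supplement panel: each sample
#' carries at most one detected element at a true matrix concentration in
#' ug/g; every other element is truly zero and yields only sub-detection
#' instrument noise.
#'
#' @param spikes Data frame with columns `sample_id`, `element`,
#'   `true_c_ug_per_g`; samples absent from it carry no spike. `element`
#'   may repeat across samples but not within one.
#' @param sample_ids All sample identifiers in the panel (defaults to the
#'   ids present in `spikes`).
#' @param n_replicates Replicates per sample-by-element cell (default 3,
#'   the triplicate design).
#' @param noise_rel_sd Relative SD of replicate reading noise (default
#'   0.3, the magnitude seen in triplicate sub-ppb readings).
#' @param seed Integer seed.
#' @return A `spike_plan` object.
#' @export
spike_plan <- function(spikes, sample_ids = NULL, n_replicates = 3,
                       noise_rel_sd = 0.3, seed = 1L) {
  spikes <- tibble::as_tibble(spikes)
  required <- c("sample_id", "element", "true_c_ug_per_g")
  if (nrow(spikes) > 0) {
    missing_cols <- setdiff(required, names(spikes))
    if (length(missing_cols) > 0) {
      stop("spikes are missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    if (any(spikes$true_c_ug_per_g < 0)) {
      stop("true concentrations must be >= 0", call. = FALSE)
    }
    if (anyDuplicated(spikes$sample_id) > 0) {
      stop("at most one spiked element per sample", call. = FALSE)
    }
  }
  if (is.null(sample_ids)) sample_ids <- unique(spikes$sample_id)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (noise_rel_sd < 0) stop("noise_rel_sd must be >= 0", call. = FALSE)
  structure(
    list(spikes = spikes, sample_ids = sample_ids,
         n_replicates = as.integer(n_replicates),
         noise_rel_sd = noise_rel_sd, seed = as.integer(seed)),
    class = "spike_plan"
  )
}

#' The reference 12-sample panel design
#'
#' A panel shaped like the study's screening result: Hg spiked in samples
#' 1, 2, 8 and 9 at 0.25, 0.45, 0.30 and 0.40 ug/g; Cr in samples 5, 10
#' and 11 at 0.55, 0.80 and 0.65 ug/g; samples 3, 4, 6, 7 and 12 clean.
#'
#' @inheritParams spike_plan
#' @return A `spike_plan` over samples `S1`..`S12`.
#' @export
study_spike_plan <- function(noise_rel_sd = 0.3, seed = 1L) {
  spikes <- tibble::tibble(
    sample_id = c("S01", "S02", "S08", "S09", "S05", "S10", "S11"),
    element = c("Hg", "Hg", "Hg", "Hg", "Cr", "Cr", "Cr"),
    true_c_ug_per_g = c(0.25, 0.45, 0.30, 0.40, 0.55, 0.80, 0.65)
  )
  spike_plan(spikes,
             sample_ids = sprintf("S%02d", 1:12),
             n_replicates = 3, noise_rel_sd = noise_rel_sd, seed = seed)
}

#' Generate a synthetic replicate-readings panel
#'
#' For spiked cells, the true instrument reading is the exact inversion of
#' the dilution-chain conversion, `a = C * m * 1000 / V` ppb, perturbed
#' per replicate by multiplicative truncated-normal noise; noise 0 gives
#' exact readings. True-zero cells draw replicates uniformly on
#' `[0, LOD/2]`, guaranteeing censoring while exercising nonzero signals.
#' A spike whose expected reading falls below the element LOD is still
#' emitted but flagged with a warning (it exercises the censoring path).
#'
#' @param plan A [spike_plan()].
#' @param prep A [sample_prep()].
#' @param refs Element reference set.
#' @return Readings tibble (`sample_id`, `element`, `replicate`, `value`
#'   in ppb) directly consumable by [summarize_replicates()].
#' @export
#' @examples
#' panel <- generate_panel(study_spike_plan(noise_rel_sd = 0), sample_prep())
#' subset(panel, element == "Hg" & sample_id == "S01") # 0.005 ppb each
generate_panel <- function(plan, prep = sample_prep(),
                           refs = default_reference_set()) {
  stopifnot(inherits(plan, "spike_plan"), inherits(prep, "sample_prep"))
  unknown <- setdiff(plan$spikes$element, refs$symbol)
  if (length(unknown) > 0) {
    stop("unknown element(s) in spike plan: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  grid <- expand.grid(sample_id = plan$sample_ids, element = refs$symbol,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$sample_id, match(grid$element, refs$symbol)), ]
  grid <- dplyr::left_join(grid, plan$spikes,
                           by = c("sample_id", "element"))
  grid$lod <- refs$lod[match(grid$element, refs$symbol)]
  # expected ppb reading for spiked cells via exact inversion of the
  # ppb -> ug/g conversion
  grid$a_true <- grid$true_c_ug_per_g * prep$tablet_mass_g * 1000 /
    effective_volume(prep)
  low_spikes <- !is.na(grid$a_true) & grid$a_true < grid$lod
  if (any(low_spikes)) {
    warning("spike(s) with expected reading below LOD (censoring path): ",
            paste(unique(grid$element[low_spikes]), collapse = ", "),
            call. = FALSE)
  }
  n_rep <- plan$n_replicates
  n_cells <- nrow(grid)
  values <- withr::with_seed(plan$seed, {
    spiked <- !is.na(grid$a_true)
    v <- numeric(n_cells * n_rep)
    base <- rep(ifelse(spiked, grid$a_true, 0), each = n_rep)
    is_spike_row <- rep(spiked, each = n_rep)
    v[is_spike_row] <- base[is_spike_row] *
      rtnorm_pos(sum(is_spike_row), 1, plan$noise_rel_sd)
    lod_rows <- rep(grid$lod, each = n_rep)[!is_spike_row]
    v[!is_spike_row] <- stats::runif(sum(!is_spike_row), 0, lod_rows / 2)
    v
  })
  tibble::tibble(
    sample_id = rep(grid$sample_id, each = n_rep),
    element = rep(grid$element, each = n_rep),
    replicate = rep(seq_len(n_rep), times = n_cells),
    value = values
  )
}

#' Write a synthetic panel in the readings format
#'
#' @param panel Output of [generate_panel()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_readings <- function(panel, path) {
  panel <- tibble::as_tibble(panel)
  panel$value_kind <- "ppb"
  utils::write.csv(panel, path, row.names = FALSE)
  invisible(path)
}
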