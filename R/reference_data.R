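#' Element symbols covered by the packaged reference set
#'
#' The ten elemental impurities routinely screened in orally administered
#' products: the ICH Q3D Class 1 elements (Cd, Pb, As, Hg), Class 2A (Co, V,
#' Ni) and the Class 3 elements commonly encountered in oral dosage forms
#' (Cr, Sb, Sn).
#'
#' @format Character vector of length 10.
#' @export
ELEMENT_SYMBOLS <- c("Cd", "Pb", "As", "Hg", "Co", "V", "Ni", "Cr", "Sb", "Sn")

# Columns every element reference set must carry, in canonical order.
.ref_columns <- c(
  "symbol", "isotope", "ich_class", "rfd", "pde", "csf",
  "lod", "cal_low", "cal_high", "note"
)

#' Packaged default element reference set
#'
#' Regulatory and instrumental constants for the ten screened elements:
#' ICH Q3D class, USEPA oral reference dose (RfD, mg/kg/day), oral permitted
#' daily exposure (PDE, ug/day), cancer slope factor (CSF, (mg/kg/day)^-1,
#' defined only for the five carcinogens Cd, Cr, Pb, Ni and As), ICP-MS limit
#' of detection (ppb) and calibration range (ppb).
#'
#' Pb carries no oral RfD, so hazard quotients for Pb are not computable and
#' are reported as such rather than as zero. The Ni RfD is 0.02 mg/kg/day
#' (20 ug/kg/day); some compendial listings print the same figure in
#' ug/kg/day units without converting, recorded in the `note` column.
#'
#' @return A validated `element_ref` tibble with one row per element.
#' @seealso [load_reference_set()], [csf_for()]
#' @export
#' @examples
#' refs <- default_reference_set()
#' refs[refs$symbol == "Hg", c("rfd", "pde", "lod")]
default_reference_set <- function() {
  refs <- tibble::tibble(
    symbol    = ELEMENT_SYMBOLS,
    isotope   = c(111L, 208L, 75L, 202L, 59L, 51L, 60L, 52L, 121L, 118L),
    ich_class = c("1", "1", "1", "1", "2A", "2A", "2A", "3", "3", "3"),
    rfd       = c(0.0005, NA, 0.0003, 0.0003, 0.0003, 0.005, 0.02, 0.003,
                  0.0004, 0.6),
    pde       = c(5, 5, 15, 30, 50, 100, 200, 11000, 1200, 6000),
    csf       = c(0.38, 0.0085, 1.5, NA, NA, NA, 1.7, 0.5, NA, NA),
    lod       = c(0.01, 0.01, 0.01, 0.001, 0.01, 0.002, 0.01, 0.001,
                  0.002, 0.002),
    cal_low   = c(0.1, 0.1, 0.1, 0.005, 0.1, 0.1, 0.1, 0.01, 0.01, 0.01),
    cal_high  = c(1000, 1000, 1000, 2, 1000, 1000, 1000, 50, 500, 500),
    note      = c(
      NA, "no oral RfD established; HQ not computable", NA, NA, NA, NA,
      "RfD 0.02 mg/kg/day (20 ug/kg/day); also seen printed as 20000 in ug/kg/day units",
      NA, NA, NA
    )
  )
  validate_reference_set(refs)
}

#' Validate an element reference set
#'
#' Checks structural and range invariants: unique symbols, positive PDE and
#' LOD, `cal_low < cal_high`, `lod <= cal_low`, positive RfD/CSF where
#' present, and a recognised ICH class.
#'
#' @param refs A data frame with the columns of [default_reference_set()]
#'   (`note` optional).
#' @return The validated set as an `element_ref` tibble, columns in
#'   canonical order.
#' @export
validate_reference_set <- function(refs) {
  refs <- tibble::as_tibble(refs)
  if (!"note" %in% names(refs)) refs$note <- NA_character_
  missing_cols <- setdiff(.ref_columns, names(refs))
  if (length(missing_cols) > 0) {
    stop("reference set is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  refs <- refs[.ref_columns]
  if (anyNA(refs$symbol) || any(!nzchar(refs$symbol))) {
    stop("reference set contains an empty element symbol", call. = FALSE)
  }
  dup <- refs$symbol[duplicated(refs$symbol)]
  if (length(dup) > 0) {
    stop("duplicate element symbol(s) in reference set: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }

  check_field <- function(ok, field) {
    bad <- refs$symbol[!ok]
    if (length(bad) > 0) {
      stop(sprintf("invalid '%s' for element(s): %s",
                   field, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  check_field(refs$ich_class %in% c("1", "2A", "2B", "3"), "ich_class")
  check_field(!is.na(refs$isotope) & refs$isotope > 0, "isotope")
  check_field(!is.na(refs$pde) & refs$pde > 0, "pde")
  check_field(!is.na(refs$lod) & refs$lod > 0, "lod")
  check_field(!is.na(refs$cal_low) & !is.na(refs$cal_high) &
                refs$cal_low < refs$cal_high, "cal_low/cal_high")
  check_field(refs$lod <= refs$cal_low, "lod (must not exceed cal_low)")
  check_field(is.na(refs$rfd) | refs$rfd > 0, "rfd")
  check_field(is.na(refs$csf) | refs$csf > 0, "csf")

  refs$rfd <- as.numeric(refs$rfd)
  refs$csf <- as.numeric(refs$csf)
  refs$isotope <- as.integer(refs$isotope)
  class(refs) <- c("element_ref", class(tibble::tibble()))
  refs
}

#' Load an element reference set
#'
#' Reference constants are data, not code: the packaged defaults can be
#' overridden from a YAML file (one block per element) or an in-memory list
#' so that regulatory updates do not require a package release.
#'
#' @param source `NULL` for the packaged default, a path to a YAML file
#'   written by [write_reference_set()], or a named list of per-element
#'   field lists.
#' @return A validated `element_ref` tibble.
#' @export
#' @examples
#' refs <- load_reference_set()
#' path <- tempfile(fileext = ".yaml")
#' write_reference_set(refs, path)
#' identical_set <- load_reference_set(path)
load_reference_set <- function(source = NULL) {
  if (is.null(source)) {
    return(default_reference_set())
  }
  if (is.character(source) && length(source) == 1) {
    if (!file.exists(source)) {
      stop("reference config not found: ", source, call. = FALSE)
    }
    source <- yaml::read_yaml(source)
  }
  if (!is.list(source)) {
    stop("reference source must be NULL, a file path, or a list", call. = FALSE)
  }
  if (!is.null(source$elements)) source <- source$elements
  rows <- lapply(names(source), function(sym) {
    block <- source[[sym]]
    if (!is.list(block)) {
      stop("malformed reference block for element '", sym, "'", call. = FALSE)
    }
    get_num <- function(field, required = TRUE) {
      v <- block[[field]]
      if (is.null(v)) {
        if (required) {
          stop(sprintf("element '%s' is missing required field '%s'",
                       sym, field), call. = FALSE)
        }
        return(NA_real_)
      }
      if (!is.numeric(v) || length(v) != 1) {
        stop(sprintf("field '%s' of element '%s' must be a single number",
                     field, sym), call. = FALSE)
      }
      as.numeric(v)
    }
    tibble::tibble(
      symbol    = sym,
      isotope   = as.integer(get_num("isotope")),
      ich_class = as.character(block$ich_class %||% NA_character_),
      rfd       = get_num("rfd", required = FALSE),
      pde       = get_num("pde"),
      csf       = get_num("csf", required = FALSE),
      lod       = get_num("lod"),
      cal_low   = get_num("cal_low"),
      cal_high  = get_num("cal_high"),
      note      = as.character(block$note %||% NA_character_)
    )
  })
  validate_reference_set(dplyr::bind_rows(rows))
}

#' Serialize an element reference set to YAML
#'
#' Writes one block per element; optional fields (`rfd`, `csf`, `note`) are
#' omitted when absent so a reload reproduces the set field by field.
#'
#' @param refs An `element_ref` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reference_set <- function(refs, path) {
  refs <- validate_reference_set(refs)
  blocks <- lapply(seq_len(nrow(refs)), function(i) {
    row <- refs[i, ]
    block <- list(
      isotope   = row$isotope,
      ich_class = row$ich_class,
      pde       = row$pde,
      lod       = row$lod,
      cal_low   = row$cal_low,
      cal_high  = row$cal_high
    )
    if (!is.na(row$rfd)) block$rfd <- row$rfd
    if (!is.na(row$csf)) block$csf <- row$csf
    if (!is.na(row$note)) block$note <- row$note
    block
  })
  names(blocks) <- refs$symbol
  yaml::write_yaml(list(elements = blocks), path, precision = 15)
  invisible(path)
}

#' Look up one element in a reference set
#'
#' @param symbol Element symbol, e.g. `"Hg"`.
#' @param refs Reference set; packaged default if omitted.
#' @return A one-row `element_ref` tibble.
#' @export
ref_for <- function(symbol, refs = default_reference_set()) {
  stopifnot(is.character(symbol), length(symbol) == 1)
  hit <- refs[refs$symbol == symbol, ]
  if (nrow(hit) != 1) {
    stop("unknown element symbol: '", symbol, "'", call. = FALSE)
  }
  hit
}

#' Cancer slope factor for an element
#'
#' Returns the oral cancer slope factor, defined in this framework only for
#' the five carcinogenic elements Cd, Cr, Pb, Ni and As; `NA` signals
#' "non-carcinogenic in this framework" for the other elements.
#'
#' @inheritParams ref_for
#' @return A single numeric CSF in (mg/kg/day)^-1, or `NA_real_`.
#' @export
#' @examples
#' csf_for("Ni") # 1.7
#' csf_for("Hg") # NA: not treated as carcinogenic here
csf_for <- function(symbol, refs = default_reference_set()) {
  ref_for(symbol, refs)$csf
}

`%||%` <- function(x, y) if (is.null(x)) y else x
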