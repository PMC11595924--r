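#' Trait descriptors for the PEG screening assay
#'
#' The screen measures twelve traits per accession, treatment and replicate:
#' five morphological (germination percentage and seedling growth/biomass) and
#' seven biochemical (osmolyte, antioxidant and damage markers). Each trait
#' carries an orientation used when ranking accessions: `higher_is_better` for
#' every trait except lipid peroxidation (`LP`), a membrane-damage marker for
#' which accumulation indicates injury, not tolerance. Dry weight (`DW`)
#' typically *increases* under osmotic stress; it keeps `higher_is_better` by
#' default but, like any trait, its orientation can be overridden via
#' [ranking_config()].
#'
#' Units are carried as opaque labels and never converted.
#'
#' @return A tibble with one row per trait and columns `trait`, `label`,
#'   `units`, `category` (`"morphological"` or `"biochemical"`) and
#'   `orientation`.
#' @examples
#' trait_descriptors()
#' @export
trait_descriptors <- function() {
  tibble::tribble(
    ~trait, ~label,                       ~units,              ~category,       ~orientation,
    "GP",   "germination percentage",     "%",                 "morphological", "higher_is_better",
    "RL",   "root length",                "cm",                "morphological", "higher_is_better",
    "SL",   "shoot length",               "cm",                "morphological", "higher_is_better",
    "FW",   "seedling fresh weight",      "mg",                "morphological", "higher_is_better",
    "DW",   "seedling dry weight",        "mg",                "morphological", "higher_is_better",
    "PC",   "proline content",            "ug/g FW",           "biochemical",   "higher_is_better",
    "SSC",  "soluble sugar content",      "ug/g FW",           "biochemical",   "higher_is_better",
    "TPC",  "total phenolic content",     "ug/g FW",           "biochemical",   "higher_is_better",
    "AC",   "antioxidant activity",       "ug/g FW",           "biochemical",   "higher_is_better",
    "GPA",  "guaiacol peroxidase",        "units/min/g FW",    "biochemical",   "higher_is_better",
    "CAT",  "catalase activity",          "units/min/g FW",    "biochemical",   "higher_is_better",
    "LP",   "lipid peroxidation",         "nmol/g FW",         "biochemical",   "lower_is_better"
  )
}

#' @rdname trait_descriptors
#' @export
trait_names <- function() trait_descriptors()$trait

#' Stress treatment levels
#'
#' The assay exposes germinating seeds to three osmotic potentials imposed with
#' PEG-6000: distilled water (T0, control), 7.5% PEG (T1) and 15% PEG (T2).
#' `dose` is the stress level normalised to `[0, 1]`.
#'
#' @return A tibble with columns `treatment`, `peg_percent` and `dose`.
#' @examples
#' treatments()
#' @export
treatments <- function() {
  tibble::tibble(
    treatment = c("T0", "T1", "T2"),
    peg_percent = c(0, 7.5, 15),
    dose = c(0, 0.5, 1)
  )
}

#' Germination percentage
#'
#' A seed counts as germinated once its radicle reaches 2 mm. The percentage is
#' `100 * germinated / total`.
#'
#' @param germinated Number of germinated seeds (vectorised).
#' @param total Number of seeds sown; must be positive and at least
#'   `germinated`.
#' @return Germination percentage in `[0, 100]`.
#' @examples
#' germination_percentage(25, 25)
#' germination_percentage(20, 25)
#' @export
germination_percentage <- function(germinated, total) {
  if (any(total <= 0)) {
    abort("`total` must be positive.", class = "pegscreen_invalid_input")
  }
  if (any(germinated < 0) || any(germinated > total)) {
    abort("`germinated` must lie in [0, total].",
          class = "pegscreen_invalid_input")
  }
  100 * germinated / total
}

# internal: resolve a treatment given either a code or a PEG percentage
normalize_treatment <- function(x) {
  tr <- treatments()
  x_chr <- trimws(as.character(x))
  out <- rep(NA_character_, length(x_chr))
  out[x_chr %in% tr$treatment] <- x_chr[x_chr %in% tr$treatment]
  num <- suppressWarnings(as.numeric(x_chr))
  idx <- is.na(out) & !is.na(num)
  if (any(idx)) {
    m <- match(num[idx], tr$peg_percent)
    out[idx] <- tr$treatment[m]
  }
  out
}
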