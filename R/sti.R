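#' Stress tolerance index (STI)
#'
#' Fernandez's selection index for a single trait:
#' `STI = (Y_p * Y_s) / Ybar_p^2`, where `Y_p` is the accession's mean under
#' control, `Y_s` its mean under stress, and `Ybar_p` the grand control mean
#' over all accessions. An average accession that loses nothing under stress
#' scores 1; total failure under stress scores 0. Higher is more tolerant,
#' and the product form rewards genotypes productive under *both* conditions.
#'
#' @param y_control Accession trait mean under the control treatment (>= 0).
#' @param y_stress Accession trait mean under the stress treatment (>= 0).
#' @param grand_control_mean Grand mean of the control means over all
#'   accessions; must be positive.
#' @return The STI value (vectorised).
#' @examples
#' compute_sti(8, 4, 8) # 0.5
#' @export
compute_sti <- function(y_control, y_stress, grand_control_mean) {
  if (any(grand_control_mean <= 0)) {
    abort("`grand_control_mean` must be positive.",
          class = "pegscreen_invalid_input")
  }
  if (any(y_control < 0) || any(y_stress < 0)) {
    abort("Trait means must be non-negative.",
          class = "pegscreen_invalid_input")
  }
  (y_control * y_stress) / grand_control_mean^2
}

#' Aggregate per-trait STI values for one accession
#'
#' Arithmetic mean over the configured STI trait set.
#'
#' @param per_trait_stis Non-empty numeric vector of per-trait STI values.
#' @return A single aggregate STI.
#' @export
aggregate_sti <- function(per_trait_stis) {
  if (length(per_trait_stis) == 0) {
    abort("Cannot aggregate an empty STI list.",
          class = "pegscreen_invalid_input")
  }
  mean(per_trait_stis)
}

#' Combine the two stress-level STIs
#'
#' The combined-scope index is the arithmetic mean of the moderate-stress
#' (T1) and severe-stress (T2) aggregate STIs.
#'
#' @param sti_t1,sti_t2 Aggregate STI under T1 and T2 (>= 0, vectorised).
#' @return The combined STI.
#' @examples
#' combined_sti(1.13, 1.07) # 1.10
#' @export
combined_sti <- function(sti_t1, sti_t2) {
  if (any(sti_t1 < 0) || any(sti_t2 < 0)) {
    abort("STI values must be non-negative.", class = "pegscreen_invalid_input")
  }
  (sti_t1 + sti_t2) / 2
}
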