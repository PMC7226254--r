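#' Differential drug-sensitivity score
#'
#' The screen's primary statistic: the difference in normalized viability
#' between the resistance-mutant line and the sensitive line for the same
#' compound and dose, `d = viability(E41K_C481S) - viability(E41K)`, in
#' percentage points. Positive d means the compound is selectively active
#' against the sensitive line (the expected profile of a covalent BTK
#' inhibitor); negative d at both doses is the collateral-sensitivity
#' signature. Vectorised; antisymmetric under swapping the lines.
#'
#' @param v_mut Viability (% of vehicle) of the resistant line `E41K_C481S`.
#' @param v_wt Viability (% of vehicle) of the sensitive line `E41K`.
#' @return `v_mut - v_wt`; NA (with a warning) where either member is NA.
#' @export
differential_score <- function(v_mut, v_wt) {
  d <- v_mut - v_wt
  if (anyNA(d)) {
    warning(sum(is.na(d)),
            " pair(s) missing a viability; scored as NA and excluded",
            call. = FALSE)
  }
  d
}

#' Quadrant of the dual-dose differential-score plane
#'
#' Maps the sign pair of (d at 100 nM, d at 1 uM) to the screen scatter's
#' quadrants: `(+,+)` upper_right, `(-,-)` lower_left, `(-,+)` upper_left,
#' `(+,-)` lower_right. Zero counts as non-negative, so the map is total and
#' mutually exclusive over the plane. Compounds selectively active against
#' the sensitive line land upper-right; collateral-sensitivity compounds
#' land lower-left.
#'
#' @param d_low,d_high Differential scores at the low (x-axis) and high
#'   (y-axis) dose; vectorised.
#' @return Character vector of quadrant labels (NA where a d is NA).
#' @export
classify_quadrant <- function(d_low, d_high) {
  dplyr::case_when(
    is.na(d_low) | is.na(d_high) ~ NA_character_,
    d_low >= 0 & d_high >= 0 ~ "upper_right",
    d_low < 0 & d_high < 0 ~ "lower_left",
    d_low < 0 ~ "upper_left",
    TRUE ~ "lower_right"
  )
}

#' Score a dual-dose screen
#'
#' Turns replicate-mean viabilities into the per-compound score table: one
#' row per compound with the mean viability of each line at each dose, the
#' differential score at each dose, the quadrant, and the candidate-hit flag
#' (`d <= -hit_threshold` at >= 1 dose). The score is computed on
#' replicate-mean viabilities.
#'
#' @param aggregated Output of [aggregate_replicates()].
#' @param doses_nM Length-2 vector: the low (x-axis) then high (y-axis) dose.
#' @param hit_threshold Candidate threshold in percentage points (> 0).
#' @return Tibble with columns `compound_id`, `v_wt_low`, `v_mut_low`,
#'   `v_wt_high`, `v_mut_high`, `d_low`, `d_high`, `quadrant`,
#'   `is_candidate_hit`, plus attributes recording the dose labels.
#' @export
score_screen <- function(aggregated, doses_nM = c(100, 1000),
                         hit_threshold = 20) {
  stopifnot(length(doses_nM) == 2, hit_threshold > 0)
  lo <- doses_nM[1]; hi <- doses_nM[2]
  sub <- dplyr::filter(aggregated, .data$dose_nM %in% doses_nM)
  wide <- tidyr::pivot_wider(
    dplyr::transmute(sub, .data$compound_id,
                     key = paste0(ifelse(.data$line == "E41K", "v_wt", "v_mut"),
                                  ifelse(.data$dose_nM == lo, "_low", "_high")),
                     .data$viability_pct),
    names_from = "key", values_from = "viability_pct")
  for (col in c("v_wt_low", "v_mut_low", "v_wt_high", "v_mut_high")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  out <- dplyr::mutate(
    wide,
    d_low = differential_score(.data$v_mut_low, .data$v_wt_low),
    d_high = differential_score(.data$v_mut_high, .data$v_wt_high),
    quadrant = classify_quadrant(.data$d_low, .data$d_high),
    is_candidate_hit = !is.na(.data$d_low) & !is.na(.data$d_high) &
      (.data$d_low <= -hit_threshold | .data$d_high <= -hit_threshold)
  )
  out <- dplyr::select(out, "compound_id", "v_wt_low", "v_mut_low",
                       "v_wt_high", "v_mut_high", "d_low", "d_high",
                       "quadrant", "is_candidate_hit")
  attr(out, "doses_nM") <- doses_nM
  attr(out, "hit_threshold") <- hit_threshold
  out
}

#' Select candidate hits from a score table
#'
#' A compound is a candidate when its differential score is at or below
#' `-threshold` at at least one dose (the one-dose rule used by the screen's
#' triage). Candidates are returned sorted by their most negative d.
#'
#' @param scores Output of [score_screen()].
#' @param threshold Percentage points, > 0.
#' @return The candidate rows of `scores`, with `min_d`, sorted ascending.
#' @export
select_candidate_hits <- function(scores, threshold = 20) {
  stopifnot(threshold > 0)
  cand <- dplyr::filter(scores,
                        !is.na(.data$d_low) & !is.na(.data$d_high) &
                          (.data$d_low <= -threshold |
                             .data$d_high <= -threshold))
  cand <- dplyr::mutate(cand, min_d = pmin(.data$d_low, .data$d_high))
  dplyr::arrange(cand, .data$min_d)
}
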