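#' Normalize well counts to percent-of-vehicle viability
#'
#' Anchors every well to the DMSO vehicle wells of its own plate x line
#' stratum: `viability_pct = 100 * count / mean(vehicle counts in stratum)`.
#' By construction the vehicle wells of each stratum average exactly 100
#' after normalization. Viability is deliberately not capped at 100, so
#' stimulatory compounds can exceed it and the differential score stays
#' antisymmetric.
#'
#' @param counts Tibble from [simulate_plate()] (or measured counts with the
#'   same columns: `plate_id`, `well`, `compound_id`, `dose_nM`, `line`,
#'   `replicate`, `role`, `count`).
#' @return The input rows minus `empty` wells, with a `viability_pct` column.
#' @export
normalize_viability <- function(counts) {
  counts <- dplyr::filter(counts, .data$role != "empty")
  veh <- dplyr::filter(counts, .data$role == "vehicle")
  anchors <- dplyr::summarise(
    dplyr::group_by(veh, .data$plate_id, .data$line),
    vehicle_mean = mean(.data$count), .groups = "drop")
  strata <- dplyr::distinct(counts, .data$plate_id, .data$line)
  missing <- dplyr::anti_join(strata, anchors, by = c("plate_id", "line"))
  if (nrow(missing) > 0) {
    stop("no vehicle wells in stratum (plate x line): ",
         paste(missing$plate_id, missing$line, sep = "/", collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::left_join(counts, anchors, by = c("plate_id", "line"))
  out$viability_pct <- 100 * out$count / out$vehicle_mean
  dplyr::select(out, -"vehicle_mean")
}

#' Average replicate viabilities per compound x line x dose
#'
#' Arithmetic mean across replicate wells; replicate count and range are kept
#' for QC.
#'
#' @param records Tibble with `compound_id`, `line`, `dose_nM`,
#'   `viability_pct` (typically [normalize_viability()] output filtered to
#'   `role == "compound"`).
#' @return Tibble with `compound_id`, `line`, `dose_nM`, `viability_pct`
#'   (mean), `n_replicates`, `replicate_range`.
#' @export
aggregate_replicates <- function(records) {
  if ("role" %in% names(records)) {
    records <- dplyr::filter(records, .data$role == "compound")
  }
  dplyr::summarise(
    dplyr::group_by(records, .data$compound_id, .data$line, .data$dose_nM),
    n_replicates = dplyr::n(),
    replicate_range = if (dplyr::n() == 0) NA_real_ else
      diff(range(.data$viability_pct)),
    viability_pct = mean(.data$viability_pct),
    .groups = "drop")
}

#' Plate quality control via the Z-prime factor
#'
#' Computes, per plate, the vehicle mean and CV, the positive-control mean,
#' and `z_prime = 1 - 3 * (sd_vehicle + sd_positive) / |mean_vehicle -
#' mean_positive|`. A plate whose control means coincide gets `z_prime =
#' -Inf`. Plates below `z_floor` are flagged, never dropped. By default only
#' the broadly cytotoxic control (pentamidine) enters the calculation: the
#' covalent BTK-inhibitor control is intentionally inactive on the resistant
#' line and would invalidate z-prime there.
#'
#' @param counts Tibble of well counts ([simulate_plate()] schema).
#' @param control_compound Positive-control compound id(s) used for z-prime.
#' @param z_floor Flagging threshold on z-prime.
#' @return Tibble with `plate_id`, `line`, `vehicle_mean`, `vehicle_cv`,
#'   `positive_control_mean`, `z_prime`, `flagged`.
#' @export
compute_plate_qc <- function(counts, control_compound = "pentamidine",
                             z_floor = 0.5) {
  per_plate <- function(df) {
    veh <- df$count[df$role == "vehicle"]
    pos <- df$count[df$role == "positive_control" &
                      df$compound_id %in% control_compound]
    if (length(veh) == 0 || length(pos) == 0) {
      stop("plate ", df$plate_id[1],
           ": missing vehicle or positive-control wells", call. = FALSE)
    }
    sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
    sep <- abs(mean(veh) - mean(pos))
    zp <- if (sep == 0) -Inf else 1 - 3 * (sd0(veh) + sd0(pos)) / sep
    tibble::tibble(vehicle_mean = mean(veh),
                   vehicle_cv = if (mean(veh) > 0) sd0(veh) / mean(veh) else NA_real_,
                   positive_control_mean = mean(pos),
                   z_prime = zp)
  }
  qc <- dplyr::reframe(dplyr::group_by(counts, .data$plate_id, .data$line),
                       per_plate(dplyr::pick(dplyr::everything())))
  qc$flagged <- qc$z_prime < z_floor
  qc
}
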