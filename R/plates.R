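#' 384-well names in row-letter / zero-padded-column form
#' @param row,col Integer vectors (1..16, 1..24).
#' @return Character well names `A01`..`P24`.
#' @export
well_name <- function(row, col) sprintf("%s%02d", LETTERS[row], col)

#' Build the screen's plate maps
#'
#' Lays out the full screen: for every line x dose x replicate combination,
#' as many 384-well plates as the library needs. On each plate, column 1
#' holds vehicle (DMSO) wells, column 24 holds positive controls (rows A-H
#' ibrutinib, rows I-P pentamidine, at the configured control dose), and
#' columns 2-23 hold library compounds filled column-major; surplus wells on
#' the last plate are marked `empty`. Each plate carries a single line at a
#' single dose, so the per-plate DMSO anchor is stratified by construction.
#'
#' @param config A [screen_config()].
#' @param profiles Library tibble from [generate_library()]; only
#'   `compound_id` is used.
#' @return A tibble with columns `plate_id`, `well`, `row`, `col`,
#'   `compound_id`, `dose_nM`, `line`, `replicate`, `role` (one of
#'   `compound`, `vehicle`, `positive_control`, `empty`).
#' @export
build_plate_maps <- function(config, profiles) {
  stopifnot(inherits(config, "screen_config"))
  compound_ids <- profiles$compound_id
  slots_per_plate <- 16L * 22L
  n_plates_per_combo <- max(1L, ceiling(length(compound_ids) / slots_per_plate))

  combos <- expand.grid(replicate = seq_len(config$n_replicates),
                        dose_nM = config$doses_nM,
                        line = cell_lines(),
                        stringsAsFactors = FALSE)

  grid <- expand.grid(row = 1:16, col = 1:24)
  one_plate_roles <- function(plate_index) {
    role <- rep("compound", nrow(grid))
    role[grid$col == 1] <- "vehicle"
    role[grid$col == 24] <- "positive_control"
    cmpd <- rep(NA_character_, nrow(grid))
    ctrl <- grid$col == 24
    cmpd[ctrl] <- ifelse(grid$row[ctrl] <= 8, "ibrutinib", "pentamidine")
    slot_cells <- grid$col >= 2 & grid$col <= 23
    # column-major within the compound block
    ord <- order(grid$col[slot_cells], grid$row[slot_cells])
    idx_global <- (plate_index - 1L) * slots_per_plate + seq_len(slots_per_plate)
    assigned <- compound_ids[idx_global]
    cmpd[which(slot_cells)[ord]] <- assigned
    role[slot_cells][is.na(cmpd[slot_cells])] <- "empty"
    tibble::tibble(row = grid$row, col = grid$col,
                   well = well_name(grid$row, grid$col),
                   compound_id = cmpd, role = role)
  }
  plate_templates <- lapply(seq_len(n_plates_per_combo), one_plate_roles)

  maps <- vector("list", nrow(combos) * n_plates_per_combo)
  k <- 0L
  for (i in seq_len(nrow(combos))) {
    for (p in seq_len(n_plates_per_combo)) {
      k <- k + 1L
      tmpl <- plate_templates[[p]]
      maps[[k]] <- dplyr::mutate(
        tmpl,
        plate_id = sprintf("P%03d", k),
        line = combos$line[i],
        replicate = combos$replicate[i],
        dose_nM = dplyr::case_when(
          role == "compound" ~ combos$dose_nM[i],
          role == "positive_control" ~ config$control_dose_nM,
          TRUE ~ 0
        )
      )
    }
  }
  out <- dplyr::bind_rows(maps)
  dplyr::select(out, "plate_id", "well", "row", "col", "compound_id",
                "dose_nM", "line", "replicate", "role")
}

# Multiplicative lognormal noise with unit mean and coefficient of
# variation `cv`; returns 1 exactly when cv = 0.
.lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate per-well live-cell counts for a plate map
#'
#' Each well's expected surviving count is
#' `cells_seeded * growth_factor * (1 - true_kill_fraction)`, where the kill
#' fraction comes from the well's compound profile at the well's dose (0 for
#' vehicle wells), perturbed by multiplicative lognormal noise with CV
#' `cv_well_noise`. Counts are left continuous: with `cv_well_noise = 0` they
#' equal the expectation exactly, which downstream normalization relies on.
#'
#' @param plate_map Tibble from [build_plate_maps()].
#' @param profiles Compound profiles covering every `compound_id` referenced
#'   by non-vehicle, non-empty wells (library plus [control_profiles()]).
#' @param config A [screen_config()].
#' @param seed Integer seed; defaults to the plate stream of the master seed.
#' @return `plate_map` with a numeric `count` column (NA for `empty` wells).
#' @export
simulate_plate <- function(plate_map, profiles, config,
                           seed = stage_seed(config$rng_seed, "plate")) {
  stopifnot(inherits(config, "screen_config"))
  needed <- unique(plate_map$compound_id[plate_map$role %in%
                                           c("compound", "positive_control")])
  unknown <- setdiff(needed, profiles$compound_id)
  if (length(unknown) > 0) {
    stop("plate map references unknown compound(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  idx <- match(plate_map$compound_id, profiles$compound_id)
  kill <- rep(0, nrow(plate_map))
  has_cmpd <- !is.na(idx) & plate_map$role != "empty"
  kill[has_cmpd] <- true_kill_fraction(profiles[idx[has_cmpd], ],
                                       plate_map$line[has_cmpd],
                                       plate_map$dose_nM[has_cmpd])
  expected <- config$cells_seeded_per_well * config$growth_factor * (1 - kill)
  out <- plate_map
  withr::with_seed(seed, {
    out$count <- expected * .lognormal_noise(nrow(out), config$cv_well_noise)
  })
  out$count[out$role == "empty"] <- NA_real_
  out
}
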