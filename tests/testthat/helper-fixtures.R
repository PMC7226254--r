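# Small screen configuration used across tests: same plate geometry and
# class structure as the full screen, fewer compounds.
tiny_config <- function(n_compounds = 12, cv = 0, seed = 42L, ...) {
  screen_config(
    n_compounds = n_compounds,
    class_proportions = c(btk_inhibitor = 0.25, pi3k_inhibitor = 0.25,
                          cytotoxic = 0.25, collateral_sensitive = 0.25),
    cv_well_noise = cv,
    rng_seed = seed,
    ...
  )
}

# One-row compound profile with explicit parameters, for oracle arithmetic.
profile_row <- function(ic50_sens, ic50_res, hill = 1, max_kill = 1,
                        id = "X", class = "cytotoxic") {
  tibble::tibble(compound_id = id, effect_class = class,
                 ic50_sensitive_nM = ic50_sens, ic50_resistant_nM = ic50_res,
                 hill_slope = hill, max_kill = max_kill)
}

# Minimal single-plate count table: one vehicle pair, one positive control,
# plus caller-specified compound wells.
mini_counts <- function(compound_counts, vehicle_counts = c(80, 120),
                        pos_counts = 10, line = "E41K", plate = "P001") {
  n_c <- length(compound_counts)
  n_v <- length(vehicle_counts)
  n_p <- length(pos_counts)
  tibble::tibble(
    plate_id = plate,
    well = well_name(seq_len(n_c + n_v + n_p), 1),
    compound_id = c(sprintf("C%02d", seq_len(n_c)), rep(NA, n_v),
                    rep("pentamidine", n_p)),
    dose_nM = c(rep(100, n_c), rep(0, n_v), rep(1000, n_p)),
    line = line,
    replicate = 1L,
    role = c(rep("compound", n_c), rep("vehicle", n_v),
             rep("positive_control", n_p)),
    count = c(compound_counts, vehicle_counts, pos_counts)
  )
}
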