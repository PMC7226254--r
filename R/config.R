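#' Screen simulation configuration
#'
#' Builds the configuration object that drives every stage of the simulated
#' screen: library composition, plate design, noise levels and analysis
#' thresholds. Defaults reproduce the screen design the package models: a
#' 590-compound kinase-inhibitor library tested in duplicate at 100 nM and
#' 1 uM on two isogenic reporter lines seeded at 10,000 cells per 384-well
#' plate well, read out after 48 h by counting GFP-positive cells over 5
#' imaging fields per well.
#'
#' @param n_compounds Number of library compounds.
#' @param class_proportions Named numeric vector of effect-class mixture
#'   proportions over `btk_inhibitor`, `pi3k_inhibitor`, `cytotoxic`,
#'   `collateral_sensitive`, `inert`. Must sum to 1 (tolerance 1e-9).
#' @param doses_nM Screening doses in nM (strictly positive).
#' @param n_replicates Replicate wells per compound x line x dose.
#' @param cells_seeded_per_well Cells seeded per well.
#' @param growth_factor Deterministic 48 h expansion factor applied to every
#'   well of either line (both lines are IL3-independent in the screen, so a
#'   single factor suffices; it cancels out of normalized viability).
#' @param cv_well_noise Coefficient of variation of the multiplicative
#'   lognormal well noise on counts. 0 gives noise-free counts.
#' @param fields_per_well Imaging fields acquired per well.
#' @param field_fraction Fraction of a well's cells visible in one field
#'   (sets the rendered cell density when the image route is used).
#' @param control_dose_nM Dose applied to positive-control wells.
#' @param hit_threshold Candidate-hit threshold on the differential score, in
#'   percentage points: a compound is a candidate when d <= -hit_threshold at
#'   at least one dose.
#' @param ratio_threshold IC50-ratio threshold for calling a resistance or
#'   collateral-sensitivity phenotype in dose-response confirmation.
#' @param rng_seed Master seed; per-stage seeds are derived from it via
#'   [stage_seed()].
#'
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(n_compounds = 590,
                          class_proportions = c(btk_inhibitor = 0.02,
                                                pi3k_inhibitor = 0.04,
                                                cytotoxic = 0.15,
                                                collateral_sensitive = 0.005,
                                                inert = 0.785),
                          doses_nM = c(100, 1000),
                          n_replicates = 2,
                          cells_seeded_per_well = 10000,
                          growth_factor = 8,
                          cv_well_noise = 0.1,
                          fields_per_well = 5,
                          field_fraction = 0.005,
                          control_dose_nM = 1000,
                          hit_threshold = 20,
                          ratio_threshold = 10,
                          rng_seed = 1L) {
  if (!is.numeric(n_compounds) || length(n_compounds) != 1 || n_compounds < 0 ||
      n_compounds != round(n_compounds)) {
    stop("`n_compounds` must be a single non-negative integer", call. = FALSE)
  }
  if (is.null(names(class_proportions)) ||
      !all(names(class_proportions) %in% effect_classes())) {
    stop("`class_proportions` must be named with effect classes among: ",
         paste(effect_classes(), collapse = ", "), call. = FALSE)
  }
  if (any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-9) {
    stop("`class_proportions` must be non-negative and sum to 1 (tolerance 1e-9)",
         call. = FALSE)
  }
  if (length(doses_nM) == 0 || any(doses_nM <= 0)) {
    stop("`doses_nM` must be non-empty and strictly positive", call. = FALSE)
  }
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  if (cv_well_noise < 0) stop("`cv_well_noise` must be >= 0", call. = FALSE)
  if (fields_per_well < 1) stop("`fields_per_well` must be >= 1", call. = FALSE)
  if (hit_threshold <= 0) stop("`hit_threshold` must be > 0", call. = FALSE)
  if (ratio_threshold <= 1) stop("`ratio_threshold` must be > 1", call. = FALSE)

  structure(
    list(
      n_compounds = as.integer(n_compounds),
      class_proportions = class_proportions,
      doses_nM = as.numeric(doses_nM),
      n_replicates = as.integer(n_replicates),
      cells_seeded_per_well = cells_seeded_per_well,
      growth_factor = growth_factor,
      cv_well_noise = cv_well_noise,
      fields_per_well = as.integer(fields_per_well),
      field_fraction = field_fraction,
      control_dose_nM = control_dose_nM,
      hit_threshold = hit_threshold,
      ratio_threshold = ratio_threshold,
      rng_seed = as.integer(rng_seed)
    ),
    class = "screen_config"
  )
}

#' Effect classes recognised by the compound generator
#' @return Character vector of class names.
#' @export
effect_classes <- function() {
  c("btk_inhibitor", "pi3k_inhibitor", "cytotoxic", "collateral_sensitive",
    "inert")
}

#' Cell-line labels of the isogenic reporter pair
#'
#' `E41K` carries only the activating mutation (sensitive to covalent BTK
#' inhibition); `E41K_C481S` additionally carries the resistance mutation.
#' @return Character vector of the two line labels.
#' @export
cell_lines <- function() c("E41K", "E41K_C481S")

# Named stage offsets for seed splitting; order is part of the contract.
.stage_offsets <- c(library = 1L, plate = 2L, render = 3L,
                    dose_response = 4L, competition = 5L, pipeline = 6L)

#' Derive a per-stage seed from the master seed
#'
#' Stages draw from independent RNG streams derived deterministically from a
#' single master seed, so each stage is reproducible in isolation. The
#' splitting rule is a fixed affine map modulo the Mersenne prime 2^31 - 1:
#' `seed_stage = (master * 48271 + 7919 * offset) mod (2^31 - 1)`, with a
#' documented integer offset per stage name.
#'
#' @param master Master integer seed.
#' @param stage One of `"library"`, `"plate"`, `"render"`, `"dose_response"`,
#'   `"competition"`, `"pipeline"`.
#' @return A single integer seed below 2^31.
#' @export
stage_seed <- function(master, stage = names(.stage_offsets)) {
  stage <- match.arg(stage)
  off <- .stage_offsets[[stage]]
  as.integer((as.numeric(master) %% 2147483647 * 48271 + 7919 * off) %%
               2147483647)
}
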