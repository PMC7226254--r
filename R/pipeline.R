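#' Run the full simulated screen pipeline
#'
#' Orchestrates every stage end to end: compound-library generation, plate
#' layout, well-count simulation (optionally through rendered field images
#' and segmentation instead of tabular counts), DMSO normalization, plate
#' QC, replicate aggregation, differential scoring and quadrant
#' classification, candidate triage, and dose-response confirmation of the
#' candidates. All tabular outputs are written as CSV under `out_dir`,
#' followed by a JSON run manifest with a config hash and per-file MD5
#' checksums; re-running with the same config and seed reproduces
#' byte-identical tables.
#'
#' @param config A [screen_config()].
#' @param out_dir Output directory (created if needed); NULL skips writing.
#' @param seed Master seed (defaults to `config$rng_seed`); per-stage seeds
#'   derive from it via [stage_seed()].
#' @param use_images If TRUE, well counts are measured by rendering
#'   `fields_per_well` fields per well (at `field_fraction` visible cells)
#'   and counting them with [count_well()]; intended for small
#'   demonstration configs, as rendering every well of a full screen is
#'   slow. If FALSE (default) the simulated counts are used directly.
#' @param seg Segmentation parameters for the image route.
#' @param image_field_spec [field_spec()] used when rendering wells on the
#'   image route; pick small fields for demonstration configs.
#' @return Invisibly, a list with all stage tibbles (`profiles`,
#'   `plate_map`, `counts`, `qc`, `viability`, `aggregated`, `scores`,
#'   `candidates`, `dose_response`, `confirmations`) and the `manifest`.
#' @export
run_screen_pipeline <- function(config = screen_config(), out_dir = NULL,
                                seed = config$rng_seed, use_images = FALSE,
                                seg = seg_params(),
                                image_field_spec = field_spec(width = 512,
                                                              height = 512)) {
  stopifnot(inherits(config, "screen_config"))
  stage <- "generate_library"
  res <- tryCatch({
    profiles <- generate_library(config, seed = stage_seed(seed, "library"))
    all_profiles <- dplyr::bind_rows(profiles, control_profiles())

    stage <- "build_plate_maps"
    plate_map <- build_plate_maps(config, profiles)

    stage <- "simulate_plate"
    counts <- simulate_plate(plate_map, all_profiles, config,
                             seed = stage_seed(seed, "plate"))

    if (use_images) {
      stage <- "count_images"
      counts <- .recount_via_images(counts, config, seg, image_field_spec,
                                    seed = stage_seed(seed, "render"))
    }

    stage <- "compute_plate_qc"
    qc <- compute_plate_qc(counts)

    stage <- "normalize_viability"
    viability <- normalize_viability(counts)

    stage <- "aggregate_replicates"
    aggregated <- aggregate_replicates(viability)

    stage <- "score_screen"
    scores <- score_screen(aggregated, doses_nM = config$doses_nM,
                           hit_threshold = config$hit_threshold)
    candidates <- select_candidate_hits(scores, config$hit_threshold)

    stage <- "confirm_hits"
    dr_seed <- stage_seed(seed, "dose_response")
    dr_data <- dplyr::bind_rows(lapply(seq_len(nrow(candidates)), function(i) {
      id <- candidates$compound_id[i]
      prof <- dplyr::filter(all_profiles, .data$compound_id == id)
      dplyr::bind_rows(
        simulate_dose_response(prof, "E41K", confirmation_doses(),
                               cv = config$cv_well_noise / 2,
                               seed = dr_seed + 2L * i),
        simulate_dose_response(prof, "E41K_C481S", confirmation_doses(),
                               cv = config$cv_well_noise / 2,
                               seed = dr_seed + 2L * i + 1L))
    }))
    confirmations <- confirm_hits(candidates$compound_id, dr_data,
                                  config$ratio_threshold)
    list(profiles = profiles, plate_map = plate_map, counts = counts,
         qc = qc, viability = viability, aggregated = aggregated,
         scores = scores, candidates = candidates, dose_response = dr_data,
         confirmations = confirmations)
  }, error = function(e) {
    stop("pipeline failed at stage `", stage, "`: ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tables <- c("profiles", "plate_map", "counts", "qc", "viability",
                "aggregated", "scores", "candidates", "dose_response",
                "confirmations")
    paths <- file.path(out_dir, paste0(tables, ".csv"))
    for (i in seq_along(tables)) {
      readr::write_csv(res[[tables[i]]], paths[i])
    }
    res$manifest <- write_run_manifest(out_dir, config, seed, paths)
  }
  invisible(res)
}

# Replace each non-empty well's simulated count with an image-derived
# estimate: render fields holding `count * field_fraction` cells in total,
# segment, and scale the accepted count back to the well.
.recount_via_images <- function(counts, config, seg, spec, seed) {
  total_frac <- config$field_fraction * config$fields_per_well
  live <- which(counts$role != "empty")
  for (j in seq_along(live)) {
    i <- live[j]
    n_vis <- round(counts$count[i] * total_frac)
    fields <- render_well_fields(n_vis, config$fields_per_well, spec,
                                 seed = seed + j, split = "multinomial")
    counts$count[i] <- count_well(fields, seg)$count / total_frac
  }
  counts
}

#' Write the JSON run manifest
#'
#' Records the configuration (and its MD5 hash), the master seed, the
#' package version, MD5 checksums of every tabular output, and a timestamp.
#' Identical config + seed reproduce identical table checksums; the
#' timestamp is metadata and excluded from that guarantee.
#'
#' @param out_dir Run output directory.
#' @param config The [screen_config()] used.
#' @param seed Master seed used.
#' @param paths Character vector of written output files.
#' @return Invisibly, the manifest list (also written to `manifest.json`).
#' @export
write_run_manifest <- function(out_dir, config, seed, paths) {
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(config), cfg_file, auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("collatscreen")),
    seed = seed,
    config = unclass(config),
    config_md5 = unname(tools::md5sum(cfg_file)),
    outputs = lapply(stats::setNames(paths, basename(paths)),
                     function(p) list(md5 = unname(tools::md5sum(p)),
                                      bytes = file.size(p))),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Screen scatter of differential scores (quadrant plot)
#'
#' The screen's headline figure: every compound plotted by its differential
#' score at the low dose (x) and high dose (y), with quadrant gridlines at
#' zero and symmetric axes. Compounds selectively active against the
#' sensitive line fall upper-right; collateral-sensitivity compounds fall
#' lower-left. An effect class can be highlighted as large coloured dots
#' over the grey library.
#'
#' @param scores Output of [score_screen()].
#' @param profiles Optional library tibble supplying `effect_class` for
#'   highlighting.
#' @param highlight_class Effect class to emphasise, or NULL for the base
#'   plot.
#' @return A ggplot object.
#' @export
plot_screen <- function(scores, profiles = NULL, highlight_class = NULL) {
  stopifnot(nrow(scores) > 0)
  doses <- attr(scores, "doses_nM")
  labs <- if (!is.null(doses)) {
    sprintf("differential score d at %g nM (percentage points)", doses)
  } else {
    c("differential score d, low dose", "differential score d, high dose")
  }
  lim <- max(abs(c(scores$d_low, scores$d_high)), 1, na.rm = TRUE) * 1.05
  p <- ggplot2::ggplot(scores, ggplot2::aes(x = .data$d_low,
                                            y = .data$d_high)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(colour = "grey55", size = 1.3, alpha = 0.7) +
    ggplot2::coord_cartesian(xlim = c(-lim, lim), ylim = c(-lim, lim)) +
    ggplot2::labs(x = labs[1], y = labs[2]) +
    ggplot2::theme_classic()
  if (!is.null(highlight_class) && !is.null(profiles)) {
    hi <- dplyr::semi_join(
      scores,
      dplyr::filter(profiles, .data$effect_class == highlight_class),
      by = "compound_id")
    if (nrow(hi) > 0) {
      p <- p + ggplot2::geom_point(data = hi, colour = "firebrick",
                                   size = 2.6) +
        ggplot2::labs(subtitle = paste0(highlight_class,
                                        " compounds highlighted"))
    }
  }
  p
}
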