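#!/usr/bin/env Rscript
# Stage 3 — normalize, QC, and score the screen.
#
# Reads the simulated counts from stage 1, anchors every well to its plate's
# DMSO vehicle mean (100% viability), checks plate quality via the Z-prime
# factor, averages duplicates, computes the differential score
# d = viability(E41K_C481S) - viability(E41K) at 100 nM and 1 uM, classifies
# every compound into a quadrant, and triages candidate hits
# (d <= -20 points at >= 1 dose). Writes the score table and the quadrant
# scatter, plus BTK- and PI3K-class highlighted versions.

suppressPackageStartupMessages({
  library(collatscreen)
  library(dplyr)
})

out <- "results/screen"
counts <- readr::read_csv(file.path(out, "counts.csv"),
                          show_col_types = FALSE)
lib <- readr::read_csv(file.path(out, "library.csv"), show_col_types = FALSE)
cfg <- screen_config(rng_seed = 20260928L)

qc <- compute_plate_qc(counts)
viab <- normalize_viability(counts)
agg <- aggregate_replicates(viab)
scores <- score_screen(agg, doses_nM = cfg$doses_nM,
                       hit_threshold = cfg$hit_threshold)
candidates <- select_candidate_hits(scores, cfg$hit_threshold)

readr::write_csv(qc, file.path(out, "plate_qc.csv"))
readr::write_csv(scores, file.path(out, "scores.csv"))
readr::write_csv(candidates, file.path(out, "candidates.csv"))

ggplot2::ggsave(file.path(out, "quadrant_scatter.png"),
                plot_screen(scores), width = 5, height = 5, dpi = 150)
for (cl in c("btk_inhibitor", "pi3k_inhibitor", "collateral_sensitive")) {
  ggplot2::ggsave(file.path(out, paste0("quadrant_", cl, ".png")),
                  plot_screen(scores, lib, cl), width = 5, height = 5,
                  dpi = 150)
}

by_class <- left_join(scores, lib[, c("compound_id", "effect_class")],
                      by = "compound_id") |>
  count(effect_class, quadrant) |>
  tidyr::pivot_wider(names_from = quadrant, values_from = n,
                     values_fill = 0)
readr::write_csv(by_class, file.path(out, "quadrant_by_class.csv"))

message("plate QC:   z' range ",
        paste(round(range(qc$z_prime), 2), collapse = " .. "),
        " (", sum(qc$flagged), " flagged)")
message("vehicle anchoring: max |mean - 100| = ",
        signif(max(abs(tapply(viab$viability_pct[viab$role == "vehicle"],
                              viab$plate_id[viab$role == "vehicle"], mean)
                       - 100)), 3))
print(as.data.frame(by_class))
message("candidates (d <= -", cfg$hit_threshold, " at >= 1 dose): ",
        nrow(candidates))
message("wrote scores, candidates, QC and quadrant scatters under ", out)
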