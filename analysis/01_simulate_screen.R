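#!/usr/bin/env Rscript
# Stage 1 — simulate the screen's raw data.
#
# Generates the 590-compound kinase-inhibitor library with known effect
# classes, lays out the 384-well plates (two lines x two doses x duplicates,
# DMSO vehicle column, ibrutinib/pentamidine control column), and simulates
# per-well live-cell counts at the screen's noise level. Everything
# downstream reads the CSVs written here.

suppressPackageStartupMessages({
  library(collatscreen)
  library(dplyr)
})

out <- "results/screen"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- screen_config(rng_seed = 20260928L)
lib <- generate_library(cfg)
plate_map <- build_plate_maps(cfg, lib)
counts <- simulate_plate(plate_map, bind_rows(lib, control_profiles()), cfg)

readr::write_csv(lib, file.path(out, "library.csv"))
readr::write_csv(plate_map, file.path(out, "plate_map.csv"))
readr::write_csv(counts, file.path(out, "counts.csv"))

message("library:    ", nrow(lib), " compounds — ",
        paste(names(table(lib$effect_class)), table(lib$effect_class),
              sep = ":", collapse = ", "))
message("plates:     ", length(unique(plate_map$plate_id)),
        " (", nrow(plate_map), " wells; ",
        sum(plate_map$role == "vehicle"), " vehicle, ",
        sum(plate_map$role == "positive_control"), " control)")
message("counts:     median vehicle well ",
        round(median(counts$count[counts$role == "vehicle"])), " cells")
message("wrote ", out, "/{library,plate_map,counts}.csv")
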