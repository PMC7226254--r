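#!/usr/bin/env Rscript
# Stage 4 — confirm candidate hits on a wide dose range.
#
# Mirrors the screen's triage-then-confirm design: every candidate from
# stage 3 is re-tested in simulated independent experiments (8 log-spaced
# doses, 1 nM - 100 uM, triplicate) on both lines; 4PL fits give per-line
# IC50s and the resistance ratio. A candidate is confirmed as collateral-
# sensitive when the resistant line is >= 10-fold more sensitive.

suppressPackageStartupMessages({
  library(collatscreen)
  library(dplyr)
})

out <- "results/screen"
lib <- readr::read_csv(file.path(out, "library.csv"), show_col_types = FALSE)
candidates <- readr::read_csv(file.path(out, "candidates.csv"),
                              show_col_types = FALSE)
cfg <- screen_config(rng_seed = 20260928L)

dr_seed <- stage_seed(cfg$rng_seed, "dose_response")
dr <- bind_rows(lapply(seq_len(nrow(candidates)), function(i) {
  prof <- filter(lib, compound_id == candidates$compound_id[i])
  bind_rows(
    simulate_dose_response(prof, "E41K", confirmation_doses(),
                           n_replicates = 3, cv = 0.05,
                           seed = dr_seed + 2L * i),
    simulate_dose_response(prof, "E41K_C481S", confirmation_doses(),
                           n_replicates = 3, cv = 0.05,
                           seed = dr_seed + 2L * i + 1L))
}))
confirmations <- confirm_hits(candidates$compound_id, dr,
                              cfg$ratio_threshold)

readr::write_csv(dr, file.path(out, "confirmation_dose_response.csv"))
readr::write_csv(confirmations, file.path(out, "confirmations.csv"))

tab <- left_join(confirmations, lib[, c("compound_id", "effect_class")],
                 by = "compound_id")
message("candidates tested: ", nrow(tab))
print(as.data.frame(count(tab, effect_class, status)))
conf <- filter(tab, confirmed_collateral)
message("confirmed collateral-sensitive: ", nrow(conf), " — all of class: ",
        paste(unique(conf$effect_class), collapse = ", "))
print(as.data.frame(conf[, c("compound_id", "ic50_sensitive_nM",
                             "ic50_resistant_nM", "resistance_ratio")]))
message("wrote ", out, "/{confirmation_dose_response,confirmations}.csv")
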