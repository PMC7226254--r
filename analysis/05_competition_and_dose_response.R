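#!/usr/bin/env Rscript
# Stage 5 — the cell-model characterisation experiments.
#
# Reproduces, on the generative model, the two experiments that establish
# the reporter system: (a) the two-clone competition assay — GFP+ activated-
# kinase cells vs mCherry+ wild-type cells, with and without IL3 — and
# (b) the ibrutinib dose-response of the sensitive vs resistant line, with
# the IL3-rescue control.

suppressPackageStartupMessages({
  library(collatscreen)
  library(dplyr)
  library(ggplot2)
})

out <- "results/model"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## (a) competition assay
traj <- bind_rows(
  mutate(simulate_competition(competition_params(il3 = TRUE)),
         condition = "with IL3"),
  mutate(simulate_competition(competition_params(il3 = FALSE)),
         condition = "without IL3"))
readr::write_csv(traj, file.path(out, "competition_trajectories.csv"))

day3 <- traj |> group_by(condition) |>
  summarise(gfp_pct_day3 = 100 * fraction_mut[which.min(abs(time_days - 3))])
readr::write_csv(day3, file.path(out, "competition_day3.csv"))
message("day-3 GFP+ fraction: ",
        paste(day3$condition, round(day3$gfp_pct_day3, 1), sep = " = ",
              collapse = "%, "), "%")

ggsave(file.path(out, "competition.png"),
       ggplot(traj, aes(time_days, 100 * fraction_mut,
                        colour = condition)) +
         geom_line(linewidth = 1) +
         labs(x = "days", y = "GFP-positive fraction (%)") +
         ylim(0, 100) + theme_classic(),
       width = 5, height = 3.5, dpi = 150)

## (b) ibrutinib dose-response, both lines, +/- IL3
ibr <- control_profiles()[1, ]
doses <- confirmation_doses()
dr <- bind_rows(lapply(cell_lines(), function(ln) {
  bind_rows(
    mutate(simulate_dose_response(ibr, ln, doses, n_replicates = 3,
                                  cv = 0.05, seed = 81L), il3 = FALSE),
    mutate(simulate_dose_response(ibr, ln, doses, n_replicates = 3,
                                  cv = 0.05, seed = 82L, il3 = TRUE),
           il3 = TRUE))
}))
readr::write_csv(dr, file.path(out, "ibrutinib_dose_response.csv"))

fits <- bind_rows(lapply(cell_lines(), function(ln) {
  d <- filter(dr, line == ln, !il3)
  mutate(fit_4pl(d$dose_nM, d$viability_pct), line = ln, .before = 1)
}))
readr::write_csv(fits, file.path(out, "ibrutinib_fits.csv"))
message("ibrutinib IC50 (no IL3): ",
        paste(fits$line, round(fits$ic50_nM), sep = " = ", collapse = " nM, "),
        " nM; ratio = ",
        round(fits$ic50_nM[fits$line == "E41K_C481S"] /
                fits$ic50_nM[fits$line == "E41K"], 1))

mean_dr <- dr |> group_by(line, il3, dose_nM) |>
  summarise(viability_pct = mean(viability_pct), .groups = "drop")
ggsave(file.path(out, "ibrutinib_dose_response.png"),
       ggplot(mean_dr, aes(dose_nM, viability_pct, colour = line,
                           linewidth = il3)) +
         geom_line() + geom_point(size = 1.5) +
         scale_x_log10() +
         scale_linewidth_manual(values = c(`FALSE` = 1, `TRUE` = 0.4),
                                labels = c("no IL3", "with IL3"),
                                name = NULL) +
         labs(x = "ibrutinib (nM)", y = "relative survival (%)") +
         theme_classic(),
       width = 5.5, height = 3.5, dpi = 150)
message("wrote competition and dose-response tables/figures under ", out)
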