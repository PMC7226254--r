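test_that("largest-remainder apportionment matches the enumeration oracle", {
  # brute-force oracle: floor quotas, then distribute leftovers by remainder
  oracle <- function(n, p) {
    q <- n * p; base <- floor(q); left <- n - sum(base)
    extra <- order(-(q - base))[seq_len(left)]
    base[extra] <- base[extra] + 1
    as.integer(base)
  }
  cases <- list(
    list(n = 10, p = c(a = 0.5, b = 0.5)),
    list(n = 590, p = c(a = 0.02, b = 0.04, c = 0.15, d = 0.005, e = 0.785)),
    list(n = 7, p = c(a = 1 / 3, b = 1 / 3, c = 1 / 3)),
    list(n = 0, p = c(a = 0.3, b = 0.7)),
    list(n = 1, p = c(a = 0.49, b = 0.51))
  )
  for (cs in cases) {
    got <- largest_remainder(cs$n, cs$p)
    expect_identical(unname(got), oracle(cs$n, cs$p))
    expect_identical(sum(got), as.integer(cs$n))
  }
  expect_identical(unname(largest_remainder(10, c(a = 0.5, b = 0.5))),
                   c(5L, 5L))
})

test_that("library generation is deterministic and respects the class mixture", {
  cfg <- screen_config()
  lib1 <- generate_library(cfg)
  lib2 <- generate_library(cfg)
  expect_identical(lib1, lib2)
  expect_identical(nrow(lib1), 590L)
  counts <- table(lib1$effect_class)
  expected <- largest_remainder(590, cfg$class_proportions)
  expect_identical(as.integer(counts[names(expected)]),
                   unname(expected))
  # class-level ground-truth invariants
  btk <- lib1[lib1$effect_class == "btk_inhibitor", ]
  col <- lib1[lib1$effect_class == "collateral_sensitive", ]
  inert <- lib1[lib1$effect_class == "inert", ]
  expect_true(all(btk$ic50_sensitive_nM < btk$ic50_resistant_nM))
  expect_true(all(col$ic50_resistant_nM < col$ic50_sensitive_nM))
  expect_true(all(inert$max_kill == 0))
  expect_true(all(lib1$ic50_sensitive_nM > 0 & lib1$ic50_resistant_nM > 0))
  expect_true(all(lib1$hill_slope > 0))
  expect_true(all(lib1$max_kill >= 0 & lib1$max_kill <= 1))
})

test_that("a pure-inert mixture yields only zero-kill profiles", {
  cfg <- screen_config(n_compounds = 25,
                       class_proportions = c(inert = 1))
  lib <- generate_library(cfg)
  expect_identical(nrow(lib), 25L)
  expect_true(all(lib$max_kill == 0))
  expect_true(all(true_kill_fraction(lib, "E41K", 1e6) == 0))
})

test_that("invalid configurations are rejected", {
  expect_error(screen_config(class_proportions = c(inert = 0.9)),
               "sum to 1")
  expect_error(screen_config(class_proportions = c(bogus = 1)),
               "effect classes")
  expect_error(screen_config(doses_nM = c(-1, 100)), "strictly positive")
  expect_error(screen_config(n_replicates = 0), ">= 1")
})

test_that("true kill fraction matches hand-computed values and is monotone", {
  p <- profile_row(ic50_sens = 10, ic50_res = 100, hill = 1, max_kill = 1)
  # half-maximal at the line's IC50 by construction
  expect_equal(true_kill_fraction(p, "E41K", 10), 0.5)
  expect_equal(true_kill_fraction(p, "E41K_C481S", 100), 0.5)
  # hand arithmetic: max_kill 0.8, h = 1, dose = 9 * ic50 -> 0.8 * 9/10
  p2 <- profile_row(50, 50, hill = 1, max_kill = 0.8)
  expect_equal(true_kill_fraction(p2, "E41K", 450), 0.72)
  # zero dose kills nothing; monotone non-decreasing in dose
  expect_equal(true_kill_fraction(p, "E41K", 0), 0)
  doses <- 10^seq(-2, 5, length.out = 40)
  kills <- vapply(doses, function(d) true_kill_fraction(p, "E41K", d),
                  numeric(1))
  expect_true(all(diff(kills) >= 0))
  expect_true(all(kills >= 0 & kills <= 1))
})

test_that("simulated counts are exact when noise-free and track the noise CV", {
  cfg <- tiny_config(cv = 0)
  lib <- generate_library(cfg)
  pm <- build_plate_maps(cfg, lib)
  cnt <- simulate_plate(pm, dplyr::bind_rows(lib, control_profiles()), cfg)
  veh <- cnt[cnt$role == "vehicle", ]
  expect_true(all(veh$count ==
                    cfg$cells_seeded_per_well * cfg$growth_factor))
  # inert compound wells equal the vehicle expectation exactly
  inert_cfg <- screen_config(n_compounds = 4,
                             class_proportions = c(inert = 1),
                             cv_well_noise = 0, rng_seed = 3L)
  ilib <- generate_library(inert_cfg)
  ipm <- build_plate_maps(inert_cfg, ilib)
  icnt <- simulate_plate(ipm, dplyr::bind_rows(ilib, control_profiles()),
                         inert_cfg)
  expect_true(all(icnt$count[icnt$role == "compound"] ==
                    inert_cfg$cells_seeded_per_well * inert_cfg$growth_factor))
  # saturating kill drives the count to ~0
  hot <- profile_row(1, 1, hill = 2, max_kill = 1, id = "HOT")
  map1 <- tibble::tibble(plate_id = "P001", well = "A02", row = 1, col = 2,
                         compound_id = "HOT", dose_nM = 1e6, line = "E41K",
                         replicate = 1L, role = "compound")
  c1 <- simulate_plate(map1, hot, inert_cfg)
  expect_lt(c1$count, 1e-4 * inert_cfg$cells_seeded_per_well)
  # Monte-Carlo: 10,000 vehicle wells at cv = 0.1 show sample CV 0.1 +- 0.01
  mc_map <- tibble::tibble(plate_id = "P001",
                           well = sprintf("W%05d", 1:10000),
                           row = 1, col = 1, compound_id = NA_character_,
                           dose_nM = 0, line = "E41K", replicate = 1L,
                           role = "vehicle")
  mc_cfg <- screen_config(n_compounds = 0,
                          class_proportions = c(inert = 1),
                          cv_well_noise = 0.1, rng_seed = 11L)
  mc <- simulate_plate(mc_map, control_profiles(), mc_cfg)
  cv_hat <- stats::sd(mc$count) / mean(mc$count)
  expect_gt(cv_hat, 0.09)
  expect_lt(cv_hat, 0.11)
})

test_that("unknown compounds in a plate map raise a layout error", {
  cfg <- tiny_config()
  lib <- generate_library(cfg)
  pm <- build_plate_maps(cfg, lib)
  expect_error(simulate_plate(pm, lib, cfg), "unknown compound")
  expect_error(simulate_plate(pm, lib, cfg), "ibrutinib")
})

test_that("dose-response simulation is anchored at 100% and rescued by IL3", {
  p <- profile_row(100, 10000, hill = 1, max_kill = 0.97, id = "ibr")
  doses <- c(0, confirmation_doses())
  dr <- simulate_dose_response(p, "E41K", doses, n_replicates = 1, cv = 0,
                               seed = 1)
  expect_equal(dr$viability_pct[dr$dose_nM == 0], 100)
  expect_equal(dr$viability_pct,
               100 * (1 - true_kill_fraction(p, "E41K", dr$dose_nM)))
  # IL3 suppresses the kill entirely: thin-line control behaviour
  dr_il3 <- simulate_dose_response(p, "E41K", doses, n_replicates = 1,
                                   cv = 0, seed = 1, il3 = TRUE)
  expect_true(all(dr_il3$viability_pct == 100))
  # the default 8-point series brackets both reference IC50s
  expect_lt(min(confirmation_doses()), 100)
  expect_gt(max(confirmation_doses()), 10000)
  # determinism at fixed seed
  a <- simulate_dose_response(p, "E41K", doses, cv = 0.05, seed = 9)
  b <- simulate_dose_response(p, "E41K", doses, cv = 0.05, seed = 9)
  expect_identical(a, b)
})

test_that("competition trajectories match the exponential-ratio closed form", {
  # closed form computed inline, independently of the ODE solver
  closed <- function(f0, rm, rw, t) {
    f0 * exp(rm * t) / (f0 * exp(rm * t) + (1 - f0) * exp(rw * t))
  }
  # hand case: rw = -1, rm = +1, f0 = 0.5, t = 3 -> e^3 / (e^3 + e^-3)
  p <- competition_params(il3 = FALSE, growth_rate_wt = -1,
                          growth_rate_mut = 1,
                          initial_fraction_mut = 0.5)
  tr <- simulate_competition(p, times = c(0, 3))
  expect_equal(tr$fraction_mut[2], exp(3) / (exp(3) + exp(-3)),
               tolerance = 1e-9)
  expect_equal(tr$fraction_mut[2], 0.9975274, tolerance = 1e-6)
  # equal growth rates leave the composition constant
  pe <- competition_params(il3 = TRUE, growth_rate_wt = 0.5,
                           growth_rate_mut = 0.5,
                           initial_fraction_mut = 0.37)
  tre <- simulate_competition(pe)
  expect_equal(tre$fraction_mut, rep(0.37, nrow(tre)), tolerance = 1e-9)
  # random parameter sets match the closed form everywhere on the grid
  withr::with_seed(20, {
    for (i in 1:25) {
      pi <- competition_params(il3 = FALSE,
                               growth_rate_wt = runif(1, -2, 0),
                               growth_rate_mut = runif(1, -1, 2),
                               initial_fraction_mut = runif(1, 0.05, 0.95))
      tri <- simulate_competition(pi)
      expect_lt(max(abs(tri$fraction_mut -
                          closed(pi$initial_fraction_mut,
                                 pi$growth_rate_mut, pi$growth_rate_wt,
                                 tri$time_days))), 1e-9)
      # monotone increasing when the mutant outgrows the wild type
      if (pi$growth_rate_mut > pi$growth_rate_wt) {
        expect_true(all(diff(tri$fraction_mut) > 0))
      }
    }
  })
  # defaults emulate the competitive assay: stable ~49% with IL3,
  # sweep past 90% without
  with_il3 <- simulate_competition(competition_params(il3 = TRUE))
  no_il3 <- simulate_competition(competition_params(il3 = FALSE))
  expect_equal(100 * with_il3$fraction_mut[nrow(with_il3)], 49,
               tolerance = 0.01)
  expect_gt(100 * no_il3$fraction_mut[nrow(no_il3)], 90)
  expect_error(competition_params(il3 = FALSE, growth_rate_wt = 0.1),
               "<= 0")
})

test_that("per-stage seeds are deterministic, distinct, and in integer range", {
  s1 <- stage_seed(123L, "library")
  expect_identical(s1, stage_seed(123L, "library"))
  all_stages <- c("library", "plate", "render", "dose_response",
                  "competition", "pipeline")
  seeds <- vapply(all_stages, stage_seed, integer(1), master = 123L)
  expect_identical(anyDuplicated(unname(seeds)), 0L)
  expect_true(all(seeds >= 0 & seeds < 2^31))
  expect_false(stage_seed(124L, "library") == s1)
})
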