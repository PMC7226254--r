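test_that("viability normalization anchors vehicle wells at exactly 100", {
  cnt <- mini_counts(compound_counts = c(50, 0, 150),
                     vehicle_counts = c(80, 120))
  viab <- normalize_viability(cnt)
  # vehicle mean is (80+120)/2 = 100, so test well 50 -> 50.0 exactly
  cmpd <- viab[viab$role == "compound", ]
  expect_equal(cmpd$viability_pct, c(50, 0, 150))
  expect_equal(mean(viab$viability_pct[viab$role == "vehicle"]), 100)
  # count equal to the vehicle mean maps to 100; zero count to 0
  expect_equal(viab$viability_pct[viab$count == 100 &
                                    viab$role == "compound"], numeric(0))
  # uncapped: stimulatory wells exceed 100
  expect_gt(max(cmpd$viability_pct), 100)
})

test_that("normalization is stratified by plate x line and errors without vehicles", {
  a <- mini_counts(c(60), vehicle_counts = c(100, 140), line = "E41K",
                   plate = "P001")
  b <- mini_counts(c(60), vehicle_counts = c(40, 60), line = "E41K_C481S",
                   plate = "P002")
  viab <- normalize_viability(dplyr::bind_rows(a, b))
  strat <- dplyr::summarise(
    dplyr::group_by(viab[viab$role == "vehicle", ], .data$plate_id),
    m = mean(.data$viability_pct))
  expect_equal(strat$m, c(100, 100))
  # same raw count, different anchors
  expect_equal(viab$viability_pct[viab$role == "compound"],
               c(60 / 120 * 100, 60 / 50 * 100))
  no_veh <- a[a$role != "vehicle", ]
  expect_error(normalize_viability(no_veh), "P001/E41K")
})

test_that("replicate aggregation averages and keeps QC information", {
  rec <- tibble::tibble(compound_id = "C1", line = "E41K", dose_nM = 100,
                        replicate = 1:2, viability_pct = c(40, 60),
                        role = "compound")
  agg <- aggregate_replicates(rec)
  expect_equal(agg$viability_pct, 50)
  expect_identical(agg$n_replicates, 2L)
  expect_equal(agg$replicate_range, 20)
  # single replicate passes through; permutation invariance
  one <- aggregate_replicates(rec[1, ])
  expect_equal(one$viability_pct, 40)
  expect_equal(aggregate_replicates(rec[2:1, ])$viability_pct, 50)
})

test_that("the differential score is subtraction and antisymmetric", {
  expect_equal(differential_score(90, 20), 70)
  expect_equal(differential_score(20, 90), -70)
  expect_equal(differential_score(55, 55), 0)
  withr::with_seed(4, {
    a <- runif(1000, 0, 150); b <- runif(1000, 0, 150)
    expect_equal(differential_score(a, b), a - b)
    expect_equal(differential_score(a, b), -differential_score(b, a))
    expect_identical(differential_score(a, b) == 0, a == b)
  })
  expect_warning(differential_score(c(10, NA), c(5, 5)), "missing")
})

test_that("quadrant classification is total, exclusive, and tie-consistent", {
  expect_identical(classify_quadrant(70, 80), "upper_right")
  expect_identical(classify_quadrant(-70, -80), "lower_left")
  expect_identical(classify_quadrant(-70, 80), "upper_left")
  expect_identical(classify_quadrant(70, -80), "lower_right")
  # zero counts as non-negative
  expect_identical(classify_quadrant(0, 5), "upper_right")
  expect_identical(classify_quadrant(0, 0), "upper_right")
  expect_identical(classify_quadrant(0, -5), "lower_right")
  expect_identical(classify_quadrant(-5, 0), "upper_left")
  withr::with_seed(5, {
    d1 <- c(runif(500, -100, 100), 0, 0, -3, 3)
    d2 <- c(runif(500, -100, 100), 0, -1, 0, 0)
    q <- classify_quadrant(d1, d2)
    expect_false(anyNA(q))
    expect_true(all(q %in% c("upper_right", "lower_left", "upper_left",
                             "lower_right")))
    # exclusivity: recomputing via sign logic agrees everywhere
    manual <- ifelse(d1 >= 0 & d2 >= 0, "upper_right",
                     ifelse(d1 < 0 & d2 < 0, "lower_left",
                            ifelse(d1 < 0, "upper_left", "lower_right")))
    expect_identical(q, manual)
  })
})

test_that("candidate selection applies the one-dose rule and sorts by min d", {
  sc <- tibble::tibble(
    compound_id = c("A", "B", "C", "D"),
    v_wt_low = 100, v_mut_low = 100, v_wt_high = 100, v_mut_high = 100,
    d_low = c(-25, 5, -10, -40),
    d_high = c(5, -30, -10, -45),
    quadrant = classify_quadrant(c(-25, 5, -10, -40), c(5, -30, -10, -45)),
    is_candidate_hit = NA
  )
  cand <- select_candidate_hits(sc, threshold = 20)
  # A: one dose below -20 -> in; B: high dose -> in; C: never -> out
  expect_identical(cand$compound_id, c("D", "B", "A"))
  expect_equal(cand$min_d, c(-45, -30, -25))
  # all-inert screens produce an empty candidate list
  cfg <- screen_config(n_compounds = 8, class_proportions = c(inert = 1),
                       cv_well_noise = 0, rng_seed = 2L)
  res <- run_screen_pipeline(cfg)
  expect_identical(nrow(res$candidates), 0L)
})

test_that("screen scoring reproduces the expected quadrant geometry", {
  # noise-free screen: BTK-like compounds upper-right, collateral lower-left
  cfg <- tiny_config(n_compounds = 20, cv = 0)
  res <- run_screen_pipeline(cfg)
  joined <- dplyr::left_join(res$scores,
                             res$profiles[, c("compound_id", "effect_class")],
                             by = "compound_id")
  btk <- joined[joined$effect_class == "btk_inhibitor", ]
  col <- joined[joined$effect_class == "collateral_sensitive", ]
  expect_true(all(btk$quadrant == "upper_right"))
  expect_true(all(col$quadrant == "lower_left"))
  # d columns are exactly the viability differences
  expect_equal(joined$d_low, joined$v_mut_low - joined$v_wt_low)
  expect_equal(joined$d_high, joined$v_mut_high - joined$v_wt_high)
})

test_that("plate QC computes the Z-prime factor from control wells", {
  # formula oracle on explicit numbers
  cnt <- mini_counts(compound_counts = 70,
                     vehicle_counts = c(95, 100, 105),
                     pos_counts = c(8, 10, 12))
  qc <- compute_plate_qc(cnt)
  z_oracle <- 1 - 3 * (stats::sd(c(95, 100, 105)) + stats::sd(c(8, 10, 12))) /
    abs(100 - 10)
  expect_equal(qc$z_prime, z_oracle)
  expect_equal(qc$vehicle_mean, 100)
  expect_equal(qc$positive_control_mean, 10)
  # zero spread in both roles gives the ideal z' = 1
  perfect <- mini_counts(70, vehicle_counts = c(100, 100), pos_counts = c(5, 5))
  expect_equal(compute_plate_qc(perfect)$z_prime, 1)
  # coincident means are reported as -Inf and flagged
  degenerate <- mini_counts(70, vehicle_counts = c(100, 100),
                            pos_counts = c(100, 100))
  dq <- compute_plate_qc(degenerate)
  expect_identical(dq$z_prime, -Inf)
  expect_true(dq$flagged)
  # missing control role errors
  no_pos <- cnt[cnt$role != "positive_control", ]
  expect_error(compute_plate_qc(no_pos), "positive-control")
})
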