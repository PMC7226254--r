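#' Simulate a dose-response viability series
#'
#' Draws replicate viabilities `100 * (1 - kill)` from a compound's
#' ground-truth profile with multiplicative lognormal noise, emulating the
#' confirmation experiments run on triaged screen hits over a wide dose
#' range. With `il3 = TRUE` the kill is forced to 0 at every dose: cells
#' rescued by IL3 no longer depend on the drugged kinase, which is the
#' hallmark control for oncogene addiction.
#'
#' @param profile One-row compound profile ([generate_library()] schema).
#' @param line `"E41K"` or `"E41K_C481S"`.
#' @param doses_nM Dose series (>= 4 distinct positive doses for downstream
#'   fitting).
#' @param n_replicates Replicates per dose.
#' @param cv Lognormal noise CV on viability (0 = noise-free).
#' @param seed Integer seed.
#' @param il3 Simulate in IL3-containing medium (kill suppressed).
#' @return Tibble `compound_id`, `line`, `dose_nM`, `replicate`,
#'   `viability_pct`.
#' @export
simulate_dose_response <- function(profile, line, doses_nM,
                                   n_replicates = 3, cv = 0.05, seed = 1L,
                                   il3 = FALSE) {
  stopifnot(nrow(profile) == 1, line %in% cell_lines(), all(doses_nM >= 0))
  grid <- expand.grid(replicate = seq_len(n_replicates), dose_nM = doses_nM)
  kill <- if (il3) 0 else true_kill_fraction(profile, line, grid$dose_nM)
  withr::with_seed(seed, {
    viab <- 100 * (1 - kill) * .lognormal_noise(nrow(grid), cv)
  })
  tibble::tibble(compound_id = profile$compound_id, line = line,
                 dose_nM = grid$dose_nM, replicate = grid$replicate,
                 viability_pct = viab)
}

#' Default confirmation dose series
#'
#' Eight log-spaced doses spanning 1 nM to 100 uM, bracketing both the
#' sensitive-line and resistant-line IC50s of the screen's reference
#' scenario.
#' @return Numeric vector of doses in nM.
#' @export
confirmation_doses <- function() 10^seq(0, 5, length.out = 8)

#' Fit a four-parameter log-logistic dose-response curve
#'
#' Least-squares fit of `v(x) = bottom + (top - bottom) / (1 + (x/ic50)^h)`
#' on log dose by Levenberg-Marquardt, with `h > 0` so viability decreases
#' with dose. Initialisation takes top/bottom from the data extremes, the
#' IC50 from the dose whose mean response is nearest the half-range, and
#' `h = 1`; three additional log-spaced IC50 starts are tried before
#' declaring non-convergence. The fit is reported unconverged when the
#' optimiser fails, the response shows no dose effect (fitted amplitude
#' `top - bottom` below `min_effect` viability points, so fits to pure
#' noise around a flat response are rejected), or the fitted IC50 leaves
#' the tested dose range; the IC50 is the curve's inflection (relative
#' IC50), which stays well-defined when the maximal effect is partial.
#'
#' @param dose_nM Doses (>= 4 distinct, strictly positive).
#' @param viability_pct Viabilities (% of vehicle), same length.
#' @param min_effect Minimum fitted response amplitude (viability points)
#'   for the curve to count as a real dose effect.
#' @return One-row tibble: `bottom`, `top`, `ic50_nM`, `hill_slope`, `rss`,
#'   `converged`, `n_points`, `message`.
#' @export
fit_4pl <- function(dose_nM, viability_pct, min_effect = 10) {
  if (length(dose_nM) != length(viability_pct)) {
    stop("`dose_nM` and `viability_pct` must have equal length", call. = FALSE)
  }
  if (any(dose_nM <= 0)) stop("doses must be strictly positive", call. = FALSE)
  if (length(unique(dose_nM)) < 4) {
    stop("need >= 4 distinct doses to fit a 4PL curve", call. = FALSE)
  }
  unconverged <- function(msg) {
    tibble::tibble(bottom = NA_real_, top = NA_real_, ic50_nM = NA_real_,
                   hill_slope = NA_real_, rss = NA_real_, converged = FALSE,
                   n_points = length(dose_nM), message = msg)
  }
  dose_means <- tapply(viability_pct, dose_nM, mean)
  if (diff(range(dose_means)) < 1e-6) {
    return(unconverged("no dose effect (flat response)"))
  }
  lx <- log(dose_nM)
  top0 <- max(dose_means); bot0 <- min(dose_means)
  half <- (top0 + bot0) / 2
  near <- as.numeric(names(dose_means))[which.min(abs(dose_means - half))]
  starts_lic50 <- unique(c(log(near),
                           stats::quantile(lx, c(0.25, 0.5, 0.75))))
  df <- data.frame(lx = lx, v = viability_pct)
  best <- NULL
  for (s in starts_lic50) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ bottom + (top - bottom) / (1 + exp(h * (lx - lic50))),
        data = df,
        start = list(bottom = bot0, top = top0, lic50 = s, h = 1),
        lower = c(bottom = -Inf, top = -Inf, lic50 = -Inf, h = 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) return(unconverged("optimizer failed at all starts"))
  cf <- stats::coef(best$fit)
  ic50 <- exp(cf[["lic50"]])
  if (abs(cf[["top"]] - cf[["bottom"]]) < min_effect) {
    return(unconverged("no dose effect (amplitude below min_effect)"))
  }
  if (ic50 < min(dose_nM) || ic50 > max(dose_nM)) {
    out <- unconverged("fitted IC50 outside tested dose range")
    out$ic50_nM <- ic50
    return(out)
  }
  bottom <- min(cf[["bottom"]], cf[["top"]])
  top <- max(cf[["bottom"]], cf[["top"]])
  tibble::tibble(bottom = bottom, top = top, ic50_nM = ic50,
                 hill_slope = cf[["h"]], rss = best$rss, converged = TRUE,
                 n_points = length(dose_nM), message = "ok")
}

#' Resistance ratio of two fitted IC50s
#'
#' `ic50_resistant / ic50_sensitive`. Ratios above `ratio_threshold`
#' indicate a resistance phenotype (the mutation protects); ratios below
#' `1 / ratio_threshold` indicate collateral sensitivity (the mutation
#' sensitises). Undefined (NA) when either fit did not converge.
#'
#' @param fit_resistant,fit_sensitive One-row tibbles from [fit_4pl()].
#' @return A single numeric ratio, or NA.
#' @export
resistance_ratio <- function(fit_resistant, fit_sensitive) {
  if (!isTRUE(fit_resistant$converged) || !isTRUE(fit_sensitive$converged)) {
    return(NA_real_)
  }
  fit_resistant$ic50_nM / fit_sensitive$ic50_nM
}

#' Confirm candidate hits by dual-line dose-response
#'
#' For each candidate compound, fits a 4PL curve per line from the supplied
#' dose-response data and computes the resistance ratio. A candidate is
#' `confirmed_collateral` when both fits converge and the ratio is below
#' `1 / ratio_threshold` (the resistant line is at least `ratio_threshold`-
#' fold more sensitive). Candidates missing a line's series are marked
#' untestable; the full table is returned regardless of confirmation.
#'
#' @param candidate_ids Character vector of compound ids to test.
#' @param dr_data Tibble `compound_id`, `line`, `dose_nM`, `replicate`,
#'   `viability_pct` covering both lines per candidate.
#' @param ratio_threshold Fold-change threshold (> 1).
#' @return Tibble `compound_id`, `ic50_sensitive_nM`, `ic50_resistant_nM`,
#'   `resistance_ratio`, `confirmed_collateral`, `status`.
#' @export
confirm_hits <- function(candidate_ids, dr_data, ratio_threshold = 10) {
  stopifnot(ratio_threshold > 1)
  res <- lapply(candidate_ids, function(id) {
    row <- tibble::tibble(compound_id = id, ic50_sensitive_nM = NA_real_,
                          ic50_resistant_nM = NA_real_,
                          resistance_ratio = NA_real_,
                          confirmed_collateral = FALSE, status = "untestable")
    sens <- dplyr::filter(dr_data, .data$compound_id == id,
                          .data$line == "E41K")
    resi <- dplyr::filter(dr_data, .data$compound_id == id,
                          .data$line == "E41K_C481S")
    if (nrow(sens) == 0 || nrow(resi) == 0) return(row)
    fs <- fit_4pl(sens$dose_nM, sens$viability_pct)
    fr <- fit_4pl(resi$dose_nM, resi$viability_pct)
    row$ic50_sensitive_nM <- fs$ic50_nM
    row$ic50_resistant_nM <- fr$ic50_nM
    ratio <- resistance_ratio(fr, fs)
    row$resistance_ratio <- ratio
    if (is.na(ratio)) {
      row$status <- "unconverged_fit"
    } else {
      row$confirmed_collateral <- ratio < 1 / ratio_threshold
      row$status <- if (row$confirmed_collateral) "confirmed" else
        "not_confirmed"
    }
    row
  })
  out <- dplyr::bind_rows(res)
  if (length(candidate_ids) == 0) {
    out <- tibble::tibble(compound_id = character(),
                          ic50_sensitive_nM = numeric(),
                          ic50_resistant_nM = numeric(),
                          resistance_ratio = numeric(),
                          confirmed_collateral = logical(),
                          status = character())
  }
  out
}
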