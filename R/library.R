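#' Largest-remainder apportionment of counts to mixture proportions
#'
#' Splits `n` items over classes so that counts match `n * proportions` after
#' largest-remainder (Hamilton) rounding: each class first receives the floor
#' of its quota, then the remaining items go to the classes with the largest
#' fractional remainders (ties broken by class order).
#'
#' @param n Total count.
#' @param proportions Named non-negative numeric vector summing to 1.
#' @return Named integer vector of counts summing to `n`.
#' @export
largest_remainder <- function(n, proportions) {
  quota <- n * proportions
  base <- floor(quota)
  remainder <- quota - base
  short <- n - sum(base)
  counts <- base
  if (short > 0) {
    # order(-remainder) is stable, so ties fall to the earlier class
    top_up <- order(-remainder)[seq_len(short)]
    counts[top_up] <- counts[top_up] + 1
  }
  stats::setNames(as.integer(counts), names(proportions))
}

# Per-class parameter distributions for the simulated compound library.
# IC50s in nM. BTK-like compounds are potent on the sensitive line and
# strongly protected by the resistance mutation; PI3K-like compounds are
# mildly differential in the same direction; cytotoxics hit both lines
# equally; collateral-sensitive compounds invert the BTK pattern.
.sample_class_profiles <- function(class, k) {
  runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))
  hill <- stats::runif(k, 0.8, 1.5)
  switch(
    class,
    btk_inhibitor = {
      sens <- runif_log(k, 20, 150)
      tibble::tibble(ic50_sensitive_nM = sens,
                     ic50_resistant_nM = sens * runif_log(k, 30, 300),
                     hill_slope = hill,
                     max_kill = stats::runif(k, 0.85, 1))
    },
    pi3k_inhibitor = {
      sens <- runif_log(k, 100, 500)
      tibble::tibble(ic50_sensitive_nM = sens,
                     ic50_resistant_nM = sens * runif_log(k, 2, 6),
                     hill_slope = hill,
                     max_kill = stats::runif(k, 0.7, 0.95))
    },
    cytotoxic = {
      ic50 <- runif_log(k, 50, 2000)
      tibble::tibble(ic50_sensitive_nM = ic50,
                     ic50_resistant_nM = ic50,
                     hill_slope = hill,
                     max_kill = stats::runif(k, 0.85, 1))
    },
    collateral_sensitive = {
      res <- runif_log(k, 20, 100)
      tibble::tibble(ic50_sensitive_nM = res * runif_log(k, 30, 300),
                     ic50_resistant_nM = res,
                     hill_slope = hill,
                     max_kill = stats::runif(k, 0.85, 1))
    },
    inert = tibble::tibble(ic50_sensitive_nM = rep(1e6, k),
                           ic50_resistant_nM = rep(1e6, k),
                           hill_slope = rep(1, k),
                           max_kill = rep(0, k))
  )
}

#' Generate a compound library with known effect classes
#'
#' Draws `n_compounds` compound effect profiles from the configured class
#' mixture. Class counts follow [largest_remainder()] rounding of the mixture
#' proportions, so they are exact and reproducible. Each profile carries the
#' ground-truth per-line IC50s, Hill slope and maximal kill fraction used by
#' every downstream simulation stage.
#'
#' @param config A [screen_config()].
#' @param seed Integer seed; defaults to the library stream of the config's
#'   master seed.
#' @return A tibble with columns `compound_id`, `effect_class`,
#'   `ic50_sensitive_nM`, `ic50_resistant_nM`, `hill_slope`, `max_kill`.
#' @export
generate_library <- function(config,
                             seed = stage_seed(config$rng_seed, "library")) {
  stopifnot(inherits(config, "screen_config"))
  counts <- largest_remainder(config$n_compounds, config$class_proportions)
  withr::with_seed(seed, {
    profiles <- dplyr::bind_rows(lapply(names(counts), function(cl) {
      k <- counts[[cl]]
      if (k == 0) return(NULL)
      dplyr::mutate(.sample_class_profiles(cl, k), effect_class = cl,
                    .before = 1)
    }))
  })
  if (is.null(profiles) || nrow(profiles) == 0) {
    profiles <- tibble::tibble(effect_class = character(),
                               ic50_sensitive_nM = numeric(),
                               ic50_resistant_nM = numeric(),
                               hill_slope = numeric(),
                               max_kill = numeric())
  }
  tibble::add_column(profiles,
                     compound_id = sprintf("C%04d", seq_len(nrow(profiles))),
                     .before = 1)
}

#' Ground-truth positive-control profiles
#'
#' Ibrutinib (covalent BTK inhibitor, potent on the sensitive line, ~100-fold
#' protected by the resistance mutation) and pentamidine (broadly cytotoxic)
#' serve as cell-death positive controls on every plate.
#'
#' @return A tibble in the [generate_library()] schema.
#' @export
control_profiles <- function() {
  tibble::tibble(
    compound_id = c("ibrutinib", "pentamidine"),
    effect_class = c("btk_inhibitor", "cytotoxic"),
    ic50_sensitive_nM = c(100, 200),
    ic50_resistant_nM = c(10000, 200),
    hill_slope = c(1, 1.2),
    max_kill = c(0.97, 0.98)
  )
}

#' True kill fraction of a compound at a dose
#'
#' Evaluates the generative dose-response model: a four-parameter log-logistic
#' kill curve with floor 0 and ceiling `max_kill`,
#' `kill(x) = max_kill * x^h / (x^h + ic50^h)`,
#' using the IC50 of the requested line. Vectorised over all arguments.
#'
#' @param profiles Tibble of compound effect profiles ([generate_library()]
#'   schema), recycled against `dose_nM`.
#' @param line `"E41K"` (sensitive) or `"E41K_C481S"` (resistant); vector ok.
#' @param dose_nM Dose(s) in nM, >= 0.
#' @return Kill fraction(s) in `[0, 1]`; 0 at dose 0 and non-decreasing in
#'   dose.
#' @export
true_kill_fraction <- function(profiles, line, dose_nM) {
  stopifnot(all(dose_nM >= 0), all(line %in% cell_lines()))
  ic50 <- ifelse(line == "E41K", profiles$ic50_sensitive_nM,
                 profiles$ic50_resistant_nM)
  h <- profiles$hill_slope
  xh <- dose_nM^h
  profiles$max_kill * xh / (xh + ic50^h)
}
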