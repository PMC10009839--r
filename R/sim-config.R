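#' Configuration for the synthetic pharmacy-data generator
#'
#' Bundles every tunable of the synthetic data generator: the size of the drug
#' hierarchy, the monthly demand process, the latent shortage process, how
#' demand responds to shortages, and the defects injected into the raw
#' shortage reports.
#'
#' The defaults describe a mid-sized study: 20 interchangeable groups (IGs)
#' observed monthly from January 2017 to April 2021, a per-pack monthly
#' shortage hazard of 2% with geometric durations averaging about 2.5 months,
#' moderately concentrated pharmacist preference among the DINs of an IG, and
#' a visible demand response to shortages (patient shares shift away from a
#' shorted DIN with a one-month lag and days of supply per patient fall during
#' large shortages).
#'
#' @param n_igs Number of interchangeable groups.
#' @param dins_per_ig Integer range `c(min, max)`: DINs per IG.
#' @param packs_per_din Integer range `c(min, max)`: catalog pack listings per
#'   DIN.
#' @param months Inclusive `"YYYY-MM"` range `c(first, last)`; must span at
#'   least 18 months (four feature lags, a minimum training window and a
#'   holdout need that much room).
#' @param n_patients_scale Positive scale of monthly patients per IG.
#' @param preference_concentration Positive Dirichlet concentration for DIN
#'   shares within an IG; small values give one dominant DIN, large values
#'   give near-uniform shares.
#' @param shortage_rate Monthly hazard, in \[0,1\], that a DIN pack listing
#'   enters shortage.
#' @param shortage_duration_p Geometric parameter in (0,1\]; durations are
#'   `1 + rgeom(p)` months.
#' @param tc_correlation Probability, in \[0,1\], that a new shortage
#'   propagates to a sibling IG under the same therapeutic-class parent the
#'   following month.
#' @param substitution_strength In \[0,1\]: how strongly patient share shifts
#'   away from a shorted DIN (applied with a one-month lag).
#' @param dos_drop In \[0,1\]: relative fall of days of supply per patient
#'   during a large shortage of the IG.
#' @param seasonal_amplitude In \[0,1\]: amplitude of the 12-month demand
#'   cycle.
#' @param text_dialects Character vector of pack-size rendering templates.
#'   `"{n}"` is replaced by the pack size; a template without `"{n}"` (e.g.
#'   `"UNKNOWN"`) renders unparseable text. `"{a}x{b}"` renders the size as a
#'   product of two factors.
#' @param status_probs Named numeric probabilities over how a latent shortage
#'   event is reported: `actual`, `anticipated`, `avoided`. Must sum to 1.
#' @param defect_rates Named list with `missing_date` and `inverted_date`
#'   probabilities in \[0,1\] applied to the actual dates of each report.
#' @param day_level Logical; if `TRUE`, shortage starts/ends fall on random
#'   days within their boundary months rather than on month boundaries.
#' @param seed Integer seed; all three generators are deterministic given the
#'   config (the seed is part of it).
#'
#' @return An object of class `"sim_config"` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(n_igs = 5, seed = 1)
#' cfg$months
sim_config <- function(n_igs = 20,
                       dins_per_ig = c(2L, 6L),
                       packs_per_din = c(1L, 3L),
                       months = c("2017-01", "2021-04"),
                       n_patients_scale = 200,
                       preference_concentration = 0.7,
                       shortage_rate = 0.02,
                       shortage_duration_p = 0.4,
                       tc_correlation = 0.3,
                       substitution_strength = 0.6,
                       dos_drop = 0.3,
                       seasonal_amplitude = 0.15,
                       text_dialects = c("{n} Bottle", "{n} BTL", "BTL {n}", "{a}x{b} Blister"),
                       status_probs = c(actual = 0.85, anticipated = 0.10, avoided = 0.05),
                       defect_rates = list(missing_date = 0.05, inverted_date = 0.02),
                       day_level = FALSE,
                       seed = 1L) {
  cfg <- list(
    n_igs = as.integer(n_igs),
    dins_per_ig = as.integer(dins_per_ig),
    packs_per_din = as.integer(packs_per_din),
    months = as.character(months),
    n_patients_scale = n_patients_scale,
    preference_concentration = preference_concentration,
    shortage_rate = shortage_rate,
    shortage_duration_p = shortage_duration_p,
    tc_correlation = tc_correlation,
    substitution_strength = substitution_strength,
    dos_drop = dos_drop,
    seasonal_amplitude = seasonal_amplitude,
    text_dialects = as.character(text_dialects),
    status_probs = status_probs,
    defect_rates = defect_rates,
    day_level = isTRUE(day_level),
    seed = as.integer(seed)
  )

  check_scalar <- function(name, ok) {
    if (!ok) rlang::abort(sprintf("Invalid `%s` in sim_config().", name),
                          class = "shortcast_config_error")
  }
  check_scalar("n_igs", length(cfg$n_igs) == 1 && !is.na(cfg$n_igs) && cfg$n_igs >= 1)
  check_range <- function(name, r) {
    check_scalar(name, length(r) == 2 && !anyNA(r) && r[1] >= 1 && r[1] <= r[2])
  }
  check_range("dins_per_ig", cfg$dins_per_ig)
  check_range("packs_per_din", cfg$packs_per_din)
  check_scalar("months", length(cfg$months) == 2)
  ym_check(cfg$months)
  if (ym_diff(cfg$months[2], cfg$months[1]) + 1L < 18L) {
    rlang::abort("Invalid `months` in sim_config(): range must span at least 18 months.",
                 class = "shortcast_config_error")
  }
  check_scalar("n_patients_scale", is.numeric(cfg$n_patients_scale) && cfg$n_patients_scale > 0)
  check_scalar("preference_concentration",
               is.numeric(cfg$preference_concentration) && cfg$preference_concentration > 0)
  prob01 <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1
  check_scalar("shortage_rate", prob01(cfg$shortage_rate))
  check_scalar("shortage_duration_p",
               is.numeric(cfg$shortage_duration_p) &&
                 cfg$shortage_duration_p > 0 && cfg$shortage_duration_p <= 1)
  check_scalar("tc_correlation", prob01(cfg$tc_correlation))
  check_scalar("substitution_strength", prob01(cfg$substitution_strength))
  check_scalar("dos_drop", prob01(cfg$dos_drop))
  check_scalar("seasonal_amplitude", prob01(cfg$seasonal_amplitude))
  check_scalar("text_dialects", length(cfg$text_dialects) >= 1)
  check_scalar("status_probs",
               is.numeric(cfg$status_probs) &&
                 setequal(names(cfg$status_probs), c("actual", "anticipated", "avoided")) &&
                 all(cfg$status_probs >= 0) && abs(sum(cfg$status_probs) - 1) < 1e-8)
  check_scalar("defect_rates",
               is.list(cfg$defect_rates) &&
                 all(c("missing_date", "inverted_date") %in% names(cfg$defect_rates)) &&
                 prob01(cfg$defect_rates$missing_date) && prob01(cfg$defect_rates$inverted_date))
  check_scalar("seed", length(cfg$seed) == 1 && !is.na(cfg$seed))

  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d IGs, %d-%d DINs each, %d-%d packs per DIN\n",
              x$n_igs, x$dins_per_ig[1], x$dins_per_ig[2],
              x$packs_per_din[1], x$packs_per_din[2]))
  cat(sprintf("  months %s .. %s  (seed %d)\n", x$months[1], x$months[2], x$seed))
  cat(sprintf("  shortage hazard %.3f/pack-month, duration 1+Geom(%.2f)\n",
              x$shortage_rate, x$shortage_duration_p))
  invisible(x)
}

# Deterministic sub-seed for a generator stage, kept inside 32-bit range.
stage_seed <- function(config, stage) {
  offsets <- c(catalog = 11L, latent = 23L, dispense = 37L, reports = 53L)
  (config$seed %% 1000003L) * 1009L + offsets[[stage]]
}

with_stage_seed <- function(config, stage, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stage_seed(config, stage))
  code
}
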