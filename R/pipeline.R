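#' Run the full shortage-forecasting pipeline on synthetic data
#'
#' End-to-end convenience wrapper: generate synthetic catalog, dispensing and
#' shortage-report tables, clean the reports into resolved intervals, compute
#' the monthly impact-score series, assemble the lagged feature table, fit
#' one boosted-tree model per IG on all pre-holdout months, and forecast the
#' final `holdout_len` months one step ahead.
#'
#' @param config A [sim_config()].
#' @param holdout_len Number of trailing months held out (default 4).
#' @param hyperparams List from [shortage_hyperparams()].
#' @param lags Number of feature lags.
#' @param earliest Earliest admissible shortage start date for cleaning.
#' @return A list with the simulation (`sim`), resolved `intervals`, the
#'   `impact` series, nested `features`, `holdout_months`, holdout
#'   `forecasts`, per-IG `fits`, and the `evaluation` (a
#'   `"shortage_eval"`).
#' @export
#' @examples
#' \donttest{
#' res <- run_shortage_pipeline(sim_config(n_igs = 5, seed = 3))
#' glance(res$evaluation)
#' }
run_shortage_pipeline <- function(config, holdout_len = 4L,
                                  hyperparams = shortage_hyperparams(),
                                  lags = 4L,
                                  earliest = as.Date("2017-03-01")) {
  sim <- simulate_shortage_data(config)
  intervals <- build_intervals(sim$reports, sim$packs, earliest = earliest,
                               clamp_end = ym_last_day(sim$months[length(sim$months)]))
  impact <- impact_series(sim$dispense, intervals, sim$packs, sim$catalog,
                          months = sim$months)
  features <- assemble_features(sim$dispense, impact, sim$catalog, lags = lags)
  holdout_months <- utils::tail(sim$months, holdout_len)
  ho <- forecast_holdout(features, holdout_months, hyperparams = hyperparams,
                         seed = config$seed)
  list(
    sim = sim,
    intervals = intervals,
    impact = impact,
    features = features,
    holdout_months = holdout_months,
    forecasts = ho$forecasts,
    fits = ho$fits,
    evaluation = evaluate_forecasts(ho$forecasts)
  )
}
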