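# Shared fixtures built in code, plus a lazy cache so expensive pipeline
# runs are shared across test files.

worked_example <- function() {
  catalog <- tibble::tibble(
    din = c("x", "y", "z"), ig_code = "w", tc_code = "84:04.08.28",
    strength = "10MG", common_name = "A"
  )
  packs <- tibble::tibble(
    din = c("x", "x", "y", "z"),
    pack_size = c(100L, 300L, 100L, 100L),
    listing_id = c("a", "b", "c", "d")
  )
  # DIN x holds 40% of cumulative prior DOS (800 of 2000)
  dispense <- tidyr::expand_grid(
    din = c("x", "y", "z"), month = c("2019-01", "2019-02")
  ) |>
    dplyr::mutate(
      ig_code = "w",
      tot_dos = ifelse(din == "x", 400, 300),
      tot_patients = 10L, tot_qty_disp = 100, tot_rx = 10L
    )
  intervals <- tibble::tibble(
    interval_id = 1L, din = "x", listing_id = "b",
    start = as.Date("2019-03-01"), end = as.Date("2019-03-31")
  )
  list(catalog = catalog, packs = packs, dispense = dispense,
       intervals = intervals)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# The full-scale run used by the holdout-shape check and downstream
# evaluation tests: 100 IGs, the 2017-01..2021-04 span, 4 holdout months.
full_scale_pipeline <- function() {
  cached("full_scale", run_shortage_pipeline(sim_config(n_igs = 100, seed = 7)))
}

# A small high-persistence run (long shortage spells, elevated hazard):
# generous lag-1 signal for the planted-importance and signal-vs-control
# checks.
persistent_pipeline <- function() {
  cached("persistent", run_shortage_pipeline(sim_config(
    n_igs = 12, seed = 11,
    shortage_rate = 0.05, shortage_duration_p = 0.15,
    substitution_strength = 0.4
  )))
}

records_from_matrix <- function(m) {
  # rebuild ForecastRecords whose binned confusion matrix equals `m`,
  # using a representative score inside each bin
  rep_score <- c(None = 0, Low = 0.2, Medium = 0.5, High = 0.9)
  bins <- names(rep_score)
  rows <- list()
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (m[i, j] > 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          ig_code = "IG1", month = "2021-01",
          actual = rep(rep_score[[bins[i]]], m[i, j]),
          forecast = rep(rep_score[[bins[j]]], m[i, j])
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
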