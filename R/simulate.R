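#' Generate a synthetic drug catalog
#'
#' Builds the drug hierarchy the analysis assumes: DINs (drug identification
#' numbers) grouped into interchangeable groups (IGs), each IG carrying a
#' four-level AHFS-style therapeutic-class code `"AA:BB.CC.DD"`, plus a
#' catalog of pack-size listings per DIN (distinct listings may share a
#' numeric size, emulating different manufacturers).
#'
#' Therapeutic-class codes are drawn from a small pool of families and
#' branches, so several IGs share each prefix at levels 1-3 and
#' neighbourhood features are non-degenerate.
#'
#' @param config A [sim_config()].
#' @return A list with two tibbles: `catalog` (din, ig_code, tc_code,
#'   strength, common_name) and `packs` (din, pack_size, listing_id).
#' @export
#' @examples
#' cat <- generate_catalog(sim_config(n_igs = 5, seed = 1))
#' head(cat$catalog)
generate_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stage_seed(config, "catalog", {
    n <- config$n_igs
    fam_pool <- c("84", "88", "92", "40", "52", "28", "08", "68", "24", "56")
    n_fam <- max(1L, min(length(fam_pool), ceiling(n / 12)))
    fams <- fam_pool[seq_len(n_fam)]

    seg <- function(k) sprintf("%02d", sample(1:2, k, replace = TRUE) * 4)
    ig_code <- sprintf("IG%04d", seq_len(n))
    tc_code <- paste0(
      sample(fams, n, replace = TRUE), ":",
      seg(n), ".", sprintf("%02d", sample(1:3, n, replace = TRUE) * 8), ".",
      sprintf("%02d", sample(1:4, n, replace = TRUE) * 7)
    )

    n_dins <- sample(config$dins_per_ig[1]:config$dins_per_ig[2], n, replace = TRUE)
    catalog <- tibble::tibble(
      din = sprintf("D%05d", seq_len(sum(n_dins))),
      ig_code = rep(ig_code, n_dins),
      tc_code = rep(tc_code, n_dins),
      strength = paste0(sample(c(5, 10, 25, 40, 50, 100, 250, 500),
                               sum(n_dins), replace = TRUE), "MG"),
      common_name = paste0("AGENT-", rep(sprintf("%03d", seq_len(n)), n_dins))
    )

    n_packs <- sample(config$packs_per_din[1]:config$packs_per_din[2],
                      nrow(catalog), replace = TRUE)
    packs <- tibble::tibble(
      din = rep(catalog$din, n_packs),
      pack_size = sample(c(30L, 50L, 100L, 250L, 500L, 1000L),
                         sum(n_packs), replace = TRUE),
      listing_id = sprintf("L%05d", seq_len(sum(n_packs)))
    )
    list(catalog = catalog, packs = packs)
  })
}

# Latent shortage schedule at DIN/pack-size granularity (the granularity at
# which shortages are reported): one event per (din, pack_size) spell, with
# the affected listing set = every listing of that size. Events never overlap
# within a unit except through therapeutic-class propagation.
draw_latent_schedule <- function(catalog, packs, config) {
  with_stage_seed(config, "latent", {
    months <- ym_seq(config$months[1], config$months[2])
    n_m <- length(months)

    units <- packs |>
      dplyr::group_by(.data$din, .data$pack_size) |>
      dplyr::summarise(listing_ids = paste(sort(.data$listing_id), collapse = ";"),
                       .groups = "drop") |>
      dplyr::left_join(dplyr::select(catalog, "din", "ig_code", "tc_code"), by = "din")

    events <- list()
    for (u in seq_len(nrow(units))) {
      m <- 1L
      while (m <= n_m) {
        if (stats::runif(1) < config$shortage_rate) {
          dur <- 1L + stats::rgeom(1, config$shortage_duration_p)
          end <- min(n_m, m + dur - 1L)
          events[[length(events) + 1L]] <-
            list(unit = u, start = m, end = end, propagated = FALSE)
          m <- end + 2L  # at least one clear month before the next spell
        } else {
          m <- m + 1L
        }
      }
    }

    # Propagation: a new shortage may seed one in a sibling IG (same
    # one-level-up TC prefix) the following month.
    parent <- tc_prefix(units$tc_code, 1L)
    base_n <- length(events)
    for (e in seq_len(base_n)) {
      ev <- events[[e]]
      if (stats::runif(1) >= config$tc_correlation) next
      sibs <- which(parent == parent[ev$unit] & units$ig_code != units$ig_code[ev$unit])
      if (!length(sibs) || ev$start + 1L > n_m) next
      tgt <- if (length(sibs) == 1L) sibs else sample(sibs, 1L)
      dur <- 1L + stats::rgeom(1, config$shortage_duration_p)
      events[[length(events) + 1L]] <- list(
        unit = tgt, start = ev$start + 1L,
        end = min(n_m, ev$start + dur), propagated = TRUE
      )
    }

    if (!length(events)) {
      return(tibble::tibble(
        event_id = integer(), din = character(), ig_code = character(),
        pack_size = integer(), listing_ids = character(),
        start_month = character(), end_month = character(),
        start_date = as.Date(character()), end_date = as.Date(character()),
        propagated = logical()
      ))
    }

    sched <- tibble::tibble(
      unit = vapply(events, `[[`, 1L, "unit"),
      start_idx = vapply(events, `[[`, 1L, "start"),
      end_idx = vapply(events, `[[`, 1L, "end"),
      propagated = vapply(events, `[[`, TRUE, "propagated")
    )
    sched <- dplyr::bind_cols(units[sched$unit, ], sched["start_idx"],
                              sched["end_idx"], sched["propagated"])
    sched$start_month <- months[sched$start_idx]
    sched$end_month <- months[sched$end_idx]
    sched$start_date <- ym_first_day(sched$start_month)
    sched$end_date <- ym_last_day(sched$end_month)
    if (config$day_level) {
      off_s <- floor(stats::runif(nrow(sched)) * (ym_ndays(sched$start_month) - 1))
      off_e <- floor(stats::runif(nrow(sched)) * (ym_ndays(sched$end_month) - 1))
      sched$start_date <- ym_first_day(sched$start_month) + off_s
      sched$end_date <- pmax(ym_last_day(sched$end_month) - off_e, sched$start_date)
    }
    sched |>
      dplyr::arrange(.data$din, .data$pack_size, .data$start_date) |>
      dplyr::mutate(event_id = dplyr::row_number()) |>
      dplyr::select("event_id", "din", "ig_code", "pack_size", "listing_ids",
                    "start_month", "end_month", "start_date", "end_date",
                    "propagated")
  })
}

# Per DIN x month fraction of listings unavailable under the latent schedule
# (month-level: a listing counts as unavailable for the fraction of the
# month's days it spends inside a shortage event).
latent_unavailability <- function(truth, packs, months) {
  if (!nrow(truth)) {
    return(tidyr::expand_grid(din = unique(packs$din), month = months) |>
             dplyr::mutate(unavail = 0))
  }
  intervals <- truth |>
    dplyr::mutate(listing_id = strsplit(.data$listing_ids, ";")) |>
    tidyr::unnest("listing_id") |>
    dplyr::transmute(.data$din, .data$listing_id,
                     start = .data$start_date, end = .data$end_date)
  n_listings <- dplyr::count(packs, .data$din, name = "n_listings")
  monthly_unavailability(intervals, packs, months) |>
    dplyr::group_by(.data$din, .data$month) |>
    dplyr::summarise(sum_frac = sum(.data$frac), .groups = "drop") |>
    dplyr::left_join(n_listings, by = "din") |>
    dplyr::transmute(.data$din, .data$month,
                     unavail = .data$sum_frac / .data$n_listings) |>
    tidyr::complete(din = unique(packs$din), month = months,
                    fill = list(unavail = 0))
}

#' Generate synthetic monthly dispensing records
#'
#' Emits one record per DIN per month with total days of supply (DOS),
#' patients, quantity dispensed and prescription counts. Within each IG,
#' patient shares across DINs follow a Dirichlet draw with the configured
#' concentration, evolving as a slow random walk on the simplex; during a
#' latent shortage of a DIN its share is multiplied by
#' `1 - substitution_strength * unavailable-pack-fraction` (one month after
#' onset) and renormalized across the IG; DOS per patient falls by
#' `dos_drop` times the IG-level unavailable fraction; a 12-month seasonal
#' cycle modulates demand.
#'
#' @param catalog,packs Tibbles from [generate_catalog()].
#' @param config The same [sim_config()] used for the catalog; the latent
#'   shortage schedule is redrawn internally from the config seed, so
#'   dispensing is consistent with [generate_shortage_reports()].
#' @return A tibble with columns din, ig_code, month, tot_dos, tot_patients,
#'   tot_qty_disp, tot_rx, avgdos_pat.
#' @export
generate_dispensing <- function(catalog, packs, config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- draw_latent_schedule(catalog, packs, config)
  months <- ym_seq(config$months[1], config$months[2])
  unav <- latent_unavailability(truth, packs, months) |>
    tidyr::pivot_wider(names_from = "month", values_from = "unavail",
                       values_fill = 0)

  with_stage_seed(config, "dispense", {
    out <- vector("list", length(unique(catalog$ig_code)))
    igs <- unique(catalog$ig_code)
    n_m <- length(months)
    for (i in seq_along(igs)) {
      dins <- catalog$din[catalog$ig_code == igs[i]]
      k <- length(dins)
      base_pat <- max(20, round(config$n_patients_scale * stats::rlnorm(1, 0, 0.4)))
      alpha <- rep(config$preference_concentration, k)
      shares <- stats::rgamma(k, alpha)
      if (sum(shares) == 0) shares <- rep(1, k)
      shares <- shares / sum(shares)
      base_dpp <- stats::runif(k, 25, 35)
      upd <- stats::runif(k, 0.9, 2.5)     # dispensed units per day of supply
      rx_per_pat <- stats::runif(1, 1.0, 1.3)
      phase <- stats::runif(1, 0, 12)

      um <- as.matrix(unav[match(dins, unav$din), months, drop = FALSE])
      um[is.na(um)] <- 0

      rows <- matrix(0, nrow = k * n_m, ncol = 4)
      for (m in seq_len(n_m)) {
        shares <- shares * exp(stats::rnorm(k, 0, 0.05))
        shares <- shares / sum(shares)
        lag_unav <- if (m > 1) um[, m - 1] else rep(0, k)
        eff <- shares * (1 - config$substitution_strength * lag_unav)
        eff <- if (sum(eff) > 0) eff / sum(eff) else rep(1 / k, k)
        season <- 1 + config$seasonal_amplitude * sin(2 * pi * (m + phase) / 12)
        lam <- base_pat * season * eff
        patients <- stats::rpois(k, lam)
        ig_unav <- mean(lag_unav)
        dpp <- pmax(1, base_dpp * (1 - config$dos_drop * ig_unav) *
                      exp(stats::rnorm(k, 0, 0.03)))
        dos <- ifelse(patients > 0, pmax(patients, round(patients * dpp)), 0)
        qty <- round(dos * upd)
        rx <- ifelse(patients > 0, pmax(1, round(patients * rx_per_pat)), 0)
        rows[(m - 1L) * k + seq_len(k), ] <- cbind(dos, patients, qty, rx)
      }
      out[[i]] <- tibble::tibble(
        din = rep(dins, n_m),
        ig_code = igs[i],
        month = rep(months, each = k),
        tot_dos = rows[, 1],
        tot_patients = as.integer(rows[, 2]),
        tot_qty_disp = rows[, 3],
        tot_rx = as.integer(rows[, 4])
      )
    }
    dplyr::bind_rows(out) |>
      dplyr::mutate(avgdos_pat = ifelse(.data$tot_patients > 0,
                                        .data$tot_dos / .data$tot_patients, 0)) |>
      dplyr::arrange(.data$ig_code, .data$din, .data$month)
  })
}

render_pack_text <- function(size, template) {
  if (grepl("{a}", template, fixed = TRUE)) {
    divs <- which(size %% seq_len(size) == 0)
    divs <- divs[divs > 1 & divs < size]
    if (!length(divs)) return(paste(size, "Bottle"))
    a <- divs[ceiling(length(divs) / 2)]
    out <- sub("{a}", a, template, fixed = TRUE)
    return(sub("{b}", size %/% a, out, fixed = TRUE))
  }
  sub("{n}", size, template, fixed = TRUE)
}

#' Generate raw synthetic shortage reports
#'
#' Renders the latent shortage schedule as the kind of raw export a public
#' shortage registry produces: per-report status (actual / anticipated /
#' avoided), pack sizes as free-form text in one of the configured dialects,
#' and date-field defects (blanked or inverted actual dates) at the
#' configured rates. The report date always precedes or equals the
#' anticipated start where both are present, and every record carries a
#' report date.
#'
#' @inheritParams generate_dispensing
#' @return A tibble with columns din, pack_size_text, status, actual_start,
#'   actual_end, anticipated_start, report_date, updated_date (dates as
#'   `Date`, `NA` where absent).
#' @export
generate_shortage_reports <- function(catalog, packs, config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- draw_latent_schedule(catalog, packs, config)
  with_stage_seed(config, "reports", {
    n <- nrow(truth)
    if (!n) {
      return(tibble::tibble(
        din = character(), pack_size_text = character(), status = character(),
        actual_start = as.Date(character()), actual_end = as.Date(character()),
        anticipated_start = as.Date(character()), report_date = as.Date(character()),
        updated_date = as.Date(character())
      ))
    }
    status <- sample(names(config$status_probs), n, replace = TRUE,
                     prob = config$status_probs)
    dialect <- sample(config$text_dialects, n, replace = TRUE)
    txt <- vapply(seq_len(n), function(i) {
      render_pack_text(truth$pack_size[i], dialect[i])
    }, character(1))

    anticipated_start <- truth$start_date - sample(0:14, n, replace = TRUE)
    report_date <- anticipated_start - sample(0:21, n, replace = TRUE)
    actual_start <- truth$start_date
    actual_end <- truth$end_date
    updated_date <- truth$end_date

    is_actual <- status == "actual"
    actual_start[!is_actual] <- NA
    actual_end[!is_actual] <- NA
    updated_date[!is_actual] <- anticipated_start[!is_actual] + 7

    blank_s <- stats::runif(n) < config$defect_rates$missing_date
    blank_e <- stats::runif(n) < config$defect_rates$missing_date
    invert <- stats::runif(n) < config$defect_rates$inverted_date
    actual_start[blank_s] <- NA
    actual_end[blank_e] <- NA
    swap <- invert & !is.na(actual_start) & !is.na(actual_end) &
      actual_start < actual_end
    tmp <- actual_start[swap]
    actual_start[swap] <- actual_end[swap]
    actual_end[swap] <- tmp
    # an inverted record must also not be rescued through the update date
    updated_date[swap] <- actual_end[swap]

    tibble::tibble(
      din = truth$din,
      pack_size_text = txt,
      status = status,
      actual_start = actual_start,
      actual_end = actual_end,
      anticipated_start = anticipated_start,
      report_date = report_date,
      updated_date = updated_date
    )
  })
}

#' Run the full synthetic generator
#'
#' Convenience wrapper producing all generator outputs at once, including the
#' latent-truth ledger (the ground-truth shortage schedule) used to verify
#' the cleaning and scoring stages. The ledger is a testability artifact; no
#' real data source provides one.
#'
#' @param config A [sim_config()].
#' @return A list with tibbles `catalog`, `packs`, `dispense`, `reports`,
#'   `latent_truth`, and the vector `months`.
#' @export
#' @examples
#' sim <- simulate_shortage_data(sim_config(n_igs = 4, seed = 42))
#' names(sim)
simulate_shortage_data <- function(config) {
  cat <- generate_catalog(config)
  list(
    catalog = cat$catalog,
    packs = cat$packs,
    dispense = generate_dispensing(cat$catalog, cat$packs, config),
    reports = generate_shortage_reports(cat$catalog, cat$packs, config),
    latent_truth = draw_latent_schedule(cat$catalog, cat$packs, config),
    months = ym_seq(config$months[1], config$months[2])
  )
}

#' Write a simulation to CSV files
#'
#' Writes `catalog.csv`, `packs.csv`, `dispense.csv`, `shortage_reports.csv`
#' and `latent_truth.csv` into a directory. Dates are ISO-8601; months are
#' `"YYYY-MM"`.
#'
#' @param sim Output of [simulate_shortage_data()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(sim$catalog, file.path(dir, "catalog.csv"))
  readr::write_csv(sim$packs, file.path(dir, "packs.csv"))
  readr::write_csv(sim$dispense, file.path(dir, "dispense.csv"))
  readr::write_csv(sim$reports, file.path(dir, "shortage_reports.csv"))
  readr::write_csv(sim$latent_truth, file.path(dir, "latent_truth.csv"))
  invisible(dir)
}
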