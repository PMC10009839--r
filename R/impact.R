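#' Historical DOS weights of DINs within an IG
#'
#' The weight of a DIN in its interchangeable group for a given month is its
#' share of the group's cumulative days of supply (DOS) from the start of the
#' dispensing series through the month before — "past" usage only, so the
#' weight at month t never sees month t. An IG with no dispensing history in
#' that window gets uniform weights over its component DINs.
#'
#' @param dispense Monthly dispensing tibble (din, ig_code, month, tot_dos,
#'   ...).
#' @param ig IG code.
#' @param month `"YYYY-MM"` month for which weights are needed.
#' @param catalog Optional catalog tibble; when given, the DIN universe is
#'   the IG's component DINs in the catalog (so never-dispensed DINs carry
#'   weight 0, or share in the uniform fallback).
#' @return A tibble (din, ig_code, month, w) whose weights sum to 1.
#' @export
#' @examples
#' d <- tibble::tibble(din = c("x", "y", "z"), ig_code = "w",
#'                     month = "2020-01", tot_dos = c(200, 100, 100))
#' dos_weights(d, "w", "2020-02")
dos_weights <- function(dispense, ig, month, catalog = NULL) {
  ym_check(month)
  dins <- if (!is.null(catalog)) {
    unique(catalog$din[catalog$ig_code == ig])
  } else {
    unique(dispense$din[dispense$ig_code == ig])
  }
  if (!length(dins)) {
    rlang::abort(sprintf("IG %s has no component DINs.", ig),
                 class = "shortcast_lookup_error")
  }
  hist <- dispense |>
    dplyr::filter(.data$ig_code == ig, .data$month < !!month) |>
    dplyr::group_by(.data$din) |>
    dplyr::summarise(dos = sum(.data$tot_dos), .groups = "drop")
  dos <- hist$dos[match(dins, hist$din)]
  dos[is.na(dos)] <- 0
  w <- if (sum(dos) > 0) dos / sum(dos) else rep(1 / length(dins), length(dins))
  tibble::tibble(din = dins, ig_code = ig, month = month, w = w)
}

# Per (listing, month) fraction of the month's days spent inside any
# resolved shortage interval, with overlapping intervals counted once.
# Only listings with at least one interval appear in the output.
monthly_unavailability <- function(intervals, packs, months) {
  empty <- tibble::tibble(din = character(), listing_id = character(),
                          month = character(), frac = numeric())
  if (!nrow(intervals)) return(empty)
  iv <- intervals |>
    dplyr::group_by(.data$din, .data$listing_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::group_modify(function(d, ...) {
      # merge overlapping/abutting intervals so days are counted once
      s <- d$start; e <- d$end
      ms <- s[1]; me <- e[1]; out_s <- c(); out_e <- c()
      for (j in seq_along(s)[-1]) {
        if (s[j] <= me + 1) {
          me <- max(me, e[j])
        } else {
          out_s <- c(out_s, ms); out_e <- c(out_e, me)
          ms <- s[j]; me <- e[j]
        }
      }
      tibble::tibble(start = as.Date(c(out_s, ms), origin = "1970-01-01"),
                     end = as.Date(c(out_e, me), origin = "1970-01-01"))
    }) |>
    dplyr::ungroup()

  grid <- tidyr::expand_grid(
    iv,
    tibble::tibble(month = months,
                   m_first = ym_first_day(months),
                   m_last = ym_last_day(months),
                   m_days = ym_ndays(months))
  )
  grid |>
    dplyr::mutate(
      ov = pmax(0, as.integer(pmin(.data$end, .data$m_last) -
                                pmax(.data$start, .data$m_first)) + 1L)
    ) |>
    dplyr::group_by(.data$din, .data$listing_id, .data$month) |>
    dplyr::summarise(frac = sum(.data$ov) / .data$m_days[1], .groups = "drop") |>
    dplyr::filter(.data$frac > 0)
}

#' Fraction of a DIN's pack listings unavailable in a month
#'
#' All pack listings of a DIN are treated as equally important, so the DIN's
#' unavailability is the mean over its listings of the fraction of the
#' month's days each listing spends inside a shortage interval (overlapping
#' intervals counted once). A DIN with one of two listings shorted for the
#' whole month scores 0.5.
#'
#' @param din DIN identifier.
#' @param month `"YYYY-MM"`.
#' @param intervals Resolved shortages (din, listing_id, start, end), e.g.
#'   from [build_intervals()].
#' @param packs Pack catalog tibble.
#' @return A number in \[0, 1\].
#' @export
pack_unavailability <- function(din, month, intervals, packs) {
  ym_check(month)
  own <- packs[packs$din == din, , drop = FALSE]
  if (!nrow(own)) {
    rlang::abort(sprintf("DIN %s not found in the pack catalog.", din),
                 class = "shortcast_lookup_error")
  }
  iv <- intervals[intervals$din == din, , drop = FALSE]
  if (!nrow(iv)) return(0)
  u <- monthly_unavailability(iv, own, month)
  frac <- u$frac[match(own$listing_id, u$listing_id)]
  frac[is.na(frac)] <- 0
  mean(frac)
}

#' Monthly shortage impact score of one IG
#'
#' The outcome variable: the sum over the IG's component DINs of the DIN's
#' historical-DOS weight times its fraction of unavailable pack listings.
#' Zero means every listing of every component DIN is available; one means
#' nothing in the IG is available.
#'
#' @param ig IG code.
#' @param month `"YYYY-MM"`.
#' @param dispense Monthly dispensing tibble.
#' @param intervals Resolved shortages.
#' @param packs Pack catalog.
#' @param catalog Drug catalog (din, ig_code, ...).
#' @return A score in \[0, 1\].
#' @export
impact_score <- function(ig, month, dispense, intervals, packs, catalog) {
  w <- dos_weights(dispense, ig, month, catalog)
  u <- vapply(w$din, function(d) pack_unavailability(d, month, intervals, packs),
              numeric(1))
  min(1, max(0, sum(w$w * u)))
}

#' Monthly shortage impact series for every IG
#'
#' Computes the impact score on the full IG-by-month grid. This is the
#' vectorized equivalent of calling [impact_score()] per cell.
#'
#' @inheritParams impact_score
#' @param months Contiguous `"YYYY-MM"` vector; defaults to the range of the
#'   dispensing data.
#' @return A tibble (ig_code, month, score) with one row per IG per month.
#' @export
impact_series <- function(dispense, intervals, packs, catalog, months = NULL) {
  if (is.null(months)) {
    months <- ym_seq(min(dispense$month), max(dispense$month))
  }
  ym_check(months)
  igs <- sort(unique(catalog$ig_code))

  # DIN-level unavailability (mean over all catalog listings of the DIN)
  n_listings <- packs |> dplyr::count(.data$din, name = "n_listings")
  u <- monthly_unavailability(intervals, packs, months) |>
    dplyr::group_by(.data$din, .data$month) |>
    dplyr::summarise(sum_frac = sum(.data$frac), .groups = "drop") |>
    dplyr::left_join(n_listings, by = "din") |>
    dplyr::mutate(unavail = .data$sum_frac / .data$n_listings)

  # cumulative prior DOS per DIN-month (through month - 1), over the
  # catalog's DIN universe so never-dispensed DINs still carry weight rows
  all_months <- sort(unique(c(months, dispense$month[dispense$month < months[1]])))
  cum <- tidyr::expand_grid(
    dplyr::distinct(catalog, .data$din, .data$ig_code),
    month = all_months
  ) |>
    dplyr::left_join(dplyr::select(dispense, "din", "month", "tot_dos"),
                     by = c("din", "month")) |>
    dplyr::mutate(tot_dos = dplyr::coalesce(.data$tot_dos, 0)) |>
    dplyr::arrange(.data$din, .data$month) |>
    dplyr::group_by(.data$din, .data$ig_code) |>
    dplyr::mutate(prior_dos = dplyr::lag(cumsum(.data$tot_dos), default = 0)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$month %in% months)

  scores <- cum |>
    dplyr::group_by(.data$ig_code, .data$month) |>
    dplyr::mutate(w = if (sum(.data$prior_dos) > 0) {
      .data$prior_dos / sum(.data$prior_dos)
    } else {
      rep(1 / dplyr::n(), dplyr::n())
    }) |>
    dplyr::ungroup() |>
    dplyr::left_join(u[, c("din", "month", "unavail")], by = c("din", "month")) |>
    dplyr::mutate(unavail = dplyr::coalesce(.data$unavail, 0)) |>
    dplyr::group_by(.data$ig_code, .data$month) |>
    dplyr::summarise(score = pmin(1, pmax(0, sum(.data$w * .data$unavail))),
                     .groups = "drop")

  tidyr::expand_grid(ig_code = igs, month = months) |>
    dplyr::left_join(scores, by = c("ig_code", "month")) |>
    dplyr::mutate(score = dplyr::coalesce(.data$score, 0)) |>
    dplyr::arrange(.data$ig_code, .data$month)
}
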