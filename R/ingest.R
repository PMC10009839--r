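#' Parse free-form pack-size text
#'
#' Shortage registries record pack sizes as free text ("100 Bottle",
#' "100 BTL", "10x10 Blister", ...). This extracts every maximal digit run,
#' in order of appearance, as integers; text with no digits yields an empty
#' vector.
#'
#' @param text A character vector.
#' @return A list (one element per input) of integer vectors.
#' @export
#' @examples
#' parse_pack_text(c("100 Bottle", "10x10 Blister", "UNKNOWN"))
parse_pack_text <- function(text) {
  m <- gregexpr("[0-9]+", as.character(text))
  lapply(regmatches(as.character(text), m), function(x) as.integer(x))
}

#' Impute shortage start and end dates
#'
#' Applies the imputation cascade used for registry exports: the start date
#' is the first present of actual start, anticipated start, report date; the
#' end date is the first present of actual end, last-updated date. A record
#' whose end remains missing, or whose imputed start falls after its imputed
#' end, is marked rejected (it will be removed and counted, never silently
#' dropped).
#'
#' @param reports A data frame of raw shortage reports with columns
#'   `actual_start`, `actual_end`, `anticipated_start`, `report_date`,
#'   `updated_date` (Date or NA). `report_date` must be present on every
#'   record.
#' @return The input tibble with added columns `start`, `end` (Date) and
#'   `rejected` (logical).
#' @export
impute_dates <- function(reports) {
  reports <- tibble::as_tibble(reports)
  if (any(is.na(reports$report_date))) {
    rlang::abort("`report_date` must be present on every shortage report.")
  }
  start <- dplyr::coalesce(as.Date(reports$actual_start),
                           as.Date(reports$anticipated_start),
                           as.Date(reports$report_date))
  end <- dplyr::coalesce(as.Date(reports$actual_end),
                         as.Date(reports$updated_date))
  rejected <- is.na(end) | (!is.na(end) & start > end)
  dplyr::mutate(reports, start = start, end = end, rejected = rejected)
}

#' Filter shortage reports to actual, in-window records
#'
#' Keeps only records with status `"actual"` whose imputed start date is on
#' or after `earliest`. Mandatory shortage reporting in Canada began in
#' March 2017; earlier records are incomplete and excluded by default.
#'
#' @inheritParams impute_dates
#' @param earliest Earliest admissible (imputed) start date.
#' @return The filtered tibble (with imputed `start`, `end`, `rejected`
#'   columns added).
#' @export
filter_reports <- function(reports, earliest = as.Date("2017-03-01")) {
  reports <- impute_dates(reports)
  dplyr::filter(reports, .data$status == "actual", .data$start >= as.Date(earliest))
}

#' Match parsed pack numbers against a DIN's catalog listings
#'
#' A number matches every listing of the DIN with that pack size (listings by
#' different manufacturers share a size and are not distinguished). Texts
#' rendering a size as a product ("10 x 10") are caught by also matching the
#' product of all parsed numbers. When nothing matches — including when no
#' number could be parsed — the DIN is assumed in shortage in all of its
#' pack sizes.
#'
#' @param din A single DIN identifier.
#' @param numbers Integer vector of parsed pack numbers (possibly empty).
#' @param packs Pack catalog tibble (din, pack_size, listing_id).
#' @return Character vector of matched listing ids (never empty).
#' @export
#' @examples
#' packs <- tibble::tibble(din = "D1", pack_size = c(100L, 100L, 500L),
#'                         listing_id = c("a", "b", "c"))
#' match_packs("D1", 100L, packs)     # both 100-packs
#' match_packs("D1", c(10L, 50L), packs)  # product rule -> the 500-pack
#' match_packs("D1", integer(), packs)    # fallback -> all listings
match_packs <- function(din, numbers, packs) {
  own <- packs[packs$din == din, , drop = FALSE]
  if (!nrow(own)) {
    rlang::abort(sprintf("DIN %s not found in the pack catalog.", din),
                 class = "shortcast_lookup_error")
  }
  hit <- own$pack_size %in% numbers
  if (length(numbers) >= 1) {
    hit <- hit | own$pack_size == prod(as.numeric(numbers))
  }
  if (!any(hit)) hit <- rep(TRUE, nrow(own))
  own$listing_id[hit]
}

#' Build clean shortage intervals from raw reports
#'
#' The full cleaning pipeline: status/date filtering, date imputation with
#' rejection of intractable records, pack-text parsing, and catalog matching.
#' One resolved interval is produced per surviving report, covering the
#' matched listing set of its DIN.
#'
#' @inheritParams filter_reports
#' @param packs Pack catalog tibble (din, pack_size, listing_id).
#' @param clamp_end Optional date; interval ends later than this (e.g.
#'   still-open shortages whose end was imputed from an update date) are
#'   clamped to it. Use the last day of the observed data range.
#' @return A tibble of resolved shortages with columns `din`, `listing_id`,
#'   `start`, `end` — one row per (report, matched listing) — carrying an
#'   `interval_id` per source report. The cleaning log is attached as
#'   attribute `"cleaning_log"` and retrievable with [cleaning_log()].
#' @export
build_intervals <- function(reports, packs, earliest = as.Date("2017-03-01"),
                            clamp_end = NULL) {
  kept <- filter_reports(reports, earliest)
  n_window <- nrow(kept)
  rejected <- dplyr::filter(kept, .data$rejected)
  kept <- dplyr::filter(kept, !.data$rejected)

  unknown <- setdiff(unique(kept$din), unique(packs$din))
  if (length(unknown)) {
    rlang::abort(sprintf("DIN(s) not found in the pack catalog: %s",
                         paste(unknown, collapse = ", ")),
                 class = "shortcast_lookup_error")
  }

  nums <- parse_pack_text(kept$pack_size_text)
  n_fallback <- 0L
  rows <- vector("list", nrow(kept))
  for (i in seq_len(nrow(kept))) {
    own <- packs[packs$din == kept$din[i], , drop = FALSE]
    ids <- match_packs(kept$din[i], nums[[i]], packs)
    if (length(ids) == nrow(own) &&
        !any(own$pack_size %in% nums[[i]]) &&
        (length(nums[[i]]) == 0 ||
         !any(own$pack_size == prod(as.numeric(nums[[i]]))))) {
      n_fallback <- n_fallback + 1L
    }
    rows[[i]] <- tibble::tibble(
      interval_id = i,
      din = kept$din[i],
      listing_id = ids,
      start = kept$start[i],
      end = kept$end[i]
    )
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(interval_id = integer(), din = character(),
                   listing_id = character(), start = as.Date(character()),
                   end = as.Date(character()))
  }
  if (!is.null(clamp_end)) {
    out$end <- pmin(out$end, as.Date(clamp_end))
    out <- dplyr::filter(out, .data$start <= .data$end)
  }
  log <- list(
    n_input = nrow(reports),
    n_actual_in_window = n_window,
    n_rejected = nrow(rejected),
    n_resolved = length(unique(out$interval_id)),
    n_all_pack_fallback = n_fallback
  )
  attr(out, "cleaning_log") <- log
  out
}

#' Retrieve the cleaning log of a resolved-shortage table
#'
#' @param intervals Output of [build_intervals()].
#' @return A named list of record counts: raw inputs, actual in-window
#'   records, rejections, resolved intervals, all-pack fallbacks.
#' @export
cleaning_log <- function(intervals) {
  attr(intervals, "cleaning_log")
}
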