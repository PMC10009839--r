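#' Truncate a therapeutic-class code by trailing levels
#'
#' AHFS-style codes are hierarchical, e.g. `"84:04.08.28"`. The prefix at
#' level 0 is the full code; each level up drops one trailing segment, so
#' level 2 of `"84:04.08.28"` is `"84:04"` — the set of classes matching
#' `84:04.**.**`.
#'
#' @param tc_code Character vector of codes with 1-4 `:`/`.`-separated
#'   segments.
#' @param level Integer in 0..3: number of trailing segments to drop.
#' @return Character vector of prefixes (empty string when every segment is
#'   dropped).
#' @export
#' @examples
#' tc_prefix("84:04.08.28", 0:3)
tc_prefix <- function(tc_code, level) {
  stopifnot(all(level %in% 0:3))
  if (length(level) > 1 && length(tc_code) == 1) {
    tc_code <- rep(tc_code, length(level))
  }
  mapply(function(code, lv) {
    if (lv == 0) return(code)
    seps <- gregexpr("[:.]", code)[[1]]
    if (identical(as.integer(seps), -1L)) seps <- integer(0)
    nseg <- length(seps) + 1L
    keep <- nseg - lv
    if (keep <= 0) return("")
    if (keep == nseg) return(code)
    substr(code, 1L, seps[keep] - 1L)
  }, tc_code, level, USE.NAMES = FALSE)
}

#' Within-IG DIN shares for a month
#'
#' The fraction of the IG's patients (or days of supply) dispensed under each
#' component DIN in a month. When the IG's total is zero that month, shares
#' are uniform.
#'
#' @param dispense Monthly dispensing tibble.
#' @param ig IG code.
#' @param month `"YYYY-MM"`.
#' @param basis `"patients"` or `"dos"`.
#' @param catalog Optional catalog fixing the DIN universe.
#' @return A tibble (din, share) with shares summing to 1.
#' @export
din_share <- function(dispense, ig, month, basis = c("patients", "dos"),
                      catalog = NULL) {
  basis <- match.arg(basis)
  col <- if (basis == "patients") "tot_patients" else "tot_dos"
  dins <- if (!is.null(catalog)) {
    unique(catalog$din[catalog$ig_code == ig])
  } else {
    unique(dispense$din[dispense$ig_code == ig])
  }
  rows <- dispense[dispense$ig_code == ig & dispense$month == month, , drop = FALSE]
  v <- rows[[col]][match(dins, rows$din)]
  v[is.na(v)] <- 0
  share <- if (sum(v) > 0) v / sum(v) else rep(1 / length(dins), length(dins))
  tibble::tibble(din = dins, share = share)
}

#' Maximum month-to-month change in DIN shares
#'
#' For an IG whose DIN shares move from one month to the next, the feature is
#' the largest absolute change across DINs, expressed in percent: shares
#' (80, 10, 10)% moving to (50, 30, 20)% give 30. DINs present in only one of
#' the two maps are treated as share 0 in the other.
#'
#' @param shares_t,shares_t_minus_1 Named numeric vectors of shares, or
#'   tibbles with columns `din` and `share`.
#' @return Maximum absolute share change, in percent.
#' @export
#' @examples
#' max_share_change(c(x = 0.5, y = 0.3, z = 0.2), c(x = 0.8, y = 0.1, z = 0.1))
max_share_change <- function(shares_t, shares_t_minus_1) {
  as_vec <- function(s) {
    if (is.data.frame(s)) stats::setNames(s$share, s$din) else s
  }
  a <- as_vec(shares_t)
  b <- as_vec(shares_t_minus_1)
  dins <- union(names(a), names(b))
  if (is.null(names(a)) || is.null(names(b))) {
    if (length(a) != length(b)) {
      rlang::abort("Unnamed share vectors must have equal length.")
    }
    return(100 * max(abs(a - b)))
  }
  av <- a[dins]; av[is.na(av)] <- 0
  bv <- b[dins]; bv[is.na(bv)] <- 0
  100 * max(abs(av - bv))
}

#' Preference-strength Gini coefficient
#'
#' Measures how strongly pharmacists prefer one DIN over the others in an IG
#' in a month, from the shares of patients (or DOS) per DIN. Computed as the
#' mean absolute pairwise difference of shares relative to the mean,
#' `sum |p_i - p_j| / (2 n sum p)`, rescaled by `n / (n - 1)` so that total
#' concentration on a single DIN yields exactly 1 for any group size; uniform
#' shares yield 0, as does a single-DIN group.
#'
#' @param shares Numeric vector of non-negative shares (any positive scale),
#'   or a tibble with a `share` column.
#' @return A value in \[0, 1\].
#' @export
#' @examples
#' gini_preference(c(0.25, 0.25, 0.25, 0.25))  # 0
#' gini_preference(c(1, 0, 0, 0))              # 1
gini_preference <- function(shares) {
  p <- if (is.data.frame(shares)) shares$share else shares
  n <- length(p)
  if (n < 1) rlang::abort("`shares` must be non-empty.")
  if (any(p < 0)) rlang::abort("`shares` must be non-negative.")
  if (n == 1) return(0)
  tot <- sum(p)
  if (tot == 0) return(0)
  # pairwise sum via the sorted-rank identity, O(n log n)
  ps <- sort(p)
  g <- 2 * sum(seq_len(n) * ps) / (n * tot) - (n + 1) / n
  min(1, max(0, g * n / (n - 1)))
}

#' Shortage pressure from neighbouring IGs in the TC hierarchy
#'
#' The DOS-weighted mean impact score of all other IGs whose
#' therapeutic-class code shares the target IG's prefix at the given level
#' (0 = identical TC, 3 = same top family). Weights are each neighbour's
#' cumulative DOS through the prior month; the target IG itself is excluded.
#' Returns 0 when the IG has no neighbours at that level.
#'
#' @param impact Impact-score tibble (ig_code, month, score) from
#'   [impact_series()].
#' @param catalog Drug catalog (provides each IG's tc_code).
#' @param dispense Monthly dispensing tibble (provides the DOS weights).
#' @param ig Target IG code.
#' @param level Integer 0..3.
#' @param month `"YYYY-MM"`.
#' @return A value in \[0, 1\].
#' @export
neighbour_shortage <- function(impact, catalog, dispense, ig, level, month) {
  nb <- neighbour_table(impact, catalog, dispense, levels = level)
  out <- nb[[paste0("shortage_tc", if (level == 0) "" else level)]][
    nb$ig_code == ig & nb$month == month]
  if (!length(out)) {
    rlang::abort(sprintf("IG %s / month %s not found.", ig, month),
                 class = "shortcast_lookup_error")
  }
  out
}

# Vectorized neighbour features for all IGs and months.
# Columns: ig_code, month, shortage_tc, shortage_tc1, shortage_tc2,
# shortage_tc3 (only the requested levels).
neighbour_table <- function(impact, catalog, dispense, levels = 0:3) {
  ig_tc <- dplyr::distinct(catalog, .data$ig_code, .data$tc_code)
  months <- sort(unique(impact$month))

  # cumulative IG DOS through the prior month
  ig_dos <- dispense |>
    dplyr::group_by(.data$ig_code, .data$month) |>
    dplyr::summarise(dos = sum(.data$tot_dos), .groups = "drop") |>
    tidyr::complete(ig_code = ig_tc$ig_code, month = months,
                    fill = list(dos = 0)) |>
    dplyr::filter(.data$ig_code %in% ig_tc$ig_code) |>
    dplyr::arrange(.data$ig_code, .data$month) |>
    dplyr::group_by(.data$ig_code) |>
    dplyr::mutate(w = dplyr::lag(cumsum(.data$dos), default = 0)) |>
    dplyr::ungroup() |>
    dplyr::select("ig_code", "month", "w")

  base <- impact |>
    dplyr::inner_join(ig_tc, by = "ig_code") |>
    dplyr::inner_join(ig_dos, by = c("ig_code", "month"))

  out <- dplyr::distinct(impact, .data$ig_code, .data$month)
  for (lv in levels) {
    cname <- paste0("shortage_tc", if (lv == 0) "" else lv)
    grp <- base |>
      dplyr::mutate(prefix = tc_prefix(.data$tc_code, lv)) |>
      dplyr::group_by(.data$prefix, .data$month) |>
      dplyr::mutate(
        sw = sum(.data$w), swy = sum(.data$w * .data$score), n_ig = dplyr::n()
      ) |>
      dplyr::ungroup() |>
      dplyr::mutate(
        denom = .data$sw - .data$w,
        !!cname := dplyr::case_when(
          .data$n_ig <= 1 ~ 0,
          .data$denom > 0 ~ (.data$swy - .data$w * .data$score) / .data$denom,
          TRUE ~ 0
        )
      ) |>
      dplyr::select("ig_code", "month", dplyr::all_of(cname))
    out <- dplyr::left_join(out, grp, by = c("ig_code", "month"))
  }
  out
}

feature_families <- function() {
  c("shortage_impact", "avgdos_pat", "tot_dos", "tot_qty_disp", "tot_rx",
    "dos", "qty", "rx", "dos_per_pat", "chg_dist_dos", "chg_dist_pat",
    "gini_pat", "gini_dos", "shortage_tc", "shortage_tc1", "shortage_tc2",
    "shortage_tc3", "dos_change")
}

#' Parse feature-column names into a schema
#'
#' Feature columns are named `<family>[.<din>]_lag<k>`. This decomposes a
#' set of column names into (column, family, din, lag) — the machine-readable
#' manifest used to aggregate permutation importances by feature family and
#' by lag.
#'
#' @param columns Character vector of feature column names.
#' @return A tibble (column, family, din, lag); `din` is `NA` for IG-level
#'   features, `lag` is `NA` for unlagged columns.
#' @export
feature_schema <- function(columns) {
  lag <- suppressWarnings(as.integer(stringr::str_match(columns, "_lag(\\d+)$")[, 2]))
  stem <- sub("_lag\\d+$", "", columns)
  din <- stringr::str_match(stem, "^[a-z_0-9]+?\\.(.+)$")[, 2]
  family <- sub("\\..*$", "", stem)
  tibble::tibble(column = columns, family = family, din = din, lag = lag)
}

# Unlagged feature table for a single IG: one row per month.
ig_feature_base <- function(dispense, impact, catalog, ig, nb,
                            dos_change = FALSE) {
  months <- sort(unique(impact$month[impact$ig_code == ig]))
  dins <- sort(unique(catalog$din[catalog$ig_code == ig]))
  d <- dispense |>
    dplyr::filter(.data$ig_code == ig) |>
    dplyr::select("din", "month", "tot_dos", "tot_patients",
                  "tot_qty_disp", "tot_rx") |>
    tidyr::complete(din = dins, month = months,
                    fill = list(tot_dos = 0, tot_patients = 0,
                                tot_qty_disp = 0, tot_rx = 0)) |>
    dplyr::mutate(avgdos_pat = ifelse(.data$tot_patients > 0,
                                      .data$tot_dos / .data$tot_patients, 0))

  per_din <- d |>
    tidyr::pivot_wider(
      id_cols = "month", names_from = "din",
      values_from = c("avgdos_pat", "tot_dos", "tot_qty_disp", "tot_rx"),
      names_glue = "{.value}.{din}"
    )

  agg <- d |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(
      dos = sum(.data$tot_dos),
      qty = sum(.data$tot_qty_disp),
      rx = sum(.data$tot_rx),
      patients = sum(.data$tot_patients),
      .groups = "drop"
    ) |>
    dplyr::mutate(dos_per_pat = ifelse(.data$patients > 0,
                                       .data$dos / .data$patients, 0)) |>
    dplyr::select(-"patients")

  # share-distribution features per month
  share_mat <- function(col) {
    m <- d |>
      dplyr::select("din", "month", val = dplyr::all_of(col)) |>
      tidyr::pivot_wider(names_from = "din", values_from = "val")
    mm <- as.matrix(m[, dins, drop = FALSE])
    tot <- rowSums(mm)
    sh <- mm / ifelse(tot > 0, tot, 1)
    sh[tot == 0, ] <- 1 / length(dins)
    rownames(sh) <- m$month
    sh[months, , drop = FALSE]
  }
  sh_pat <- share_mat("tot_patients")
  sh_dos <- share_mat("tot_dos")
  chg <- function(sh) {
    c(NA_real_, vapply(seq_along(months)[-1], function(m) {
      100 * max(abs(sh[m, ] - sh[m - 1, ]))
    }, numeric(1)))
  }
  dist <- tibble::tibble(
    month = months,
    chg_dist_pat = chg(sh_pat),
    chg_dist_dos = chg(sh_dos),
    gini_pat = unname(apply(sh_pat, 1, gini_preference)),
    gini_dos = unname(apply(sh_dos, 1, gini_preference))
  )

  base <- impact |>
    dplyr::filter(.data$ig_code == ig) |>
    dplyr::select("month", shortage_impact = "score") |>
    dplyr::left_join(per_din, by = "month") |>
    dplyr::left_join(agg, by = "month") |>
    dplyr::left_join(dist, by = "month") |>
    dplyr::left_join(dplyr::filter(nb, .data$ig_code == ig) |>
                       dplyr::select(-"ig_code"),
                     by = "month") |>
    dplyr::arrange(.data$month)
  if (dos_change) {
    base$dos_change <- c(NA_real_, diff(base$dos))
  }
  base
}

#' Assemble the lagged model feature table
#'
#' Builds, for every IG, one row per month holding the contemporaneous
#' shortage impact score (the target) and every predictor at lags 1 through
#' `lags`: per-DIN demand aggregates, IG-level aggregates, month-to-month
#' DIN-share change, preference-strength Gini coefficients, and neighbouring
#' shortage pressure at four therapeutic-class levels. No unlagged predictor
#' is emitted — the model forecasts one month ahead, so a feature at month t
#' may use information through t-1 only. Months whose lag window precedes
#' the data start are dropped.
#'
#' Because the per-DIN feature block covers exactly each IG's component DINs,
#' column sets differ across IGs; the result is therefore nested, one
#' feature tibble per IG.
#'
#' @param dispense Monthly dispensing tibble.
#' @param impact Impact-score tibble from [impact_series()].
#' @param catalog Drug catalog.
#' @param lags Number of monthly lags (default 4).
#' @param dos_change If `TRUE`, additionally emit the month-over-month change
#'   in IG DOS (a seasonality proxy) as a lagged feature.
#' @return A tibble (ig_code, features) where `features` is a list of
#'   per-IG tibbles with columns ig_code, month, shortage_impact and the
#'   lagged predictors named `<family>[.<din>]_lag<k>`.
#' @export
assemble_features <- function(dispense, impact, catalog, lags = 4L,
                              dos_change = FALSE) {
  lags <- as.integer(lags)
  months <- sort(unique(impact$month))
  if (length(months) < lags + 1L) {
    rlang::abort("Need at least `lags` + 1 months of data.",
                 class = "shortcast_config_error")
  }
  bad <- setdiff(unique(dispense$ig_code), unique(catalog$ig_code))
  if (length(bad)) {
    rlang::abort(sprintf("Dispensing references IG(s) missing from the catalog: %s",
                         paste(bad, collapse = ", ")),
                 class = "shortcast_schema_error")
  }
  nb <- neighbour_table(impact, catalog, dispense, levels = 0:3)
  igs <- sort(unique(catalog$ig_code))
  feats <- purrr::map(igs, function(ig) {
    base <- ig_feature_base(dispense, impact, catalog, ig, nb, dos_change)
    pred_cols <- setdiff(names(base), c("month", "shortage_impact"))
    lagged <- base["month"]
    lagged$shortage_impact <- base$shortage_impact
    for (k in seq_len(lags)) {
      block <- dplyr::mutate(base[pred_cols],
                             shortage_impact = base$shortage_impact) |>
        dplyr::mutate(dplyr::across(dplyr::everything(), ~dplyr::lag(.x, k)))
      names(block) <- paste0(names(block), "_lag", k)
      lagged <- dplyr::bind_cols(lagged, block)
    }
    lagged <- lagged[-seq_len(lags), , drop = FALSE]
    # chg_dist/dos_change are undefined at the first month; their lags can
    # still reach it — drop any residual incomplete rows
    lagged <- lagged[stats::complete.cases(lagged), , drop = FALSE]
    dplyr::mutate(tibble::as_tibble(lagged), ig_code = ig, .before = 1)
  })
  tibble::tibble(ig_code = igs, features = feats)
}
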