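shortage_bins <- function() c("None", "Low", "Medium", "High")

#' Bin a shortage impact score into four ordinal classes
#'
#' None when the score is exactly 0; Low for (0, 0.33]; Medium for
#' (0.33, 0.67]; High for (0.67, 1]. The bins partition \[0, 1\] and the
#' boundaries are half-open on the left, so 0.33 is Low and 0.67 is Medium.
#'
#' @param score Numeric vector in \[0, 1\].
#' @return An ordered factor with levels None < Low < Medium < High.
#' @export
#' @examples
#' bin_score(c(0, 0.33, 0.330001, 0.788))
bin_score <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 1)) {
    rlang::abort("`score` must lie in [0, 1].")
  }
  out <- cut(score, breaks = c(-Inf, 0, 0.33, 0.67, 1),
             labels = shortage_bins(), right = TRUE)
  factor(out, levels = shortage_bins(), ordered = TRUE)
}

#' Mean absolute error of shortage forecasts
#'
#' Overall MAE of forecast vs actual impact scores, with breakdowns by the
#' bin of the ACTUAL score (mean actual, mean forecast and MAE per bin) and
#' by IG.
#'
#' @param records ForecastRecord tibble (ig_code, month, actual, forecast).
#' @return A list with `overall` (a number), `by_bin` and `by_ig` tibbles.
#' @export
shortage_mae <- function(records) {
  if (!nrow(records)) rlang::abort("`records` must be non-empty.")
  err <- abs(records$actual - records$forecast)
  by_bin <- records |>
    dplyr::mutate(bin = bin_score(.data$actual)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_actual = mean(.data$actual),
      mean_forecast = mean(.data$forecast),
      mae = mean(abs(.data$actual - .data$forecast)),
      .groups = "drop"
    )
  by_ig <- records |>
    dplyr::group_by(.data$ig_code) |>
    dplyr::summarise(mae = mean(abs(.data$actual - .data$forecast)),
                     .groups = "drop")
  list(overall = mean(err), by_bin = by_bin, by_ig = by_ig)
}

#' Confusion matrix, accuracy and Cohen's kappa of binned forecasts
#'
#' Bins actual and forecast scores into the four shortage classes and
#' tabulates them (actual in rows, forecast in columns). Accuracy is the
#' trace over the total with an exact (Clopper-Pearson) binomial 95%
#' confidence interval by default; Cohen's kappa is unweighted, with chance
#' agreement from the marginal products.
#'
#' @param records ForecastRecord tibble.
#' @param ci_method `"exact"` (Clopper-Pearson) or `"normal"` (Wald).
#' @return A list: `matrix` (4x4 table), `accuracy`, `ci95` (length-2
#'   vector), `kappa`.
#' @export
confusion_and_agreement <- function(records, ci_method = c("exact", "normal")) {
  ci_method <- match.arg(ci_method)
  if (!nrow(records)) rlang::abort("`records` must be non-empty.")
  m <- table(actual = bin_score(records$actual),
             forecast = bin_score(records$forecast))
  n <- sum(m)
  correct <- sum(diag(m))
  accuracy <- correct / n
  ci <- if (ci_method == "exact") {
    as.numeric(stats::binom.test(correct, n)$conf.int)
  } else {
    half <- stats::qnorm(0.975) * sqrt(accuracy * (1 - accuracy) / n)
    c(max(0, accuracy - half), min(1, accuracy + half))
  }
  p_o <- accuracy
  p_e <- sum(rowSums(m) * colSums(m)) / n^2
  kappa <- if (abs(1 - p_e) < .Machine$double.eps) 1 else (p_o - p_e) / (1 - p_e)
  list(matrix = m, accuracy = accuracy, ci95 = ci, kappa = kappa)
}

#' Per-class precision, recall and specificity
#'
#' One-vs-rest metrics from a square confusion matrix (actual in rows,
#' forecast in columns). Ratios with a zero denominator are reported as
#' `NaN` with the `undefined` flag set — never silently imputed to 0.
#'
#' @param matrix A square confusion matrix (table or matrix).
#' @return A tibble (class, precision, recall, specificity, undefined).
#' @export
class_metrics <- function(matrix) {
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) rlang::abort("`matrix` must be square.")
  classes <- rownames(m)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(m)))
  total <- sum(m)
  purrr::map_dfr(seq_len(nrow(m)), function(i) {
    tp <- m[i, i]
    fp <- sum(m[, i]) - tp
    fn <- sum(m[i, ]) - tp
    tn <- total - tp - fp - fn
    ratio <- function(num, den) if (den == 0) NaN else num / den
    prec <- ratio(tp, tp + fp)
    rec <- ratio(tp, tp + fn)
    spec <- ratio(tn, tn + fp)
    tibble::tibble(class = classes[i], precision = prec, recall = rec,
                   specificity = spec,
                   undefined = is.nan(prec) || is.nan(rec) || is.nan(spec))
  })
}

#' Impactful-shortage detection
#'
#' An IG-month is an impactful shortage when its actual impact score is at
#' least `threshold` (at least half the group unavailable, by default). A
#' forecast detects it when the forecast score also reaches the threshold.
#'
#' @param records ForecastRecord tibble.
#' @param threshold Impact threshold (default 0.5).
#' @return A list: `table` (ig_code, month, actual, forecast, detected) and
#'   `detection_rate` (`NaN` when no actual impactful shortages exist).
#' @export
#' @examples
#' r <- tibble::tibble(ig_code = "IG1", month = "2021-01",
#'                     actual = 0.509, forecast = 0.510)
#' impactful_detection(r)$detection_rate  # 1
impactful_detection <- function(records, threshold = 0.5) {
  tab <- records |>
    dplyr::filter(.data$actual >= threshold) |>
    dplyr::mutate(detected = .data$forecast >= threshold) |>
    dplyr::select(dplyr::any_of(c("ig_code", "month")), "actual", "forecast",
                  "detected")
  rate <- if (nrow(tab)) mean(tab$detected) else NaN
  list(table = tab, detection_rate = rate)
}

#' Full forecast evaluation battery
#'
#' Runs every evaluation the forecasting study reports on a set of forecast
#' records: MAE (overall, per actual-score bin, per IG), the 4-class
#' confusion matrix with accuracy, exact binomial confidence interval and
#' Cohen's kappa, per-class precision/recall/specificity, and the
#' impactful-shortage detection table.
#'
#' @inheritParams confusion_and_agreement
#' @param impact_threshold Threshold defining an impactful shortage.
#' @return An object of class `"shortage_eval"`: a list with elements
#'   `records`, `mae`, `confusion` (list), `class_metrics` (tibble),
#'   `impactful` (list) and `n`.
#' @export
evaluate_forecasts <- function(records, impact_threshold = 0.5,
                               ci_method = c("exact", "normal")) {
  ci_method <- match.arg(ci_method)
  conf <- confusion_and_agreement(records, ci_method)
  structure(
    list(
      records = tibble::as_tibble(records),
      mae = shortage_mae(records),
      confusion = conf,
      class_metrics = class_metrics(conf$matrix),
      impactful = impactful_detection(records, impact_threshold),
      n = nrow(records)
    ),
    class = "shortage_eval"
  )
}

#' @export
print.shortage_eval <- function(x, ...) {
  cat(sprintf("<shortage_eval> %d forecasts\n", x$n))
  cat(sprintf("  MAE %.4f | accuracy %.3f (95%% CI %.3f-%.3f) | kappa %.3f\n",
              x$mae$overall, x$confusion$accuracy, x$confusion$ci95[1],
              x$confusion$ci95[2], x$confusion$kappa))
  if (nrow(x$impactful$table)) {
    cat(sprintf("  impactful shortages: %d, detected %.0f%%\n",
                nrow(x$impactful$table), 100 * x$impactful$detection_rate))
  } else {
    cat("  impactful shortages: none in these records\n")
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Writes `eval_report.json` (MAE, accuracy, CI, kappa, detection rate),
#' `confusion_matrix.csv` and `impactful_table.csv` into a directory.
#'
#' @param eval A `"shortage_eval"` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(eval, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  report <- list(
    n = eval$n,
    mae = eval$mae$overall,
    accuracy = eval$confusion$accuracy,
    ci95 = eval$confusion$ci95,
    kappa = eval$confusion$kappa,
    detection_rate = eval$impactful$detection_rate,
    mae_by_bin = eval$mae$by_bin
  )
  jsonlite::write_json(report, file.path(dir, "eval_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  cm <- as.data.frame.matrix(eval$confusion$matrix)
  cm <- cbind(actual = rownames(cm), cm)
  readr::write_csv(cm, file.path(dir, "confusion_matrix.csv"))
  readr::write_csv(eval$impactful$table, file.path(dir, "impactful_table.csv"))
  invisible(dir)
}
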