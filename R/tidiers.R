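#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted IG shortage model
#'
#' Returns the booster's native per-feature importance (gain, cover,
#' frequency) joined with the feature schema, one row per feature used by at
#' least one tree. For the permutation-based importance the study reports,
#' see [permutation_importance()].
#'
#' @param x An `"ig_shortage_fit"`.
#' @param ... Unused.
#' @return A tibble (column, family, din, lag, gain, cover, frequency).
#' @method tidy ig_shortage_fit
#' @export
tidy.ig_shortage_fit <- function(x, ...) {
  imp <- tibble::as_tibble(xgboost::xgb.importance(model = x$booster))
  names(imp) <- tolower(names(imp))
  out <- feature_schema(x$feature_cols) |>
    dplyr::left_join(imp, by = c(column = "feature")) |>
    dplyr::mutate(dplyr::across(dplyr::any_of(c("gain", "cover", "frequency")),
                                ~dplyr::coalesce(.x, 0)))
  dplyr::arrange(out, dplyr::desc(.data$gain))
}

#' @rdname tidy.ig_shortage_fit
#' @method glance ig_shortage_fit
#' @export
glance.ig_shortage_fit <- function(x, ...) {
  tibble::tibble(
    ig_code = x$ig_code,
    n_features = length(x$feature_cols),
    n_train_months = length(x$train_months),
    nrounds = x$hyperparams$nrounds,
    train_mae = x$train_mae
  )
}

#' Tidy an evaluation report
#'
#' `tidy()` returns the per-class precision/recall/specificity table;
#' `glance()` returns a one-row summary (n, MAE, accuracy, CI bounds, kappa,
#' impactful-shortage counts and detection rate).
#'
#' @param x A `"shortage_eval"` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy shortage_eval
#' @export
tidy.shortage_eval <- function(x, ...) {
  x$class_metrics
}

#' @rdname tidy.shortage_eval
#' @method glance shortage_eval
#' @export
glance.shortage_eval <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    mae = x$mae$overall,
    accuracy = x$confusion$accuracy,
    ci_low = x$confusion$ci95[1],
    ci_high = x$confusion$ci95[2],
    kappa = x$confusion$kappa,
    n_impactful = nrow(x$impactful$table),
    detection_rate = x$impactful$detection_rate
  )
}

#' Tidy a permutation-importance table
#'
#' `tidy()` returns the by-family shares (or by family and lag with
#' `by = "family_lag"`); `glance()` returns the baseline MAE and column
#' count.
#'
#' @param x An `"importance_table"`.
#' @param by `"family"`, `"family_lag"` or `"column"`.
#' @param ... Unused.
#' @return A tibble of percentage shares.
#' @method tidy importance_table
#' @export
tidy.importance_table <- function(x, by = c("family", "family_lag", "column"),
                                  ...) {
  by <- match.arg(by)
  switch(by,
         family = x$by_family,
         family_lag = x$by_family_lag,
         column = x$by_column)
}

#' @rdname tidy.importance_table
#' @method glance importance_table
#' @export
glance.importance_table <- function(x, ...) {
  tibble::tibble(n_columns = nrow(x$by_column), base_mae = x$base_mae)
}
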