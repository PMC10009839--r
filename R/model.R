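#' Blocked time-series cross-validation splits
#'
#' Expanding-window resamples: split k trains on the first
#' `min_train + k - 1` months and tests on the following `test_len` months,
#' so every test block strictly follows its training window and successive
#' splits extend training by exactly one month. A 48-month range with the
#' defaults yields 36 resamples.
#'
#' @param months Contiguous `"YYYY-MM"` vector.
#' @param min_train Minimum training window, months (default 12).
#' @param test_len Test block length, months (default 1).
#' @return A tibble (split_id, train_months, test_months) with list-columns
#'   of month vectors.
#' @export
#' @examples
#' s <- make_blocked_splits(ym_seq("2017-01", "2020-12"))
#' nrow(s)  # 36
make_blocked_splits <- function(months, min_train = 12L, test_len = 1L) {
  ym_check(months)
  n <- length(months)
  if (!identical(months, ym_seq(months[1], months[n]))) {
    rlang::abort("`months` must be a contiguous ascending month range.",
                 class = "shortcast_config_error")
  }
  n_splits <- n - min_train - test_len + 1L
  if (n_splits < 1L) {
    rlang::abort(sprintf(
      "Month range too short: %d months cannot hold a %d-month training window plus a %d-month test block.",
      n, min_train, test_len), class = "shortcast_config_error")
  }
  tibble::tibble(
    split_id = seq_len(n_splits),
    train_months = lapply(seq_len(n_splits), function(k) months[seq_len(min_train + k - 1L)]),
    test_months = lapply(seq_len(n_splits), function(k) {
      months[min_train + k - 1L + seq_len(test_len)]
    })
  )
}

#' Default boosted-tree hyperparameters
#'
#' @param nrounds Number of boosting rounds.
#' @param max_depth Maximum tree depth.
#' @param learning_rate Shrinkage per round.
#' @param subsample Row subsampling fraction per round.
#' @return A named list.
#' @export
shortage_hyperparams <- function(nrounds = 300L, max_depth = 4L,
                                 learning_rate = 0.1, subsample = 0.9) {
  list(nrounds = as.integer(nrounds), max_depth = as.integer(max_depth),
       learning_rate = learning_rate, subsample = subsample)
}

feature_matrix <- function(features, target = "shortage_impact") {
  cols <- setdiff(names(features), c("ig_code", "month", target))
  x <- as.matrix(features[cols])
  storage.mode(x) <- "double"
  x
}

#' Fit one IG's shortage forecaster
#'
#' Trains a gradient-boosted tree regressor (xgboost, single-threaded and
#' seeded, hence deterministic) of the monthly shortage impact score on the
#' lagged feature table of one IG. Training uses only `train_months`; if
#' `test_months` is given, out-of-sample predictions for those months are
#' recorded with phase `"cv"`. Predictions are clipped to \[0, 1\] — the
#' outcome is a bounded score.
#'
#' @param features One IG's feature tibble (an element of
#'   [assemble_features()]'s `features` column).
#' @param train_months Months to train on (character vector, or a one-row
#'   slice of [make_blocked_splits()] via `split`).
#' @param split Optional one-row tibble from [make_blocked_splits()];
#'   overrides `train_months`/`test_months`.
#' @param test_months Optional months to predict out-of-sample.
#' @param hyperparams List from [shortage_hyperparams()].
#' @param seed Integer seed passed to the booster.
#' @param target Name of the outcome column.
#' @return An object of class `"ig_shortage_fit"`: a list with the fitted
#'   booster, feature columns, training months, and a `predictions` tibble of
#'   ForecastRecords (ig_code, month, actual, forecast, phase).
#' @export
fit_ig_model <- function(features, train_months = NULL, split = NULL,
                         test_months = NULL,
                         hyperparams = shortage_hyperparams(), seed = 1L,
                         target = "shortage_impact") {
  if (!is.null(split)) {
    train_months <- split$train_months[[1]]
    test_months <- split$test_months[[1]]
  }
  if (is.null(train_months)) {
    rlang::abort("Provide `train_months` or a `split`.")
  }
  tr <- features[features$month %in% train_months, , drop = FALSE]
  if (!nrow(tr)) {
    rlang::abort("No training rows fall inside `train_months`.",
                 class = "shortcast_config_error")
  }
  x <- feature_matrix(tr, target)
  y <- tr[[target]]
  booster <- xgboost::xgboost(
    x, y,
    objective = "reg:squarederror",
    nrounds = hyperparams$nrounds,
    max_depth = hyperparams$max_depth,
    learning_rate = hyperparams$learning_rate,
    subsample = hyperparams$subsample,
    nthreads = 1L,
    seed = as.integer(seed) %% .Machine$integer.max,
    verbosity = 0L
  )
  fit <- structure(
    list(booster = booster, feature_cols = colnames(x), target = target,
         train_months = train_months, ig_code = features$ig_code[1],
         hyperparams = hyperparams, seed = seed,
         train_mae = mean(abs(clip01(predict(booster, x)) - y))),
    class = "ig_shortage_fit"
  )
  preds <- NULL
  if (!is.null(test_months)) {
    te <- features[features$month %in% test_months, , drop = FALSE]
    if (nrow(te)) {
      preds <- tibble::tibble(
        ig_code = te$ig_code,
        month = te$month,
        actual = te[[target]],
        forecast = predict_ig(fit, te),
        phase = "cv"
      )
    }
  }
  fit$predictions <- preds
  fit
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Predict from a fitted IG model
#'
#' @param fit An `"ig_shortage_fit"`.
#' @param features Feature rows to predict (same columns as training).
#' @return Numeric forecasts clipped to \[0, 1\].
#' @export
predict_ig <- function(fit, features) {
  x <- as.matrix(features[fit$feature_cols])
  storage.mode(x) <- "double"
  clip01(predict(fit$booster, x))
}

#' @export
print.ig_shortage_fit <- function(x, ...) {
  cat(sprintf("<ig_shortage_fit> IG %s: %d features, %d training months, train MAE %.4f\n",
              x$ig_code, length(x$feature_cols), length(x$train_months),
              x$train_mae))
  invisible(x)
}

#' Run blocked cross-validation for one IG
#'
#' Fits one model per resample and collects the out-of-sample test
#' predictions of every split.
#'
#' @param features One IG's feature tibble.
#' @param splits Tibble from [make_blocked_splits()].
#' @inheritParams fit_ig_model
#' @return A tibble of ForecastRecords (phase `"cv"`) with a `split_id`
#'   column.
#' @export
run_cv <- function(features, splits, hyperparams = shortage_hyperparams(),
                   seed = 1L, target = "shortage_impact") {
  purrr::map_dfr(seq_len(nrow(splits)), function(k) {
    fit <- fit_ig_model(features,
                        train_months = splits$train_months[[k]],
                        test_months = splits$test_months[[k]],
                        hyperparams = hyperparams, seed = seed, target = target)
    if (is.null(fit$predictions)) return(NULL)
    dplyr::mutate(fit$predictions, split_id = splits$split_id[k])
  })
}

#' One-step-ahead holdout forecasts for all IGs
#'
#' For each IG, refits the model once on all pre-holdout months and predicts
#' each holdout month from its observed lagged features (reported shortages
#' and dispensing through the prior month are known at forecast time under
#' the 30-day horizon, so lags are observed, not recursively predicted).
#'
#' @param features_by_ig Nested tibble from [assemble_features()].
#' @param holdout_months Character vector of holdout months.
#' @inheritParams fit_ig_model
#' @return A list with `forecasts` (tibble of ForecastRecords, phase
#'   `"holdout"`) and `fits` (named list of `"ig_shortage_fit"`).
#' @export
forecast_holdout <- function(features_by_ig, holdout_months,
                             hyperparams = shortage_hyperparams(), seed = 1L,
                             target = "shortage_impact") {
  ym_check(holdout_months)
  fits <- list()
  recs <- purrr::map_dfr(seq_len(nrow(features_by_ig)), function(i) {
    feats <- features_by_ig$features[[i]]
    ig <- features_by_ig$ig_code[i]
    missing <- setdiff(holdout_months, feats$month)
    if (length(missing)) {
      rlang::abort(sprintf("IG %s has no feature rows (lag coverage) for month(s): %s",
                           ig, paste(missing, collapse = ", ")),
                   class = "shortcast_config_error")
    }
    train_m <- setdiff(feats$month, feats$month[feats$month >= min(holdout_months)])
    fit <- fit_ig_model(feats, train_months = train_m,
                        hyperparams = hyperparams, seed = seed, target = target)
    fits[[ig]] <<- fit
    ho <- feats[feats$month %in% holdout_months, , drop = FALSE]
    tibble::tibble(
      ig_code = ig, month = ho$month, actual = ho[[target]],
      forecast = predict_ig(fit, ho), phase = "holdout"
    )
  })
  list(forecasts = recs, fits = fits)
}

#' Permutation feature importance
#'
#' Measures each feature's contribution as the mean increase in MAE when the
#' feature column is independently permuted (the model-agnostic
#' "not available" probe), over `n_repeats` seeded shuffles. Negative
#' increases are floored at zero and shares are normalized to sum to 100%.
#' The raw per-column table is aggregated two ways: by feature family
#' (summing over lags and component DINs) and by family x lag.
#'
#' @param fit An `"ig_shortage_fit"`.
#' @param features Evaluation rows (typically the fit's training rows or CV
#'   test rows).
#' @param n_repeats Number of shuffles per column.
#' @param seed Integer seed for the shuffles.
#' @return An object of class `"importance_table"`: a list with tibbles
#'   `by_column` (column, family, din, lag, increase, share),
#'   `by_family` (family, share) and `by_family_lag` (family, lag, share);
#'   shares are percentages summing to 100.
#' @export
permutation_importance <- function(fit, features, n_repeats = 5L, seed = 1L) {
  x <- as.matrix(features[fit$feature_cols])
  storage.mode(x) <- "double"
  y <- features[[fit$target]]
  base_mae <- mean(abs(clip01(predict(fit$booster, x)) - y))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  inc <- vapply(seq_along(fit$feature_cols), function(j) {
    deltas <- vapply(seq_len(n_repeats), function(r) {
      xp <- x
      xp[, j] <- xp[sample(nrow(xp)), j]
      mean(abs(clip01(predict(fit$booster, xp)) - y)) - base_mae
    }, numeric(1))
    mean(deltas)
  }, numeric(1))
  inc <- pmax(inc, 0)
  total <- sum(inc)
  if (total <= 0) {
    rlang::warn("Permutation importance: no column changed the MAE; reporting uniform shares.")
    share <- rep(100 / length(inc), length(inc))
  } else {
    share <- 100 * inc / total
  }
  by_column <- feature_schema(fit$feature_cols) |>
    dplyr::mutate(increase = inc, share = share)
  by_family <- by_column |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(share = sum(.data$share), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$share))
  by_family_lag <- by_column |>
    dplyr::group_by(.data$family, .data$lag) |>
    dplyr::summarise(share = sum(.data$share), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$share))
  structure(list(by_column = by_column, by_family = by_family,
                 by_family_lag = by_family_lag, base_mae = base_mae),
            class = "importance_table")
}

#' Average importance tables across IGs
#'
#' Cross-IG average of permutation-importance shares, weighting IGs equally.
#' Families absent from an IG's model (e.g. its DIN block differs) contribute
#' zero for that IG.
#'
#' @param tables A list of `"importance_table"` objects.
#' @return A list with tibbles `by_family` and `by_family_lag` of averaged
#'   percentage shares (each sums to 100).
#' @export
average_importance <- function(tables) {
  n <- length(tables)
  fam <- purrr::map_dfr(tables, "by_family") |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(share = sum(.data$share) / n, .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$share))
  fam_lag <- purrr::map_dfr(tables, "by_family_lag") |>
    dplyr::group_by(.data$family, .data$lag) |>
    dplyr::summarise(share = sum(.data$share) / n, .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$share))
  list(by_family = fam, by_family_lag = fam_lag)
}

#' @export
print.importance_table <- function(x, ...) {
  cat("<importance_table> top families (% of MAE increase):\n")
  print(utils::head(x$by_family, 8))
  invisible(x)
}
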