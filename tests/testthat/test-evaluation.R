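test_that("score binning follows the four-class boundaries", {
  expect_equal(as.character(bin_score(c(0, 0.33, 0.330001, 0.67, 0.6700001, 0.788, 1))),
               c("None", "Low", "Medium", "Medium", "High", "High", "High"))
  expect_equal(as.character(bin_score(1e-9)), "Low")  # None is exactly zero
  expect_true(is.ordered(bin_score(0.5)))
  expect_error(bin_score(1.2), "0, 1")
  expect_error(bin_score(-0.1), "0, 1")
})

test_that("MAE summaries match hand computations overall and per bin", {
  perfect <- tibble::tibble(ig_code = "a", month = "2021-01",
                            actual = c(0, 0.5), forecast = c(0, 0.5))
  expect_equal(shortage_mae(perfect)$overall, 0)

  half <- tibble::tibble(ig_code = "a", month = "2021-01",
                         actual = c(0, 1), forecast = c(0.5, 0.5))
  expect_equal(shortage_mae(half)$overall, 0.5)

  high_bin <- tibble::tibble(ig_code = c("a", "b"), month = "2021-01",
                             actual = c(0.8, 0.9), forecast = c(0.6, 0.7))
  mb <- shortage_mae(high_bin)$by_bin
  expect_equal(mb$bin, factor("High", levels = c("None", "Low", "Medium", "High"),
                              ordered = TRUE))
  expect_equal(mb$mae, 0.2)
  expect_equal(mb$mean_actual, 0.85)
  expect_equal(mb$mean_forecast, 0.65)

  expect_error(shortage_mae(perfect[0, ]), "non-empty")
})

test_that("confusion matrix totals, accuracy and kappa behave on canonical cases", {
  all_correct <- tibble::tibble(ig_code = "a", month = "2021-01",
                                actual = c(0, 0, 0.9, 0.9),
                                forecast = c(0, 0, 0.9, 0.9))
  ca <- confusion_and_agreement(all_correct)
  expect_equal(sum(ca$matrix), 4)
  expect_equal(ca$accuracy, 1)
  expect_equal(ca$kappa, 1)

  # independent marginals: accuracy 0.5, kappa 0
  chance <- records_from_matrix(matrix(c(25, 25, 0, 0,
                                         25, 25, 0, 0,
                                         0, 0, 0, 0,
                                         0, 0, 0, 0), 4, 4, byrow = TRUE))
  cc <- confusion_and_agreement(chance)
  expect_equal(cc$accuracy, 0.5)
  expect_equal(cc$kappa, 0)
  expect_equal(sum(cc$matrix), 100)
})

test_that("kappa equals a first-principles computation on random 4x4 matrices", {
  set.seed(77)
  for (i in 1:25) {
    m <- matrix(stats::rpois(16, 6), 4, 4)
    if (sum(diag(m)) == 0) m[1, 1] <- 3
    rec <- records_from_matrix(m)
    ca <- confusion_and_agreement(rec)
    expect_equal(unname(ca$kappa), unname(oracle_kappa(m)), tolerance = 1e-12)
    expect_equal(ca$accuracy, sum(diag(m)) / sum(m), tolerance = 1e-12)
    # accuracy lies inside its own exact CI
    expect_gte(ca$accuracy, ca$ci95[1])
    expect_lte(ca$accuracy, ca$ci95[2])
  }
})

test_that("exact and normal accuracy intervals are both available", {
  rec <- records_from_matrix(diag(c(10, 10, 10, 10)))
  exact <- confusion_and_agreement(rec, ci_method = "exact")$ci95
  normal <- confusion_and_agreement(rec, ci_method = "normal")$ci95
  expect_equal(exact, as.numeric(stats::binom.test(40, 40)$conf.int))
  expect_equal(normal, c(1, 1))  # degenerate Wald at p = 1
  expect_false(identical(exact, normal))
})

test_that("kappa is 1 only for diagonal matrices with at least two occupied classes", {
  two_class <- records_from_matrix(diag(c(5, 7, 0, 0)))
  expect_equal(confusion_and_agreement(two_class)$kappa, 1)
  # a single occupied class has p_e = 1: chance and observed coincide
  one_class <- records_from_matrix(diag(c(12, 0, 0, 0)))
  expect_equal(confusion_and_agreement(one_class)$kappa, 1)
  off <- records_from_matrix(matrix(c(5, 1, 0, 0,
                                      0, 6, 0, 0,
                                      0, 0, 4, 0,
                                      0, 0, 0, 3), 4, 4, byrow = TRUE))
  expect_lt(confusion_and_agreement(off)$kappa, 1)
})

test_that("class metrics match hand tallies and flag undefined ratios", {
  ident <- diag(c(3, 4, 5, 6))
  rownames(ident) <- colnames(ident) <- c("None", "Low", "Medium", "High")
  cm <- class_metrics(ident)
  expect_true(all(cm$precision == 1 & cm$recall == 1 & cm$specificity == 1))
  expect_false(any(cm$undefined))

  hand <- matrix(c(5, 1, 0,
                   2, 3, 1,
                   0, 1, 4), 3, 3, byrow = TRUE)
  cm <- class_metrics(hand)
  for (i in 1:3) {
    want <- oracle_class_metrics(hand, i)
    expect_equal(cm$precision[i], unname(want["precision"]))
    expect_equal(cm$recall[i], unname(want["recall"]))
    expect_equal(cm$specificity[i], unname(want["specificity"]))
  }

  # class never forecast -> precision undefined, surfaced not imputed
  absent <- matrix(c(4, 0, 1, 0,
                     2, 0, 1, 0,
                     0, 0, 3, 0,
                     0, 0, 0, 2), 4, 4, byrow = TRUE)
  rownames(absent) <- colnames(absent) <- c("None", "Low", "Medium", "High")
  cm <- class_metrics(absent)
  expect_true(is.nan(cm$precision[cm$class == "Low"]))
  expect_true(cm$undefined[cm$class == "Low"])
  expect_error(class_metrics(matrix(1:6, 2, 3)), "square")
})

test_that("impactful-shortage detection applies the 0.5 threshold on both sides", {
  rec <- tibble::tibble(
    ig_code = c("a", "b", "c", "d"), month = "2021-01",
    actual = c(0.509, 0.812, 0.510, 0.3),
    forecast = c(0.510, 0.469, 0.011, 0.9)
  )
  det <- impactful_detection(rec)
  expect_equal(nrow(det$table), 3)  # actual >= 0.5 only
  expect_equal(det$table$detected, c(TRUE, FALSE, FALSE))
  expect_equal(det$detection_rate, 1 / 3)

  none <- impactful_detection(dplyr::filter(rec, actual < 0.5))
  expect_equal(nrow(none$table), 0)
  expect_true(is.nan(none$detection_rate))
})

test_that("within-bin perturbations leave the confusion matrix unchanged", {
  set.seed(5)
  rec <- tibble::tibble(
    ig_code = "a", month = "2021-01",
    actual = c(0, 0.1, 0.2, 0.4, 0.5, 0.8, 0.95, 0),
    forecast = c(0, 0.15, 0.5, 0.4, 0.1, 0.9, 0.7, 0.3)
  )
  base <- confusion_and_agreement(rec)$matrix
  # nudge every positive score within its bin
  nudge <- function(s) {
    idx <- pmax(1L, findInterval(s, c(0, 0.33, 0.67), left.open = TRUE))
    lo <- c(0, 0.33, 0.67)[idx]
    hi <- c(0.33, 0.67, 1)[idx]
    ifelse(s == 0, 0, pmin(hi, pmax(lo + 1e-6, s + stats::runif(length(s), -0.02, 0.02))))
  }
  rec2 <- dplyr::mutate(rec, actual = nudge(actual), forecast = nudge(forecast))
  expect_equal(confusion_and_agreement(rec2)$matrix, base)
})

test_that("full evaluation report is internally consistent and tidies cleanly", {
  p <- persistent_pipeline()
  ev <- p$evaluation
  expect_s3_class(ev, "shortage_eval")
  expect_equal(sum(ev$confusion$matrix), nrow(p$forecasts))
  expect_true(ev$confusion$accuracy >= 0 && ev$confusion$accuracy <= 1)
  expect_true(ev$confusion$kappa >= -1 && ev$confusion$kappa <= 1)
  g <- glance(ev)
  expect_equal(g$n, nrow(p$forecasts))
  expect_equal(nrow(tidy(ev)), 4)
  dir <- withr::local_tempdir()
  write_eval_report(ev, dir)
  expect_setequal(list.files(dir),
                  c("eval_report.json", "confusion_matrix.csv",
                    "impactful_table.csv"))
  back <- jsonlite::read_json(file.path(dir, "eval_report.json"))
  expect_equal(back$accuracy, ev$confusion$accuracy)
})

test_that("forecasts with real signal beat a label-shuffled control", {
  p <- persistent_pipeline()
  real <- p$evaluation
  set.seed(123)
  shuffled <- dplyr::mutate(p$forecasts, forecast = sample(forecast))
  control <- evaluate_forecasts(shuffled)
  expect_gt(real$confusion$accuracy, control$confusion$accuracy)
  if (nrow(real$impactful$table) > 0 && !is.nan(control$impactful$detection_rate)) {
    expect_gte(real$impactful$detection_rate, control$impactful$detection_rate)
  }
})
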