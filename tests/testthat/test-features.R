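test_that("therapeutic-class prefixes truncate trailing segments", {
  expect_equal(tc_prefix("84:04.08.28", 0), "84:04.08.28")
  expect_equal(tc_prefix("84:04.08.28", 1), "84:04.08")
  expect_equal(tc_prefix("84:04.08.28", 2), "84:04")
  expect_equal(tc_prefix("84:04.08.28", 3), "84")
  # prefix algebra: level-k of level-j (k >= j) equals level-k of the code
  codes <- c("84:04.08.28", "10:20.30", "52:08")
  for (code in codes) {
    nseg <- length(strsplit(code, "[:.]")[[1]])
    for (j in 0:min(3, nseg - 1)) {
      for (k in j:min(3, nseg - 1)) {
        expect_equal(tc_prefix(tc_prefix(code, j), k - j), tc_prefix(code, k))
      }
    }
  }
})

test_that("DIN shares normalize by patients or DOS", {
  d <- tibble::tibble(din = c("x", "y", "z"), ig_code = "w", month = "2020-01",
                      tot_patients = c(80L, 10L, 10L), tot_dos = c(60, 40, 0),
                      tot_qty_disp = 0, tot_rx = 0L)
  expect_equal(din_share(d, "w", "2020-01", "patients")$share, c(0.8, 0.1, 0.1))
  expect_equal(din_share(d[1:2, ], "w", "2020-01", "dos")$share, c(0.6, 0.4))
  expect_equal(din_share(d[1, ], "w", "2020-01")$share, 1)
  # zero total falls back to uniform shares
  d0 <- dplyr::mutate(d, tot_patients = 0L)
  expect_equal(din_share(d0, "w", "2020-01")$share, rep(1 / 3, 3))
})

test_that("max share change matches the worked 30% example and is symmetric", {
  prev <- c(x = 0.8, y = 0.1, z = 0.1)
  curr <- c(x = 0.5, y = 0.3, z = 0.2)
  expect_equal(max_share_change(curr, prev), 30)
  expect_equal(max_share_change(prev, curr), 30)  # symmetry
  expect_equal(max_share_change(prev, prev), 0)
  expect_equal(max_share_change(c(a = 1, b = 0), c(a = 0, b = 1)), 100)
  # a DIN missing from one month counts as share 0 there
  expect_equal(max_share_change(c(a = 1), c(a = 0.6, b = 0.4)), 40)
})

test_that("preference Gini hits its documented extremes", {
  for (n in 2:6) {
    expect_equal(gini_preference(rep(1 / n, n)), 0)
    expect_equal(gini_preference(c(1, rep(0, n - 1))), 1)
  }
  expect_equal(gini_preference(1), 0)       # single DIN
  expect_equal(gini_preference(c(0, 0, 0)), 0)  # empty month
  expect_error(gini_preference(numeric(0)))
})

test_that("Gini agrees with the pairwise oracle and is permutation/scale invariant", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(2:8, 1)
    p <- stats::rgamma(n, 0.7)
    p <- p / sum(p)
    g <- gini_preference(p)
    expect_equal(g, oracle_gini(p), tolerance = 1e-12)
    expect_equal(gini_preference(sample(p)), g, tolerance = 1e-12)
    expect_equal(gini_preference(p * 1000), g, tolerance = 1e-12)
  }
  expect_equal(gini_preference(c(0.5, 0.5, 0)), oracle_gini(c(0.5, 0.5, 0)),
               tolerance = 1e-12)
})

nb_fixture <- function(scores = c(1, 0), dos = c(100, 100)) {
  catalog <- tibble::tibble(
    din = c("a", "b", "c"),
    ig_code = c("IG1", "IG2", "IG3"),
    tc_code = c("84:04.08.28", "84:04.08.12", "84:04.08.16")
  )
  months <- c("2020-01", "2020-02")
  impact <- tidyr::expand_grid(ig_code = catalog$ig_code, month = months) |>
    dplyr::mutate(score = c(0, 0.4, scores[1], scores[1], scores[2], scores[2]))
  dispense <- tibble::tibble(
    din = c("a", "b", "c"), ig_code = catalog$ig_code, month = "2020-01",
    tot_dos = c(50, dos[1], dos[2]), tot_patients = 1L, tot_qty_disp = 0,
    tot_rx = 0L
  )
  list(catalog = catalog, impact = impact, dispense = dispense)
}

test_that("neighbour shortage is the DOS-weighted mean over other IGs in the prefix group", {
  f <- nb_fixture(scores = c(1, 0), dos = c(100, 100))
  # at level 1 all three IGs share "84:04.08"; neighbours of IG1 have equal
  # cumulative DOS and scores 1 and 0 in 2020-02
  expect_equal(neighbour_shortage(f$impact, f$catalog, f$dispense,
                                  "IG1", 1, "2020-02"), 0.5)
  # unequal DOS tilts the mean: weights 300 vs 100 on scores 1 and 0
  f2 <- nb_fixture(scores = c(1, 0), dos = c(300, 100))
  expect_equal(neighbour_shortage(f2$impact, f2$catalog, f2$dispense,
                                  "IG1", 1, "2020-02"), 0.75)
  # level 0: no other IG shares the full code
  expect_equal(neighbour_shortage(f$impact, f$catalog, f$dispense,
                                  "IG1", 0, "2020-02"), 0)
})

test_that("an IG's own score never leaks into its neighbour feature", {
  f <- nb_fixture()
  base <- neighbour_shortage(f$impact, f$catalog, f$dispense, "IG1", 1, "2020-02")
  bumped <- dplyr::mutate(f$impact,
                          score = ifelse(ig_code == "IG1", 0.9, score))
  expect_equal(neighbour_shortage(bumped, f$catalog, f$dispense,
                                  "IG1", 1, "2020-02"), base)
})

feature_fixture <- function(seed = 13, n_igs = 4) {
  cfg <- sim_config(n_igs = n_igs, months = c("2018-01", "2019-12"),
                    shortage_rate = 0.06, seed = seed)
  sim <- simulate_shortage_data(cfg)
  iv <- build_intervals(sim$reports, sim$packs,
                        earliest = as.Date("2018-01-01"),
                        clamp_end = max(ym_last_day(sim$months)))
  impact <- impact_series(sim$dispense, iv, sim$packs, sim$catalog, sim$months)
  list(sim = sim, impact = impact)
}

test_that("lagged feature columns shift the unlagged series correctly", {
  f <- feature_fixture()
  feats <- assemble_features(f$sim$dispense, f$impact, f$sim$catalog)
  one <- feats$features[[1]]
  ig <- feats$ig_code[1]
  si <- f$impact[f$impact$ig_code == ig, ]
  for (k in 1:4) {
    col <- paste0("shortage_impact_lag", k)
    expect_equal(
      one[[col]],
      si$score[match(ym_add(one$month, -k), si$month)],
      label = col
    )
  }
  # the target column is the contemporaneous score
  expect_equal(one$shortage_impact, si$score[match(one$month, si$month)])
})

test_that("per-DIN feature blocks cover exactly the IG's component DINs at all lags", {
  f <- feature_fixture()
  feats <- assemble_features(f$sim$dispense, f$impact, f$sim$catalog)
  for (i in seq_len(nrow(feats))) {
    dins <- sort(f$sim$catalog$din[f$sim$catalog$ig_code == feats$ig_code[i]])
    sc <- feature_schema(names(feats$features[[i]]))
    per_din <- sc[!is.na(sc$din) & sc$family == "tot_dos", ]
    expect_setequal(unique(per_din$din), dins)
    expect_equal(nrow(per_din), length(dins) * 4)
  }
  # no unlagged predictors besides the target
  sc <- feature_schema(names(feats$features[[1]]))
  unlagged <- sc$column[is.na(sc$lag)]
  expect_setequal(unlagged, c("ig_code", "month", "shortage_impact"))
})

test_that("constant dispensing yields zero share-change features and equal lag copies", {
  months <- ym_seq("2019-01", "2019-12")
  catalog <- tibble::tibble(din = c("a", "b"), ig_code = "IG1",
                            tc_code = "84:04.08.28", strength = "1MG",
                            common_name = "X")
  dispense <- tidyr::expand_grid(din = c("a", "b"), month = months) |>
    dplyr::mutate(ig_code = "IG1", tot_dos = ifelse(din == "a", 300, 100),
                  tot_patients = 10L, tot_qty_disp = 50, tot_rx = 5L)
  impact <- tibble::tibble(ig_code = "IG1", month = months, score = 0)
  feats <- assemble_features(dispense, impact, catalog)$features[[1]]
  expect_true(all(feats$chg_dist_pat_lag1 == 0))
  expect_true(all(feats$chg_dist_dos_lag1 == 0))
  for (fam in c("gini_pat", "dos", "avgdos_pat.a")) {
    expect_equal(feats[[paste0(fam, "_lag1")]], feats[[paste0(fam, "_lag4")]],
                 label = fam)
  }
})

test_that("features never peek past their month (truncation leaves earlier rows unchanged)", {
  f <- feature_fixture(seed = 21)
  months <- f$sim$months
  cut <- months[18]
  full <- assemble_features(f$sim$dispense, f$impact, f$sim$catalog)
  trunc_disp <- f$sim$dispense[f$sim$dispense$month <= cut, ]
  trunc_imp <- f$impact[f$impact$month <= cut, ]
  trunc <- assemble_features(trunc_disp, trunc_imp, f$sim$catalog)
  for (i in seq_len(nrow(full))) {
    a <- full$features[[i]]
    a <- a[a$month <= ym_add(cut, -1), ]
    b <- trunc$features[[i]]
    b <- b[b$month <= ym_add(cut, -1), ]
    expect_equal(as.data.frame(a), as.data.frame(b),
                 label = paste("IG", full$ig_code[i]))
  }
})

test_that("the optional DOS-change seasonality feature appears only when asked", {
  f <- feature_fixture()
  off <- assemble_features(f$sim$dispense, f$impact, f$sim$catalog)
  on <- assemble_features(f$sim$dispense, f$impact, f$sim$catalog,
                          dos_change = TRUE)
  expect_false(any(grepl("^dos_change_lag", names(off$features[[1]]))))
  expect_true(all(paste0("dos_change_lag", 1:4) %in% names(on$features[[1]])))
})

test_that("feature schema parses family, DIN and lag from column names", {
  sc <- feature_schema(c("shortage_impact_lag2", "avgdos_pat.D00012_lag4",
                         "gini_pat_lag1", "shortage_tc3_lag1", "month"))
  expect_equal(sc$family, c("shortage_impact", "avgdos_pat", "gini_pat",
                            "shortage_tc3", "month"))
  expect_equal(sc$din, c(NA, "D00012", NA, NA, NA))
  expect_equal(sc$lag, c(2L, 4L, 1L, 1L, NA))
})
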