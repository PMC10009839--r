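# Independent brute-force oracles, written against first principles only
# (base R, no package internals). They are deliberately slow and literal.

# Daily-enumeration impact score: for each listing and each day of the month,
# decide availability from the raw interval list, average per DIN over
# listings, weight DINs by cumulative DOS through the prior month.
oracle_impact <- function(ig, month, dispense, intervals, packs, catalog) {
  dins <- unique(catalog$din[catalog$ig_code == ig])
  first <- as.Date(paste0(month, "-01"))
  last <- seq(first, by = "month", length.out = 2)[2] - 1
  days <- seq(first, last, by = "day")

  unavail <- vapply(dins, function(d) {
    ids <- packs$listing_id[packs$din == d]
    per_listing <- vapply(ids, function(l) {
      iv <- intervals[intervals$listing_id == l & intervals$din == d, , drop = FALSE]
      if (!nrow(iv)) return(0)
      covered <- vapply(days, function(day) {
        any(iv$start <= day & day <= iv$end)
      }, logical(1))
      mean(covered)
    }, numeric(1))
    mean(per_listing)
  }, numeric(1))

  prior <- dispense[dispense$ig_code == ig & dispense$month < month, , drop = FALSE]
  dos <- vapply(dins, function(d) sum(prior$tot_dos[prior$din == d]), numeric(1))
  w <- if (sum(dos) > 0) dos / sum(dos) else rep(1 / length(dins), length(dins))
  min(1, max(0, sum(w * unavail)))
}

# O(n^2) pairwise-difference Gini with the n/(n-1) finite-sample rescale.
oracle_gini <- function(p) {
  n <- length(p)
  if (n == 1 || sum(p) == 0) return(0)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(p[i] - p[j])
  g <- s / (2 * n * sum(p))
  min(1, g * n / (n - 1))
}

# Cohen's kappa from a confusion matrix, spelled out.
oracle_kappa <- function(m) {
  m <- as.matrix(m)
  n <- sum(m)
  p_o <- sum(diag(m)) / n
  p_e <- 0
  for (i in seq_len(nrow(m))) {
    p_e <- p_e + (sum(m[i, ]) / n) * (sum(m[, i]) / n)
  }
  (p_o - p_e) / (1 - p_e)
}

# One-vs-rest precision/recall/specificity by explicit TP/FP/FN/TN tally.
oracle_class_metrics <- function(m, class_i) {
  m <- as.matrix(m)
  tp <- m[class_i, class_i]
  fp <- sum(m[-class_i, class_i])
  fn <- sum(m[class_i, -class_i])
  tn <- sum(m[-class_i, -class_i])
  c(precision = tp / (tp + fp), recall = tp / (tp + fn),
    specificity = tn / (tn + fp))
}

# A small random scoring instance: 1-2 IGs, 2-4 DINs, 1-3 listings each,
# a handful of random intervals, 4 months of dispensing history.
random_impact_instance <- function(seed) {
  set.seed(seed)
  months <- c("2019-01", "2019-02", "2019-03", "2019-04")
  n_ig <- sample(1:2, 1)
  catalog <- do.call(rbind, lapply(seq_len(n_ig), function(i) {
    nd <- sample(2:4, 1)
    data.frame(din = paste0("D", i, "_", seq_len(nd)),
               ig_code = paste0("IG", i),
               tc_code = "10:20.30.40", strength = "1MG", common_name = "A")
  }))
  packs <- do.call(rbind, lapply(catalog$din, function(d) {
    np <- sample(1:3, 1)
    data.frame(din = d, pack_size = sample(c(30L, 100L, 500L), np, replace = TRUE),
               listing_id = paste0(d, "_L", seq_len(np)))
  }))
  dispense <- expand.grid(din = catalog$din, month = months,
                          stringsAsFactors = FALSE)
  dispense$ig_code <- catalog$ig_code[match(dispense$din, catalog$din)]
  dispense$tot_dos <- sample(0:500, nrow(dispense), replace = TRUE)
  dispense$tot_patients <- pmin(dispense$tot_dos, sample(0:20, nrow(dispense), TRUE))
  dispense$tot_qty_disp <- dispense$tot_dos
  dispense$tot_rx <- dispense$tot_patients
  n_iv <- sample(0:5, 1)
  intervals <- if (n_iv > 0) {
    idx <- sample(nrow(packs), n_iv, replace = TRUE)
    start <- as.Date("2019-01-01") + sample(0:100, n_iv, replace = TRUE)
    data.frame(interval_id = seq_len(n_iv), din = packs$din[idx],
               listing_id = packs$listing_id[idx], start = start,
               end = start + sample(0:80, n_iv, replace = TRUE))
  } else {
    data.frame(interval_id = integer(), din = character(),
               listing_id = character(), start = as.Date(character()),
               end = as.Date(character()))
  }
  list(catalog = catalog, packs = packs, dispense = dispense,
       intervals = intervals, months = months)
}
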