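test_that("energy labeling uses a strict threshold", {
  expect_equal(label_by_energy(c(1, 4, 3.09), 3.09), c(0L, 1L, 0L))
  expect_equal(label_by_energy(c(0.1, 0.2), 3.09), c(0L, 0L))
})

test_that("noise-free synthetic energies reproduce the generator's labels", {
  lr <- synth_generate(small_synth(seed = 9, dur = 10, noise_sd = 0))
  en <- vapply(segment_recording(lr$recording, 200),
               function(s) sum(s$samples^2), numeric(1))
  expect_equal(label_by_energy(en, 0), lr$labels, ignore_attr = TRUE)
})

test_that("label files round-trip including empty series", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_labels(c(0L, 1L, 1L, 0L, 0L), tmp)
  expect_equal(read_labels(tmp), c(0L, 1L, 1L, 0L, 0L), ignore_attr = TRUE)
  expect_equal(length(readLines(tmp)), 6) # header + 5 rows

  write_labels(integer(0), tmp)
  expect_length(read_labels(tmp), 0)

  big <- rep(c(0L, 1L), 250)
  write_labels(big, tmp)
  expect_equal(length(readLines(tmp)), 501)
  expect_equal(read_labels(tmp), big, ignore_attr = TRUE)

  expect_error(write_labels(c(0, 2), tmp), "0/1")
})

test_that("median and MAD thresholds follow their definitions", {
  expect_equal(threshold_value(c(1, 2, 3), "median"), 2)
  v <- c(4, 1, 7, 2, 9, 3, 8)
  expect_equal(threshold_value(v, "median_plus_M_dev", M = 2),
               stats::median(v) + 2 * stats::mad(v, constant = 1))
  expect_equal(threshold_value(v, "fixed", fixed = 5), 5)
  expect_error(threshold_value(numeric(0), "median"), "empty")
  expect_error(threshold_value(v, "roc_optimal"), "labels")
})

test_that("the ROC-optimal cutoff attains the brute-force optimum", {
  # perfectly separated: distance 0
  v <- c(10, 9, 8, 1, 2, 3)
  lab <- c(1, 1, 1, 0, 0, 0)
  cut <- threshold_value(v, "roc_optimal", labels = lab)
  expect_gt(min(v[lab == 1]), cut)
  expect_lte(max(v[lab == 0]), cut)

  set.seed(14)
  for (rep in 1:25) {
    n <- sample(6:40, 1)
    v <- round(stats::rnorm(n), 1) # ties likely
    lab <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    for (pol in c("high_is_positive", "low_is_positive")) {
      cut <- threshold_value(v, "roc_optimal", labels = lab, polarity = pol)
      pred <- detect(v, cut, pol)
      cc <- confusion(pred, lab)
      r <- rates(cc)
      d <- sqrt(r$fpr^2 + (1 - r$tpr)^2)
      expect_equal(d, brute_optimal_point(v, lab, pol)$d, tolerance = 1e-12)
    }
  }
})

test_that("detection respects polarity and strict comparisons", {
  expect_equal(detect(c(5, 1), 3, "high_is_positive"), c(1L, 0L))
  expect_equal(detect(c(5, 1), 3, "low_is_positive"), c(0L, 1L))
  expect_equal(detect(c(5, 1), 99, "high_is_positive"), c(0L, 0L))
  expect_equal(detect(c(3, 3), 3, "high_is_positive"), c(0L, 0L))
})

test_that("confusion counts tally all four cells and zones", {
  cc <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(c(cc$tp, cc$fp, cc$tn, cc$fn), c(2, 0, 1, 0))
  cc <- confusion(c(0, 1, 0), c(1, 0, 1))
  expect_equal(c(cc$tp, cc$tn), c(0, 0))

  set.seed(15)
  pred <- sample(c(0, 1), 100, replace = TRUE)
  truth <- sample(c(0, 1), 100, replace = TRUE)
  zones <- sample(c("A", "B", NA), 100, replace = TRUE)
  cc <- confusion(pred, truth, zones)
  expect_equal(cc$tp, sum(pred == 1 & truth == 1))
  expect_equal(cc$fn, sum(pred == 0 & truth == 1))
  expect_equal(cc$tp_by_zone[["A"]],
               sum(pred == 1 & truth == 1 & zones == "A", na.rm = TRUE))
  expect_equal(cc$tp + cc$fn, sum(truth == 1))
  expect_equal(cc$fp + cc$tn, sum(truth == 0))
  expect_error(confusion(c(1, 0), c(1, 0, 1)), "mismatch")
})

test_that("rates produce exact ratios and flag empty classes", {
  r <- rates(structure(list(tp = 148, fn = 27, fp = 0, tn = 0),
                       class = "confusion_counts"))
  expect_equal(r$tpr, 148 / 175)
  expect_equal(as_percent(r$tpr), "84.57%")
  r <- rates(structure(list(tp = 0, fn = 0, fp = 124, tn = 201),
                       class = "confusion_counts"))
  expect_equal(r$fpr, 124 / 325)
  expect_equal(as_percent(r$fpr), "38.15%")
  expect_false(r$tpr_defined)
  expect_equal(r$tpr, 0)
})

test_that("ROC curves are monotone with pinned endpoints", {
  set.seed(16)
  for (rep in 1:10) {
    v <- round(stats::rnorm(30), 1)
    lab <- sample(c(0, 1), 30, replace = TRUE)
    if (length(unique(lab)) < 2) next
    roc <- roc_curve(v, lab)
    expect_true(all(diff(roc$tpr) >= 0))
    expect_true(all(diff(roc$fpr) >= 0))
    expect_equal(c(roc$tpr[1], roc$fpr[1]), c(0, 0))
    expect_equal(c(roc$tpr[length(roc$tpr)], roc$fpr[length(roc$fpr)]),
                 c(1, 1))
    # every operating point matches a per-cutoff confusion tally
    for (k in seq_along(roc$thresholds)) {
      cc <- confusion(detect(v, roc$thresholds[k]), lab)
      r <- rates(cc)
      expect_equal(c(roc$tpr[k], roc$fpr[k]), c(r$tpr, r$fpr))
    }
  }
  expect_error(roc_curve(c(1, 2), c(1, 1)), "classes")
})

test_that("AUC equals the Mann-Whitney statistic and handles extremes", {
  v <- c(10, 9, 8, 1, 2, 3)
  lab <- c(1, 1, 1, 0, 0, 0)
  expect_equal(auc(roc_curve(v, lab)), 1)
  expect_equal(auc(roc_curve(v, 1 - lab)), 0)
  expect_equal(auc(roc_curve(rep(2, 6), lab)), 0.5)

  set.seed(17)
  for (rep in 1:20) {
    n <- sample(8:50, 1)
    v <- sample(seq(0, 5, 0.5), n, replace = TRUE)
    lab <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(auc(roc_curve(v, lab)), mw_auc(v, lab), tolerance = 1e-12)
    # polarity reversal complements the AUC
    expect_equal(auc(roc_curve(v, lab, "low_is_positive")),
                 mw_auc(v, lab, "low_is_positive"), tolerance = 1e-12)
  }
  # without ties, AUC(reversed) = 1 - AUC
  v <- stats::rnorm(40)
  lab <- sample(c(0, 1), 40, replace = TRUE)
  expect_equal(auc(roc_curve(v, lab, "low_is_positive")),
               1 - auc(roc_curve(v, lab)), tolerance = 1e-12)
})

test_that("the metric battery reproduces its formulas", {
  cc <- structure(list(tp = 148, fp = 69, fn = 27, tn = 256),
                  class = "confusion_counts")
  m <- metrics(cc)
  expect_equal(as_percent(m$precision), "68.20%")
  expect_equal(as_percent(m$recall), "84.57%")
  expect_equal(as_percent(m$f1), "75.51%")

  perfect <- metrics(structure(list(tp = 10, fp = 0, fn = 0, tn = 20),
                               class = "confusion_counts"))
  expect_equal(c(perfect$accuracy, perfect$precision, perfect$recall,
                 perfect$f1), rep(1, 4))

  set.seed(18)
  for (rep in 1:10) {
    k <- as.list(sample(0:50, 4, replace = TRUE))
    names(k) <- c("tp", "fp", "tn", "fn")
    m <- metrics(structure(k, class = "confusion_counts"))
    expect_equal(m$accuracy, (k$tp + k$tn) / sum(unlist(k)))
    if (k$tp + k$fp > 0) expect_equal(m$precision, k$tp / (k$tp + k$fp))
    if (k$tp + k$fn > 0) expect_equal(m$recall, k$tp / (k$tp + k$fn))
    if (m$precision + m$recall > 0) {
      expect_equal(m$f1, 2 * m$precision * m$recall /
                     (m$precision + m$recall))
    }
  }
})
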