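#' Energy-threshold ground-truth labels
#'
#' Surrogate for manual labeling by an experienced operator: a segment is a
#' positive (call present) when its energy exceeds the threshold, strictly.
#'
#' @param energy Numeric per-segment energies.
#' @param threshold Finite energy cutoff.
#' @return Integer 0/1 vector.
#' @export
label_by_energy <- function(energy, threshold) {
  stopifnot(is.finite(threshold))
  as.integer(energy > threshold)
}

#' Write / read per-segment label files
#'
#' Two-column CSV `segment,label` with 0-based segment indices; round-trips
#' exactly.
#'
#' @param labels Integer 0/1 vector.
#' @param path File path.
#' @return `write_labels()` returns `path` invisibly; `read_labels()`
#'   returns the integer label vector (with optional `zone` attribute when
#'   the file carries a third `zone` column).
#' @export
write_labels <- function(labels, path) {
  if (length(labels) && !all(labels %in% c(0L, 1L))) {
    stop("labels must be 0/1", call. = FALSE)
  }
  zone <- attr(labels, "zone")
  df <- data.frame(segment = seq_along(labels) - 1L,
                   label = as.integer(labels))
  if (!is.null(zone)) df$zone <- zone
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("segment", "label") %in% names(df))) {
    stop("label file lacks segment/label columns: ", path, call. = FALSE)
  }
  df <- df[order(df$segment), ]
  out <- as.integer(df$label)
  if ("zone" %in% names(df)) attr(out, "zone") <- as.character(df$zone)
  out
}

#' Threshold selection for a feature series
#'
#' Three data-driven rules plus a fixed value:
#' * `median` — the median of the feature values;
#' * `median_plus_M_dev` — median + `M` times the (raw) median absolute
#'   deviation, a Chebyshev-style robust margin;
#' * `roc_optimal` — the cutoff whose `(FPR, TPR)` point lies closest (in
#'   Euclidean distance) to the perfect corner `(0, 1)`; requires labels.
#'   Ties prefer higher TPR, then lower FPR.
#'
#' @param features A `feature_series` or numeric vector.
#' @param method One of `"median"`, `"median_plus_M_dev"`, `"roc_optimal"`,
#'   `"fixed"`.
#' @param M Deviation multiplier (>= 0) for `median_plus_M_dev`.
#' @param labels 0/1 truth vector, needed for `roc_optimal`.
#' @param polarity `"high_is_positive"` (default) or `"low_is_positive"`.
#' @param fixed Numeric cutoff for `method = "fixed"`.
#' @return The cutoff value (numeric scalar).
#' @export
threshold_value <- function(features,
                            method = c("median", "median_plus_M_dev",
                                       "roc_optimal", "fixed"),
                            M = 1, labels = NULL,
                            polarity = c("high_is_positive",
                                         "low_is_positive"),
                            fixed = NULL) {
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  v <- if (inherits(features, "feature_series")) features$values else
    as.numeric(features)
  if (length(v) == 0L) stop("empty feature series", call. = FALSE)
  switch(method,
    median = stats::median(v),
    median_plus_M_dev = {
      stopifnot(M >= 0)
      stats::median(v) + M * stats::mad(v, constant = 1)
    },
    roc_optimal = {
      if (is.null(labels)) {
        stop("`roc_optimal` needs ground-truth labels", call. = FALSE)
      }
      .roc_optimal_cutoff(v, labels, polarity)
    },
    fixed = {
      if (is.null(fixed)) stop("`fixed` cutoff not given", call. = FALSE)
      fixed
    }
  )
}

.roc_optimal_cutoff <- function(v, truth, polarity) {
  truth <- as.integer(truth)
  p <- sum(truth == 1L)
  n <- sum(truth == 0L)
  if (p == 0L || n == 0L) {
    stop("labels must contain both classes", call. = FALSE)
  }
  cand <- sort(unique(v))
  cand <- c(cand[1L] - 1, cand) # sentinel admitting the all-positive rule
  best <- NULL
  for (cut in cand) {
    pred <- if (polarity == "high_is_positive") v > cut else v < cut
    tpr <- sum(pred & truth == 1L) / p
    fpr <- sum(pred & truth == 0L) / n
    d <- sqrt(fpr^2 + (1 - tpr)^2)
    if (is.null(best) || d < best$d - 1e-15 ||
        (abs(d - best$d) <= 1e-15 &&
         (tpr > best$tpr + 1e-15 ||
          (abs(tpr - best$tpr) <= 1e-15 && fpr < best$fpr - 1e-15)))) {
      best <- list(cut = cut, d = d, tpr = tpr, fpr = fpr)
    }
  }
  best$cut
}

#' Binary detection of a feature series at a cutoff
#'
#' With `high_is_positive`, a segment is a detection when its feature value
#' strictly exceeds the cutoff; with `low_is_positive`, when it falls
#' strictly below.
#'
#' @inheritParams threshold_value
#' @param cutoff Numeric threshold.
#' @return Integer 0/1 vector.
#' @export
detect <- function(features, cutoff,
                   polarity = c("high_is_positive", "low_is_positive")) {
  polarity <- match.arg(polarity)
  v <- if (inherits(features, "feature_series")) features$values else
    as.numeric(features)
  if (polarity == "high_is_positive") as.integer(v > cutoff) else
    as.integer(v < cutoff)
}

#' Confusion counts
#'
#' TP/FP/TN/FN tallies of a prediction against the truth, with an optional
#' per-zone breakdown of the TP and FP counts (e.g. A call zone vs B call
#' zone).
#'
#' @param pred Integer 0/1 predictions.
#' @param truth Integer 0/1 ground truth, same length.
#' @param zones Optional character vector of zone tags per segment (`NA` for
#'   unzoned segments).
#' @return Object of class `confusion_counts`: `tp`, `fp`, `tn`, `fn`, and
#'   when zones are given `tp_by_zone`, `fp_by_zone`.
#' @export
confusion <- function(pred, truth, zones = NULL) {
  pred <- as.integer(pred)
  truth <- as.integer(truth)
  if (length(pred) != length(truth)) {
    stop("prediction/truth length mismatch", call. = FALSE)
  }
  out <- list(
    tp = sum(pred == 1L & truth == 1L),
    fp = sum(pred == 1L & truth == 0L),
    tn = sum(pred == 0L & truth == 0L),
    fn = sum(pred == 0L & truth == 1L)
  )
  if (!is.null(zones)) {
    zs <- unique(zones[!is.na(zones)])
    out$tp_by_zone <- vapply(
      zs, function(z) sum(pred == 1L & truth == 1L & zones == z, na.rm = TRUE),
      integer(1)
    )
    out$fp_by_zone <- vapply(
      zs, function(z) sum(pred == 1L & truth == 0L & zones == z, na.rm = TRUE),
      integer(1)
    )
  }
  structure(out, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d  FP %d  TN %d  FN %d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' True- and false-positive rates
#'
#' `TPR = TP / (TP + FN)`, `FPR = FP / (FP + TN)`. A zero denominator gives
#' a 0 rate with the corresponding flag set.
#'
#' @param c A `confusion_counts`.
#' @return List with `tpr`, `fpr`, `tpr_defined`, `fpr_defined`.
#' @export
rates <- function(c) {
  pos <- c$tp + c$fn
  neg <- c$fp + c$tn
  list(
    tpr = if (pos > 0) c$tp / pos else 0,
    fpr = if (neg > 0) c$fp / neg else 0,
    tpr_defined = pos > 0,
    fpr_defined = neg > 0
  )
}

#' ROC curve of a feature series
#'
#' Sweeps the cutoff over every distinct feature value (descending for
#' `high_is_positive`), each cutoff classifying by the strict rule of
#' [detect()], plus sentinels pinning the endpoints `(0, 0)` and `(1, 1)`.
#' Tied feature values share one operating point.
#'
#' @inheritParams threshold_value
#' @param truth 0/1 truth with at least one positive and one negative.
#' @return Object of class `roc_curve`: `thresholds`, `tpr`, `fpr`,
#'   `polarity`.
#' @export
roc_curve <- function(features, truth,
                      polarity = c("high_is_positive", "low_is_positive")) {
  polarity <- match.arg(polarity)
  v <- if (inherits(features, "feature_series")) features$values else
    as.numeric(features)
  truth <- as.integer(truth)
  p <- sum(truth == 1L)
  n <- sum(truth == 0L)
  if (p == 0L || n == 0L) {
    stop("truth must contain both classes", call. = FALSE)
  }
  if (polarity == "high_is_positive") {
    cuts <- c(Inf, sort(unique(v), decreasing = TRUE), min(v) - 1)
    pred_at <- function(cut) v > cut
  } else {
    cuts <- c(-Inf, sort(unique(v)), max(v) + 1)
    pred_at <- function(cut) v < cut
  }
  tpr <- fpr <- numeric(length(cuts))
  for (k in seq_along(cuts)) {
    pred <- pred_at(cuts[k])
    tpr[k] <- sum(pred & truth == 1L) / p
    fpr[k] <- sum(pred & truth == 0L) / n
  }
  structure(
    list(thresholds = cuts, tpr = tpr, fpr = fpr, polarity = polarity),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d operating points, AUC %.4f\n",
              length(x$tpr), auc(x)))
  invisible(x)
}

#' Area under an ROC curve
#'
#' Trapezoidal integration of TPR over FPR.
#'
#' @param roc A [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]
  y <- roc$tpr[o]
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Detection metric battery
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and their harmonic mean F1, each as a proportion in
#' `[0, 1]`; a zero denominator gives 0 with a flag. Use [as_percent()] for
#' the 2-decimal percent formatting of reports.
#'
#' @param c A `confusion_counts`.
#' @param auc Optional AUC to carry along in the report.
#' @return Object of class `metric_report`.
#' @export
metrics <- function(c, auc = NA_real_) {
  total <- c$tp + c$tn + c$fp + c$fn
  prec_den <- c$tp + c$fp
  rec_den <- c$tp + c$fn
  precision <- if (prec_den > 0) c$tp / prec_den else 0
  recall <- if (rec_den > 0) c$tp / rec_den else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(
    list(
      accuracy = if (total > 0) (c$tp + c$tn) / total else 0,
      precision = precision, recall = recall, f1 = f1, auc = auc,
      precision_defined = prec_den > 0, recall_defined = rec_den > 0
    ),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> accuracy %s  precision %s  recall %s  F1 %s  AUC %s\n",
    as_percent(x$accuracy), as_percent(x$precision), as_percent(x$recall),
    as_percent(x$f1),
    if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc)
  ))
  invisible(x)
}

#' Percent formatting with half-up rounding
#'
#' Formats a proportion as a percentage rounded half-up to `digits`
#' decimals (the convention of printed detection tables, where e.g.
#' 148/175 = 0.845714... prints as 84.57).
#'
#' @param x Proportion(s) in `[0, 1]`.
#' @param digits Decimal places.
#' @return Character vector like `"84.57%"`.
#' @export
as_percent <- function(x, digits = 2) {
  scale <- 10^digits
  v <- floor(x * 100 * scale + 0.5) / scale
  sprintf(paste0("%.", digits, "f%%"), v)
}
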