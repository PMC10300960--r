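#' End-to-end call detection on a recording
#'
#' Runs the five-stage detection pipeline: (1) segment the recording into
#' fixed windows; (2) EMD each segment; (3) select the competent IMF by
#' average energy ratio and derive its main frequency band/domain from the
#' averaged marginal spectrum; (4) compute the requested detector features;
#' (5) threshold each feature and, when ground truth is available, evaluate
#' with confusion counts, ROC and the metric battery.
#'
#' @param rec A [recording()] or a `labeled_recording` (labels then default
#'   from it).
#' @param labels Optional 0/1 truth per segment (with optional `zone`
#'   attribute).
#' @param window_ms Segment length, ms.
#' @param imf `"auto"` (use the top CIMF) or a 1-based IMF index.
#' @param algorithms Detectors to run, subset of
#'   `c("erd", "esd", "esed", "cesed")`.
#' @param band_threshold Percent threshold defining the main band/domain on
#'   the averaged marginal spectrum.
#' @param esed_range `"full"` band or main `"domain"` for the ESED feature.
#' @param threshold_method Passed to [threshold_value()]; `roc_optimal`
#'   requires labels.
#' @param M Deviation factor for `median_plus_M_dev`.
#' @param polarity Detection polarity: `"high_is_positive"`,
#'   `"low_is_positive"`, or `"auto"` (needs labels) which chooses, per
#'   feature, the direction that separates the labeled classes (raw AUC
#'   >= 0.5) and records it in the result. Entropy features are not assumed
#'   to point either way a priori.
#' @param emd An [emd_config()].
#' @param keep_decompositions Keep the per-segment decompositions in the
#'   result (memory-heavy; default FALSE).
#' @return Object of class `detection_run`: segment metadata, `avg_ratios`,
#'   `cimf`, `band` (a [band_summary()]), `features`, `thresholds`,
#'   `detections`, and (with labels) `confusion`, `rates`, `roc`, `metrics`
#'   per algorithm.
#' @examples
#' \donttest{
#' lr <- synth_generate(synth_config(total_duration = 20, seed = 2))
#' run <- detect_calls(lr)
#' run$metrics$cesed
#' }
#' @export
detect_calls <- function(rec, labels = NULL, window_ms = 200,
                         imf = "auto",
                         algorithms = c("erd", "esd", "esed", "cesed"),
                         band_threshold = 0.3,
                         esed_range = c("full", "domain"),
                         threshold_method = "roc_optimal", M = 1,
                         polarity = "high_is_positive",
                         emd = emd_config(),
                         keep_decompositions = FALSE) {
  esed_range <- match.arg(esed_range)
  if (inherits(rec, "labeled_recording")) {
    if (is.null(labels)) labels <- rec$labels
    rec <- rec$recording
  }
  segs <- segment_recording(rec, window_ms)
  if (!is.null(labels) && length(labels) != length(segs)) {
    stop("labels length (", length(labels), ") != segment count (",
         length(segs), ")", call. = FALSE)
  }
  zones <- if (!is.null(labels)) attr(labels, "zone") else NULL

  decs <- lapply(segs, emd_decompose, config = emd)
  avg_ratios <- average_energy_ratios(decs)
  cimf <- if (identical(imf, "auto")) select_cimf(avg_ratios, 1L) else
    as.integer(imf)
  if (cimf > length(avg_ratios)) {
    stop("requested IMF index ", cimf, " exceeds the deepest decomposition",
         call. = FALSE)
  }

  marg <- segment_marginals(decs, cimf)
  band <- band_summary(average_marginal(marg), band_threshold)
  domain <- if (band$empty) c(1, floor(rec$fs / 2)) else band$main_domain

  features <- feature_table(decs, cimf, algorithms, main_domain = domain,
                            esed_range = esed_range)

  if (identical(polarity, "auto") && is.null(labels)) {
    stop("polarity = \"auto\" needs ground-truth labels", call. = FALSE)
  }
  thresholds <- detections <- conf <- rts <- rocs <- mets <- list()
  polarities <- list()
  for (a in names(features)) {
    pol <- if (identical(polarity, "auto")) {
      raw <- auc(roc_curve(features[[a]], labels, "high_is_positive"))
      if (raw >= 0.5) "high_is_positive" else "low_is_positive"
    } else polarity
    polarities[[a]] <- pol
    thresholds[[a]] <- threshold_value(features[[a]],
                                       method = threshold_method, M = M,
                                       labels = labels, polarity = pol)
    detections[[a]] <- detect(features[[a]], thresholds[[a]], pol)
    if (!is.null(labels)) {
      conf[[a]] <- confusion(detections[[a]], labels, zones)
      rts[[a]] <- rates(conf[[a]])
      rocs[[a]] <- roc_curve(features[[a]], labels, pol)
      mets[[a]] <- metrics(conf[[a]], auc = auc(rocs[[a]]))
    }
  }

  structure(
    list(
      n_segments = length(segs),
      start_times = vapply(segs, function(s) s$start_time, numeric(1)),
      imf_counts = table(vapply(decs, function(d) d$n_imfs, integer(1))),
      avg_ratios = avg_ratios, cimf = cimf, band = band, domain = domain,
      features = features, polarity = polarities,
      thresholds = thresholds,
      detections = detections,
      labels = labels,
      confusion = if (length(conf)) conf else NULL,
      rates = if (length(rts)) rts else NULL,
      roc = if (length(rocs)) rocs else NULL,
      metrics = if (length(mets)) mets else NULL,
      decompositions = if (keep_decompositions) decs else NULL
    ),
    class = "detection_run"
  )
}

#' @export
print.detection_run <- function(x, ...) {
  cat(sprintf("<detection_run> %d segments, CIMF %d, domain %g~%g Hz\n",
              x$n_segments, x$cimf, x$domain[1], x$domain[2]))
  show <- x$avg_ratios[seq_len(max(which(x$avg_ratios >= 0.005), 1L))]
  cat("  avg IMF energy ratios (%):",
      paste(sprintf("%.2f", show), collapse = " "),
      if (length(show) < length(x$avg_ratios)) "...", "\n")
  for (a in names(x$features)) {
    if (!is.null(x$metrics)) {
      m <- x$metrics[[a]]
      cat(sprintf(
        "  %-5s threshold %8.4g  AUC %.4f  acc %s  prec %s  rec %s  F1 %s\n",
        toupper(a), x$thresholds[[a]], m$auc, as_percent(m$accuracy),
        as_percent(m$precision), as_percent(m$recall), as_percent(m$f1)
      ))
    } else {
      cat(sprintf("  %-5s threshold %8.4g  detections %d\n", toupper(a),
                  x$thresholds[[a]], sum(x$detections[[a]])))
    }
  }
  invisible(x)
}
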