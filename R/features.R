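#' Energy summary of a decomposition
#'
#' Total signal energy `E_total = sum_i sum_t IMF_i(t)^2 + sum_t rf(t)^2`
#' and the per-component energy ratios `E_IMFi = 100 * sum_t IMF_i(t)^2 /
#' E_total` (the residual reported as its own ratio). Ratios sum to 100.
#'
#' @param dec An `imf_decomposition` from [emd_decompose()].
#' @return Object of class `energy_summary`: `e_total`, `imf_ratio` (vector,
#'   one per IMF, possibly empty), `residual_ratio`, `degenerate` flag (all
#'   ratios 0 when `e_total` is 0).
#' @examples
#' dec <- emd_decompose(sin(2 * pi * 39 * (0:959) / 4800), fs = 4800)
#' energy_summary(dec)$imf_ratio
#' @export
energy_summary <- function(dec) {
  stopifnot(inherits(dec, "imf_decomposition"))
  e_imf <- if (dec$n_imfs > 0) colSums(dec$imfs^2) else numeric(0)
  e_rf <- sum(dec$residual^2)
  e_total <- sum(e_imf) + e_rf
  if (e_total == 0) {
    return(structure(
      list(e_total = 0, imf_ratio = rep(0, dec$n_imfs), residual_ratio = 0,
           degenerate = TRUE),
      class = "energy_summary"
    ))
  }
  structure(
    list(e_total = e_total, imf_ratio = 100 * e_imf / e_total,
         residual_ratio = 100 * e_rf / e_total, degenerate = FALSE),
    class = "energy_summary"
  )
}

#' @export
print.energy_summary <- function(x, ...) {
  cat(sprintf("<energy_summary> E_total %.4g; IMF ratios %%: %s; rf %.2f%%\n",
              x$e_total, paste(sprintf("%.2f", x$imf_ratio), collapse = " "),
              x$residual_ratio))
  invisible(x)
}

#' Average per-index energy ratios over segments
#'
#' Segments may have different numbers of IMFs; a missing index contributes
#' 0 to the mean of that position (the index is simply absent from that
#' segment's decomposition).
#'
#' @param decs List of `imf_decomposition` objects.
#' @return Numeric vector of mean energy ratios (%), one per IMF position.
#' @export
average_energy_ratios <- function(decs) {
  if (length(decs) == 0L) stop("no decompositions given", call. = FALSE)
  nmax <- max(vapply(decs, function(d) d$n_imfs, integer(1)))
  if (nmax == 0L) return(numeric(0))
  acc <- matrix(0, nrow = length(decs), ncol = nmax)
  for (k in seq_along(decs)) {
    r <- energy_summary(decs[[k]])$imf_ratio
    if (length(r)) acc[k, seq_along(r)] <- r
  }
  colMeans(acc)
}

#' Select the competent IMFs (CIMFs)
#'
#' The k IMF positions with the largest average energy ratio over all
#' segments, in descending order of ratio; ties break toward the lower
#' index. These carry the dominant share of signal energy and serve as the
#' analysis channel for the detectors.
#'
#' @param avg_ratios Numeric vector of mean energy ratios (%) per IMF index.
#' @param k Number of competent IMFs to return.
#' @return Integer vector of 1-based IMF indices, length `k`.
#' @examples
#' select_cimf(c(31.92, 25.09, 19.29, 12.14, 6.62, 1.90, 0.21), k = 2)
#' @export
select_cimf <- function(avg_ratios, k = 2L) {
  if (length(avg_ratios) == 0L) stop("empty ratio vector", call. = FALSE)
  if (k > length(avg_ratios)) {
    stop("k exceeds the number of IMF positions", call. = FALSE)
  }
  order(-avg_ratios, seq_along(avg_ratios))[seq_len(k)]
}

# internal: marginal spectra of IMF index i for every segment (zero spectrum
# when a segment lacks that index or has zero energy)
segment_marginals <- function(decs, i, fs = NULL) {
  lapply(decs, function(d) {
    f <- if (!is.null(d$fs)) d$fs else fs
    es <- energy_summary(d)
    if (d$n_imfs < i || es$degenerate) {
      bins <- .bin_grid(f)
      structure(
        list(bins = bins, energy_ratio = numeric(length(bins)),
             imf_index = i, fs = f, n_clamped = 0L),
        class = "marginal_spectrum"
      )
    } else {
      marginal_spectrum(d$imfs[, i], e_total = es$e_total, fs = f,
                        imf_index = i)
    }
  })
}

.new_feature_series <- function(algorithm, imf_index, values, units,
                                flags = rep(FALSE, length(values))) {
  structure(
    list(algorithm = algorithm, imf_index = imf_index,
         values = as.numeric(values), units = units, flags = flags),
    class = "feature_series"
  )
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf(
    "<feature_series> %s (IMF %d), %d segments, units %s, range [%.4g, %.4g]\n",
    x$algorithm, x$imf_index, length(x$values), x$units,
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Energy ratio distribution (ERD)
#'
#' Per-segment energy ratio (%) of a chosen IMF index: the fraction of the
#' segment's total energy carried by that mode. Segments lacking the index
#' get 0 (flagged).
#'
#' @param decs List of `imf_decomposition` objects, one per segment.
#' @param i 1-based IMF index (typically a CIMF).
#' @return A `feature_series` in percent units.
#' @export
feature_erd <- function(decs, i) {
  stopifnot(i >= 1)
  flags <- logical(length(decs))
  vals <- vapply(seq_along(decs), function(k) {
    es <- energy_summary(decs[[k]])
    if (decs[[k]]$n_imfs < i || es$degenerate) {
      flags[k] <<- TRUE
      0
    } else {
      es$imf_ratio[i]
    }
  }, numeric(1))
  .new_feature_series("ERD", i, vals, "%", flags)
}

#' Energy spectrum distribution (ESD)
#'
#' Per-segment maximum of the IMF's marginal frequency distribution (%)
#' within the main frequency domain: the height of the strongest 1-Hz energy
#' concentration.
#'
#' @inheritParams feature_erd
#' @param main_domain Length-2 numeric `(f1, f2)` in Hz, within `(0, fs/2]`.
#' @param marginals Optional precomputed result of the per-segment marginal
#'   spectra (reused by the pipeline to avoid recomputation).
#' @return A `feature_series` in percent units.
#' @export
feature_esd <- function(decs, i, main_domain,
                        marginals = segment_marginals(decs, i)) {
  if (main_domain[1] >= main_domain[2]) {
    stop("empty main domain", call. = FALSE)
  }
  vals <- vapply(marginals, function(m) {
    keep <- m$bins >= main_domain[1] & m$bins <= main_domain[2]
    if (!any(keep)) 0 else max(m$energy_ratio[keep])
  }, numeric(1))
  .new_feature_series("ESD", i, vals, "%")
}

# -sum(p log p) with 0 log 0 := 0, natural log (nats)
.shannon <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0L) return(0)
  -sum(p * log(p))
}

#' Energy spectrum entropy distribution (ESED)
#'
#' Shannon entropy (nats) of the IMF's marginal energy distribution over a
#' frequency range, with each bin's probability defined as `P_j = E_j /
#' E_total` — normalized by the segment's *total* energy, not by the energy
#' inside the range. The probabilities therefore need not sum to 1; the
#' formula is applied literally (this deviation is precisely what motivates
#' the concentrated variant, [feature_cesed()]).
#'
#' @inheritParams feature_esd
#' @param freq_range Length-2 `(m, n)` Hz; default the full band
#'   `(1, fs/2)`. A restricted range gives the main-domain entropy variant.
#' @return A `feature_series` in nats; zero-energy segments give 0, flagged.
#' @export
feature_esed <- function(decs, i, freq_range = NULL,
                         marginals = segment_marginals(decs, i)) {
  if (is.null(freq_range)) {
    fs <- marginals[[1L]]$fs
    freq_range <- c(1, floor(fs / 2))
  }
  if (freq_range[1] >= freq_range[2]) stop("empty freq_range", call. = FALSE)
  flags <- vapply(marginals, function(m) sum(m$energy_ratio) == 0,
                  logical(1))
  vals <- vapply(marginals, function(m) {
    keep <- m$bins >= freq_range[1] & m$bins <= freq_range[2]
    .shannon(m$energy_ratio[keep] / 100)
  }, numeric(1))
  .new_feature_series("ESED", i, vals, "nats", flags)
}

#' Concentrated energy spectrum entropy distribution (CESED)
#'
#' Shannon entropy (nats) of the min-max rescaled marginal energy
#' distribution restricted to the main frequency domain `(a, b)`: bin
#' energies are scaled to `S_j = (E_j - min E) / (max E - min E)` and then
#' normalized to a probability vector `P_j = S_j / sum S`. The rescaling
#' makes the feature invariant to the gain and offset of the in-domain
#' energies, so it measures the *shape* of the energy concentration rather
#' than its magnitude.
#'
#' A flat (or empty) in-domain spectrum, where `max E = min E`, carries no
#' shape information; the feature is defined as 0 and flagged.
#'
#' @inheritParams feature_esd
#' @param main_domain Length-2 `(a, b)` Hz.
#' @return A `feature_series` in nats.
#' @export
feature_cesed <- function(decs, i, main_domain,
                          marginals = segment_marginals(decs, i)) {
  if (main_domain[1] >= main_domain[2]) {
    stop("empty main domain", call. = FALSE)
  }
  flags <- logical(length(marginals))
  vals <- vapply(seq_along(marginals), function(k) {
    m <- marginals[[k]]
    keep <- m$bins >= main_domain[1] & m$bins <= main_domain[2]
    e <- m$energy_ratio[keep]
    if (length(e) == 0L || max(e) == min(e)) {
      flags[k] <<- TRUE
      return(0)
    }
    s <- (e - min(e)) / (max(e) - min(e))
    .shannon(s / sum(s))
  }, numeric(1))
  .new_feature_series("CESED", i, vals, "nats", flags)
}

#' Feature table for one or more detectors
#'
#' Convenience wrapper computing any subset of the four detector features on
#' a shared set of decompositions, reusing one marginal-spectrum pass.
#'
#' @param decs List of `imf_decomposition` objects.
#' @param i IMF index to analyze.
#' @param algorithms Character subset of `c("erd", "esd", "esed", "cesed")`.
#' @param main_domain `(a, b)` Hz for ESD/CESED (and ESED when
#'   `esed_range = "domain"`).
#' @param esed_range `"full"` (default) or `"domain"`.
#' @return Named list of `feature_series`.
#' @export
feature_table <- function(decs, i,
                          algorithms = c("erd", "esd", "esed", "cesed"),
                          main_domain, esed_range = c("full", "domain")) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  esed_range <- match.arg(esed_range)
  need_marg <- any(algorithms %in% c("esd", "esed", "cesed"))
  marg <- if (need_marg) segment_marginals(decs, i) else NULL
  out <- list()
  for (a in algorithms) {
    out[[a]] <- switch(a,
      erd = feature_erd(decs, i),
      esd = feature_esd(decs, i, main_domain, marginals = marg),
      esed = feature_esed(
        decs, i,
        freq_range = if (esed_range == "domain") main_domain else NULL,
        marginals = marg
      ),
      cesed = feature_cesed(decs, i, main_domain, marginals = marg)
    )
  }
  out
}

#' Write feature series to CSV
#'
#' Long-format table with columns `segment`, `start_s`, `algorithm`, `imf`,
#' `value`.
#'
#' @param features Named list of `feature_series` (as from
#'   [feature_table()]).
#' @param path Output path.
#' @param start_times Optional vector of segment start times (s).
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, start_times = NULL) {
  rows <- do.call(rbind, lapply(features, function(f) {
    n <- length(f$values)
    data.frame(
      segment = seq_len(n) - 1L,
      start_s = if (is.null(start_times)) NA_real_ else start_times,
      algorithm = f$algorithm,
      imf = f$imf_index,
      value = f$values
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature CSV back into feature series
#'
#' @param path Path written by [write_features()].
#' @return Named list of `feature_series` (names lowercase algorithm).
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path)
  need <- c("segment", "algorithm", "imf", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("feature CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (a in unique(df$algorithm)) {
    sub <- df[df$algorithm == a, ]
    sub <- sub[order(sub$segment), ]
    units <- if (a %in% c("ERD", "ESD")) "%" else "nats"
    out[[tolower(a)]] <- .new_feature_series(a, sub$imf[1L], sub$value,
                                             units)
  }
  out
}
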