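# Independent oracles and small fixture builders shared across the suite.

make_tone <- function(freq, dur_s = 0.2, fs = 4800, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (seq_len(round(fs * dur_s)) - 1) / fs + phase)
}

make_chirp <- function(f0, f1, dur_s = 0.2, fs = 4800) {
  t <- (seq_len(round(fs * dur_s)) - 1) / fs
  sin(2 * pi * (f0 * t + (f1 - f0) / (2 * dur_s) * t^2))
}

# Mann-Whitney formulation of the AUC: concordant pairs plus half ties over
# all positive/negative pairs.
mw_auc <- function(values, truth, polarity = "high_is_positive") {
  pos <- values[truth == 1]
  neg <- values[truth == 0]
  if (polarity == "low_is_positive") {
    pos <- -pos
    neg <- -neg
  }
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  sum(cmp) / (length(pos) * length(neg))
}

# Exhaustive midpoint search for the ROC-optimal operating point: every
# midpoint between adjacent distinct values, plus sentinels admitting all or
# none, scored by distance to (0, 1).
brute_optimal_point <- function(values, truth, polarity = "high_is_positive") {
  v <- sort(unique(values))
  cand <- c(v[1] - 1, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2,
            v[length(v)] + 1)
  p <- sum(truth == 1)
  n <- sum(truth == 0)
  best <- list(d = Inf, tpr = NA, fpr = NA)
  for (cut in cand) {
    pred <- if (polarity == "high_is_positive") values > cut else
      values < cut
    tpr <- sum(pred & truth == 1) / p
    fpr <- sum(pred & truth == 0) / n
    d <- sqrt(fpr^2 + (1 - tpr)^2)
    if (d < best$d - 1e-12) best <- list(d = d, tpr = tpr, fpr = fpr)
  }
  best
}

# synthetic marginal_spectrum with prescribed bin energies (percent of a
# notional total); bins 0..nyq
fake_marginal <- function(energies_pct, fs = 4800, imf_index = 1L) {
  bins <- 0:floor(fs / 2)
  e <- numeric(length(bins))
  e[seq_along(energies_pct)] <- energies_pct # energies_pct[1] lands in bin 0
  structure(
    list(bins = bins, energy_ratio = e, imf_index = imf_index, fs = fs,
         n_clamped = 0L),
    class = "marginal_spectrum"
  )
}

# place energies at explicit bin frequencies
fake_marginal_at <- function(freqs, energies_pct, fs = 4800,
                             imf_index = 1L) {
  bins <- 0:floor(fs / 2)
  e <- numeric(length(bins))
  e[freqs + 1L] <- energies_pct
  structure(
    list(bins = bins, energy_ratio = e, imf_index = imf_index, fs = fs,
         n_clamped = 0L),
    class = "marginal_spectrum"
  )
}

entropy_direct <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# tiny low-noise two-zone config for fast end-to-end tests
small_synth <- function(seed = 1L, dur = 20, noise_sd = 0.2) {
  synth_config(
    total_duration = dur,
    zones = list(
      list(name = "A", start = 0, end = dur / 2, freq = 39, bandwidth = 4,
           on_fraction = 0.4, amplitude = 1),
      list(name = "B", start = dur / 2, end = dur, freq = 13, bandwidth = 4,
           on_fraction = 0.4, amplitude = 1)
    ),
    noise_sd = noise_sd, seed = seed
  )
}
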