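# Analytic signal by the FFT one-sided-spectrum method: zero the negative
# frequencies, double the positive ones, keep DC (and Nyquist for even n).
.analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  w <- numeric(n)
  if (n %% 2L == 0L) {
    w[1L] <- 1
    w[n / 2L + 1L] <- 1
    w[2:(n / 2L)] <- 2
  } else {
    w[1L] <- 1
    w[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * w, inverse = TRUE) / n
}

#' Analytic series of an intrinsic mode function
#'
#' Forms the analytic signal `IMF(t) + j·HT[IMF(t)] = A(t)·exp(j·theta(t))`
#' via the Hilbert transform, unwraps the phase, and differentiates it to the
#' instantaneous frequency `F(t) = (1/2pi)·d theta/dt` (central differences;
#' one-sided at the ends). Negative instantaneous frequencies — a known
#' artifact of phase differentiation on weak or wide-band modes — are clamped
#' to 0 and counted in `n_clamped`.
#'
#' An all-zero input returns zero amplitude and zero frequency with
#' `degenerate = TRUE`.
#'
#' @param imf Numeric amplitude series (length >= 8).
#' @param fs Sampling frequency, Hz.
#' @return An object of class `analytic_series`: `amplitude`, `phase`
#'   (unwrapped radians), `inst_freq` (Hz), `n_clamped`, `degenerate`, `fs`.
#' @examples
#' a <- analytic_series(sin(2 * pi * 39 * (0:959) / 4800), fs = 4800)
#' stats::median(a$inst_freq)
#' @export
analytic_series <- function(imf, fs) {
  imf <- as.numeric(imf)
  n <- length(imf)
  if (n < 8L) stop("series too short (need >= 8 samples)", call. = FALSE)
  if (all(imf == imf[1L])) { # constant (incl. all-zero): no oscillation
    return(structure(
      list(amplitude = rep(abs(imf[1L]), n), phase = numeric(n),
           inst_freq = numeric(n), n_clamped = 0L, degenerate = TRUE,
           fs = fs),
      class = "analytic_series"
    ))
  }
  z <- .analytic_signal(imf)
  amp <- Mod(z)
  ph <- signal::unwrap(Arg(z))
  f <- numeric(n)
  f[2:(n - 1L)] <- (ph[3:n] - ph[1:(n - 2L)]) * fs / (4 * pi)
  f[1L] <- (ph[2L] - ph[1L]) * fs / (2 * pi)
  f[n] <- (ph[n] - ph[n - 1L]) * fs / (2 * pi)
  neg <- f < 0
  f[neg] <- 0
  structure(
    list(amplitude = amp, phase = ph, inst_freq = f,
         n_clamped = sum(neg), degenerate = FALSE, fs = fs),
    class = "analytic_series"
  )
}

#' @export
print.analytic_series <- function(x, ...) {
  cat(sprintf(
    "<analytic_series> %d samples @ %g Hz, median IF %.2f Hz (%d clamped)\n",
    length(x$amplitude), x$fs, stats::median(x$inst_freq), x$n_clamped
  ))
  invisible(x)
}

# shared bin grid: integer 1-Hz bins 0..floor(fs/2); bin 0 collects samples
# whose instantaneous frequency is clamped/undefined (< 0.5 Hz)
.bin_grid <- function(fs) 0:floor(fs / 2)

#' Marginal frequency distribution of an IMF
#'
#' Distributes each sample's squared amplitude `IMF(t)^2` into the 1-Hz
#' frequency bin containing its instantaneous frequency, then divides by the
#' segment's total energy `E_total` and scales to percent. Summed over bins
#' this equals the IMF's energy ratio, so energy mass is conserved exactly.
#'
#' Bins are integers `0..floor(fs/2)`; bin 0 holds clamped or sub-0.5 Hz
#' frequencies and is excluded from band logic downstream.
#'
#' @param imf Numeric amplitude series of one IMF.
#' @param analytic Its [analytic_series()]; computed when omitted.
#' @param e_total Total segment energy (> 0), see [energy_summary()].
#' @param fs Sampling frequency, Hz.
#' @param imf_index Optional 1-based index tag.
#' @return Object of class `marginal_spectrum`: `bins` (Hz), `energy_ratio`
#'   (% of `e_total` per bin), `imf_index`, `fs`, `n_clamped`.
#' @export
marginal_spectrum <- function(imf, analytic = NULL, e_total, fs,
                              imf_index = NA_integer_) {
  if (e_total <= 0) stop("`e_total` must be positive", call. = FALSE)
  imf <- as.numeric(imf)
  if (is.null(analytic)) analytic <- analytic_series(imf, fs)
  bins <- .bin_grid(fs)
  nb <- length(bins)
  idx <- pmin(pmax(round(analytic$inst_freq), 0), bins[nb]) + 1L
  idx[!is.finite(idx)] <- 1L
  e <- numeric(nb)
  acc <- tapply(imf^2, idx, sum)
  e[as.integer(names(acc))] <- acc
  structure(
    list(bins = bins, energy_ratio = 100 * e / e_total,
         imf_index = imf_index, fs = fs, n_clamped = analytic$n_clamped),
    class = "marginal_spectrum"
  )
}

#' @export
print.marginal_spectrum <- function(x, ...) {
  tot <- sum(x$energy_ratio)
  pk <- x$bins[which.max(x$energy_ratio)]
  cat(sprintf(
    "<marginal_spectrum> IMF %s: %.2f%% of segment energy, peak bin %d Hz\n",
    as.character(x$imf_index), tot, pk
  ))
  invisible(x)
}

#' Average several marginal spectra
#'
#' Element-wise arithmetic mean of the per-bin energy ratios, e.g. the
#' average distribution of one IMF index over all sampled signals of a
#' recording.
#'
#' @param spectra List of [marginal_spectrum()] objects on identical bins.
#' @return A `marginal_spectrum` of the means.
#' @export
average_marginal <- function(spectra) {
  if (length(spectra) == 0L) stop("no spectra to average", call. = FALSE)
  b <- spectra[[1L]]$bins
  for (s in spectra) {
    if (length(s$bins) != length(b) || any(s$bins != b)) {
      stop("bin grids differ between spectra", call. = FALSE)
    }
  }
  m <- rowMeans(vapply(spectra, function(s) s$energy_ratio,
                       numeric(length(b))))
  out <- spectra[[1L]]
  out$energy_ratio <- m
  out$n_clamped <- NA_integer_
  out
}

#' Main band and main frequency domain of an averaged spectrum
#'
#' The peak frequency is the bin with the highest energy ratio (ties go to
#' the lowest frequency). The main band is the maximal contiguous run of bins
#' at or above `threshold_pct` that contains the peak. The main frequency
#' domain is the smallest range `1..(multiple of 50 Hz)` covering every bin
#' at or above the threshold — the analysis range used by the ESD and CESED
#' features. Bin 0 is ignored.
#'
#' @param avg A [marginal_spectrum()] (typically from [average_marginal()]).
#' @param threshold_pct Threshold on the energy ratio, percent units.
#' @return Object of class `band_summary`: `peak_freq`, `main_band` (lo, hi),
#'   `main_domain` (lo, hi), `threshold`, `empty` flag.
#' @export
band_summary <- function(avg, threshold_pct) {
  keep <- avg$bins >= 1L
  bins <- avg$bins[keep]
  e <- avg$energy_ratio[keep]
  if (length(e) == 0L) stop("spectrum has no bins >= 1 Hz", call. = FALSE)
  peak <- bins[which.max(e)]
  above <- e >= threshold_pct
  if (!any(above)) {
    return(structure(
      list(peak_freq = peak, main_band = c(NA_real_, NA_real_),
           main_domain = c(NA_real_, NA_real_), threshold = threshold_pct,
           empty = TRUE),
      class = "band_summary"
    ))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run <- which(r$values & bins[starts] <= peak & peak <= bins[ends])
  if (length(run) == 0L) { # peak itself below threshold: take nearest run
    run_start <- bins[starts[r$values]]
    run <- which(r$values)[which.min(abs(run_start - peak))]
  }
  band <- c(bins[starts[run[1L]]], bins[ends[run[1L]]])
  hi <- 50 * ceiling(max(bins[above]) / 50)
  structure(
    list(peak_freq = peak, main_band = band, main_domain = c(1, hi),
         threshold = threshold_pct, empty = FALSE),
    class = "band_summary"
  )
}

#' @export
print.band_summary <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("<band_summary> no bins above %.2f%%; peak %d Hz\n",
                x$threshold, x$peak_freq))
  } else {
    cat(sprintf(
      "<band_summary> peak %d Hz, main band %d~%d Hz, main domain %d~%d Hz (threshold %.2f%%)\n",
      x$peak_freq, x$main_band[1], x$main_band[2],
      x$main_domain[1], x$main_domain[2], x$threshold
    ))
  }
  invisible(x)
}

#' Hilbert time-frequency energy spectrum of an IMF
#'
#' The un-summed `(t, f)` energy grid: each sample contributes `IMF(t)^2 /
#' E_total` at its instantaneous-frequency bin. Its frequency marginal equals
#' [marginal_spectrum()] by construction.
#'
#' @inheritParams marginal_spectrum
#' @param time_decimation Keep every k-th sample column (grid rows are
#'   summed into the kept columns), default 1 (none).
#' @return Object of class `tf_energy`: `energy` matrix (bins x time
#'   columns, normalized by `e_total`, percent), `bins`, `times` (s).
#' @export
hilbert_spectrum <- function(imf, analytic = NULL, e_total, fs,
                             time_decimation = 1L) {
  if (e_total <= 0) stop("`e_total` must be positive", call. = FALSE)
  imf <- as.numeric(imf)
  if (is.null(analytic)) analytic <- analytic_series(imf, fs)
  bins <- .bin_grid(fs)
  nb <- length(bins)
  n <- length(imf)
  bi <- pmin(pmax(round(analytic$inst_freq), 0), bins[nb]) + 1L
  bi[!is.finite(bi)] <- 1L
  ti <- ((seq_len(n) - 1L) %/% time_decimation) + 1L
  nt <- max(ti)
  grid <- matrix(0, nrow = nb, ncol = nt)
  vals <- 100 * imf^2 / e_total
  for (k in seq_len(n)) grid[bi[k], ti[k]] <- grid[bi[k], ti[k]] + vals[k]
  structure(
    list(energy = grid, bins = bins,
         times = (unique(ti) - 1L) * time_decimation / fs),
    class = "tf_energy"
  )
}
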