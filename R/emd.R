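#' EMD configuration
#'
#' Stopping rules for the sifting process. Sifting of one mode stops when the
#' Cauchy-type criterion `sum((h_prev - h)^2) / sum(h_prev^2)` drops below
#' `sd_threshold` while the mode also satisfies the intrinsic-mode condition
#' (numbers of extrema and zero crossings differing by at most one), or after
#' `max_sift_iters` iterations. The decomposition stops when the residual is
#' monotonic / has fewer than three extrema, or after `max_imfs` modes.
#'
#' @param max_imfs Maximum number of modes; `Inf` (default) applies the
#'   dyadic bound `floor(log2(n))` for a segment of `n` samples.
#' @param sd_threshold Sifting stop tolerance (> 0), default 0.2.
#' @param max_sift_iters Maximum sift iterations per mode (>= 1).
#' @param boundary Envelope end policy; only `"mirror"` (symmetric extension
#'   of two extrema at each end) is implemented.
#' @param envelope Envelope interpolant through the extrema: `"pchip"`
#'   (default; shape-preserving piecewise-cubic Hermite, immune to spline
#'   overshoot near irregular extrema) or `"natural"` (natural cubic
#'   spline, the textbook choice).
#' @return An object of class `emd_config`.
#' @export
emd_config <- function(max_imfs = Inf, sd_threshold = 0.2,
                       max_sift_iters = 100L, boundary = "mirror",
                       envelope = c("pchip", "natural")) {
  stopifnot(sd_threshold > 0, max_sift_iters >= 1)
  boundary <- match.arg(boundary, "mirror")
  envelope <- match.arg(envelope)
  structure(
    list(max_imfs = max_imfs, sd_threshold = sd_threshold,
         max_sift_iters = as.integer(max_sift_iters), boundary = boundary,
         envelope = envelope),
    class = "emd_config"
  )
}

# Indices of local maxima / minima. Two-sample plateaus count once; longer
# exact ties are vanishingly rare in continuous-valued audio.
.extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(max = integer(0), min = integer(0)))
  d <- diff(x)
  a <- d[-(n - 1L)]
  b <- d[-1L]
  list(
    max = which(a > 0 & b <= 0) + 1L,
    min = which(a < 0 & b >= 0) + 1L
  )
}

.zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

# Mirror extension of extrema beyond both ends (symmetrized about the end
# sample or the outermost extremum, whichever keeps the envelope anchored
# outside the signal support). Returns extended (position, value) knots for
# the upper and lower envelopes.
.mirror_extrema <- function(x, imax, imin, nbsym = 2L) {
  n <- length(x)
  take_head <- function(v, k) v[seq_len(min(length(v), k))]
  take_tail <- function(v, k) v[seq.int(max(1L, length(v) - k + 1L), length(v))]

  # ---- left end
  if (imax[1L] < imin[1L]) {
    if (x[1L] > x[imin[1L]]) {
      lmax <- rev(take_head(imax[-1L], nbsym))
      lmin <- rev(take_head(imin, nbsym))
      lsym <- imax[1L]
    } else {
      lmax <- rev(take_head(imax, nbsym))
      lmin <- c(rev(take_head(imin, nbsym - 1L)), 1L)
      lsym <- 1L
    }
  } else {
    if (x[1L] < x[imax[1L]]) {
      lmax <- rev(take_head(imax, nbsym))
      lmin <- rev(take_head(imin[-1L], nbsym))
      lsym <- imin[1L]
    } else {
      lmax <- c(rev(take_head(imax, nbsym - 1L)), 1L)
      lmin <- rev(take_head(imin, nbsym))
      lsym <- 1L
    }
  }
  if (length(lmax) == 0L) lmax <- imax[1L]
  if (length(lmin) == 0L) lmin <- imin[1L]
  tlmax <- 2L * lsym - lmax
  tlmin <- 2L * lsym - lmin
  if (tlmin[1L] > 1L || tlmax[1L] > 1L) { # extension too short: re-mirror at 1
    if (lsym == imax[1L]) lmax <- rev(take_head(imax, nbsym))
    else lmin <- rev(take_head(imin, nbsym))
    lsym <- 1L
    tlmax <- 2L * lsym - lmax
    tlmin <- 2L * lsym - lmin
  }

  # ---- right end
  nmax <- length(imax); nmin <- length(imin)
  if (imax[nmax] < imin[nmin]) {
    if (x[n] < x[imax[nmax]]) {
      rmax <- rev(take_tail(imax, nbsym))
      rmin <- rev(take_tail(imin[-nmin], nbsym))
      rsym <- imin[nmin]
    } else {
      rmax <- c(n, rev(take_tail(imax, nbsym - 1L)))
      rmin <- rev(take_tail(imin, nbsym))
      rsym <- n
    }
  } else {
    if (x[n] > x[imin[nmin]]) {
      rmax <- rev(take_tail(imax[-nmax], nbsym))
      rmin <- rev(take_tail(imin, nbsym))
      rsym <- imax[nmax]
    } else {
      rmax <- rev(take_tail(imax, nbsym))
      rmin <- c(n, rev(take_tail(imin, nbsym - 1L)))
      rsym <- n
    }
  }
  if (length(rmax) == 0L) rmax <- imax[nmax]
  if (length(rmin) == 0L) rmin <- imin[nmin]
  trmax <- 2L * rsym - rmax
  trmin <- 2L * rsym - rmin
  if (trmin[length(trmin)] < n || trmax[length(trmax)] < n) {
    if (rsym == imax[nmax]) rmax <- rev(take_tail(imax, nbsym))
    else rmin <- rev(take_tail(imin, nbsym))
    rsym <- n
    trmax <- 2L * rsym - rmax
    trmin <- 2L * rsym - rmin
  }

  list(
    tmax = c(tlmax, imax, trmax), vmax = c(x[lmax], x[imax], x[rmax]),
    tmin = c(tlmin, imin, trmin), vmin = c(x[lmin], x[imin], x[rmin])
  )
}

# Mean of the upper and lower envelopes through the (mirror-extended)
# extrema, or NULL when a two-sided envelope cannot be formed.
.envelope_mean <- function(x, envelope = "pchip") {
  ext <- .extrema(x)
  if (length(ext$max) < 1L || length(ext$min) < 1L) return(NULL)
  knots <- .mirror_extrema(x, ext$max, ext$min)
  ou <- order(knots$tmax)
  ol <- order(knots$tmin)
  tu <- knots$tmax[ou]; vu <- knots$vmax[ou]
  tl <- knots$tmin[ol]; vl <- knots$vmin[ol]
  ku <- !duplicated(tu); kl <- !duplicated(tl)
  if (sum(ku) < 2L || sum(kl) < 2L) return(NULL)
  n <- length(x)
  if (envelope == "pchip") {
    up <- signal::pchip(tu[ku], vu[ku], seq_len(n))
    lo <- signal::pchip(tl[kl], vl[kl], seq_len(n))
  } else {
    up <- stats::spline(tu[ku], vu[ku], xout = seq_len(n),
                        method = "natural")$y
    lo <- stats::spline(tl[kl], vl[kl], xout = seq_len(n),
                        method = "natural")$y
  }
  (up + lo) / 2
}

.sift_one_mode <- function(r, config) {
  h <- r
  for (k in seq_len(config$max_sift_iters)) {
    m <- .envelope_mean(h, config$envelope)
    if (is.null(m)) break
    h_new <- h - m
    if (any(!is.finite(h_new))) break # degenerate envelope: keep iterate
    sd_k <- sum(m^2) / sum(h^2)
    h <- h_new
    ext <- .extrema(h)
    n_ext <- length(ext$max) + length(ext$min)
    if (n_ext < 3L) break
    if (sd_k < config$sd_threshold &&
        abs(n_ext - .zero_crossings(h)) <= 1L) {
      break
    }
  }
  h
}

#' Empirical mode decomposition of a sampled signal
#'
#' Decomposes one sampled signal `X(t)` into intrinsic mode functions (IMFs,
#' highest local frequency first) plus a residual, `X(t) = sum_i IMF_i(t) +
#' rf(t)`, by iterative sifting between cubic-spline envelopes of the local
#' extrema. Reconstruction is exact by construction.
#'
#' A constant or all-zero segment yields zero IMFs with the residual equal to
#' the input.
#'
#' @param x A `sampled_signal`, a [recording()], or a numeric vector.
#' @param config An [emd_config()].
#' @param fs Sampling frequency when `x` is a bare vector (stored for
#'   downstream spectral analysis; the decomposition itself is fs-free).
#' @return An object of class `imf_decomposition`: list with `imfs` (a
#'   `length(x)` by `n_imfs` matrix, possibly 0 columns), `residual`, `fs`
#'   and `n_imfs`.
#' @examples
#' x <- sin(2 * pi * 39 * (0:959) / 4800)
#' dec <- emd_decompose(x, fs = 4800)
#' dec$n_imfs
#' @export
emd_decompose <- function(x, config = emd_config(), fs = NULL) {
  if (inherits(x, "sampled_signal") || inherits(x, "recording")) {
    fs <- x$fs
    x <- x$samples
  }
  x <- as.numeric(x)
  if (length(x) < 8L) stop("segment too short for EMD (need >= 8 samples)",
                           call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite samples in segment", call. = FALSE)

  imfs <- list()
  r <- x
  e_x <- sum(x^2)
  # a dyadic filter bank cannot hold more than ~log2(n) genuine modes
  n_cap <- if (is.finite(config$max_imfs)) config$max_imfs else
    floor(log2(length(x)))
  repeat {
    if (length(imfs) >= n_cap) break
    if (sum(r^2) <= 1e-12 * e_x) break # residual is numerically exhausted
    ext <- .extrema(r)
    if (length(ext$max) + length(ext$min) < 3L) break # monotone-ish residual
    imf <- .sift_one_mode(r, config)
    if (all(imf == 0)) break
    imfs[[length(imfs) + 1L]] <- imf
    r <- r - imf
  }
  m <- if (length(imfs)) do.call(cbind, imfs) else
    matrix(numeric(0), nrow = length(x), ncol = 0L)
  structure(
    list(imfs = m, residual = r, fs = fs, n_imfs = ncol(m)),
    class = "imf_decomposition"
  )
}

#' @export
print.imf_decomposition <- function(x, ...) {
  cat(sprintf("<imf_decomposition> %d IMFs + residual, %d samples\n",
              x$n_imfs, length(x$residual)))
  invisible(x)
}

#' Reconstruct the signal from a decomposition
#'
#' Element-wise sum of all IMFs and the residual; inverse of
#' [emd_decompose()] up to floating-point rounding.
#'
#' @param dec An `imf_decomposition`.
#' @return Numeric amplitude series.
#' @export
emd_reconstruct <- function(dec) {
  stopifnot(inherits(dec, "imf_decomposition"))
  if (dec$n_imfs > 0 && nrow(dec$imfs) != length(dec$residual)) {
    stop("component length mismatch in decomposition", call. = FALSE)
  }
  if (dec$n_imfs == 0L) return(dec$residual)
  rowSums(dec$imfs) + dec$residual
}
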