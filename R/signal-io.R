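#' Create a recording object
#'
#' A recording is a mono amplitude series with its sampling frequency. It is
#' the raw material from which fixed-duration sampled signals are cut by
#' [segment_recording()].
#'
#' @param samples Numeric vector of (dimensionless) amplitudes.
#' @param fs Sampling frequency in Hz (> 0).
#' @return An object of class `recording` with elements `samples`, `fs` and
#'   the derived `duration` in seconds.
#' @examples
#' rec <- recording(sin(2 * pi * 39 * seq(0, 1, by = 1 / 4800)), fs = 4800)
#' rec$duration
#' @export
recording <- function(samples, fs) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  samples <- as.numeric(samples)
  structure(
    list(samples = samples, fs = fs, duration = length(samples) / fs),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %d samples @ %g Hz (%.3f s)\n",
    length(x$samples), x$fs, x$duration
  ))
  invisible(x)
}

#' Read a WAV file
#'
#' Reads a RIFF/WAVE file containing PCM (16-, 24- or 32-bit integer) or
#' IEEE-float (32- or 64-bit) audio. Integer PCM samples are scaled to
#' `[-1, 1]` by the full-scale value of the sample width. Multi-channel
#' files are reduced to their first channel with a warning.
#'
#' @param path Path to an existing WAV file.
#' @return A [recording()].
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1L, size = 4, endian = "little") # total size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = .le_uint(body[1:2]),
        n_channels   = .le_uint(body[3:4]),
        fs           = .le_uint(body[5:8]),
        bits         = .le_uint(body[15:16])
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      seek(con, size, origin = "current")
    }
    if (size %% 2L == 1L) seek(con, 1, origin = "current") # pad byte
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("corrupt WAV: no fmt chunk in ", path, call. = FALSE)
  if (is.null(data_raw) || length(data_raw) == 0L) {
    stop("zero-length audio in ", path, call. = FALSE)
  }

  x <- .decode_wav_samples(data_raw, fmt$audio_format, fmt$bits)
  if (fmt$n_channels > 1L) {
    warning("multi-channel WAV: taking first of ", fmt$n_channels, " channels")
    x <- x[seq(1L, length(x), by = fmt$n_channels)]
  }
  recording(x, fs = fmt$fs)
}

# little-endian unsigned integer from raw bytes
.le_uint <- function(bytes) {
  sum(as.numeric(bytes) * 256^(seq_along(bytes) - 1))
}

.decode_wav_samples <- function(raw, audio_format, bits) {
  if (audio_format == 1L) { # integer PCM
    if (bits == 16L) {
      readBin(raw, "integer", length(raw) %/% 2L, size = 2,
              signed = TRUE, endian = "little") / 32768
    } else if (bits == 24L) {
      b <- matrix(as.integer(raw), nrow = 3L)
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      v <- ifelse(v >= 2^23, v - 2^24, v)
      v / 2^23
    } else if (bits == 32L) {
      readBin(raw, "integer", length(raw) %/% 4L, size = 4,
              endian = "little") / 2^31
    } else {
      stop("unsupported PCM bit depth: ", bits, call. = FALSE)
    }
  } else if (audio_format == 3L) { # IEEE float
    if (bits == 32L) {
      readBin(raw, "double", length(raw) %/% 4L, size = 4, endian = "little")
    } else if (bits == 64L) {
      readBin(raw, "double", length(raw) %/% 8L, size = 8, endian = "little")
    } else {
      stop("unsupported float bit depth: ", bits, call. = FALSE)
    }
  } else {
    stop("unsupported WAV audio format code: ", audio_format, call. = FALSE)
  }
}

#' Write a WAV file
#'
#' Writes a mono recording as 16-bit PCM (values clipped to `[-1, 1]` and
#' scaled by 32767) or as IEEE float32 (values written verbatim, the format
#' used by the synthetic generator since its amplitudes are unbounded).
#'
#' @param rec A [recording()] or numeric vector (then `fs` is required).
#' @param path Output path.
#' @param format `"pcm16"` or `"float32"`.
#' @param fs Sampling frequency, only when `rec` is a bare vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, format = c("pcm16", "float32"), fs = NULL) {
  format <- match.arg(format)
  if (!inherits(rec, "recording")) rec <- recording(rec, fs = fs)
  x <- rec$samples
  bits <- if (format == "pcm16") 16L else 32L
  fmt_code <- if (format == "pcm16") 1L else 3L
  bytes_per <- bits %/% 8L
  data_size <- length(x) * bytes_per

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little") # mono
  writeBin(as.integer(rec$fs), con, size = 4, endian = "little")
  writeBin(as.integer(rec$fs * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "pcm16") {
    v <- as.integer(round(pmin(1, pmax(-1, x)) * 32767))
    writeBin(v, con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Cut a recording into fixed-duration sampled signals
#'
#' Produces contiguous, non-overlapping windows of `window_ms` milliseconds —
#' the unit of all downstream analysis (a 100 s recording at 200 ms windows
#' gives 500 sampled signals). Any trailing remainder shorter than one window
#' is dropped.
#'
#' @param rec A [recording()].
#' @param window_ms Window length in milliseconds (> 0).
#' @param start_s Offset into the recording, seconds.
#' @param duration_s Span to segment, seconds; default to the end.
#' @return A list of `sampled_signal` objects, each with `index` (0-based),
#'   `start_time` (s), `samples` and `fs`.
#' @examples
#' rec <- recording(rnorm(4800), fs = 4800)
#' length(segment_recording(rec, 200)) # 5 windows of 960 samples
#' @export
segment_recording <- function(rec, window_ms, start_s = 0,
                              duration_s = NULL) {
  stopifnot(inherits(rec, "recording"))
  if (window_ms <= 0) stop("`window_ms` must be positive", call. = FALSE)
  if (is.null(duration_s)) duration_s <- rec$duration - start_s
  if (start_s + duration_s > rec$duration + 1e-9) {
    stop("requested span exceeds recording duration", call. = FALSE)
  }
  if (window_ms / 1000 > duration_s) {
    stop("window longer than the requested span", call. = FALSE)
  }
  win_n <- round(rec$fs * window_ms / 1000)
  n_seg <- floor(duration_s * 1000 / window_ms)
  start_i <- round(start_s * rec$fs)
  lapply(seq_len(n_seg) - 1L, function(k) {
    i0 <- start_i + k * win_n
    structure(
      list(
        index = k,
        start_time = start_s + k * window_ms / 1000,
        samples = rec$samples[(i0 + 1L):(i0 + win_n)],
        fs = rec$fs
      ),
      class = "sampled_signal"
    )
  })
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf(
    "<sampled_signal> #%d at %.3f s: %d samples @ %g Hz\n",
    x$index, x$start_time, length(x$samples), x$fs
  ))
  invisible(x)
}
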