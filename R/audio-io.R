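#' Audio signal container
#'
#' Light-weight container for a mono, full-scale-normalized audio signal.
#' The coding-strategy front end expects signals at 16 kHz; [load_audio()]
#' produces them in that form from arbitrary WAV input.
#'
#' @param samples numeric vector of samples, nominally in \[-1, 1\].
#' @param sample_rate_hz positive integer sampling rate in Hz.
#' @return An object of class `audio_signal`: a list with elements
#'   `samples` and `sample_rate_hz`.
#' @export
audio_signal <- function(samples, sample_rate_hz) {
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (any(!is.finite(samples))) stop("samples must be finite")
  sample_rate_hz <- as.integer(sample_rate_hz)
  if (length(sample_rate_hz) != 1L || is.na(sample_rate_hz) || sample_rate_hz <= 0L)
    stop("sample_rate_hz must be a positive integer")
  structure(list(samples = as.numeric(samples), sample_rate_hz = sample_rate_hz),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  n <- length(x$samples)
  cat(sprintf("<audio_signal: %d samples @ %d Hz (%.3f s), peak %.3f>\n",
              n, x$sample_rate_hz, n / x$sample_rate_hz,
              if (n) max(abs(x$samples)) else 0))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

# ---- WAV file I/O -----------------------------------------------------------
# Minimal RIFF/WAVE reader and writer (PCM 16/24-bit and IEEE float32).
# Written in base R over readBin/writeBin; no audio package is available.

#' Read a WAV file
#'
#' Supports PCM 16-bit, PCM 24-bit and IEEE float (32-bit) encodings,
#' mono or multichannel.  Samples are returned as a channels-by-frames
#' numeric matrix scaled to \[-1, 1\].
#'
#' @param path path to a WAV file.
#' @return list with `samples` (matrix, channels x frames) and
#'   `sample_rate_hz`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("cannot read WAV file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        code        = sum(as.integer(fmt_raw[1:2]) * c(1L, 256L)),
        channels    = sum(as.integer(fmt_raw[3:4]) * c(1L, 256L)),
        sample_rate = sum(as.integer(fmt_raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits        = sum(as.integer(fmt_raw[15:16]) * c(1L, 256L))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + (sz %% 2L)))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("WAV file has no fmt chunk: ", path)
  if (is.null(data_raw) || length(data_raw) == 0L)
    stop("WAV file has no audio data: ", path)

  nch <- fmt$channels
  x <- switch(
    as.character(fmt$code),
    "1" = {  # integer PCM
      if (fmt$bits == 16L) {
        readBin(data_raw, "integer", length(data_raw) %/% 2L, size = 2L,
                signed = TRUE, endian = "little") / 32768
      } else if (fmt$bits == 24L) {
        n <- length(data_raw) %/% 3L
        b <- matrix(as.integer(data_raw[seq_len(3L * n)]), nrow = 3L)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else stop("unsupported PCM bit depth: ", fmt$bits)
    },
    "3" = readBin(data_raw, "double", length(data_raw) %/% 4L, size = 4L,
                  endian = "little"),
    stop("unsupported WAV format code: ", fmt$code)
  )
  if (length(x) == 0L) stop("WAV file has zero-length audio: ", path)
  nfr <- length(x) %/% nch
  list(samples = matrix(x[seq_len(nfr * nch)], nrow = nch),
       sample_rate_hz = as.integer(fmt$sample_rate))
}

#' Write a WAV file
#'
#' @param samples numeric vector (mono) or channels-by-frames matrix in
#'   \[-1, 1\].
#' @param sample_rate_hz sampling rate in Hz.
#' @param path output path.
#' @param bits 16 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate_hz, path, bits = 16L) {
  if (is.matrix(samples)) {
    nch <- nrow(samples); x <- as.numeric(samples)
  } else {
    nch <- 1L; x <- as.numeric(samples)
  }
  bits <- as.integer(bits)
  if (!bits %in% c(16L, 32L)) stop("bits must be 16 or 32")
  code <- if (bits == 16L) 1L else 3L
  block <- nch * bits %/% 8L
  data_bytes <- length(x) * bits %/% 8L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(code, con, size = 2L, endian = "little")
  writeBin(nch, con, size = 2L, endian = "little")
  writeBin(as.integer(sample_rate_hz), con, size = 4L, endian = "little")
  writeBin(as.integer(sample_rate_hz * block), con, size = 4L, endian = "little")
  writeBin(as.integer(block), con, size = 2L, endian = "little")
  writeBin(bits, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4L, endian = "little")
  if (bits == 16L) {
    writeBin(as.integer(round(pmax(-1, pmin(1, x)) * 32767)), con,
             size = 2L, endian = "little")
  } else {
    writeBin(x, con, size = 4L, endian = "little")
  }
  invisible(path)
}

# ---- Resampling -------------------------------------------------------------

# Kaiser window of length n (symmetric), shape parameter beta.
kaiser_window <- function(n, beta) {
  m <- seq(0, n - 1)
  r <- 2 * m / (n - 1) - 1
  besselI(beta * sqrt(pmax(0, 1 - r^2)), 0) / besselI(beta, 0)
}

#' Band-limited rational resampling
#'
#' Polyphase-style sample-rate conversion: upsample by the rational factor
#' `to_hz/from_hz` using zero stuffing, a Kaiser-windowed sinc low-pass at
#' the narrower of the two Nyquist frequencies, and decimation.  Used by
#' [load_audio()] to bring arbitrary WAV material to the 16 kHz front-end
#' rate.
#'
#' @param x numeric signal.
#' @param from_hz,to_hz input and output sampling rates (Hz).
#' @param taps_per_phase half-width of the sinc kernel per polyphase branch;
#'   larger is sharper.
#' @return numeric vector of length `ceiling(length(x) * to_hz / from_hz)`.
#' @export
resample_audio <- function(x, from_hz, to_hz, taps_per_phase = 12L) {
  from_hz <- as.integer(from_hz); to_hz <- as.integer(to_hz)
  if (from_hz <= 0L || to_hz <= 0L) stop("sampling rates must be positive")
  n <- length(x)
  if (from_hz == to_hz || n == 0L) return(as.numeric(x))
  g <- gcd_int(from_hz, to_hz)
  p <- to_hz %/% g   # upsampling factor
  q <- from_hz %/% g # downsampling factor

  # low-pass at the narrower Nyquist, expressed at the upsampled rate
  f_c <- min(1 / p, 1 / q)          # cycles per upsampled sample, two-sided
  half <- taps_per_phase * max(p, q)
  m <- seq(-half, half)
  h <- f_c * sinc_fn(f_c * m) * kaiser_window(2L * half + 1L, 8.6)
  h <- p * h / sum(h)                # DC gain p compensates the zero stuffing

  up <- numeric(n * p)
  up[seq(1L, by = p, length.out = n)] <- x
  y_full <- conv_fft(up, h)
  delay <- half
  y <- y_full[(delay + 1L):(delay + n * p)]
  out_len <- ceiling(n * p / q)
  y[seq(1L, by = q, length.out = out_len)]
}

sinc_fn <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))

gcd_int <- function(a, b) {
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

# linear convolution via FFT; returns length(x) + length(h) - 1 values
conv_fft <- function(x, h) {
  nx <- length(x); nh <- length(h)
  nfft <- 2^ceiling(log2(nx + nh - 1L))
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - nx))) *
                     stats::fft(c(h, numeric(nfft - nh))), inverse = TRUE)) / nfft
  y[seq_len(nx + nh - 1L)]
}

#' Load audio for the coding-strategy front end
#'
#' Reads a WAV file, averages channels to mono, resamples to 16 kHz with a
#' band-limited polyphase filter and peak-normalizes to 0.99 full scale.
#' All-zero material is passed through without normalization.
#'
#' @param path path to a readable WAV file (PCM 16/24-bit or float).
#' @param target_rate_hz output rate; the strategy operates at 16 kHz.
#' @return An [audio_signal()].
#' @export
load_audio <- function(path, target_rate_hz = 16000L) {
  w <- read_wav(path)
  mono <- if (nrow(w$samples) > 1L) colMeans(w$samples) else as.numeric(w$samples)
  if (length(mono) == 0L) stop("zero-length audio: ", path)
  y <- resample_audio(mono, w$sample_rate_hz, target_rate_hz)
  pk <- max(abs(y))
  if (pk > 0) y <- y * (0.99 / pk)
  audio_signal(y, target_rate_hz)
}
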