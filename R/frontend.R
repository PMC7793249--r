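#' Default 22-channel FFT band allocation
#'
#' Partitions FFT bins 2..63 (0-based, 125 Hz spacing at 16 kHz / 128
#' samples) into 22 contiguous channels with the quasi-logarithmic bin
#' counts used by Nucleus-style filterbanks: single-bin channels at low
#' frequencies widening monotonically to 8 bins at the top, covering
#' roughly 188 Hz to 8 kHz.  DC, bin 1 and the Nyquist bin are excluded.
#'
#' @param num_channels number of channels (the default table is for 22).
#' @param bin_counts integer vector of bins per channel, non-decreasing;
#'   its sum plus `first_bin` must not exceed the number of unique bins.
#' @param first_bin first 0-based FFT bin used.
#' @param sample_rate_hz,frame_length_samples define the bin spacing.
#' @return A `band_table`: data.frame with columns `channel`, `first_bin`,
#'   `last_bin` (0-based FFT bins, inclusive) and `center_hz`.
#' @export
default_band_table <- function(num_channels = 22L,
                               bin_counts = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 2, 2,
                                              2, 2, 3, 3, 4, 4, 5, 5, 6, 7, 8),
                               first_bin = 2L,
                               sample_rate_hz = 16000,
                               frame_length_samples = 128L) {
  stopifnot(length(bin_counts) == num_channels)
  last <- first_bin + cumsum(bin_counts) - 1L
  first <- c(first_bin, utils::head(last, -1L) + 1L)
  binw <- sample_rate_hz / frame_length_samples
  band_table(data.frame(
    channel = seq_len(num_channels),
    first_bin = as.integer(first),
    last_bin = as.integer(last),
    center_hz = binw * (first + last) / 2
  ), frame_length_samples = frame_length_samples)
}

#' Band-table constructor / validator
#'
#' @param df data.frame with columns `channel`, `first_bin`, `last_bin`,
#'   `center_hz`; ranges must be contiguous, non-overlapping and have
#'   non-decreasing widths from low to high channels.
#' @param frame_length_samples FFT length the bin indices refer to.
#' @return the validated `band_table`.
#' @export
band_table <- function(df, frame_length_samples = 128L) {
  need <- c("channel", "first_bin", "last_bin", "center_hz")
  if (!all(need %in% names(df))) stop("band table needs columns: ",
                                      paste(need, collapse = ", "))
  df <- df[order(df$channel), need]
  if (any(df$last_bin < df$first_bin)) stop("empty bin range in band table")
  if (nrow(df) > 1L) {
    if (any(df$first_bin[-1L] != utils::head(df$last_bin, -1L) + 1L))
      stop("band table ranges must be contiguous and non-overlapping")
    w <- df$last_bin - df$first_bin + 1L
    if (any(diff(w) < 0L)) stop("bin counts must be non-decreasing with channel")
  }
  if (df$first_bin[1L] < 0L || df$last_bin[nrow(df)] > frame_length_samples %/% 2L)
    stop("band table bins outside the spectrum")
  structure(df, class = c("band_table", "data.frame"),
            frame_length_samples = as.integer(frame_length_samples))
}

#' Band-table plain-text serialization
#'
#' Four tab-separated columns (`channel`, `first_bin`, `last_bin`,
#' `center_hz`) with `#`-prefixed comments allowed.
#'
#' @param tab a `band_table`.
#' @param path file path.
#' @export
write_band_table <- function(tab, path) {
  stopifnot(inherits(tab, "band_table"))
  lines <- c("# channel\tfirst_bin\tlast_bin\tcenter_hz",
             sprintf("%d\t%d\t%d\t%.6g", tab$channel, tab$first_bin,
                     tab$last_bin, tab$center_hz))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_band_table
#' @export
read_band_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("channel", "first_bin", "last_bin",
                                        "center_hz"))
  band_table(df)
}

#' Short-time spectral analysis
#'
#' Slices the signal into Hann-windowed frames of
#' `config$frame_length_samples` samples advanced by `config$hop_samples`
#' (one frame per stimulation cycle) and transforms each with an FFT.
#' The trailing partial frame is zero-padded; a signal shorter than one
#' frame yields a single zero-padded frame with a warning.
#'
#' @param signal an [audio_signal()] at `config$sample_rate_hz`.
#' @param config a [strategy_config()].
#' @return object of class `spectral_frames`: list with `bins` (complex
#'   matrix, `frame_length/2 + 1` unique bins by frames), `start_time_s`,
#'   `frame_length`, `hop_samples`, `sample_rate_hz`.
#' @export
analyze_frames <- function(signal, config) {
  stopifnot(inherits(signal, "audio_signal"), inherits(config, "strategy_config"))
  if (signal$sample_rate_hz != config$sample_rate_hz)
    stop("signal rate ", signal$sample_rate_hz, " != config rate ",
         config$sample_rate_hz)
  N <- config$frame_length_samples
  hop <- config$hop_samples
  x <- signal$samples
  n <- length(x)
  if (n < N) warning("signal shorter than one analysis frame; zero-padding")
  nframes <- max(1L, as.integer(ceiling(n / hop)))
  starts <- (seq_len(nframes) - 1L) * hop           # 0-based sample offsets
  idx <- outer(seq_len(N), starts, `+`)              # 1-based into padded x
  xp <- c(x, numeric(max(0L, max(idx) - n)))
  frames <- matrix(xp[idx], nrow = N)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(N) - 1L) / N)  # periodic Hann
  spec <- stats::mvfft(frames * w)
  structure(list(
    bins = spec[seq_len(N %/% 2L + 1L), , drop = FALSE],
    start_time_s = starts / config$sample_rate_hz,
    frame_length = N,
    hop_samples = hop,
    sample_rate_hz = config$sample_rate_hz
  ), class = "spectral_frames")
}

#' @export
print.spectral_frames <- function(x, ...) {
  cat(sprintf("<spectral_frames: %d frames x %d bins, hop %d samples @ %d Hz>\n",
              ncol(x$bins), nrow(x$bins), x$hop_samples, x$sample_rate_hz))
  invisible(x)
}

#' Per-channel envelope levels
#'
#' Combines FFT bin energies within each channel's bin range and expresses
#' the result in dB relative to the channel's audibility threshold,
#' clamped at 0 (the inaudible floor).
#'
#' @param frames a `spectral_frames` object from [analyze_frames()], or a
#'   complex matrix/vector of unique FFT bins.
#' @param table a `band_table`.
#' @param thresholds_db audibility floor, scalar or per-channel vector, in
#'   the dB scale of the summed bin energies.
#' @return `envelope_frames`: numeric matrix (channels x frames) of levels
#'   in dB re threshold, with the frame start times as attribute
#'   `start_time_s`.
#' @export
band_envelopes <- function(frames, table, thresholds_db = -40) {
  stopifnot(inherits(table, "band_table"))
  times <- NULL
  if (inherits(frames, "spectral_frames")) {
    times <- frames$start_time_s
    bins <- frames$bins
  } else {
    bins <- frames
  }
  if (!is.matrix(bins)) bins <- matrix(bins, ncol = 1L)
  if (max(table$last_bin) + 1L > nrow(bins))
    stop("band table references bins beyond the spectrum")
  M <- nrow(table)
  thr <- rep_len(thresholds_db, M)
  pow <- Mod(bins)^2
  lev <- matrix(0, nrow = M, ncol = ncol(bins))
  for (z in seq_len(M)) {
    rows <- (table$first_bin[z]:table$last_bin[z]) + 1L  # 0-based bin -> row
    p <- if (length(rows) > 1L) colSums(pow[rows, , drop = FALSE]) else pow[rows, ]
    lev[z, ] <- pmax(0, 10 * log10(pmax(p, .Machine$double.xmin)) - thr[z])
  }
  structure(lev, class = "envelope_frames", start_time_s = times)
}
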