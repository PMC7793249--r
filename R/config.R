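#' Coding-strategy configuration
#'
#' Bundles every framing, filterbank, selection and masking parameter of the
#' strategy.  The defaults reproduce the clinical operating point used
#' throughout: 16 kHz input, 128-sample FFT frames, 22 channels, 5 maxima,
#' 900 pulses per second per channel.  `t_half_ms` is the forward-masking
#' half-life: the time after which a carried-over masking level has fallen to
#' half.  `t_half_ms = 0` disables temporal carry-over entirely (the masking
#' profile is reset every frame), which recovers the simultaneous-masking-only
#' strategy.
#'
#' @param sample_rate_hz input sampling rate (Hz).
#' @param frame_length_samples FFT analysis frame length.
#' @param num_channels number of filterbank channels M.
#' @param num_maxima number of channels selected per frame (n of M).
#' @param channel_rate_pps per-channel stimulation rate; the frame hop is
#'   `round(sample_rate_hz / channel_rate_pps)` samples.
#' @param t_half_ms temporal-masking half-life in milliseconds (>= 0).
#' @param spread_offset_db masker-to-masking-threshold offset a_v (dB): a
#'   masker at level L masks its own channel at L - a_v.
#' @param slope_low_db_per_ch,slope_high_db_per_ch triangular spread slopes
#'   (dB per channel) toward lower and higher channels respectively.
#' @param combine_rule how a new masker is combined into the profile:
#'   `"max"` (elementwise maximum) or `"power-sum"` (power addition in dB).
#' @param audibility_floor_db per-channel audibility threshold in the dB
#'   scale of the FFT band energies; envelopes are stored relative to it so
#'   0 dB means "just inaudible".  Scalar or length-M vector.
#' @return object of class `strategy_config` (a validated list, with the
#'   derived `hop_samples` field).
#' @export
strategy_config <- function(sample_rate_hz = 16000L,
                            frame_length_samples = 128L,
                            num_channels = 22L,
                            num_maxima = 5L,
                            channel_rate_pps = 900,
                            t_half_ms = 0.5,
                            spread_offset_db = 10,
                            slope_low_db_per_ch = 27,
                            slope_high_db_per_ch = 24,
                            combine_rule = c("max", "power-sum"),
                            audibility_floor_db = -40) {
  combine_rule <- match.arg(combine_rule)
  cfg <- list(
    sample_rate_hz = as.integer(sample_rate_hz),
    frame_length_samples = as.integer(frame_length_samples),
    num_channels = as.integer(num_channels),
    num_maxima = as.integer(num_maxima),
    channel_rate_pps = as.numeric(channel_rate_pps),
    t_half_ms = as.numeric(t_half_ms),
    spread_offset_db = as.numeric(spread_offset_db),
    slope_low_db_per_ch = as.numeric(slope_low_db_per_ch),
    slope_high_db_per_ch = as.numeric(slope_high_db_per_ch),
    combine_rule = combine_rule,
    audibility_floor_db = as.numeric(audibility_floor_db)
  )
  cfg$hop_samples <- as.integer(round(cfg$sample_rate_hz / cfg$channel_rate_pps))
  validate_strategy_config(cfg)
  structure(cfg, class = "strategy_config")
}

validate_strategy_config <- function(cfg) {
  with(cfg, {
    if (sample_rate_hz <= 0L) stop("sample_rate_hz must be positive")
    if (frame_length_samples < 2L) stop("frame_length_samples must be >= 2")
    if (num_channels < 1L) stop("num_channels must be >= 1")
    if (num_maxima < 1L || num_maxima > num_channels)
      stop("num_maxima must satisfy 0 < n <= num_channels")
    if (channel_rate_pps <= 0) stop("channel_rate_pps must be positive")
    if (t_half_ms < 0) stop("t_half_ms must be >= 0")
    if (spread_offset_db < 0) stop("spread_offset_db must be >= 0")
    if (slope_low_db_per_ch <= 0 || slope_high_db_per_ch <= 0)
      stop("spread slopes must be positive")
    if (hop_samples < 1L) stop("hop must be at least one sample")
    if (!length(audibility_floor_db) %in% c(1L, num_channels))
      stop("audibility_floor_db must be scalar or length num_channels")
  })
  invisible(cfg)
}

# per-channel floor vector, recycled from a scalar
floor_vector <- function(cfg) {
  rep_len(cfg$audibility_floor_db, cfg$num_channels)
}

# realized frame interval in seconds (hop time, not the nominal 1/rate)
hop_seconds <- function(cfg) cfg$hop_samples / cfg$sample_rate_hz

#' @export
print.strategy_config <- function(x, ...) {
  cat("Coding-strategy configuration\n")
  cat(sprintf("  %d Hz input, %d-sample FFT frames, hop %d samples (%.4g ms)\n",
              x$sample_rate_hz, x$frame_length_samples, x$hop_samples,
              1000 * hop_seconds(x)))
  cat(sprintf("  %d channels, %d maxima, %g pps per channel\n",
              x$num_channels, x$num_maxima, x$channel_rate_pps))
  cat(sprintf("  temporal masking half-life: %g ms%s\n", x$t_half_ms,
              if (x$t_half_ms == 0) " (no carry-over)" else ""))
  cat(sprintf("  spread: offset %g dB, slopes %g/%g dB per channel, combine=%s\n",
              x$spread_offset_db, x$slope_low_db_per_ch, x$slope_high_db_per_ch,
              x$combine_rule))
  cat(sprintf("  audibility floor: %s dB\n",
              paste(format(unique(x$audibility_floor_db)), collapse = "/")))
  invisible(x)
}

#' Write / read a strategy configuration as flat key=value text
#'
#' Round-trips every scalar field; a per-channel audibility floor is stored
#' comma-separated.
#'
#' @param cfg a [strategy_config()].
#' @param path file path.
#' @return `read_strategy_config` returns a `strategy_config`;
#'   `write_strategy_config` returns `path` invisibly.
#' @export
write_strategy_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "strategy_config"))
  keys <- setdiff(names(cfg), "hop_samples")  # derived field
  lines <- vapply(keys, function(k) {
    sprintf("%s=%s", k, paste(format(cfg[[k]], digits = 17), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_strategy_config
#' @export
read_strategy_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad)) stop("malformed config line ", bad[1], ": ", lines[bad[1]])
  vals <- stats::setNames(lapply(kv, function(p) {
    v <- strsplit(p[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (anyNA(num)) v else num
  }), vapply(kv, `[`, character(1), 1L))
  do.call(strategy_config, vals)
}
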