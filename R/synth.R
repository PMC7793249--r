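#' Pure-tone generator
#'
#' Sinusoid at a given RMS level with 10 ms raised-cosine on/off ramps.
#'
#' @param freq_hz tone frequency, 0 < f < Fs/2.
#' @param duration_s duration in seconds (> 0).
#' @param level_db_rms RMS level in dB re full scale (0 dB = RMS 1).
#' @param sample_rate_hz sampling rate.
#' @return an [audio_signal()].
#' @export
make_tone <- function(freq_hz, duration_s, level_db_rms = -20,
                      sample_rate_hz = 16000L) {
  if (duration_s <= 0) stop("duration must be positive")
  if (freq_hz <= 0 || freq_hz >= sample_rate_hz / 2)
    stop("frequency must lie strictly inside (0, Fs/2)")
  n <- round(duration_s * sample_rate_hz)
  amp <- sqrt(2) * 10^(level_db_rms / 20)
  x <- amp * sin(2 * pi * freq_hz * (seq_len(n) - 1L) / sample_rate_hz)
  audio_signal(apply_ramps(x, sample_rate_hz, 0.010), as.integer(sample_rate_hz))
}

apply_ramps <- function(x, fs, ramp_s) {
  nr <- min(length(x) %/% 2L, round(ramp_s * fs))
  if (nr > 0L) {
    r <- 0.5 - 0.5 * cos(pi * seq_len(nr) / nr)
    x[seq_len(nr)] <- x[seq_len(nr)] * r
    x[(length(x) - nr + 1L):length(x)] <- rev(r) * x[(length(x) - nr + 1L):length(x)]
  }
  x
}

#' Word-like test fixture
#'
#' A ~0.6 s synthetic stand-in for a spoken monosyllable: a high-frequency
#' fricative onset burst followed by a voiced segment — a harmonic complex
#' on a falling fundamental, spectrally shaped by two gliding formants —
#' under a natural attack-decay amplitude envelope.  Deterministic per
#' seed.  Used throughout the tests as the encoding fixture.
#'
#' @param seed RNG seed for the burst noise.
#' @param sample_rate_hz sampling rate.
#' @return an [audio_signal()] of about 0.6 s, peak-normalized to 0.95.
#' @export
make_word_fixture <- function(seed = 1L, sample_rate_hz = 16000L) {
  fs <- as.integer(sample_rate_hz)
  with_preserved_rng(seed, {
    # fricative onset: high-pass noise burst, 120 ms
    nb <- round(0.12 * fs)
    burst <- stats::rnorm(nb)
    spec <- stats::fft(burst)
    f <- (seq_along(spec) - 1L) * fs / nb
    f <- pmin(f, fs - f)                       # two-sided frequency axis
    spec[f < 3000] <- 0
    burst <- Re(stats::fft(spec, inverse = TRUE)) / nb
    burst <- apply_ramps(burst / max(abs(burst)) * 0.4, fs, 0.015)

    gap <- numeric(round(0.03 * fs))

    # voiced segment: harmonic complex, f0 130 -> 105 Hz, two gliding formants
    nv <- round(0.45 * fs)
    tt <- (seq_len(nv) - 1L) / fs
    f0 <- seq(130, 105, length.out = nv)
    phase0 <- cumsum(2 * pi * f0 / fs)
    F1 <- seq(650, 480, length.out = nv)
    F2 <- seq(1750, 1250, length.out = nv)
    voiced <- numeric(nv)
    for (h in 1:30) {
      fh <- h * f0
      keep <- fh < 0.45 * fs
      if (!any(keep)) break
      g <- exp(-((fh - F1) / 180)^2) + 0.5 * exp(-((fh - F2) / 260)^2) +
           0.02                       # weak broadband harmonic floor
      voiced <- voiced + ifelse(keep, g * sin(h * phase0), 0)
    }
    envl <- (tt / 0.06) * exp(1 - tt / 0.06)   # attack-decay envelope
    envl <- envl / max(envl)
    voiced <- apply_ramps(voiced / max(abs(voiced)) * envl, fs, 0.010)

    x <- c(burst, gap, voiced)
    audio_signal(x / max(abs(x)) * 0.95, fs)
  })
}

# target long-term-speech-like magnitude response (dB) of the noise shaper,
# anchored on a conventional-telephone-signal weighting: low-frequency
# roll-off, a broad maximum near 300-500 Hz, then a steady fall-off.
ssn_anchor_table <- function() {
  data.frame(
    freq_hz = c(1, 50, 100, 200, 300, 400, 600, 800, 1000,
                1500, 2000, 3000, 4000, 6000, 7900, 8000),
    gain_db = c(-60, -25, -12, -4, -1, 0, -1.5, -3.5, -5.5,
                -9.5, -13, -18.5, -22.5, -27.5, -39.8, -40)
  )
}

# linear-phase FIR (frequency-sampling design, Hamming-windowed) matching a
# piecewise-log-linear magnitude target; fir2-style
design_ssn_fir <- function(n_taps = 64L, fs = 16000) {
  anc <- ssn_anchor_table()
  ngrid <- 512L
  f <- seq(0, fs / 2, length.out = ngrid)
  mag_db <- stats::approx(log(anc$freq_hz), anc$gain_db, xout = log(pmax(f, 1)),
                          rule = 2)$y
  mag <- 10^(mag_db / 20)
  full <- c(mag, rev(mag[2:(ngrid - 1L)]))           # even spectrum
  h_long <- Re(stats::fft(full, inverse = TRUE)) / length(full)
  h_long <- c(utils::tail(h_long, (n_taps) %/% 2L),  # center the impulse
              utils::head(h_long, n_taps - n_taps %/% 2L))
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n_taps) - 1L) / (n_taps - 1L))
  h_long * w
}

#' Frequency response of the speech-noise shaping filter
#'
#' The designed magnitude response (dB, normalized to a 0 dB maximum) of
#' the 64-tap FIR used by [speech_shaped_noise()], evaluated at the given
#' frequencies.  This is the target shape the generated noise's long-term
#' spectrum follows.
#'
#' @param freq_hz frequencies (Hz).
#' @param sample_rate_hz sampling rate the filter is designed for.
#' @return gains in dB (max = 0).
#' @export
ssn_target_response <- function(freq_hz, sample_rate_hz = 16000) {
  h <- design_ssn_fir(64L, sample_rate_hz)
  H <- vapply(freq_hz, function(f0)
    abs(sum(h * exp(-2i * pi * f0 * (seq_along(h) - 1L) / sample_rate_hz))),
    numeric(1))
  g <- 20 * log10(pmax(H, 1e-12))
  g - max(g)
}

#' Speech-shaped stationary noise
#'
#' Gaussian white noise shaped by a 64-tap FIR whose magnitude response
#' approximates the long-term spectrum of speech (conventional-telephone-
#' signal weighting): the stationary masker used for SNR-controlled
#' mixtures.  Deterministic per seed.
#'
#' @param duration_s duration (> 0), seconds.
#' @param seed RNG seed.
#' @param sample_rate_hz sampling rate.
#' @param level_db_rms output RMS level, dB re full scale.
#' @return an [audio_signal()].
#' @export
speech_shaped_noise <- function(duration_s, seed = 1L, sample_rate_hz = 16000L,
                                level_db_rms = -20) {
  if (duration_s <= 0) stop("duration must be positive")
  fs <- as.integer(sample_rate_hz)
  n <- round(duration_s * fs)
  h <- design_ssn_fir(64L, fs)
  x <- with_preserved_rng(seed, stats::rnorm(n + length(h)))
  y <- stats::filter(x, h, method = "convolution", sides = 1L)
  y <- as.numeric(y[(length(h) + 1L):(length(h) + n)])
  y <- y / stats::sd(y) * 10^(level_db_rms / 20)
  audio_signal(y, fs)
}

#' Mix speech and noise at an exact signal-to-noise ratio
#'
#' Scales the noise so that the power ratio between the speech's active
#' portion and the corresponding noise equals `snr_db` exactly, then
#' returns the sum, peak-normalized to 0.99.  "Active" is measured over
#' 10 ms windows whose RMS is within 40 dB of the speech's strongest
#' window, so leading/trailing silence does not dilute the speech power.
#' The applied noise scale and post-normalization gain are attached as
#' attributes `noise_scale` and `post_gain`.
#'
#' @param speech,noise [audio_signal()]s at the same rate; the noise must
#'   be at least as long as the speech (it is truncated to match).
#' @param snr_db target signal-to-noise ratio in dB (the study used 5, 10
#'   and 15 dB).
#' @param active_threshold_db windows this far below the peak window RMS
#'   count as silence.
#' @return the mixture as an [audio_signal()].
#' @export
mix_at_snr <- function(speech, noise, snr_db, active_threshold_db = -40) {
  stopifnot(inherits(speech, "audio_signal"), inherits(noise, "audio_signal"))
  if (speech$sample_rate_hz != noise$sample_rate_hz)
    stop("sample rates differ")
  ns <- length(speech$samples)
  if (length(noise$samples) < ns) stop("noise must be at least as long as speech")
  s <- speech$samples
  v <- noise$samples[seq_len(ns)]

  act <- active_samples(s, speech$sample_rate_hz, active_threshold_db)
  if (!any(act)) stop("silent speech: SNR undefined")
  p_s <- mean(s[act]^2)
  p_n <- mean(v[act]^2)
  if (p_n == 0) stop("silent noise: SNR undefined")
  scale <- sqrt(p_s / (p_n * 10^(snr_db / 10)))
  mix <- s + scale * v
  pk <- max(abs(mix))
  gain <- if (pk > 0) 0.99 / pk else 1
  out <- audio_signal(mix * gain, speech$sample_rate_hz)
  attr(out, "noise_scale") <- scale
  attr(out, "post_gain") <- gain
  out
}

# logical mask of samples in 10 ms windows above (peak window RMS + thr_db)
active_samples <- function(x, fs, thr_db) {
  wl <- max(1L, round(0.010 * fs))
  nw <- ceiling(length(x) / wl)
  xp <- c(x, numeric(nw * wl - length(x)))
  rms2 <- colMeans(matrix(xp^2, nrow = wl))
  keep <- rms2 > max(rms2) * 10^(thr_db / 10)
  rep(keep, each = wl)[seq_along(x)]
}

#' Measured SNR of a mixture's components
#'
#' Utility mirroring [mix_at_snr()]'s definition: power ratio of speech to
#' scaled noise over the speech-active samples, in dB.
#'
#' @param speech,scaled_noise numeric vectors of equal length.
#' @param fs sampling rate.
#' @param active_threshold_db active-window threshold as in [mix_at_snr()].
#' @return SNR in dB.
#' @export
measure_snr <- function(speech, scaled_noise, fs = 16000,
                        active_threshold_db = -40) {
  act <- active_samples(speech, fs, active_threshold_db)
  10 * log10(mean(speech[act]^2) / mean(scaled_noise[act]^2))
}
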