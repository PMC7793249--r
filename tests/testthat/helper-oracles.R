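# Independent oracles used across the suite.  These are deliberately
# separate, literal transcriptions of the procedures under test; they must
# not call the package's implementation of the same step.

# Ideal band-limited resampling oracle: reconstruct x (sampled at from_hz)
# with an untruncated sinc kernel band-limited to the narrower Nyquist and
# evaluate at the output instants m/to_hz.  O(n^2); tiny signals only.
sinc_resample_oracle <- function(x, from_hz, to_hz) {
  r <- min(1, to_hz / from_hz)
  n_out <- ceiling(length(x) * to_hz / from_hz)
  k <- seq_along(x) - 1L
  vapply(seq_len(n_out) - 1L, function(m) {
    t <- m * from_hz / to_hz          # output instant in input samples
    u <- r * (t - k)
    sum(x * r * ifelse(u == 0, 1, sin(pi * u) / (pi * u)))
  }, numeric(1))
}

# Literal transcription of the reset-every-frame simultaneous-masking
# selection loop: per frame the profile starts at zero, the first pick is
# the channel with the highest level above audibility, each further pick
# is the channel least masked (largest level-minus-profile margin), and
# after every pick the triangular masking pattern of the picked channel is
# folded into the profile by elementwise maximum.
pace_select_oracle <- function(env, cfg) {
  M <- cfg$num_channels
  prof <- rep(0, M)
  selected <- integer(0)
  levels <- numeric(0)
  for (step in seq_len(cfg$num_maxima)) {
    best <- 0L; best_margin <- 0
    for (z in seq_len(M)) {
      if (z %in% selected) next
      margin <- env[z] - prof[z]
      if (env[z] > prof[z] && margin > best_margin) {
        best <- z; best_margin <- margin
      }
    }
    if (best == 0L) break
    selected <- c(selected, best)
    levels <- c(levels, env[best])
    for (j in seq_len(M)) {
      slope <- if (j < best) cfg$slope_low_db_per_ch else cfg$slope_high_db_per_ch
      contrib <- env[best] - cfg$spread_offset_db - slope * abs(j - best)
      if (contrib > prof[j]) prof[j] <- max(0, contrib)
    }
  }
  list(channels = selected, levels = levels, profile = prof)
}

# Full reset-every-frame encoder built on the oracle selection; shares only
# the front end and pulse mapping with the package (those are not under
# test here).
pace_encode_oracle <- function(signal, cfg, map) {
  tab <- default_band_table(num_channels = cfg$num_channels,
                            sample_rate_hz = cfg$sample_rate_hz,
                            frame_length_samples = cfg$frame_length_samples)
  frames <- analyze_frames(signal, cfg)
  env <- band_envelopes(frames, tab, cfg$audibility_floor_db)
  out <- vector("list", ncol(env))
  for (f in seq_len(ncol(env))) {
    sel <- pace_select_oracle(env[, f], cfg)
    out[[f]] <- frame_to_pulses(
      data.frame(channel = sel$channels, level_db = sel$levels,
                 rank = seq_along(sel$channels)),
      frames$start_time_s[f], cfg, map, frame_index = f - 1L)
  }
  do.call(rbind, out)
}

# Stepwise enumeration of the greedy masked-selection rule with an
# inherited profile: at every step enumerate all remaining channels above
# the running profile, take the largest excess (ties to the lowest index),
# and update the profile with the picked channel's triangular pattern.
greedy_select_oracle <- function(env, inherited, cfg) {
  M <- cfg$num_channels
  prof <- as.numeric(inherited)
  selected <- integer(0)
  for (step in seq_len(cfg$num_maxima)) {
    cand <- setdiff(which(env > prof), selected)
    if (length(cand) == 0L) break
    ex <- env[cand] - prof[cand]
    best <- cand[which(ex == max(ex))]
    z <- min(best)                    # tie-break: lowest channel
    selected <- c(selected, z)
    for (j in seq_len(M)) {
      slope <- if (j < z) cfg$slope_low_db_per_ch else cfg$slope_high_db_per_ch
      prof[j] <- max(prof[j], max(0, env[z] - cfg$spread_offset_db -
                                     slope * abs(j - z)))
    }
  }
  list(channels = selected, profile = prof)
}

# Brute-force tie-corrected Spearman rho: Pearson correlation of midranks.
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Within-block permutation null for a block-design statistic: permutes
# condition labels independently inside every block.
permutation_null_pvalue <- function(scores, n_perm = 2000, seed = 99) {
  obs <- quade_test(scores)$statistic
  b <- nrow(scores)
  set.seed(seed)
  ge <- 0L
  for (i in seq_len(n_perm)) {
    perm <- t(apply(scores, 1L, sample))
    if (quade_test(perm)$statistic >= obs) ge <- ge + 1L
  }
  (ge + 1L) / (n_perm + 1L)
}

# shared fixtures
word_fixture <- function() make_word_fixture(seed = 20L)
small_cfg <- function(...) strategy_config(num_channels = 4L, num_maxima = 2L,
                                           spread_offset_db = 10,
                                           slope_low_db_per_ch = 20,
                                           slope_high_db_per_ch = 20, ...)

# bare pulse columns, attributes stripped, for exact table comparisons
pulse_df <- function(e) {
  data.frame(time_s = e$time_s, electrode = e$electrode,
             current_level = e$current_level, frame = e$frame,
             channel = e$channel)
}
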