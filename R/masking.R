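#' Temporal-masking attenuation factor
#'
#' The forward-masking carry-over multiplies the previous frame's masking
#' profile by `F = 2^(-t / t_half)`: after one half-life the carried-over
#' level has dropped to half.  `t_half = 0` is defined as the limit `F = 0`
#' (full reset every frame), which recovers the simultaneous-masking-only
#' strategy.
#'
#' @param t elapsed time between frames, seconds (> 0).
#' @param t_half temporal-masking half-life, seconds (>= 0).
#' @return attenuation factor in \[0, 1\].
#' @export
attenuation_factor <- function(t, t_half) {
  if (any(t <= 0)) stop("t must be positive")
  if (any(t_half < 0)) stop("t_half must be >= 0")
  ifelse(t_half == 0, 0, 2^(-t / t_half))
}

#' Masking-profile container
#'
#' A per-channel masking level in dB re the audibility threshold; 0 is the
#' absorbing "inaudible" floor.  This is the state carried from frame to
#' frame by the temporal-masking strategy.
#'
#' @param levels_db non-negative numeric vector, one level per channel.
#' @param frame_index frame the profile belongs to.
#' @return object of class `masking_profile` (numeric vector with a
#'   `frame_index` attribute).
#' @export
masking_profile <- function(levels_db, frame_index = 0L) {
  if (any(levels_db < 0)) stop("masking levels must be >= 0 dB re threshold")
  structure(as.numeric(levels_db), frame_index = as.integer(frame_index),
            class = "masking_profile")
}

profile_levels <- function(p) as.numeric(unclass(p))

#' Decay a masking profile
#'
#' Applies the carried-over attenuation in the dB domain: every channel's
#' level (dB above the audibility floor) is multiplied by `factor`, driving
#' the profile geometrically toward the inaudible state.
#'
#' @param profile a [masking_profile()] or numeric vector of levels.
#' @param factor attenuation factor in \[0, 1\] from [attenuation_factor()].
#' @return the decayed `masking_profile` with `frame_index` incremented.
#' @export
decay_profile <- function(profile, factor) {
  if (length(factor) != 1L || factor < 0 || factor > 1)
    stop("factor must be a scalar in [0, 1]")
  fi <- attr(profile, "frame_index")
  if (is.null(fi)) fi <- 0L
  masking_profile(profile_levels(profile) * factor, fi + 1L)
}

#' Spread-of-masking contribution of one masker
#'
#' Triangular masking pattern of a masker on channel `channel` at level
#' `level_db`: the masked threshold is `level_db - spread_offset_db` on the
#' masker's own channel and falls off linearly with channel distance, with
#' `slope_low_db_per_ch` toward lower (more apical) channels and
#' `slope_high_db_per_ch` toward higher channels; negative values clamp to 0.
#'
#' @param channel masker channel index in 1..M.
#' @param level_db masker level, dB re audibility threshold (>= 0).
#' @param config a [strategy_config()].
#' @return numeric vector of length M of masking contributions (dB).
#' @export
masker_spread <- function(channel, level_db, config) {
  M <- config$num_channels
  if (channel < 1L || channel > M) stop("channel out of range 1..M")
  if (level_db < 0) stop("level_db must be >= 0")
  z <- seq_len(M)
  d <- z - channel
  slope <- ifelse(d < 0, config$slope_low_db_per_ch, config$slope_high_db_per_ch)
  pmax(0, level_db - config$spread_offset_db - slope * abs(d))
}

#' Combine a masker contribution into the profile
#'
#' With `combine_rule = "max"` the new profile is the elementwise maximum
#' of the old profile and the contribution (the louder masker dominates);
#' with `"power-sum"` the two are added as powers in the dB domain.
#'
#' @param profile a [masking_profile()] or numeric vector.
#' @param contribution numeric vector of the same length (dB).
#' @param rule `"max"` or `"power-sum"`.
#' @return updated `masking_profile` (same `frame_index`).
#' @export
update_profile <- function(profile, contribution, rule = c("max", "power-sum")) {
  rule <- match.arg(rule)
  old <- profile_levels(profile)
  if (length(old) != length(contribution))
    stop("profile and contribution lengths differ")
  new <- switch(rule,
    "max" = pmax(old, contribution),
    # powers are measured re the audibility floor (0 dB <-> power 1); the
    # shared floor power is counted once, so a zero contribution is identity
    "power-sum" = 10 * log10(10^(old / 10) + 10^(contribution / 10) - 1)
  )
  fi <- attr(profile, "frame_index")
  masking_profile(new, if (is.null(fi)) 0L else fi)
}

#' Iterative masked channel selection for one frame
#'
#' Greedy n-of-m selection against a running masking profile.  Up to
#' `config$num_maxima` times: among the not-yet-selected channels whose
#' envelope level exceeds the current profile level, pick the channel with
#' the largest excess (envelope minus profile; ties go to the lowest
#' channel index), then fold its [masker_spread()] into the profile.  The
#' loop stops early when no channel remains above the profile, so fewer
#' than n channels may be returned.  With a zero inherited profile this is
#' the per-frame simultaneous-masking selection; with a decayed carry-over
#' profile it is the temporal-masking variant.
#'
#' @param envelope numeric vector of M levels (dB re audibility threshold)
#'   or one column of [band_envelopes()].
#' @param inherited the inherited [masking_profile()] (decayed carry-over
#'   from the previous frame, or all-zero).
#' @param config a [strategy_config()].
#' @return list with `selection` (data.frame: `channel`, `level_db`,
#'   `rank`) and `profile` (the final `masking_profile` after the last
#'   update — this is what the next frame inherits before decay).
#' @export
select_channels <- function(envelope, inherited, config) {
  env <- as.numeric(envelope)
  prof <- profile_levels(inherited)
  M <- config$num_channels
  if (length(env) != M || length(prof) != M)
    stop("envelope/profile length must equal num_channels")
  fi <- attr(inherited, "frame_index")
  if (is.null(fi)) fi <- 0L

  sel_ch <- integer(0)
  sel_lev <- numeric(0)
  available <- rep(TRUE, M)
  for (k in seq_len(config$num_maxima)) {
    excess <- env - prof
    excess[!available] <- -Inf
    cand <- which(available & env > prof)
    if (length(cand) == 0L) break
    z <- which.max(excess)             # ties -> lowest channel index
    sel_ch <- c(sel_ch, z)
    sel_lev <- c(sel_lev, env[z])
    available[z] <- FALSE
    prof <- pmax(0, switch(config$combine_rule,
      "max" = pmax(prof, masker_spread(z, env[z], config)),
      "power-sum" = profile_levels(
        update_profile(prof, masker_spread(z, env[z], config), "power-sum"))
    ))
  }
  list(
    selection = data.frame(channel = sel_ch, level_db = sel_lev,
                           rank = seq_along(sel_ch)),
    profile = masking_profile(prof, fi)
  )
}

#' Encode audio into an electrodogram
#'
#' Runs the full coding strategy: short-time FFT analysis
#' ([analyze_frames()]), 22-band envelope extraction ([band_envelopes()]),
#' per-frame masked channel selection ([select_channels()]) with the
#' temporal carry-over, and mapping of the selected levels to timed current
#' pulses ([frame_to_pulses()]).  Per frame, the inherited profile is the
#' previous frame's final profile decayed by
#' `attenuation_factor(hop_time, t_half)`; for the first frame, or whenever
#' `t_half_ms = 0`, the profile starts from zero, which reproduces the
#' reset-every-frame simultaneous-masking strategy pulse for pulse.
#'
#' @param signal an [audio_signal()].
#' @param config a [strategy_config()].
#' @param map a [map_parameters()].
#' @param table a `band_table`; defaults to [default_band_table()] sized to
#'   the config.
#' @return An `electrodogram`: data.frame of pulses (`time_s`, `electrode`,
#'   `current_level`, plus bookkeeping columns `frame` and `channel`) with
#'   the configuration snapshot attached.  Digital silence yields an
#'   electrodogram with zero pulses.
#' @export
encode <- function(signal, config = strategy_config(), map = map_parameters(),
                   table = NULL) {
  stopifnot(inherits(config, "strategy_config"), inherits(map, "map_parameters"))
  if (is.null(table))
    table <- default_band_table(num_channels = config$num_channels,
                                sample_rate_hz = config$sample_rate_hz,
                                frame_length_samples = config$frame_length_samples)
  frames <- analyze_frames(signal, config)
  env <- band_envelopes(frames, table, floor_vector(config))
  nf <- ncol(env)
  t_half_s <- config$t_half_ms / 1000
  Fdec <- if (t_half_s > 0) attenuation_factor(hop_seconds(config), t_half_s) else 0

  prof <- masking_profile(numeric(config$num_channels), 0L)
  pulse_list <- vector("list", nf)
  n_selected <- integer(nf)
  for (f in seq_len(nf)) {
    inherited <- if (f == 1L || Fdec == 0) {
      masking_profile(numeric(config$num_channels), f - 1L)
    } else {
      decay_profile(prof, Fdec)
    }
    res <- select_channels(env[, f], inherited, config)
    prof <- res$profile
    n_selected[f] <- nrow(res$selection)
    pulse_list[[f]] <- frame_to_pulses(res$selection,
                                       frames$start_time_s[f], config, map,
                                       frame_index = f - 1L)
  }
  pulses <- do.call(rbind, pulse_list)
  if (is.null(pulses))
    pulses <- data.frame(time_s = numeric(0), electrode = integer(0),
                         current_level = integer(0), frame = integer(0),
                         channel = integer(0))
  electrodogram(pulses, config = config, map = map,
                n_frames = nf, n_selected = n_selected)
}
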