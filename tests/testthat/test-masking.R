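test_that("attenuation factor implements the half-life law", {
  # definition of the half-life
  expect_equal(attenuation_factor(0.0005, 0.0005), 0.5)
  expect_equal(attenuation_factor(2.2, 1.1), 0.25)

  # values at the 900 pps nominal frame interval
  expect_equal(attenuation_factor(1 / 900, 0.0011), 2^(-(1 / 900) / 0.0011))
  expect_equal(attenuation_factor(1 / 900, 0.0011), 0.4965, tolerance = 1e-4)
  expect_equal(attenuation_factor(1 / 900, 0.0005), 0.2143, tolerance = 1e-3)

  # zero half-life is defined as full reset
  expect_identical(attenuation_factor(1 / 900, 0), 0)

  # strictly increasing in t_half, strictly decreasing in t
  th <- sort(stats::runif(20, 1e-4, 5e-3))
  expect_true(all(diff(attenuation_factor(1 / 900, th)) > 0))
  tt <- sort(stats::runif(20, 1e-4, 5e-3))
  expect_true(all(diff(attenuation_factor(tt, 0.0011)) < 0))

  expect_error(attenuation_factor(-1, 0.001), "positive")
  expect_error(attenuation_factor(0.001, -1), ">= 0")
})

test_that("profile decay is geometric in the dB domain and absorbing at zero", {
  p <- masking_profile(c(40, 10, 0, 25))
  expect_equal(as.numeric(decay_profile(p, 0.5)), c(20, 5, 0, 12.5))
  expect_equal(as.numeric(decay_profile(p, 1)), as.numeric(p))
  expect_equal(as.numeric(decay_profile(masking_profile(numeric(4)), 0.7)),
               numeric(4))
  expect_identical(attr(decay_profile(p, 0.5), "frame_index"), 1L)
  expect_error(decay_profile(p, 1.2), "\\[0, 1\\]")
  expect_error(decay_profile(p, -0.1), "\\[0, 1\\]")

  # half-life law: k silent frames multiply by F^k, to 1e-12 relative
  F <- attenuation_factor(18 / 16000, 0.0005)
  q <- masking_profile(c(55, 31, 7, 18))
  for (k in 1:40) q <- decay_profile(q, F)
  expect_equal(as.numeric(q), c(55, 31, 7, 18) * F^40, tolerance = 1e-12)
})

test_that("triangular masker spread matches the hand-evaluated rule", {
  cfg <- strategy_config(num_channels = 7, num_maxima = 3,
                         spread_offset_db = 10, slope_low_db_per_ch = 20,
                         slope_high_db_per_ch = 20)
  ct <- masker_spread(4, 50, cfg)
  expect_equal(ct, c(0, 0, 20, 40, 20, 0, 0))

  # asymmetric slopes
  cfg2 <- strategy_config(num_channels = 7, spread_offset_db = 10,
                          slope_low_db_per_ch = 27, slope_high_db_per_ch = 24)
  ct2 <- masker_spread(4, 60, cfg2)
  expect_equal(ct2, c(0, 0, 23, 50, 26, 2, 0))

  # level at or below the offset masks nothing
  expect_equal(masker_spread(4, 10, cfg), numeric(7))
  expect_equal(masker_spread(1, 5, cfg), numeric(7))
  expect_error(masker_spread(8, 50, cfg), "out of range")
})

test_that("profile update combines maskers per the combine rule", {
  p <- masking_profile(c(10, 0, 30, 0))
  c1 <- c(5, 20, 10, 0)
  expect_equal(as.numeric(update_profile(p, c1)), c(10, 20, 30, 0))
  expect_equal(as.numeric(update_profile(p, numeric(4))), as.numeric(p))
  expect_equal(as.numeric(update_profile(masking_profile(numeric(4)), c1)), c1)

  # max-combine is idempotent
  once <- update_profile(p, c1)
  expect_equal(as.numeric(update_profile(once, c1)), as.numeric(once))

  # power-sum: zero is the identity, equal levels add 3 dB
  ps <- update_profile(masking_profile(c(20, 0)), c(20, 0), rule = "power-sum")
  expect_equal(ps[1], 10 * log10(2 * 10^2 - 1), tolerance = 1e-12)
  expect_equal(ps[2], 0)
  expect_equal(as.numeric(update_profile(masking_profile(c(15, 3)), c(0, 0),
                                         rule = "power-sum")), c(15, 3))

  expect_error(update_profile(p, c(1, 2)), "lengths differ")
})

test_that("greedy selection reproduces the hand-traced examples", {
  cfg <- small_cfg()                           # M=4, n=2, a_v=10, slopes 20/20
  env <- c(50, 40, 30, 20)

  # zero inherited profile: pick 1, then 3 (excess 30 beats channel 2's 20)
  res <- select_channels(env, masking_profile(numeric(4)), cfg)
  expect_equal(res$selection$channel, c(1L, 3L))
  expect_equal(res$selection$level_db, c(50, 30))
  expect_equal(res$selection$rank, 1:2)

  # inherited 60 dB on channel 1 blocks it: first pick is channel 2
  res2 <- select_channels(env, masking_profile(c(60, 0, 0, 0)), cfg)
  expect_equal(res2$selection$channel[1], 2L)

  # with no spread (huge offset) selection reduces to plain top-n maxima
  cfg3 <- strategy_config(num_channels = 6, num_maxima = 3,
                          spread_offset_db = 1000)
  env3 <- c(12, 44, 8, 31, 27, 3)
  res3 <- select_channels(env3, masking_profile(numeric(6)), cfg3)
  expect_equal(res3$selection$channel, order(env3, decreasing = TRUE)[1:3])

  # nothing above the profile: empty selection, profile passed through
  res4 <- select_channels(numeric(4), masking_profile(c(5, 5, 5, 5)), cfg)
  expect_equal(nrow(res4$selection), 0L)
  expect_equal(as.numeric(res4$profile), c(5, 5, 5, 5))

  expect_error(select_channels(c(1, 2), masking_profile(numeric(4)), cfg),
               "length")
})

test_that("selection matches stepwise enumeration on 500 random frames", {
  cfg <- strategy_config(num_channels = 6, num_maxima = 3,
                         spread_offset_db = 10, slope_low_db_per_ch = 27,
                         slope_high_db_per_ch = 24)
  set.seed(11)
  for (trial in 1:500) {
    env <- round(stats::runif(6, 0, 60), 1)
    inh <- round(stats::runif(6, 0, 30), 1)
    got <- select_channels(env, masking_profile(inh), cfg)
    ref <- greedy_select_oracle(env, inh, cfg)
    expect_identical(got$selection$channel, ref$channels)
    expect_equal(as.numeric(got$profile), ref$profile, tolerance = 1e-12)
  }
})

test_that("zero half-life encoding equals the literal reset-every-frame loop", {
  cfg <- strategy_config(t_half_ms = 0)
  map <- map_parameters()
  fixtures <- list(
    word = word_fixture(),
    tone = make_tone(1000, 0.25, level_db_rms = -15),
    mix = mix_at_snr(word_fixture(), speech_shaped_noise(0.7, seed = 3), 10)
  )
  for (nm in names(fixtures)) {
    got <- encode(fixtures[[nm]], cfg, map)
    ref <- pace_encode_oracle(fixtures[[nm]], cfg, map)
    expect_identical(pulse_df(got), pulse_df(ref), label = nm)
  }
})

test_that("carry-over masking sparsens immediate electrode repeats monotonically", {
  w <- word_fixture()
  map <- map_parameters()
  rates <- vapply(c(0, 0.2, 0.4, 0.5, 0.8, 1.1, 2.0), function(th)
    repeat_rate(encode(w, strategy_config(t_half_ms = th), map)), numeric(1))
  expect_true(all(diff(rates) <= 0))
  # ...and the effect is substantive, not a flat line
  expect_lt(rates[length(rates)], rates[1])
})

test_that("encoding respects the pulse budget and degenerate inputs", {
  cfg <- strategy_config(t_half_ms = 0.5)
  map <- map_parameters()

  # digital silence yields an empty electrodogram
  e0 <- encode(audio_signal(numeric(3600), 16000), cfg, map)
  expect_equal(nrow(e0), 0L)

  # every frame of a rich fixture carries at most n pulses and no electrode
  # fires twice within a frame
  e <- encode(word_fixture(), cfg, map)
  expect_true(all(pulses_per_frame(e) <= cfg$num_maxima))
  dup <- tapply(e$electrode, e$frame, anyDuplicated)
  expect_true(all(dup == 0))

  # pulse times fit within their frame interval and are non-decreasing
  hop_s <- cfg$hop_samples / cfg$sample_rate_hz
  expect_true(all(e$time_s >= e$frame * hop_s - 1e-12))
  expect_true(all(e$time_s < (e$frame + 1) * hop_s + 1e-12))
  expect_true(!is.unsorted(e$time_s))
})
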