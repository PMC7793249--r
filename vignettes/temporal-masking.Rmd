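---
title: "Temporal-masking channel selection: model, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal-masking channel selection: model, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpace)
```

## The model

An n-of-m cochlear-implant strategy stimulates, each analysis frame, only
the n channels judged most relevant out of m = 22 filterbank bands.  The
psychoacoustic variant implemented here judges relevance with a masking
profile `L(z)`: a per-channel threshold of perception, in dB relative to
the channel's audibility floor.  Within a frame, selection is greedy:

1. among unselected channels whose envelope level exceeds the current
   profile, pick the one with the largest excess (envelope − profile);
2. fold the picked channel's triangular spread-of-masking pattern into
   the profile (elementwise maximum by default) and repeat, up to n
   times or until nothing remains above the profile.

Because envelopes are stored relative to the audibility floor, "highest
level re audibility" and "largest excess over a zero profile" coincide
for the first pick.

The temporal extension changes only what the profile is *initialized*
to.  The reset-every-frame strategy starts each frame from zero.  Here
the final profile of frame f − 1 is carried over, attenuated in the dB
domain:

    L_f(z) = F · L_{f−1}(z),   F = 2^(−t / T½),

with t the frame interval and T½ the temporal-masking half-life.  The
multiplicative decay of a dB value is deliberate — it is how the model is
defined, and with floor-relative levels it makes 0 dB an absorbing
"inaudible" state rather than a unit that can go negative.  `T½ = 0` is
defined as the limit `F = 0`, avoiding a 0/0, and `encode()` short-cuts
to a zero profile in that case; a dedicated test verifies that this path
is pulse-for-pulse identical to an independently transcribed
reset-every-frame loop.

The carried-over profile participates in the within-frame updates: new
maskers combine with the decayed inheritance, so a loud previous frame
both suppresses immediate re-selection of its own channels and shifts
picks toward its spectral neighbours.  This is the mechanism behind the
monotone drop of the immediate same-electrode repeat rate with growing
T½ that the test suite checks on the word fixture.

## Parameters, defaults, and why

| parameter | default | unit | rationale |
|---|---|---|---|
| `sample_rate_hz` | 16000 | Hz | the front end's operating rate |
| `frame_length_samples` | 128 | samples | 8 ms window, 125 Hz bin spacing |
| `num_channels` | 22 | – | electrode count of the modeled array |
| `num_maxima` | 5 | – | the clinical operating point studied |
| `channel_rate_pps` | 900 | pulses/s | clinical default rate |
| `t_half_ms` | 0.5 | ms | the half-life with the best measured benefit; spans neural refraction |
| `spread_offset_db` | 10 | dB | masker-to-threshold offset a_v |
| `slope_low/high_db_per_ch` | 27 / 24 | dB/channel | typical triangular psychoacoustic spread; steeper toward apex |
| `audibility_floor_db` | −40 | dB re FFT band energy | see below |
| `rho` | 416.2 | – | classic compressive loudness-growth steepness |
| `base/saturation_level_db` | 0 / 40 | dB re floor | 40 dB input dynamic range |
| T / C levels | 100 / 200 | clinical units | flat synthetic map; clinical fitting replaces these |

Three of these deserve comment.

**Hop and the frame interval.**  One selection cycle runs per stimulation
cycle, so the hop is `round(Fs / rate)` = 18 samples at 900 pps, a
realized frame interval of 1.125 ms.  The decay inside `encode()` uses
this realized hop time; the nominal interval 1/900 s ≈ 1.111 ms appears
only in the arithmetic checks of the attenuation factor, where the two
differ in the third decimal.  At 900 pps a 1.1 ms half-life removes about
50% of the carried level per frame; a 0.5 ms half-life leaves about 21%.
(The published figure caption pairs "50% or 20%" with 0.5/1.1 ms in the
opposite order; read as "decrease *to*" with the order swapped it is
consistent with the formula, and that literal formula is what is
implemented.)

**Audibility floor.**  Envelopes are `10·log10(Σ|bin|²) − floor`, clamped
at 0.  With peak-normalized input and a 128-point Hann window, a
full-scale sinusoid reaches roughly +30 dB on this scale, so a floor of
−40 dB yields a ~70 dB usable dynamic range, comfortably containing the
40 dB mapping range.  The floor may be per-channel; the default is flat
because the synthetic map is flat.

**Band allocation.**  Bins 2–63 (0-based) are partitioned into 22
contiguous ranges with the quasi-logarithmic count vector
1,1,1,1,1,1,1,1,1,2,2,2,2,3,3,4,4,5,5,6,7,8 — single-bin channels up to
~1.3 kHz widening monotonically to 8 bins at the top, covering
≈188–8000 Hz.  The exact vector is a config default, not a hard-coded
constant; validation only enforces contiguity, coverage and non-decreasing
widths.  Channel z drives electrode 23 − z (channel 1, lowest frequency,
on the most apical electrode 22); the direction can be flipped in
`map_parameters()`.

## Open design choices and how they were resolved

* **Window**: periodic Hann; the filterbank's source material is silent
  on the window, and Hann is the standard choice in this processing
  chain.
* **Tie-breaking**: equal selection excess goes to the lowest channel
  index, for determinism.
* **Short selections**: if fewer than n channels sit above the profile
  the frame simply carries fewer pulses; per-frame counts are retained on
  the electrodogram (`n_selected` attribute).
* **Pulse timing**: the k pulses of a frame are spaced evenly across the
  frame interval (`hop/k`, e.g. 0.225 ms for 5 pulses at 900 pps) and
  ordered base-to-apex; no two pulses are simultaneous.
* **Combine rule**: elementwise maximum by default.  The alternative
  `"power-sum"` adds maskers as powers *measured above the floor*, i.e.
  `10·log10(10^(a/10) + 10^(b/10) − 1)`, so that a zero (floor)
  contribution is exactly the identity; naive power addition would
  double-count the floor reference.

## The ECAP recovery fitter

The recovery of the electrically evoked compound action potential as a
function of masker-probe interval (MPI) is modeled as
`A·(1 − exp((t0 − MPI)/τ))`, clamped at 0 below the absolute refractory
period t0 (negative amplitudes are unphysical).  The clamp makes the
least-squares surface non-smooth in t0, so `fit_recovery()` uses a
two-stage scheme: Nelder-Mead on the clamped residual sum of squares
(run twice, `reltol 1e-14`) followed by a Gauss-Newton polish
(`nls`, port) restricted to the smooth branch MPI > t0, accepted only if
it does not worsen the clamped objective.  On noiseless data this
recovers generator parameters to better than 1e-6 relative; the test
suite asserts 1e-4.  Standard errors come from the local linearization
(numerical Jacobian of the clamped model at the optimum), which is also
what a Gauss-Newton covariance would give; whether the clamped or
unclamped model is fitted is immaterial whenever all measurements lie
above t0, as they do on the default 0.3–10 ms log-spaced 15-point grid.
Starting values: A = max amplitude, t0 = earliest MPI exceeding 10% of
the maximum, τ = 1 ms.  An all-zero curve is rejected as
non-identifiable.  The combined recovery time t0 + τ — the MPI at which
the response reaches 63.2% of A — is provided as a derived field for
descriptive correlation only.

## Study statistics

`quade_test()` wraps the standard Quade randomized-complete-block test
(subjects as blocks, strategy conditions as treatments).  The degenerate
design in which every block is internally constant produces a 0/0
statistic in the reference implementation; it is defined here as "no
effect" (statistic 0, p = 1).  One subtlety: the Quade statistic weights
blocks by the rank of their within-block sample *range*, so it is **not**
invariant under arbitrary per-block monotone rescalings (the Friedman
test is); it is invariant under a common positive gain plus per-block
shifts, and that is the property the suite tests.  The test's 5% level is
verified by a 2000-replicate null simulation (12 blocks × 3 conditions)
and a within-block permutation oracle cross-checks a strong-effect case.

`spearman_rank()` uses the tie-corrected rank correlation with the
t-approximation p-value.  `best_t_half()` reduces a subjects × conditions
score matrix to each subject's best-performing half-life, breaking ties
toward the smaller half-life and flagging them — ties at 0 ms do occur
and silently dropping them would bias the correlation toward stronger
masking.

## What the synthetic signals do and do not establish

The generators state a small, fixed world:

* `make_word_fixture()` — ~0.6 s: a high-pass fricative burst, then a
  harmonic complex (f0 130→105 Hz) shaped by two gliding formants under
  an attack-decay envelope.  It reproduces the *structural* features the
  strategy reacts to (broadband onset, low/mid-frequency harmonic
  energy, spectral glides), not the phonetics of any real word.
* `speech_shaped_noise()` — Gaussian noise through a 64-tap linear-phase
  FIR matching a conventional-telephone-signal-weighting-style long-term
  speech spectrum (broad maximum near 300–500 Hz, steady high-frequency
  roll-off).  The anchor table is an approximation, not the exact ITU
  coefficients; the generator's documented target is the designed FIR
  response itself, and the 30 s averaged periodogram sits within 2 dB of
  it across the passband.
* `mix_at_snr()` — scales noise for an *exact* power-ratio SNR over the
  speech-active samples (10 ms windows within 40 dB of the peak window),
  so leading silence does not dilute the speech power; the scale factor
  and post-normalization gain are recorded as attributes.

A green suite therefore establishes the algorithmic claims — budget
compliance, reset equivalence, decay laws, monotone sparsening, exact
SNR, parameter recovery — on this stated world.  It does not establish
speech intelligibility outcomes: those are human-subject results
(median gains of ~10–11% at T½ = 0.5 ms over the reset-every-frame
baseline) and are out of desk-scale reach by design.

## Known limitations

* No pre-emphasis, AGC or microphone model in front of the FFT; input is
  simply peak-normalized.
* The spread parameters live in clinical fitting software in practice;
  the defaults here are representative, configurable constants.
* Pulses are reported in clinical units; the device-specific
  current-law conversion to microamperes is out of scope, as are charge
  and phase-width computations.
* Backward masking is not modeled (not realizable in a causal real-time
  chain), nor are facilitation and adaptation.
```{r}
sessionInfo()
```
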