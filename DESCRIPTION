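Package: tpace
Title: Temporal-Masking Channel Selection for Cochlear-Implant Sound Coding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements an n-of-m channel-selection sound-coding strategy for
    cochlear implants in which the simultaneous-masking channel selection of
    the PACE/MP3000 family is extended by a forward (temporal) masking model:
    the per-channel masking profile is carried over between analysis frames
    and attenuated exponentially with a configurable half-life.  Provides the
    full audio-to-electrodogram pipeline (WAV ingestion, polyphase resampling
    to 16 kHz, 128-point FFT filterbank with 22 bands, iterative masked
    channel selection, loudness-growth mapping to clinical current units),
    electrodogram text I/O and plotting, an ECAP refractory recovery-function
    model with simulator and nonlinear least-squares fitter, the Quade
    randomized-block test and Spearman rank correlation used to compare
    strategy conditions, and seeded generators for tones, word-like fixtures,
    speech-shaped stationary noise and SNR-controlled mixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
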