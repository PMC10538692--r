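Package: speechrhythm
Title: Amplitude-Modulation Hierarchy, Rhythm Spectra and Cross-Band
    Transfer Entropy for Speech
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes speech recordings into a nested amplitude-modulation
    (AM) hierarchy by recursive probabilistic amplitude demodulation (PAD):
    a positive slowly varying modulator and a fast carrier are inferred by
    maximum a posteriori estimation under a Gaussian-process prior with an
    exponential link, and the recursion yields band-limited envelopes for
    the low-delta (<1 Hz), delta/prosody (1-4 Hz), theta-alpha/syllable
    (4-12 Hz) and beta-gamma/phoneme (12-40 Hz) rhythm bands riding on a
    >40 Hz carrier. Provides FFT modulation power spectra with per-band
    power summaries, continuous-wavelet scalograms, directed transfer
    entropy between hierarchy levels with circular-shift surrogate nulls,
    a synthetic nested-AM signal generator with controllable cross-band
    coupling and dyadic structure, and the group statistics (permutation
    contrasts, repeated-measures ANOVA, Shapiro-Wilk gate, one-tailed dyad
    correlation, Benjamini-Hochberg adjustment) used to compare
    conversational groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
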