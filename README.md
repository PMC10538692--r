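# speechrhythm

Speech rhythm forms a nested amplitude-modulation (AM) hierarchy: prosodic
stress at 1–4 Hz, syllables at 4–12 Hz, phonemes at 12–40 Hz, riding on a
carrier above 40 Hz. This package measures that hierarchy in conversational
recordings and asks how it differs between speaker groups — for instance,
whether a neurotypical interviewer's prosody flattens when addressing an
autistic partner, mirroring the weak prosody of autistic speech itself. It
is written for phoneticians and neurodevelopmental researchers who have
per-utterance WAV files plus a manifest of who spoke to whom.

## What it computes

1. **Probabilistic amplitude demodulation (PAD).** Each z-scored signal is
   factored as `y_t = m_t · c_t` with a positive slow modulator
   `m = exp(μ + x)`, `x` a stationary Gaussian process band-limited below a
   target rate, and an i.i.d. Gaussian carrier. The MAP pair is found by
   quasi-Newton ascent in a whitened Fourier parameterization. Run
   recursively at 40/12/4/1 Hz targets this yields four strictly positive
   band envelopes (low-delta, delta, theta-alpha, beta-gamma) whose product
   with the final carrier reconstructs the input exactly.
2. **Modulation power spectra.** FFT periodograms of each envelope,
   normalized so total one-sided power equals the envelope variance
   (Parseval-exact); "frequency power" of a rhythm is its band's summed
   power: prosody (1–4], syllable (4–12], phoneme (12–40] Hz. Plus Morlet
   scalograms over 0.1–40 Hz.
3. **Directed transfer entropy.**
   `T(X→Y) = H(Y_t|Y_past) − H(Y_t|Y_past, X_past)` between band envelopes
   (plug-in estimator, quantile bins, L = 1, 120 Hz), with circular-shift
   surrogate nulls; top-down = slower band driving faster band.
4. **Group statistics.** Permutation group × rhythm contrasts (with a
   Greenhouse–Geisser repeated-measures ANOVA reference), Shapiro–Wilk
   gating, one-tailed dyadic questioner–respondent correlation,
   Benjamini–Hochberg adjustment.
5. **A synthetic nested-AM generator** with controllable per-band depths,
   slow→fast phase-gated coupling and dyadic structure, so the whole chain
   is testable without a speech corpus.

## Worked example

```r
library(speechrhythm)

# a 10-s synthetic sample: prosody 2 Hz / depth 0.8, syllable 6 Hz / 0.6,
# phoneme 20 Hz / 0.4, strong slow->fast coupling
sy <- synth_generate(synth_spec(duration_s = 10, coupling_kappa = 0.8, seed = 3))
h  <- pad_cascade(sy$sample)
h$reconstruction_error
#> [1] 4.567764e-17
envelope_recovery(h, sy, "delta")
#> [1] 0.9636755
hierarchy_band_powers(h)
#>   sample_id prosody_power syllable_power phoneme_power
#> 1    synth3     0.4008463      0.2336217    0.09659471
band_pair_te(h, seed = 1)[, c("pair", "direction", "te_bits", "surrogate_mean_bits")]
#>               pair direction    te_bits surrogate_mean_bits
#> 1 prosody_syllable  top_down 0.08717405          0.01239244
#> 2 prosody_syllable bottom_up 0.01631216          0.01451157
#> 3  prosody_phoneme  top_down 0.02228185          0.02185424
#> 4  prosody_phoneme bottom_up 0.01184030          0.01086051
#> 5 syllable_phoneme  top_down 0.06641939          0.02085191
#> 6 syllable_phoneme bottom_up 0.02054286          0.01367943
```

The reconstruction error is machine precision (the cascade's product
identity is exact by construction); the recovered prosody envelope
correlates at 0.96 with the generator's ground truth; and transfer entropy
is elevated only in the two coupled top-down directions
(prosody→syllable, syllable→phoneme), each well above its surrogate null —
exactly the directed structure the generator planted.

A full demo study (four groups × 30 samples, dyadic structure) runs with:

```r
res <- run_pipeline(run_config(demo_n_per_group = 30, seed = 1))
res$stats$respondents$rhythm_levels   # prosody contrast significant,
                                      # syllable and phoneme not
res$stats$dyad_prosody                # positive questioner-respondent rho
```

For real data, point `run_config(manifest = "manifest.csv")` at a CSV with
columns `file, sample_id, role, group, dyad_id, topic` (see
`?read_manifest`); samples shorter than 10 s are excluded.

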