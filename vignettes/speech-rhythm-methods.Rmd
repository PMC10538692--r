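---
title: "Demodulating speech rhythm: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demodulating speech rhythm: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechrhythm)
```

## The problem

Speech rhythm is organised as a nested hierarchy of amplitude modulations
(AM): prosodic stress patterns fluctuate at roughly 1–4 Hz, syllables at
4–12 Hz and phonemes at 12–40 Hz, all riding on a carrier above 40 Hz that
conveys pitch and spectral detail rather than rhythm. Questions about how
speakers shape their rhythm for particular listeners — for example, whether
a neurotypical interviewer flattens their prosody when talking with an
autistic partner, mirroring the weak prosody typical of autistic speech —
reduce to three measurable quantities per recording:

1. the **band envelopes** of the AM hierarchy,
2. the **modulation power** each rhythm band carries ("frequency power"),
3. the **directed dependence** between bands (transfer entropy), separating
   top-down (slow drives fast) from bottom-up dynamics.

`speechrhythm` implements the full chain, from WAV files (or synthetic
stand-ins) to group statistics.

## Probabilistic amplitude demodulation

A z-scored signal is modelled as the product of a positive, slowly varying
modulator and a fast carrier,

$$y_t = m_t \, c_t, \qquad m_t = \exp(\mu + x_t), \qquad
c_t \overset{iid}{\sim} N(0, \sigma_c^2),$$

where $x$ is a zero-mean stationary Gaussian process. Writing the joint
density of signal, carrier and modulator and applying Bayes' theorem, the
maximum a posteriori (MAP) modulator/carrier pair maximises the log joint

$$\log P(y, x \mid \theta) = -\sum_t \Big[ v_t +
\tfrac{y_t^2}{2\sigma_c^2} e^{-2 v_t} \Big] - \tfrac12 x^\top K^{-1} x
+ \text{const}, \qquad v = \mu + W x,$$

with $W$ the linear interpolation operator from the latent envelope grid
(default 160 Hz) to the signal grid. The exponential link guarantees a
positive envelope; the carrier is recovered afterwards as $c = y / m$, so
the reconstruction identity $m \cdot c \equiv y$ holds to machine
precision by construction.

### Prior spectrum and the timescale constraint

The defining parameter of a demodulation round is `target_rate_hz`, the
fastest rate at which the modulator may vary. We encode it in the prior
spectral density of $x$: a squared-exponential density (lengthscale
$1/(2\pi f_c)$) multiplied by a raised-cosine low-pass gain that is 1
below $0.8 f_c$ and 0 at $f_c$. The multiplicative cutoff matters: the
squared-exponential density alone still passes ~14% of its peak at twice
the nominal cutoff, which lets fast AM leak into a nominally slow
modulator. With the cutoff the constraint is structural — a modulator
*cannot* contain content above its target rate, and our tests verify that
an 8 Hz envelope demodulated at a 4 Hz target leaves under 5% of the
modulator's non-DC power above 4 Hz.

### Optimization

MAP inference is quasi-Newton (L-BFGS-B) in a *whitened* Fourier
parameterization $x = C^{1/2} a$ with $a \sim N(0, I)$, where $C^{1/2}$ is
the circulant filter with gain $\sqrt{S(f)}$. Whitening keeps the Hessian
well conditioned at every cutoff (the raw problem is severely
ill-conditioned because prior eigenvalues span ten orders of magnitude).
The optimizer is initialised deterministically from the log of the
smoothed absolute signal; there is no randomness anywhere in inference, so
a fixed input always yields a bit-identical envelope. The objective trace
is recorded per outer iteration and is non-decreasing; iteration stops
when the relative change drops below `tolerance` (default `1e-5`) or after
`max_iterations` (default 300) quasi-Newton steps. Signals longer than
`chunk_s` (default 10 s) are processed in overlapping chunks whose
log-envelopes are cross-faded over 1 s seams — memory stays O(chunk) and
accuracy at the seams is covered by a dedicated test. A chunk with
essentially zero variance (digital silence) gets a flat modulator at its
mean magnitude and is flagged rather than fitted.

## The recursive cascade

Round 1 demodulates the waveform at a 40 Hz target: its modulator is the
broadband envelope (all AM below 40 Hz) and its carrier holds everything
faster. Each later round re-demodulates the previous round's *modulator*
at the next slower target (12, 4, 1 Hz). Because an envelope is strictly
positive, later rounds operate on its logarithm, where the same GP prior
with a Gaussian observation term is conjugate and the MAP slow/fast split
is available in closed form (a zero-phase GP smoother — mirror-padded to
avoid wrap-around bias). Writing $z = \log m^{(1)}$ and $L_f$ for the
smoother at cutoff $f$:

| band | envelope |
|---|---|
| beta/gamma (phoneme, 12–40 Hz) | $\exp(z - L_{12} z)$ |
| theta/alpha (syllable, 4–12 Hz) | $\exp(L_{12} z - L_{4} z)$ |
| delta (prosody, 1–4 Hz) | $\exp(L_{4} z - L_{1} z)$ |
| low delta (<1 Hz) | $\exp(L_{1} z)$ |

The four envelopes telescope multiplicatively back to the round-1 envelope
*exactly*, so the full product times the round-1 carrier reconstructs the
normalized input to machine precision — far inside the `1e-3` relative-RMS
contract we test. Only the modulator-recursion scheme is implemented;
recursing on the carrier instead would break this exact telescoping and is
a different analysis, not a switch of the same one. The low-delta band
absorbs the overall scale (DC) and is excluded from all rhythm summaries,
since sub-1 Hz structure reflects sentence-level timing rather than
phonological rhythm.

On synthetic nested-AM signals with known ground truth (below), the
recovered delta, theta/alpha and beta/gamma envelopes correlate with their
generating envelopes at median $r \approx 0.96 / 0.90 / 0.84$ under the
default conditions.

## Modulation spectra and "frequency power"

Envelope spectra are plain FFT periodograms of the mean-removed envelope:
no taper, full length, zero-padded to at least 0.1 Hz resolution. The
one-sided power is normalized so that it sums to the envelope's population
variance (Parseval, checked to `1e-6` on every fixture), which makes band
power additive: the *frequency power* of prosody is the summed power of
the delta-band envelope over (1, 4] Hz, and likewise for syllable
(4, 12] and phoneme (12, 40]. A Welch/Hann option was considered and
rejected for the default because summed periodogram power is the only
definition that keeps the Parseval check exact; leakage control matters
only for the band-purity diagnostic (`band_limit_check`), which therefore
does apply a Hann taper. Each rhythm's power is computed from that band's
own envelope; the delta-band power of the broadband product envelope is
available as a cross-check via `modulation_spectrum()` on the product.

Scalograms use an analytic Morlet wavelet ($\omega_0 = 6$) over 0.1–40 Hz
on a log scale axis, in dB with the maximum at 0 dB. The 4-s excerpt is
chosen by a seeded RNG (default seed 0) so a figure is reproducible.

## Transfer entropy between bands

For band envelopes $X$ (slower) and $Y$ (faster),

$$T_{X \to Y} = H(Y_t \mid Y_{t-1:t-L}) - H(Y_t \mid Y_{t-1:t-L}, X_{t-1:t-L})$$

is estimated by the plug-in method on equal-occupancy (quantile) symbols:
`n_bins = 4`, `L = 1`, envelopes resampled to 120 Hz (polyphase,
anti-aliased) so the 12–40 Hz band stays resolved. Quantile binning makes
the estimate exactly invariant to strictly monotone transforms of either
series (ties broken by first-occurrence rank), and the estimator matches
exact enumeration on small Markov chains to within 0.02 bits at
$n = 10^5$. Raw plug-in estimates can be negative by sampling noise; they
are clipped at zero (the population quantity is nonnegative) with the raw
value retained. *Top-down* means slower source, faster target.

Because plug-in TE is biased upward on finite autocorrelated data,
every estimate ships with a circular-shift surrogate null: the source is
rotated by ≥1 s seeded random offsets (19 surrogates by default),
destroying directed coupling while preserving both marginals and
autocorrelation. On independent series the observed TE falls inside the
null mean ± 2 sd about 95% of the time; on a deterministic
one-step-coupled chain it exceeds every surrogate.

Absolute TE values depend on the binning, history length and envelope
rate; only orderings and group contrasts are interpretable, and that is
all the pipeline uses.

## The synthetic generator

No speech corpus ships with the package, so every stage is validated
against a generator with known ground truth:

$$y(t) = [1 + d_p s_p(t)]\,[1 + d_s(t) s_s(t)]\,[1 + d_f(t) s_f(t)]\,c(t) + \varepsilon(t)$$

with jittered oscillations $s_\cdot$ (phase random-walk, rate jitter 10%
of the nominal rate with a one-cycle correlation time — pure sinusoids
would have unrealistically narrow envelope bandwidth), a white or >40 Hz
band-pass carrier, and additive noise at 20 dB SNR. Defaults: prosody
2 Hz / depth 0.8, syllable 6 Hz / 0.6, phoneme 20 Hz / 0.4, 10 s at
2 kHz. A 2 kHz rate keeps ample headroom above the 40 Hz carrier boundary
while making 120-sample cohorts affordable; rhythm information lives below
40 Hz, so nothing scientific depends on the audio rate being 44.1 kHz.

Slow→fast coupling gates the syllabic depth by the prosodic phase (and
phonetic by syllabic) with strength $\kappa$:

$$d_s(t) = d_s \, \frac{1 + (\kappa/2)\, s_p(t)}{\sqrt{1 + \kappa^2/8}}.$$

The $\sqrt{1+\kappa^2/8}$ normalization keeps $E[d_s(t)^2]$ independent of
$\kappa$, so coupling strength and marginal band power are controlled
separately — without it, varying $\kappa$ between groups would smuggle a
band-power difference into groups that are supposed to differ only in
coupling, confounding the two findings the pipeline is meant to separate.

Cohorts emulate the study design: 8 AUT-like and 6 NT-like dyads, one
questioner identity per dyad, four direction labels, durations uniform on
10–30 s. NT-like respondents draw prosody depth from a Beta centred on
0.7 (κ ≈ 0.7), AUT-like on 0.2 (κ ≈ 0.2); syllable and phoneme depths are
drawn from the same distribution in both groups. Per-dyad questioner
depth follows $\alpha + \beta \cdot d_{\text{respondent}} + \text{noise}$
($\beta = 0.9$, noise sd 0.08), inducing the dyadic correlation the
correlation analysis is designed to detect. These presets are qualitative
stand-ins chosen once: the study's real effect sizes are unknown, so
passing tests demonstrate that the pipeline *can* recover contrasts of
this magnitude, not that real AUT/NT speech shows them.

What the generator does **not** emulate: formants, pitch contours, pauses
and fillers, mora timing, reverberation, speaker overlap. Results on real
recordings additionally depend on recording quality and segmentation,
which no synthetic test covers.

## Group statistics

Features are analysed per sample (or per speaker after
`speaker_average()`). The primary group inference is permutation-based: a
group × rhythm interaction F computed from the standard mixed-design sums
of squares, with group labels permuted across units and each unit's
within-factor profile kept intact (999 permutations by default), plus
per-level contrasts with Benjamini–Hochberg adjustment. A
Greenhouse–Geisser-corrected repeated-measures ANOVA is reported alongside
as a parametric reference; permutation was preferred as primary because it
is calibrated by construction (verified: type-I error 5% ± 2% over 500
null simulations) without sphericity or normality assumptions. Band
powers enter the contrast on a log10 scale, since depth differences act
multiplicatively on power.

The dyadic analysis pairs each dyad's questioner mean with its respondent
mean and tests for *positive* association, one-tailed, the method gated by
Shapiro–Wilk on both margins (rank-based Spearman when either departs from
normality). For n ≤ 10 the Spearman p-value is the exact permutation
probability of the rank statistic; larger n use the asymptotic
approximation. At the study's scale of 14 dyads the test detects the
generator's built-in dyadic dependence in well over 80% of seeds, and
rejects at the nominal 5% rate when the dependence is switched off.

## Numerical and degenerate-input policy

- Constant waveform → z-scoring errors ("zero variance"); constant series
  → TE warns and returns 0; constant margin → normality gate errors.
- Negative raw TE → clipped, raw kept in `te_raw_bits`.
- Ties in quantile binning → first-occurrence rank order (stable).
- Envelope positivity is structural (exponential link / telescoping), not
  clamped.
- All RNG flows from explicit seeds; cohort per-sample seeds derive from
  the cohort seed; pipeline re-runs are byte-identical (cached per-sample
  results are the single serialization point, so fresh and resumed runs
  produce the same bytes).

## Problem sizes

Defaults throughout the tests and the acceptance script: 10-s samples at
2 kHz for single-sample checks, 20 seeds for recovery medians, cohorts of
30 samples per group (120 samples, durations 10–30 s) for the pipeline
contrast, 50 seeds for dyad power, 500 simulations for calibration rates.
These sizes keep the full validation suite comfortably on one CPU core
while leaving every conclusion stable under seed changes.

## Known limitations

- PAD here is MAP-only: no posterior uncertainty over envelopes, and
  parameters are set manually per round (no marginal-likelihood learning).
- The carrier model is i.i.d. Gaussian; strongly tonal carriers violate it
  (the demodulation still returns the exact residual, but the prior
  trade-off may shift).
- Plug-in TE values are estimator-relative; compare only within a fixed
  configuration.
- The cascade's band edges are fixed at 1/4/12/40 Hz; other languages or
  speech registers may warrant different edges (configurable, with a
  validation warning).

## A worked example

```{r example, eval = FALSE}
library(speechrhythm)

sy <- synth_generate(synth_spec(duration_s = 10, coupling_kappa = 0.8, seed = 1))
h <- pad_cascade(sy$sample)
h$reconstruction_error            # ~1e-16: exact reconstruction
envelope_recovery(h, sy, "delta") # ~0.96

hierarchy_band_powers(h)
band_pair_te(h, seed = 1)

cfg <- run_config(demo_n_per_group = 10, seed = 1)
res <- run_pipeline(cfg)
res$stats$respondents$rhythm_levels
```
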