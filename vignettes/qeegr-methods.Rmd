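---
title: "Methods: band-power qEEG analysis with nonparametric effect sizes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band-power qEEG analysis with nonparametric effect sizes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qeegr)
```

## The analysis model

`qeegr` analyses resting-state EEG from a mixed design: a between-subject
treatment factor (three arms) crossed with a within-subject visit factor
(baseline, final). The measured quantity throughout is **relative band
power**: for each electrode, the Welch power spectral density is
integrated over the four canonical bands (delta 0–4 Hz, theta 4–8 Hz,
alpha 8–13 Hz, beta 13–30 Hz) and divided by total 0–30 Hz power, giving
four fractions per electrode that sum to one. Zone values are unweighted
means of electrode values over standard 10–20 scalp zones. Relative
power is scale-free — amplifier gain, electrode impedance and reference
scaling cancel — which is why clinical qEEG prefers it over absolute
power. Its flip side is compositionality: the four fractions are coupled,
so an isolated rise in delta necessarily depresses the other three. The
interpretation of "alpha decreased" in such data is always relative.

## Preprocessing

Recordings are downsampled to 512 Hz (polyphase: upsample–FIR–downsample
with a windowed-sinc anti-alias filter), re-referenced to the
instantaneous average of all channels, and notch-filtered at 50 Hz.

The notch is a second-order IIR design (RBJ biquad, quality factor 30).
We apply its **squared magnitude response in the frequency domain**
rather than running forward–backward time-domain passes. The two are the
same linear-phase filter in steady state, but a high-Q IIR carries O(1)
internal state for an O(1) line component, and any padding scheme excites
that state at the pad junction: the resulting ring at the line frequency
decays with τ = 2Q/ω₀ ≈ 0.2 s and leaves several percent of a pure 50 Hz
tone's RMS in a 10-s record (we measured ~5 % for a standard
forward-backward implementation). The state-free spectral application
leaves < 1 % in the worst (non-integer-cycle) case and is exact for
integer cycles. It is applied circularly, without padding: a notch only
modifies the narrow removed band, so circular wrap-around cannot leak
outside it.

The 0.5–40 Hz band-pass is treated as an acquisition property of the
hardware and is only re-applied on request (`apply_bandpass = TRUE`),
implemented as a difference of zero-phase windowed-sinc low-passes.

## Spectral estimation

Welch PSD with 1-second windows and 50 % overlap (so the frequency
resolution is exactly 1 Hz), Hann taper, constant detrend per segment,
one-sided density in µV²/Hz. The exact taper of the originating
toolchain is unverifiable ("default parameters"); Hann is the
leakage-controlled standard and is configurable.

**Band integration.** Each 1-Hz bin is treated as a rectangle centred on
its bin frequency; a band's power is the sum of bin power times the
bin's overlap with the band interval. Bins that straddle a shared band
edge (4, 8, 13 Hz) are split half/half between the adjoining bands. We
adopted this over the half-open-interval convention (`[lo, hi)` with
beta closed at 30) deliberately: with 1-Hz bins the half-open rule
assigns 18 whole bins to the 17-Hz-wide beta band, biasing a flat
spectrum's beta fraction to 18/31 ≈ 0.58 instead of 17/30 ≈ 0.567 — an
error of 0.024 that no detrending choice repairs. The overlap rule
integrates a flat spectrum to exactly c·(hi − lo), keeps the
four-fraction sum at exactly 1 (both conventions do), and brings
white-noise fractions within 0.01 of the bandwidth ratios. The DC bin
contributes (half its width) to delta as defined, but constant
detrending leaves it near zero in practice.

## Cliff's delta

For independent samples, δ is computed from midranks in
O((m+n) log(m+n)): with U the tie-corrected Mann–Whitney count,
δ = 2U/(n_X n_Y) − 1, identical to the mean of sign(Yⱼ − Xᵢ) over all
pairs (ties score zero). The unit tests verify exact agreement with full
pair enumeration over hundreds of tied samples.

The paired variant is the **diagonal sign-mean** (1/n) Σ sign(x₂ᵢ − x₁ᵢ).
A full-matrix "paired" variant also exists in the literature; we chose
the diagonal form because it makes δ·n an integer, and every published
paired δ we use as a consistency anchor (0.6, 0.867, 0.467 at n = 15;
0.474, 0.579 at n = 19) is a 1/n grid point at its arm size — strong
internal evidence for the sign-mean form.

Interpretation labels use the nearest-anchor rule on |δ| against the
conventional anchors 0.2 (small), 0.5 (medium), 0.8 (large): boundaries
at the midpoints 0.1, 0.35, 0.65, with |δ| < 0.1 negligible. The anchors
are approximate by construction ("δ ≈ 0.2 is small"), so any boundary
choice is a convention; midpoints are the deterministic one, and the
thresholds are overridable.

## Nonparametric tests

Within-visit comparisons use Kruskal–Wallis (omnibus, tie-corrected,
chi-square reference) and pairwise Wilcoxon rank-sum tests; pairwise
tests are run regardless of the omnibus outcome, since both layers are
reported. Between-visit comparisons use the Wilcoxon signed-rank test
with zeros dropped (the classic convention; the source analysis states
no rule). Exactness policy: rank-sum p-values are exact for combined
n ≤ 25 without ties; signed-rank p-values are exact without ties for
n ≤ 25 via the signed-rank distribution, and exact **with** ties for
n ≤ 14 via full 2ⁿ enumeration over midranked magnitudes. The tie-aware
path exists because the design's canonical small-sample case — a uniform
shift, all |d| tied — must give the enumerated p = 2/64 at n = 6, which
the classical no-tie shortcut refuses. Larger samples use the normal
approximation with tie and continuity corrections. All tests are
two-sided.

## Resampling mixed-design ANOVA

The omnibus group × visit analysis delegates, in the original toolchain,
to a published resampling-ANOVA package whose internal statistic is not
specified in the analysis description beyond its iteration count and
seed. We therefore implement a documented stand-in with the same design
and contract:

* With two visits the split-plot design decomposes exactly: per-subject
  difference d = V2 − V1 carries the visit and interaction effects;
  per-subject mean s = (V1 + V2)/2 carries the group effect.
* Hypotheses: visit — the unweighted mean of per-group visit effects is
  zero (the factorial main effect, robust to unbalanced arms);
  interaction — per-group visit effects are equal; group — per-group
  subject means are equal.
* Statistics: Wald-type with heteroscedasticity-robust variance-of-mean
  estimates (no sphericity or variance-homogeneity assumptions — with
  two within-levels sphericity is moot, but between-group
  heteroscedasticity is not).
* Null reference: wild bootstrap with Rademacher multipliers on
  group-centred values, `n_iter` draws (default 10 000), p = (1 + #{W* ≥
  W}) / (n_iter + 1). Because squared centred values are sign-invariant,
  bootstrap means and variances have closed forms and the whole null is
  vectorized.
* Reproducibility: a single integer seed (default 20000523) fully
  determines the result; the caller's RNG state is saved and restored.

The contract is design fidelity and type-I calibration — verified by
simulation (null rejection at 0.05 within [0.03, 0.07] for each factor
at 3 × 15 subjects) — not numeric equivalence with any external package.

## Correlations and multiplicity

Each (zone, band) relative power is correlated with each
neuropsychological score by Spearman's ρ, pooling all arms and treating
each subject-visit as one observation (a 2N-row pooling; within-subject
dependence makes these descriptive screens rather than confirmatory
tests, which is how the collapsed view should be read). Missing score
cells are handled by pairwise deletion — each cell keeps its own
complete pairs, and cells with fewer than 3 pairs are flagged
unavailable and excluded from adjustment. Benjamini–Hochberg adjustment
is applied across the entire matrix as a single family. The collapsed
view retains rows and columns containing at least one adjusted p < 0.1.

## The synthetic cohort generator

The generator's defaults state the world the analysis assumes: three
arms of 16/15/19 subjects, two visits, 32-channel 10–20 montage at
1024 Hz. Each channel is 1/f^β background noise (β = 1, band-limited to
the 0.5–40 Hz acquisition passband) plus one narrowband Gaussian
oscillator per band — filtered noise rather than pure sinusoids, so
within-band power has realistic spread. Default oscillator RMS
amplitudes (6, 5, 12, 4 µV for delta/theta/alpha/beta over a 10 µV
background) give the alpha-dominant eyes-closed profile. Amplitudes vary
log-normally: between subjects (SD 0.25), between visits (SD 0.1 per
band), and across zones at the model level (SD 0.05). Treatment effects
are multiplicative amplitude factors per (group, band) at visit 2; the
probability that a band's amplitude rises is Φ(log effect / within-SD),
which is what the parameter-recovery acceptance test inverts. Default
duration is 60 s (not a clinical 5 minutes) for desk-scale runtime;
Welch at 1-s windows is insensitive to this beyond variance.

Scores are a linear function of each subject-visit's realized
whole-scalp relative alpha (positive weight) and delta (negative
weight) plus Gaussian noise, emitted on each test's natural direction —
screening scores (MoCA, Digit Span, PSI, OTS) increase with the latent
ability, time/severity scores (Stroop, TMT, HAM-A, HAM-D, RTI,
Multitasking) decrease — so sign conventions are testable per test
type. CANTAB-style missingness marks the first two subjects' visit-1 and
the next subject's visit-2 CANTAB cells as missing, reproducing the
"2N − 3 complete pairs" bookkeeping.

The generator has two consistent levels. `sample_cohort_band_powers()`
draws the latent amplitudes and returns the implied band powers directly
— this is the model the calibration studies (1000 simulated arms, 20
seeded cohorts) run on, since synthesizing 30 000 full EEG recordings
is not feasible in a test budget. `generate_recording()` realizes time
series from the same latent amplitudes; spectral tests confirm the
realized relative powers track the model. What a green test establishes
is therefore that the *statistics* recover what the *model* injected;
the time-series layer is validated separately for spectral fidelity at
small scale. The generator does not emulate artifacts (blinks, EMG),
nonstationarity, volume-conduction correlations between electrodes, or
lesion topographies — real-data conclusions still require real data.

## Numerical choices and degenerate inputs

* Relative powers: a channel with zero 0–30 Hz power is an error naming
  the channel; the four-band sum is exact to 1e-9 by construction.
* Fully tied rank-sum samples give a degenerate normal approximation;
  the p-value is clamped to 1. All-zero paired differences give p = 1
  with a warning.
* Correlation cells with < 3 complete pairs are excluded from the BH
  family rather than adjusted.
* Subjects missing one visit are dropped from the ANOVA with a warning;
  a group with < 2 complete subjects is an error.
* All seeded routines (`resampling_mixed_anova`, the generator) restore
  the caller's RNG state; CSV/JSON outputs contain no timestamps, so
  identical runs are byte-identical.
* EDF I/O quantizes to 16 bits (format property); the float formats
  (BrainVision IEEE float 32, text matrix) round-trip to ≤ 1e-6 µV.

## Known limitations

* The resampling ANOVA is a calibrated stand-in, not a reimplementation
  of any specific published package; p-values on real data will differ
  in Monte-Carlo detail from other resampling implementations.
* Zone membership for the 32-electrode montage follows conventional
  lobe assignments (TP9/TP10 temporal, PO9/PO10 occipital) and is
  overridable via a JSON zone map; the original study's exact grouping
  was not published in accessible form.
* The pooled correlation screen treats subject-visits as exchangeable
  observations; it inherits the within-subject dependence noted above.
* No ICA or artifact rejection: inputs are assumed de-artifacted
  upstream, as in the clinical workflow this mirrors.
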