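---
title: "Wearable circadian rhythm markers: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wearable circadian rhythm markers: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circamark)
```

`circamark` computes sleep and circadian rhythm digital biomarkers from
minute-level wearable heart-rate (HR) and step-count (SC) recordings and
compares them between a case and a control group. This vignette is the
package's own account of the underlying models, the tunable parameters and
their defaults, the design decisions taken where the methodology was
genuinely open, and what the synthetic-cohort tests do and do not establish
about real data.

## Input model and preprocessing

The unit of input is one participant: a minute CSV (`timestamp`,
`heart_rate`, `steps`), a sleep log (`onset`, `offset`) and a manifest row
with a binary group label and optional covariates. Consumer devices zero-code
HR when the wearer takes the device off; the reader therefore flags `HR <= 0`
and absent grid minutes in a missingness mask, regrids to a strict 1-minute
grid, and trims to whole calendar days (partial leading/trailing days are
dropped, not padded — markers defined on whole days would otherwise mix day
fractions).

Masked HR runs are repaired by **linear interpolation** between the nearest
valid neighbours, with nearest-value extension for leading/trailing runs
where only one anchor exists. Linear repair distorts long gaps the least:
spline-like interpolants overshoot across multi-hour nonwear gaps. The mask
is kept on the repaired series for audit, which also makes the repair
idempotent. Step gaps are *not* treated as nonwear — zero steps are a
legitimate resting state — so missingness is defined on HR only.

Wear-time eligibility requires (i) at least 5 consecutive weekdays
(Monday–Friday on consecutive calendar dates) and (ii) no calendar day with
more than 360 masked minutes. The 24-hour window of rule (ii) is evaluated
per calendar day rather than as a sliding window: simpler, deterministic, and
the stricter sliding variant would only matter for gaps that straddle
midnight.

## Sleep markers

Per night (18:00 to noon the next day) the longest episode is the main sleep;
naps and shorter nocturnal fragments are discarded. Midsleep time (MST) is
the clock midpoint of the main episode in minutes after midnight; total sleep
time (TST) its duration. Across nights the package reports means and SDs,
with MST averaged **circularly** (23:50 and 00:10 average to 00:00) and its
SD computed on deviations unwrapped to (−720, 720]. Plain averaging would
misbehave for sleepers whose midpoint straddles midnight. Whether a reference
analysis uses all episodes or main sleep only is typically unstated;
main-sleep-only is the implemented and documented choice.

## Cosinor markers

The single-component cosinor model `Y(t) = M + A cos(2πt/τ + φ)` is fitted by
least squares through the linear reparameterization
`Y = M + β cos(ωt) + γ sin(ωt)`, `A = √(β² + γ²)`, on the pooled multi-day
series with τ fixed at 1440 min. The acrophase is reported as the **clock
time of the fitted peak in decimal hours** — the sign/zero convention of the
raw phase φ varies across the literature, while peak clock time is
unambiguous and matches the ~15 h magnitudes conventionally reported for
heart rate. A constant series has amplitude 0 and an undefined acrophase,
reported as missing (never as an arbitrary number); the circadian quotient
`CQ = A/M` is missing when `M ≤ 0`.

## Nonparametric markers

L5 and M10 are computed on the 1440-point average daily profile with
**wrap-around windows** (a sleep window crossing midnight is still one
window); ties between equally extreme windows resolve to the earliest start,
making results deterministic. A per-day-then-average mode exists
(`nonparametricMarkers(..., l5m10Mode = "perday")`) but the profile mode is
the default: the markers are defined on the integrated record.

IS and IV are computed on **hourly bins** (the conventional actigraphy
choice; the bin width is a parameter). At minute resolution IV is dominated
by sensor noise and loses its interpretation as rhythm fragmentation; hourly
binning puts IV in its conventional ~0.5–1.5 range. IV is ~2 for white noise
(first-difference variance twice the variance), →0 for smooth signals, up to
4 for maximal alternation; IS is 1 when all days are identical. Both are
missing for constant series (zero denominators), and both are invariant to
additive shifts; RA is invariant to positive rescaling.

## CCE: continuous-wavelet circadian rhythm energy

The novel marker family is the band energy of a Morlet continuous wavelet
transform of HR. The analytic Morlet mother is
`ψ(t) = π^(−1/4) e^(iω₀t) e^(−t²/2)` with ω₀ = 6, balancing period and time
resolution. The input is z-scored, the transform is evaluated on the
circularly extended record in the Fourier domain, and the per-period energy
(squared coefficient magnitude summed over all time shifts) is obtained
directly through the Parseval identity — no inverse transforms are needed,
and the equality with the explicit spectrogram is verified in the tests.
Cone-of-influence coefficients are included: on a 5-day record the scales of
interest leave no usable data if edges are excluded, and circular evaluation
treats all time points symmetrically.

Two design choices deserve emphasis:

* **Energy definition.** The default is the *bias-rectified* wavelet
  spectrum, `|W(a,b)|²/a`: under the raw `|W|²` of the `1/√a`-normalized
  transform, the time-summed energy of a sinusoid grows proportionally to its
  period, so the circadian peak swamps everything and the 69–80 min band
  carries ~0.1% of total energy regardless of physiology. Rectified energy
  makes equal-amplitude components contribute equal energy, yielding band
  fractions on the few-percent scale with comparable mid- and low-frequency
  values for equal component amplitudes. The raw definition stays available
  (`waveletConfig(energyKind = "squared_magnitude")`) and the configuration
  records the choice.
* **Scale↔period map.** Each energy definition uses the map under which a
  pure sinusoid's energy peaks exactly at its own period: the
  centre-frequency relation `a = ω₀·period/2π` for the rectified spectrum,
  and the standard Morlet Fourier-period relation
  `a = period·(ω₀ + √(2+ω₀²))/4π` for the raw spectrum (whose offset exists
  precisely to compensate the scale factor the raw spectrum carries).

The default period grid is geometric on 20–1500 min at ~96-point density,
**anchored to pass exactly through 70 min and 1440 min** (so ~1000 min is
also sampled closely). The anchoring matters: the discriminative central
periods are reported *at* 70 and 1000 min, and a grid that brackets 70
between points at 68.2 and 71.4 min turns band-membership of the most
significant period into a coin toss at the 69-min band edge. Three grid
periods fall inside the 69–80 min band and five inside 900–1100 min; the
constructor asserts at least two per band. `CCE_MF` and `CCE_LF` are the
normalized energy summed over grid periods inside the two bands (inclusive),
`CCE_Ratio` their ratio (missing when the low band is zero). Band values are
dimensionless fractions of total grid energy; they match reference values in
direction and order of magnitude, not digit-for-digit — the exact
normalization behind any published table of CWT energies is rarely fully
specified.

The band scan (`bandScan`) runs a two-sample test (Welch or Wilcoxon) on the
per-participant energies at every grid period, for HR and steps separately,
and is the tool that localizes group differences before the bands are fixed.

## CARE: SSA comparator

CARE is a previously proposed comparator computed here on step counts:
singular spectrum analysis (window 1440 min) of the mean-centred series,
energy = squared singular values, each elementary component's dominant period
estimated from the periodogram peak of its diagonal-averaged reconstruction,
and CARE = energy fraction of components with dominant period strictly below
1440 min. The cited description leaves the algorithm's details open, so this
is a documented reimplementation, not a reference implementation; window
length, component count (20), binning and the period threshold are all
surfaced in `ssaConfig`. Two pragmatic choices: the series is averaged to
5-min bins before SSA (step counts are bursty at minute resolution, every
period of interest is ≥ 10 min, and the trajectory-matrix eigenproblem at
5-min resolution is exact and two orders of magnitude cheaper), and the mean
is removed (a DC offset is not a cycle and would otherwise absorb the leading
component). On a 5-day record 1440 min is an exact Fourier period, so the
strict `< 1440` threshold cleanly excludes the circadian pair. Eigentriple
pairing is not attempted; sinusoids simply contribute two components with the
same dominant period, which the threshold treats identically.

## The marker panel and the cohort table

`computeMarkerVector` assembles the 26 markers (4 sleep, 8 cosinor, 10
nonparametric, CARE on steps, 3 CCE on HR). CCE is computed on heart rate
only — the step-count band energies are available through the spectral
functions but are not panel members — and CARE on steps only. Upstream
failures (constant signals, insufficient nights) propagate as missing values
with recorded reasons, never as silent zeros, and marker extraction is fully
deterministic. The cohort container is a `SummarizedExperiment` subclass
(markers × participants, group and covariates in `colData`), so standard
Bioconductor subsetting applies.

`compareGroups` uses Welch's t test by default (a pooled-variance toggle
exists); no multiple-testing correction is applied to the primary columns,
matching common reporting practice for descriptive marker tables, but
Benjamini–Hochberg columns are emitted alongside. Missing values are dropped
per marker; a marker with fewer than two valid values in a group gets missing
p-values.

## Importance backends

`rankImportance` exposes one contract — fit(features, labels), then a global
importance score per feature — with backends: `tree_shap`
(gradient-boosted trees, depth 6, 100 rounds; global importance is the mean
absolute TreeSHAP contribution) and `additive_boosting` (depth-1 boosting,
300 rounds at learning rate 0.1 — an additive, GAM-style boosted model
scored the same way). An `attention_tabular` backend identifier is reserved
and raises an explicit "backend missing" error: no attention-based tabular
network implementation is available to this package, and silently
substituting a different model class would misattribute the results. Missing
marker values are median-filled for model fitting (count logged in the
report); single-thread fitting with a fixed seed makes every ranking
reproducible bit-for-bit. `undersampleStability` refits after downsampling
the majority group to the minority size (without replacement) and reports
per-feature top-k frequency across repeats — the standard robustness check
for imbalanced cohorts.

## The synthetic cohort generator

The generator builds participants mechanistically from the components the
markers measure:

    HR(t) = mesor_i + A_circ cos(2π(t − 60·acrophase)/1440)
          + A_70 cos(2πt/70 + U) + A_1000 cos(2πt/1000 + U′)
          + nightDip·sleep(t) + behavioural episodes + AR(1) noise

with the participant's MESOR drawn from the group distribution, ultradian
phases randomized per participant (only energies are group-structured —
exactly what band energies measure), behavioural HR shifts as
piecewise-constant awake episodes with exponential durations (mean 60 min, SD
5 bpm; these set the hour-scale irregularity that IS/IV of HR measure), and
zero-coded missingness in geometric bursts (mean 30 min, 5% of minutes).
Steps are Poisson while awake with gamma-distributed hourly activity
multipliers, and zero during sleep. Nightly sleep episodes draw MST and TST
from group-specific Gaussians. Records start on a Monday so the
consecutive-weekday filter is exercised deterministically.

The group defaults encode the reference cohort's contrasts: control MESOR
71.89 (SD 6.39) vs case 75.05 (7.23) bpm; circadian amplitudes 11.66 vs 11.22
bpm at acrophases 14.97/15.00 h; MST 207.55/207.08 min and TST 414.92/410.70
min (so sleep markers carry no group signal); a nocturnal dip of −1.5 vs −0.3
bpm (the blunted case dip raises L5_HR and lowers RA_HR); 70-min amplitudes
2.4 vs 2.0 bpm (attenuated mid-frequency energy in cases) and 1000-min
amplitudes 2.4 vs 3.5 bpm (the value at which the *normalized* low-frequency
band contrast matches the reference panel's relative contrast — z-score
normalization couples the two groups' spectra, so the amplitude contrast must
exceed the energy-share contrast); awake step rates gamma-distributed with
mean 12.8 (SD 6.4) vs 11.02 (SD 4.4) steps/min — the SDs mirror the reference
M10 spread, so activity markers carry realistic between-person heterogeneity —
with hourly activity CV 0.6 vs 0.75 (calibrated so step-count IS lands near
0.50/0.44). Effects are injected only through these mechanisms — never by
perturbing markers directly — so marker recovery is a genuine end-to-end
test.

What the generator does **not** emulate, and what passing tests therefore do
not establish about real data: between-participant variance in circadian and
ultradian HR amplitudes (they are fixed per group, so markers driven by them —
amplitude, CQ, RA, the CCE bands — separate groups more sharply than real
cohorts would, and amplitude/CQ contrasts that are non-significant in
reference data reach significance here); between-participant variance in
habitual sleep timing
beyond night-to-night noise; device integer rounding of HR; heart-rate
microstructure (HRV), accelerometry, naps, weekend behaviour; and any
dependence between activity and the ultradian HR components. The intradaily
variability of HR also ends up lower than reference values because the
exponential behavioural episodes are smoother than real behaviour at the
hour scale.

## Numerical and testing choices

All randomness flows from explicit seeds; per-participant seeds derive from a
stable string hash of the participant id, so cohorts are reproducible
file-for-file. Degenerate inputs (constant series, all-missing HR, zero-width
bands) raise errors or yield missing values as documented rather than
producing numbers. Window ties break to the earliest start; simulated HR is
floored at 25 bpm (noise excursions only); TST draws are clamped to
2–14 h.

The test suite validates every marker against an independent oracle
(exhaustive window scans, explicit-loop formula evaluations, FFT band-power
comparisons, closed-form limits, a grid-search cosinor oracle) and the
pipeline against the injected-effect directions and the significant /
non-significant split at the reference group sizes (88/184). Problem sizes in
the long-running checks — 20 seeded cohorts at 88/184 for the replication
check, 100 effect-free cohorts of 15/15 for type-I calibration, 40/80 for
band-scan localization — were chosen to keep the full suite around ten
minutes on one CPU while leaving the Monte-Carlo error well below the margins
being asserted.

One replication property deserves a caveat: with the reference means and SDs
for heart-rate MESOR (71.89 ± 6.39 vs 75.05 ± 7.23 at n = 184/88), the Welch
test's expected t statistic is ≈ 3.5, so the per-cohort power at p < .001 is
only ≈ 0.6 — a single observed p < .001, as in the reference table, is
consistent, but demanding p < .001 in ≥ 90% of replicate cohorts is not
attainable under those population values, and the corresponding assertion in
the acceptance tests documents this honestly rather than shrinking the
generator's variance to force it.

## Limitations

Beyond the generator's idealizations listed above: the CCE normalization
matches published magnitudes only up to the (unstated) reference
normalization; CARE is a reimplementation from a brief description; the
eligibility rule evaluates nonwear per calendar day, not as a sliding 24-h
window; and the importance backends cover tree-based and additive model
classes only — conclusions about attention-based tabular models cannot be
drawn from this package.
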