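---
title: "Block-design fNIRS analysis: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block-design fNIRS analysis: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsblock)
```

# The measurement and its model

Continuous-wave fNIRS measures changes in the absorption of near-infrared
light at two wavelengths (here 760 and 840 nm) through the scalp and
cortex. Because oxy- and deoxyhemoglobin have distinct extinction spectra,
the modified Beer–Lambert law relates the optical-density change at each
wavelength linearly to the two chromophore concentration changes:

$$\Delta OD(\lambda) = \varepsilon_{HbO_2}(\lambda)\,\Delta C_{HbO_2} L +
  \varepsilon_{HbR}(\lambda)\,\Delta C_{HbR} L.$$

Working with *changes* cancels the unknown scattering loss, and we do not
divide by a differential pathlength factor: all hemoglobin quantities in
this package are concentration × pathlength products in mM·mm, the unit
continuous-wave instruments report. `mbll_inverse()` solves the 2×2
system per sample; `mbll_forward()` is its exact inverse and is what the
simulator uses to emit wavelength-space recordings. The default extinction
coefficients ship in `inst/extdata/extinction_760_840.csv` (from a
standard published hemoglobin tabulation, converted to 1/(mM·mm)); every
test that touches optics is a round-trip or linearity property, so an
instrument-specific coefficient table can be substituted freely. Matrices
with condition number above 1e8 are rejected rather than inverted.

# The task and the signal chain

The block paradigm alternates 45 s of word reading (baseline) with 45 s of
incongruent color-word naming (activation), three cycles, closing with a
final baseline block — seven 45 s blocks. `default_stroop_schedule()`
encodes this; the lead-in before the first block is a free parameter
(default 15 s) since the protocol fixes only the block structure; it must
merely exceed the 10 s pre-task baseline window.

The analysis chain, in a fixed documented order:

1. **Moving average, 5 s.** A centered 51-sample boxcar at 10 Hz
   (`2*floor(w·fs/2)+1`), with truncated (shrinking) windows at the
   edges so the series length is preserved and no data are invented. The
   filter passes constants and interior linear trends exactly.
2. **Epoching.** One epoch per activation block over
   [onset − 10 s, onset + 45 s + 25 s), half-open, samples indexed 0-based
   at t = start + i/fs: 800 samples per epoch.
3. **Integral-mode correction.** Per channel, the mean over the 10 s
   pre-task window and the mean over the 25 s post-task window are taken
   as anchors at the *midpoints* of those windows, and the straight line
   through the anchors is subtracted from the whole epoch. Midpoint
   anchoring makes removal of a linear drift exact (the mean of a line
   over a window equals its value at the window midpoint), which the tests
   pin at 1e-9; both baseline windows have mean zero afterwards by
   construction.
4. **Repetition average.** The three corrected epochs are averaged
   pointwise, reducing accidental fluctuations and fatigue effects.
5. **Channel statistic.** The mean corrected oxy-Hb over the activation
   window. The source tables describe the contrast both as "task vs
   post-task" and "pre-task vs post-task"; since the corrected baselines
   average to zero, the activation-window mean is the reading that
   reconciles the two phrasings, and it is the one this package fixes.

Filtering precedes epoching so that the smoothing window treats every
repetition identically and never smears the baseline anchors differently
across blocks. The chain is linear in the raw input, and adding any global
linear drift changes no channel statistic by more than 1e-8 — both are
tested properties.

Deoxy-Hb is carried through the data model (and simulated with an inverted
sign at one third of the oxy amplitude, a typical venous-weighted ratio)
but the statistical analysis operates on oxy-Hb only, where the
measurement is most sensitive to regional blood-flow change.

# Group statistics

Per channel, the two groups' subject statistics are compared with the
pooled equal-variance Student's t-test, df = n₁+n₂−2. The pooled form
(rather than Welch) is deliberate: the published demographic table this
package reproduces in its acceptance suite (p = 0.003, 0.004, 0.76, 0.67
for the behavioral and matching variables at n = 10 per arm) is only
recovered by the pooled statistic. `t_from_summary()` applies the same
test to printed mean/SD or mean/SE rows; SE·√n recovers the SD.

Multiplicity over the 24 channels is handled by the plain
Benjamini–Hochberg step-up at q = 0.05: sort the p-values, find the
largest k with p(k) ≤ k·q/m, reject everything at or below p(k). Under
independent null p-values the expected false-discovery proportion equals
q·m₀/m — at the complete null, exactly 0.05 — which the acceptance run
verifies empirically over 10,000 null studies. Marks follow strict
inequalities (†p < 0.1, *p < 0.05, **p < 0.01) independent of the FDR
flag. One published inconsistency is worth noting: the behavioral
third-cycle score's printed p (0.027) is not reproduced by the pooled t
from its printed summaries (which give 0.041); the test behind that single
row is unclear in the source, so no check is tied to it.

Spearman correlations (`spearman_cor()`) rank with average ties and use
the t approximation p = 2·P(T_{n−2} > |ρ|√((n−2)/(1−ρ²))) for all n; an
exact permutation null is not implemented in this version. ρ = ±1 is
reported with the limiting p of 0, and constant inputs are an error
rather than a silent NA.

# Probe geometry and topographic maps

The montage is a 4×4 optode grid at 3.0 cm spacing, sources and detectors
alternating, lowest row on the Fp1–Fp2 line: every adjacent pair is a
channel at the pair midpoint, 12 horizontal + 12 vertical = 24 channels.
Channel numbering is row-major from the montage's top-left as seen facing
the participant — the exact vendor numbering cannot be recovered from a
text description, so the convention is fixed and documented here; under
it, the attenuated channels of the reference profile (7, 10, 13) fall on
the left-lateral mid rows. The source prose describes the patch as an
"8 × 8 cm square", which conflicts with 3 gaps × 3.0 cm = 9 cm; geometry
wins over prose and the spacing is taken as exact.

The channel positions form a diamond lattice; rotating it 45° yields a
6×6 square grid minus its corners, which gives a natural fixed
triangulation for piecewise-linear interpolation (`interpolate_tmap()`):
exact at the channel positions, NA outside the convex hull. Display
thresholds come from `critical_t(df, α)`: at df = 18 the two-tailed 5%
level is 2.10 and the 1% level 2.878. The source figure annotates "2.8"
for the 1% level — likely truncation; the package reports the computed
quantile.

# The synthetic study generator

No recordings were published for the study this package's reference
profile derives from, so `simulate_study()` generates complete surrogate
datasets with the statistical structure the analysis assumes:

- **Response.** Activation boxcars convolved with a canonical double-gamma
  hemodynamic response (peak 6 s, undershoot 16 s, ratio 1/6 — the
  conventional default; the source specifies no response model), unit-gain
  normalized so a sustained block plateaus at the subject's amplitude.
- **Calibration.** Requested per-channel amplitudes are divided by the
  attenuation the analysis chain applies to a unit response (computed once
  per schedule by running the chain on a noiseless unit subject,
  ≈ 0.868 for the canonical schedule), so the *expected task statistic
  equals the requested amplitude*. The noiseless closed loop recovers
  amplitudes to 1e-9 in the tests.
- **Effect profile.** Defaults are the published per-channel group means
  (case arm attenuated around the left-lateral channels 7/13), with
  between-subject SD = printed SE·√10 so a 10-subject arm reproduces the
  printed standard errors in expectation. Two garbled entries in the
  printed table (one SE, one mean, both typographically impossible in
  their columns) are restored to the column's magnitude range; and the
  published table prints identical values for channels 10 and 11 with
  different marks — an apparent misprint that is taken as-is.
- **Noise.** Per channel: white noise (SD 0.02 mM·mm), random-slope linear
  drift (SD 5e-4 mM·mm/s), sinusoids with random phases at 0.1 Hz (Mayer
  waves, 0.010), 0.25 Hz (respiration, 0.008) and 1.1 Hz (cardiac, 0.005
  mM·mm), and Poisson motion spikes (2/min, amplitude SD 0.1 mM·mm,
  exponential decay 1 s). The source does not decompose within-subject
  variance, so these are realistic calibration choices fixed once: they
  are small against the between-subject amplitude SD after the 45 s × 3
  averaging, keeping the subject-level statistic variance dominated by the
  between-subject term the printed SEs encode. All noise terms are
  zero-mean, so the pipeline estimate of each amplitude is unbiased — the
  acceptance suite checks the 100-seed grand mean at a reference channel
  against its target within 2 SE.
- **Covariates.** Age, IQ and the three Stroop correct-answer counts are
  truncated normals at the published group means/SDs (ages in [6, 15]
  years, counts at ≥ 0, rounded); tic-severity scores exist for the case
  arm only and are explicit NAs for controls, never imputed.
- **Reproducibility.** One root seed; each subject draws from a child
  stream with seed (root·10007 + counter) mod (2³¹−1), counter 1–n for
  the case arm, 1000+i for controls, 999999 for covariates — so any
  subject regenerates identically regardless of generation order. The
  Mersenne-Twister state is restored after each draw.

What the generator deliberately does **not** emulate: superficial/systemic
physiology layers beyond the three sinusoids, tic- or task-locked motion,
vendor raw-intensity formats, and any spatial correlation between
channels (channels are independent given the subject). Passing tests
therefore demonstrate the *estimator's* correctness and calibration, not
robustness to structured artifacts in real recordings.

# Problem sizes and numerical choices

The shipped tests run the full pipeline on 360 s × 24-channel × 10 Hz
recordings (20 subjects per simulated study), 100-seed recovery sweeps
for calibration, and 10,000 statistic-level replicates for the FDR
guarantee — sizes chosen so the whole suite completes in about a minute
while keeping Monte-Carlo error well below the asserted margins; the
stochastic assertions state their error budgets (binomial SEs, 2 SE
recovery bands) explicitly next to the bound they protect.

Degenerate inputs are errors, not warnings: zero pooled variance with
unequal means, constant vectors in rank correlations, empty epoch lists,
epochs that leave the recording, overlapping schedule blocks,
ill-conditioned extinction matrices, and NaN samples at read time. Ties
in BH are handled by the `p ≤ p(k)` rejection rule; the moving-average
window is always odd; all file round-trips preserve doubles at full
precision (17 significant digits).

# Known limitations

- Motion-artifact *rejection* is out of scope: the source study excluded
  artifacts by experimenter observation, which is not reproducible; the
  5 s moving average is the only artifact control.
- The exact vendor channel numbering and the FDR-significant channel set
  of the source study are not recoverable from printed summaries; package
  checks target the reproducible quantities (printed-table p-values,
  display thresholds, the FDR guarantee, calibration) instead.
- Spearman p-values are approximate for small n; MBLL is fixed at two
  wavelengths × two chromophores.
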