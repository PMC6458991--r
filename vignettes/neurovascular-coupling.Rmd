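---
title: "Methods: simulating and estimating neurovascular coupling from MEG and dual-echo ASL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and estimating neurovascular coupling from MEG and dual-echo ASL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nvcouple)
```

## The problem

Neurovascular coupling is the mechanism by which local neuronal activity
drives proportional changes in cerebral blood flow. `nvcouple` operationalizes
it the way a combined MEG–fMRI contrast study does: the same reversing
checkerboard is shown at five Michelson contrasts (6.25, 12.5, 25, 50, 100%),
the electrophysiological response is summarized as the stimulus-induced
percent change in gamma-band (30–80 Hz) power at the visual-cortex source, the
hemodynamic response as the percent change in BOLD and in perfusion (CBF), and
coupling as the slope of the per-subject regression of the hemodynamic measure
on the gamma measure across the 10 (contrast × eye) points. Group structure —
e.g. a patient group with reduced responses but intact median coupling — is
then probed with exact Mann–Whitney tests, Holm–Bonferroni correction, and
mixed ANOVAs with Greenhouse–Geisser (GG) correction.

Because no human data ship with the package, a first-class synthetic cohort
generator produces every input with known ground truth, and the test suite is
built around round-trip recovery of those truths.

## Study design encoded in the generators

`make_schedule()` produces the 14-min block design: four 30-s blocks per
contrast plus eight 30-s rest blocks (28 blocks, 840 s), pseudorandomized as a
deterministic function of the seed so that the MEG and fMRI runs of a subject
share one order. The checkerboard reverses every 250 ms, so each 1-s analysis
trial spans four reversals.

`subject_truth()` draws one subject's ground truth around `group_params()`
population values. The contrast–response curve is Naka–Rushton,
$r(c) = \mathrm{floor} + r_{\max}\, c^n / (c^n + c_{50}^n)$ — the design only
requires a monotone saturating law, and this is the standard parametric choice
in contrast vision; it is fully configurable. Patient defaults implement the
qualitative group pattern: gamma $r_{\max}$ reduced (18 vs 30%), so the
deficit grows with contrast (a group × contrast interaction); BOLD and CBF
$r_{\max}$ reduced by about a third (main effect); coupling slopes with equal
medians (0.035 %BOLD per %gamma) but 2.5× the between-subject spread; baseline
CBF (55 ± 10 ml/100 g/min) and evoked latency (120 ± 10 ms) indistinguishable
between groups. These values were fixed once, from the magnitudes such
experiments typically report, and are not tuned.

## MEG: forward model, beamformer, gamma statistic

The conductor is a homogeneous sphere (radius 9 cm) and the lead field is the
closed-form current-dipole-in-sphere solution; radial moments are silent, and
the radial field component equals the infinite-medium dipole field, which the
tests use as an exact oracle. The sensor array is a deterministic Fibonacci
cap of 60 radial point magnetometers at 10 cm — a reduced, license-free
stand-in for a whole-head axial gradiometer system.

Each grid location's free-orientation lead field is reduced to the dominant
SVD orientation; LCMV weights are
$w = C_r^{-1}L / (L^\top C_r^{-1} L)$ with $C_r = C + \lambda\,
\overline{\mathrm{diag}(C)}\, I$, $\lambda = 0.05$ by default (the
regularization level is not prescribed by the design; 5% of mean sensor
variance is a common default). The covariance pools all trials, band-passed
30–80 Hz with a 4th-order zero-phase Butterworth filter. The percent-change
map is $100\,(P_\text{stim} - P_\text{rest})/P_\text{rest}$ with the peak
searched inside a posterior "visual cortex" mask, ties broken at the lowest
linear index.

Two generator choices make this scan well-posed, and they are worth stating
because they are genuine modeling decisions rather than conveniences:

* **Source orientation.** The simulated dipole points along the SVD-dominant
  orientation of its own lead field — the orientation the array sees best and
  exactly the one the inverse model assumes. With an arbitrary tangential
  orientation, part of the source is invisible to the single-orientation scan
  and localization degrades.
* **Background activity.** With a single source and no other signal, the
  stimulus/rest percent-change map is analytically flat: every location's
  stimulus and rest power scale by the same leakage factor. What localizes
  the contrast in real data is that rest power elsewhere comes from *other*
  brain activity and instrument noise. The generator therefore includes 12
  seeded background dipoles with white activity, identical in stimulus and
  rest, whose in-band power is about a quarter of the source's rest power —
  a realistic interference budget for a peak visual gamma response. Two
  degenerate regimes are worth knowing about: with background but exactly
  zero sensor noise, the spatial structure of the rest-power denominator
  biases the argmax by up to ~1.7 grid spacings; with neither background nor
  noise, the map is flat and the peak undefined. At the generator's default
  acquisition conditions the peak localizes node-placed in-mask dipoles
  exactly, degrading gracefully to a median error of ≤ 2 spacings at unit
  SNR — both properties are under test. For dipoles jittered off the grid a
  further discretization effect appears: the discrete peak occasionally
  lands on a second-nearest node whose SVD orientation aligns better with
  the source, so off-grid error can reach ~1.4 spacings.

The time–frequency statistic follows the peak-gamma readout: a Hilbert filter
bank (centers 30–80 Hz in 2-Hz steps, ±4 Hz Butterworth bands applied
forward–backward — zero phase, 4th-order effective from order 2 per pass —
with 200-ms reflective padding) gives per-trial amplitude envelopes; stimulus
envelopes are trial-averaged and expressed as percent change from the
time-and-trial-averaged rest envelope per bin; the 1-s trial is split into
four 250-ms reversal windows; each window's time-averaged spectrum is
maximized over frequency (signed maxima, possibly at different bins per
window — a `fixed_freq` flag forces one bin); the statistic is the mean of
the four maxima. Baseline gamma power is the grand mean rest envelope over
30–80 Hz.

Three numerical guards make this statistic well-behaved on short, per-trial
filtered epochs, and all three were chosen from the filter physics rather
than any particular dataset: (i) the per-pass order is 2 because order 4 per
pass rings roughly twice as long at band-edge bins of a 1-s trial; (ii) the
first and last 200 ms — the pad length and over one settle time of a ±4-Hz band — are excluded
from all time averages, since a rest baseline diluted by edge-depressed
samples would inflate every percent change by 2–3 points; (iii) the
per-window maximum only considers bins whose rest baseline is at least 25%
of the strongest bin's: a percent change over an unsupported baseline (the
stopband residue of a narrowband source) is unbounded and meaningless, while
realistic rest spectra never vary enough across 30–80 Hz for the guard to
bind. With these, the noise-free round trip recovers an injected amplitude
change to about one percentage point at any admissible peak frequency.

One property of this max-over-frequency readout deserves note: with few
trials it acquires a small positive bias (the maximum of noisy per-bin
estimates), which is scale-invariant and common to all conditions and groups,
so contrasts and group comparisons are unaffected; noise-free recovery is
exact to filter ripple (tested at ±2 percentage points). Desk-scale pipeline
runs thin each 30-s block to a few 1-s trials, so their absolute gamma values
carry this offset; full 30-trial blocks reduce it.

Evoked analysis re-epochs stimulus data around each reversal (−0.04 to 0.21 s,
half-open, so a 0.25-s window is exactly 150 samples at 600 Hz), averages,
low-pass filters at 15 Hz (4th-order zero-phase Butterworth — order/type are
not prescribed, so a standard choice is documented), baseline-corrects on
[−0.04, 0), and reads the latency of the maximum *absolute* deflection in
(0, 0.21] (field polarity is orientation-dependent); ties break earliest.
Sensor space averages the five most posterior sensors; source space uses the
beamformer weights at the gamma peak.

## Dual-echo ASL: BOLD/perfusion separation and baseline CBF

The task acquisition is TR 2.2 s, 191 tag–control pairs (382 volumes per
echo), on a reduced 12×12×6 voxel grid (configurable); the analysis ROI is the
set of voxels with injected activity, standing in for a functionally defined
group ROI. BOLD is isolated from echo 2 by nearest-neighbor surround
averaging, kernel (½, ¼, ¼) with single-neighbor endpoints — this cancels any
pure alternating component exactly and passes constants and linear trends at
interior samples. The GLM contains five HRF-convolved condition boxcars
(double-gamma HRF: peak 6 s, undershoot 16 s, ratio 1/6), a ±½ alternation
regressor, the five condition × alternation interactions that carry the
perfusion responses, an intercept, and a discrete-cosine drift basis with a
90-s high-pass cutoff (the GLM equivalent of pre-filtering; high-order global
polynomials over 382 volumes are ill-conditioned).

Percent signal change uses the peak-to-baseline regressor-range convention:
$100\,\hat\beta\,\mathrm{range}/\text{baseline}$, where the baseline is the
intercept beta for BOLD and the alternation beta — the perfusion-weighted
baseline — for CBF. Because echo 2 is surround-averaged, its condition
regressors receive the same kernel (matched preprocessing of data and model);
with that, noise-free round-trip recovery is exact to machine precision. Eye
runs are analyzed separately and averaged afterward for the ANOVA inputs,
while coupling fits keep the per-eye points.

Baseline perfusion uses the QUIPSS II single-subtraction kinetic model
$$\Delta M(TI) = 2 M_{0b}\,\alpha\, f\,\min(TI - \Delta t,\ TI_1)\,
e^{-TI/T_{1b}},\qquad TI \ge \Delta t,$$
with $f = \mathrm{CBF}/6000$ converting ml/100 g/min to s⁻¹, $TI_1 = 0.7$ s,
$T_{1b} = 1.6$ s, inversion efficiency 0.98 (literature constants,
overridable). A two-compartment formulation is sometimes cited for such fits;
since no equations are printed for it, the standard single-compartment model
is the default here and the extension is a documented seam. $M_{0b}$ is
calibrated from a CSF region of the calibration volume via a single
correction ratio (default 0.87). The fit is bounded nonlinear least squares
over (CBF, $\Delta t$) with a multi-start over arrival times
{0.2, 0.5, 0.8, 1.1} s, because the piecewise model has local minima in
$\Delta t$. The 9-TI protocol (0.4–2.0 s) with ascending-slice TI increments
of TR/(2·n_slices) per slice is what `simulate_multiti()` emulates; fitting
ROI means at the ROI's mean effective TI introduces a small (<0.5%)
linearization bias that the tests budget for. Baseline CBF converts the
fractional task change to absolute units: $\Delta\mathrm{CBF} =
\mathrm{pct}/100 \times \mathrm{CBF}_0$.

## Coupling and group statistics

`fit_coupling()` is ordinary least squares of the hemodynamic measure on peak
gamma percent change over the subject's 10 points (fewer are accepted with a
warning — e.g. a subject with one unusable eye contributes 5). Three measures
are fitted per subject: BOLD %, CBF %, and absolute CBF change.

`mannwhitney_exact()` computes U from mid-ranks and, for combined n ≤ 25, the
exact permutation distribution of the rank sum by dynamic programming over
the (possibly tied) rank multiset — equivalent to enumerating all
$\binom{n}{n_1}$ labelings, which the tests verify exhaustively for all
$n_1, n_2 \le 7$. The two-tailed p doubles the smaller tail, capped at 1 (the
tail convention is not dictated by the design; this is the common one and is
stated). Beyond n = 25 a tie-corrected normal approximation with continuity
correction takes over and is labeled as such in the result.

`holm_bonferroni()` implements the step-down schedule: threshold
$\alpha/(m - i + 1)$ at sorted rank $i$, rejection stops at the first failure,
and tied p-values share the most stringent threshold of their tie block. On
the study's 14 acuity p-values this reproduces the printed per-rank
thresholds 0.004, 0.025 and 0.05.

`mixed_anova_gg()` computes the balanced split-plot decomposition from
explicit sums of squares (cross-checked against `aov()` with an error
stratum), estimates GG $\hat\varepsilon$ from the pooled within-group
covariance through an orthonormal contrast basis, clamps it to
$[1/(k-1), 1]$, and applies it to the within-subject effects. The correction
is gated on Mauchly's sphericity test by default (`gg_policy` can force it
either way): the study motivated GG by a homogeneity-of-variances violation,
but the quantity $\varepsilon$ corrects sphericity violations, so sphericity
is what is tested; both corrected and uncorrected p-values are always
reported. Simple main effects are per-level one-way between-group F tests,
used to unpack a significant group × contrast interaction. `logmar()` scores
acuity as $\log_{10}(1/\text{acuity})$.

Open choices resolved here, for the record: the percent-change peak search
pools all stimulus conditions (per-condition search is possible but noisier);
window maxima may move across frequency bins (literal reading of the peak
readout; `fixed_freq` gives the alternative); block order is unconstrained
pseudorandomization (no stated no-repeat rule); signed maxima are used in the
peak-gamma statistic; Table-4-style intercept/gradient comparisons are
Holm-corrected as two dependent tests per measure.

## What the generator does and does not emulate

It does emulate: the block/contrast design and its reuse across modalities,
monotone contrast–response with subject variability, reversal-locked evoked
transients, a dipolar gamma source with background brain activity, tag/control
interleaving with HRF-convolved block modulation of both echoes, QUIPSS II
multi-TI kinetics with slice-timing increments, CSF-based calibration, and
coupling lines with group-dependent spread.

It does not emulate: realistic head anatomy or a 275-channel gradiometer
geometry, physiological (1/f, cardiac, ocular) noise structure, motion,
scanner drift fields, spatial smoothness of BOLD noise, or atlas-based
anatomy. Passing tests therefore demonstrate the correctness and calibration
of the estimators under the stated generative model, not robustness to every
artifact of real recordings — the artifact-rejection and registration stages
of a human study are deliberately out of scope.

## Numerical choices and problem sizes

Zero-phase filtering is used throughout so group delay never biases latencies
or envelopes; trials are reflect-padded 200 ms before filtering and 50-ms
edges are excluded from averages. The analytic signal is constructed in the
frequency domain. Covariance inversion is Cholesky-based with the
regularization above; a rank-deficient unregularized covariance is a caught
error advising regularization. Degenerate (radial) lead fields are flagged
and skipped in scans. The kinetic fit bounds CBF to [0, 300] ml/100 g/min and
$\Delta t$ to [0, max TI].

Default problem sizes in the examples and tests are desk-scale choices: a
1-cm scan grid over the sphere (5-mm grids over a small occipital box for the
localization studies), one to five 1-s trials per 30-s block, a 12×12×6 (or
4×4×3 in unit tests) ASL grid, and 2–4 subjects per group in end-to-end runs;
all are arguments, and the full-size design (5-mm whole-brain grid, 30
trials/block, 64×64×12 voxels) is reachable by changing them.

## A worked run

```{r, eval = FALSE}
coh <- run_cohort(n_control = 2, n_patient = 2, seed = 1,
                  trials_per_block = 3)
res <- group_statistics(coh$measures)
print(res)
plot_cohort_responses(coh$measures)
write_results_bundle(res, coh$measures, "results/cohort")
```

The measures table carries one row per subject × eye × contrast with the
recovered gamma, BOLD, CBF and absolute-CBF responses plus the fitted baseline
perfusion; `group_statistics()` layers the four mixed ANOVAs, the gamma simple
main effects, the per-subject coupling fits and the exact Mann–Whitney
gradient/intercept comparisons on top of it.
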