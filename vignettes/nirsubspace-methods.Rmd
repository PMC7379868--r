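---
title: "Random-subspace ensembles for fNIRS BCIs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-subspace ensembles for fNIRS BCIs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsubspace)
```

This vignette is the package's own account of the science it implements:
the signal model behind the synthetic sessions, each processing stage and
its assumptions, the parameters that matter, and the places where the
design was genuinely open and a choice had to be made. Nothing stated here
as an empirical behaviour goes beyond what the test suite itself computes.

## 1. The signal model and the synthetic generator

Continuous-wave fNIRS measures attenuation changes ΔOD at several
wavelengths; concentration changes of oxygenated and reduced hemoglobin
follow from the modified Beer–Lambert law. The generator
(`simulate_chromophores()`, `forward_project()`, `simulate_session()`)
emulates a 16-channel, three-wavelength (780/805/830 nm) recording at
13.3 Hz with 30 mental-arithmetic and 30 idle trials, a 10 s task period
and a rest period drawn uniformly from 24–26 s per trial (the acquisition
protocol of the open mental-arithmetic BCI datasets this pipeline targets).
Trial order is a seeded shuffle of the balanced sequence.

**Ground truth in chromophore space.** Mental-arithmetic trials evoke a
response on a seeded random subset of channels
(`responsive_channel_fraction`, default 0.5 — spatial specificity makes
random feature subsets genuinely heterogeneous); idle trials evoke
nothing. The evoked waveform is a 10 s boxcar convolved with a canonical
double-gamma HRF (`canonical_hrf()`: gamma density peaking at ~6 s minus
1/6 of a gamma density trough at ~16 s, unit peak; zero at t = 0, decayed
to a few percent by 25 s — the SPM-style shape, chosen because it is the
field's default and nothing in this pipeline is sensitive to the exact
form). Per-trial amplitudes jitter multiplicatively (Gaussian, SD 0.2,
truncated at 0) and per-channel gains span 0.7–1.3.

**Effect sizes.** Defaults are `hrf_amplitude_hbo = 0.05` mM·cm and
`hrf_amplitude_hbr = -0.015` mM·cm: HbO rises, HbR falls with about a
third of the magnitude, the canonical activation signature. These values
are deliberately in the clearly-detectable regime — they produce
cross-validated accuracies near the top of the range reported for good
mental-arithmetic BCI subjects — and they are knobs, not claims: setting
both to zero gives exchangeable classes (the null used for calibration
tests), scaling them traces out any intermediate separability.

**Noise.** Every channel and chromophore carries, in mM·cm on the HbO
scale (HbR scaled by 0.3): a cardiac sinusoid near 1.0 Hz (amplitude
0.010), respiration near 0.3 Hz (0.008), Mayer waves near 0.1 Hz (0.006),
a linear drift of up to ±0.020 over the session, and white noise (SD
0.005). Frequencies jitter ±3 % and phases are random per channel.
Amplitudes sit at the low end of plausible physiological contamination;
the 0.1 Hz Mayer component is the only one adjacent to the analysis band
and is the effective noise floor after filtering.

**Optics.** The package's conversion applies a fixed 2×3 matrix M
(`mbll_matrix()`, mM·cm) to the ΔOD triple; the generator must therefore
produce ΔOD from 2-vector chromophore truth, an underdetermined inverse
problem. `forward_project()` uses the Moore–Penrose right inverse
P = Mᵀ(MMᵀ)⁻¹, the minimum-norm triple satisfying M·P = I. This guarantees
exact round-trip consistency with the analysis-side conversion without
positing extinction coefficients the pipeline never uses; any transposition
error in either direction fails the round-trip test loudly.

**What the generator does not emulate.** Motion artifacts (none are
added, and no removal stage exists — the target recordings are stationary
protocols), photon-transport and scalp/skull optics, serial dependence of
trial amplitudes, non-stationary noise, and spatial correlation between
channels beyond the shared-response structure. Passing tests on synthetic
sessions therefore demonstrate correctness of the pipeline's mechanics
and its statistical behaviour under the stated model, not performance on
any particular real dataset. One realistic consequence the generator
*does* reproduce: with 24–26 s rests the HRF undershoot of a task trial
has not fully decayed when the next trial's epoch begins, so an idle
trial following a mental trial can carry a small evoked residue.

## 2. Preprocessing

`od_to_chromophores()` applies (ΔHbR, ΔHbO) = M · (ΔOD₇₈₀, ΔOD₈₀₅,
ΔOD₈₃₀) per sample and channel. The row order (HbR first) and column
order (ascending wavelength) are fixed and enforced; readers normalize
permuted wavelength columns before conversion.

`nirs_bandpass()` filters each trace with a Butterworth band-pass of
order 6 (a 3rd-order low-pass prototype), pass-band 0.01–0.09 Hz, applied
forward and backward (`signal::filtfilt`), i.e. zero phase and a squared
magnitude response. The band isolates task hemodynamics from drift (below)
and Mayer/respiratory/cardiac oscillations (above). Two numerical
consequences are worth stating. First, the filter runs on the continuous
series *before* segmentation: a 0.01 Hz corner is meaningless on a 16 s
epoch. Second, edge transients at such a low corner decay with a time
constant of minutes; the implementation refuses series shorter than three
cycles of the low cutoff (~5 min at 0.01 Hz), and tests that assert deep
DC rejection (<1e-6) do so on session-length inputs where the transient
has died out in the middle of the record.

`segment_epochs()` cuts one epoch per event over a half-open window
[−1, 15) s relative to onset. The 13.3 Hz rate is not an integer, so
onsets map to samples by nearest-sample rounding and every epoch has the
same fixed length round(16 × 13.3) = 213 samples; the first sample of the
time axis lies within one sample period of −1 s. Equal lengths are what
let trials stack into one array; the rounding convention makes
segmentation exactly equivariant to integer-sample shifts of the whole
recording. `baseline_correct()` subtracts each trace's mean over
[−1, 0) s, the defining property being that the post-correction reference
mean is zero to machine precision.

## 3. Features

`build_feature_matrix()` computes, per trial, chromophore, channel and
window: AVG, the arithmetic mean of the samples in the window, and SLP,
the slope of the ordinary-least-squares line of value against time.
Windows come from `window_scheme()`: TYPE 1 is the single [0, 15) s
window, TYPES 2–4 tile it into three 5 s, five 3 s, or fifteen 1 s
windows. All windows are half-open `[start, end)` on sample times so that
adjacent windows never share a sample at the non-integer rate. Features
use only post-onset samples, so they are invariant to the baseline
segment by construction.

SLP as the OLS slope is a design choice: "average rate of change" could
also be read as (last − first)/duration, and that variant is available
via `slp_method = "endpoints"`, but the regression slope is the
convention in the temporal-feature fNIRS literature and is far less noise
sensitive. Columns are ordered feature-major, then chromophore (HbR,
HbO), channel, window, and carry a descriptor table
(`attr(x, "feature_info")`) so that a subset index always denotes the
same physical quantity across runs.

The dimensionality identity D = n_type × n_chrm × n_ch × n_win
(`feature_dimension()`) puts the default single-feature TYPE 4 layout at
D = 480 = 32 × 15 — nearly nine features per training trial in 10-fold
cross-validation of 60 trials, which is the regime the ensemble method
exists for.

## 4. Classifiers

**Strong learners** (`train_strong()`) use all D features. The linear SVM
standardizes each feature with center/scale fitted on training rows only
(a zero-variance feature gets scale 1 rather than an error) and uses a
linear kernel at unit cost with no class weighting — the plain defaults,
since nothing here depends on tuning. LDA runs on raw features;
standardization provably does not change its decisions, and omitting it
keeps the weak and strong discriminants identical in kind.

The two-class LDA is implemented in-package: pooled within-class
covariance, discriminant w = S⁻¹(μ₂ − μ₁), threshold at the midpoint plus
a log-prior offset. When S is singular — guaranteed for the strong LDA at
D = 480 with 54 training trials — a ridge of 1e-6 × mean(diag(S)) is
added. The point is *not* to fix the strong LDA's performance: it must
run, and degrade, in exactly this regime (stock LDA implementations
refuse it, which is why the discriminant is written here; on
well-conditioned data it is test-verified against MASS::lda decision for
decision).

**The ensemble** (`train_ensemble()`) draws N subsets of M feature
indices uniformly without replacement within each subset (subsets may
overlap across learners), fits one weak LDA per subset on its columns
only, and predicts by majority vote. The candidate M ladder
(`subset_size_ladder()`) is centered on c = ⌊√D + 0.5⌋ with spacing 2 —
the √D-scale center is the classic random-subspace heuristic, small
enough that a 54-trial fold estimates a well-conditioned M×M covariance.
`predict_with_first_n()` re-evaluates the same fitted learners with only
the first n votes, which is what makes accuracy-vs-n curves a property of
one training run rather than N retrainings; at n = N it coincides with
the full majority vote. Ties (possible only at even n) are broken by a
seeded coin flip — unbiased, and reproducible because the seed derives
from the ensemble seed and n.

## 5. Evaluation and the corrected test

`make_folds()` builds stratified partitions: with 30 + 30 trials and
K = 10, every test fold holds exactly 3 + 3 trials, so both classes are
present in every training split — without stratification a degenerate
split would be possible and the comparison fold-dependent.
`repeated_kfold()` fits everything (standardization, subset drawing)
inside each training fold; compared classifiers must share partitions,
and `corrected_t_test()` refuses `cv_result`s whose partitions differ.

The corrected statistic works on the R×K matrix of per-fold loss
differences d. It computes per-repetition means and variances, the grand
mean E(d), the mean variance E(σ²), the overall population variance
S² = mean((d − E(d))²), and

t = E(d) / √(S² / (df + 1)),  df = 10,

referred two-sided to Student's t with df = 10. Fixing df at the number
of repetitions rather than at RK − 1 is the essential correction: the 100
fold losses are strongly dependent (overlapping training sets), and
pretending 99 degrees of freedom would wildly overstate evidence. The
test is expected to be conservative, and the suite checks exactly that:
under an exchangeable null its rejection rate at the nominal 5 % level
must fall in [0.5 %, 15 %]. Degenerate inputs are defined, not crashed
on: identical losses give t = 0, p = 1; a constant non-zero difference
(S² = 0 up to subtraction rounding, detected with an epsilon-scale
threshold) gives t = ±∞, p = 0 with a warning.

`compare_over_learner_counts()` evaluates the curve of cross-validated
accuracy over a grid of learner counts n, comparing each point against a
strong learner trained on the same partitions, and adjusts the p-values
across the grid by Benjamini–Hochberg at q = 0.05. A classical paired
t-test variant is available (`test = "paired"`) for sensitivity analysis;
the corrected test is the default and the one any reported significance
should use.

The calibration suite constructs its exchangeable null directly in
feature space — two LDA classifiers on disjoint blocks of pure-noise
Gaussian features, identical folds — rather than through full session
simulation. Exchangeability is the only property the null needs, the
construction makes it exact by symmetry, and it keeps 200 replicates of
10×10-fold cross-validation affordable.

## 6. Problem sizes, reproducibility, limitations

The shipped tests run the full pipeline at the protocol scale (60 trials,
16 channels, D = 480, R = K = 10, N = 100, the five-value M ladder) and
the calibration study at 200 replicates; everything completes in a few
minutes on one core. All randomness flows from explicit integer seeds:
session parameters carry one, fold partitions one, subset drawing one per
training fold (derived from a base seed and the fold counter), tie-breaks
one derived from ensemble seed and n. `run_pipeline()` fans a single
master seed into the stage seeds and is byte-deterministic given its
configuration; unknown configuration keys are rejected rather than
ignored.

Known limitations. (1) Synthetic validity only: see §1 for what the
generator omits; results here say nothing quantitative about any real
recording. (2) Near the accuracy ceiling, single-realization trend
checks (e.g. comparing curve points a couple of learner counts apart)
are discreteness-limited — one hard trial out of 600 predictions moves an
accuracy estimate by 0.17 % and can locally invert an otherwise monotone
curve; conclusions about the learner-count trend should average over
sessions or be read at the resolution the trial count supports. (3) The
ladder search reports the best M over the ladder on the same
cross-validation used for reporting, which is mildly optimistic; for an
unbiased choice, select M on an inner loop (the building blocks —
`make_folds()` on a training subset — support this, but it is not wired
in as a mode). (4) Recording I/O is the package's documented CSV +
JSON-sidecar layout; SNIRF/HDF5 containers are not read or written.
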