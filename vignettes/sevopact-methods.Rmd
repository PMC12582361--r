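---
title: "Methods: sevoflurane-activated ECoG biomarkers and their verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sevoflurane-activated ECoG biomarkers and their verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and data model

`sevopact` analyses multichannel intracranial EEG recorded at a fixed
sampling rate (1000 Hz in the intended acquisition) across annotated
anaesthetic stages: an isoflurane 1 vol% control (`Iso`), stepwise
sevoflurane at 2, 3 and 4 vol% (`Sev2`–`Sev4`), and, for patients who also
undergo extraoperative monitoring, anaesthesia-free slow-wave sleep
(`SWS`). Stages are cut into 1-min epochs; for each sevoflurane stage the
first three artifact-free epochs are the *analysis epochs*, giving the
10-stage design (control plus nine sevoflurane minutes) used throughout
the statistics. Control stages keep their full span because they also
serve as z-score baselines.

Channel classification follows the operational definitions used in
intraoperative-biomarker work: *normative* sites are retained, outside the
seizure-onset zone and MRI lesions, and free of interictal epileptiform
discharges; *epileptogenic* sites are those resected in patients who
became seizure-free. Bipolar montages are used to mitigate volume
conduction; when a bipolar pair is derived with `to_bipolar()`, pathology
flags propagate by OR — a derivation touching resected tissue is not
normative. Sample ranges are 0-based and half-open so epochs concatenate
without ambiguity.

Raw signals travel as EDF (a minimal 16-bit reader/writer is included,
since signals in microvolts round-trip within the per-channel quantization
step) with CSV channel metadata and JSON stage annotations. Intermediate
arrays (z-scored amplitudes, burst trains) live in memory and are exported
as CSV; biomarker tables, model results and hotspot edge lists are CSV,
and the run manifest is JSON.

## Preprocessing

Filtering is zero-phase (forward–backward) Butterworth throughout, so no
group delay contaminates the phase estimates downstream. The band-pass
(0.016–300 Hz) is a high-pass/low-pass cascade because a single band
design with a 4.5-decade edge ratio is numerically fragile. The 60 Hz
notch is a second-order band-stop of ±1.5 Hz half-width; after the double
pass it leaves tones 5 Hz away essentially untouched while suppressing the
line to below 3%.

Visual artifact screening is replaced by a deterministic rule so results
are reproducible: samples beyond 6 robust SDs (median/MAD) of their
channel are masked, masked runs are dilated by 0.5 s, and channels more
than half masked — or with zero MAD — are rejected. Masking only
annotates; sample values are never altered. An epoch counts artifact-free
when its mean masked fraction across non-rejected channels is at most
0.25. Real visual screening is channel- and epoch-wise and subjective;
this rule is the package's fixed, documented stand-in, with all
parameters exposed.

## Spectral amplitude

Band spectral amplitude (the square root of power) comes from complex
Morlet wavelets with 7 cycles, evaluated on a grid of 3, 3.5, 4 Hz for the
delta band and 80–300 Hz in 10 Hz steps for the HFO band; per-sample band
amplitude is the mean over the grid of per-frequency amplitude. Seven
cycles and these grids are conventional time–frequency defaults; both are
configurable. The transform runs as a frequency-domain Gaussian applied to
the analytic spectrum, chunked with margins of four wavelet SDs that are
computed and discarded, so chunking introduces no interior edge effects
and a unit tone at a grid frequency returns unit amplitude. The amplitude
series stays at the native sampling rate because burst binarization counts
wave-cycles in samples.

z-scoring uses each channel's mean and SD over the unmasked control span
(Iso, or SWS in the redundant two-stage analysis); at least 60 s of usable
control data are required, and zero-SD channels are excluded with a
warning. Because the z-score is per channel, electrode gain differences
cancel, which the tests verify as an invariance.

## Phase–amplitude coupling

The modulation index is the normalized mean vector length
`MI = |mean(A·e^{iφ})| / mean(A)`, with delta phase and HFO envelope taken
from band-limited analytic signals of the raw bipolar trace (not the
wavelet amplitudes, which feed connectivity instead). Band-limiting and
the analytic construction are fused into one frequency-domain operation —
a raised-cosine band window on the positive frequencies, negative
frequencies zeroed — which is a zero-phase FIR of the epoch length. The
normalization makes MI scale-free and bounded in [0, 1], and yields the
closed form `MI = κ/2` for an envelope `1 + κ·cos(φ − φ₀)`; the suite
requires recovery within ±0.02 over κ ∈ {0, 0.2, 0.4, 0.8} on 120-s
signals and preferred phase within ±0.05 rad. Because MI is a mean-vector
length it is positively biased on finite data — a channel with sparse
bursts shows a sampling floor even with κ = 0 — so the significance aid
`surrogate_mi_z()` z-scores the observed MI against circular time-shifts
of the envelope (offsets ≥ 1 s), and the null calibration requires |z| < 2
in at least 95% of uncoupled runs. Whether the original analyses used a
surrogate normalization is not stated in their description; raw MI is
therefore the primary output and the surrogate z is optional.

Per-epoch MI is computed on each 1-min analysis epoch; stage-level maps
average the three epochs.

## Effective connectivity

Burst binarization uses the lower band edge as the wave-cycle reference (3
Hz → 2-s bins of six cycles, 1-s minimum run of three cycles; 80 Hz →
75-ms bins, 37.5-ms minimum run). The lower edge is the conservative
reading of "at least six wave-cycles" for a broad band and is
configurable. A qualifying run credits every bin it touches, including
bins it merely brushes across a boundary — the alternative (crediting only
the bin holding the run onset) is not distinguishable from the available
description, so the inclusive rule is fixed and documented. Bins
containing masked samples become missing, not zero, and missing bins are
dropped triplet-wise in the transfer entropy rather than imputed.

Transfer entropy is the plug-in estimator with history length k = 1 and a
one-bin lag; burst trains at these bin widths are near-memoryless, and k
is exposed for sensitivity analyses. No bias correction is applied — the
estimator's O(1/N) bias is quantified by the tests (below 0.001 bits at
10⁴ bins) instead of corrected. A channel's EC is the mean of its
connections: efferent (outgoing), afferent (incoming), or combined (all
2(n−1), the per-channel analysis value). Bipolar derivations sharing a
physical contact are excluded from the matrix to guard against
montage-induced coupling. One practical floor differs by band: a 1-min
epoch holds ~800 HFO bins but only 29 delta bins, so the pipeline lowers
the minimum-triplet requirement to 25 for delta EC (the operation's
default remains 50); per-epoch delta TE is accordingly noisy and relies on
averaging across epochs and channels.

## Statistics

The stage-trend model is a linear mixed model of biomarker value on an
ordinal stage code (control = 0, sevoflurane minutes 1–9; the
origin-anchored single-slope parameterization) plus the patient-level
covariates (age, sex, hemisphere, MRI lesion, daily seizures, number of
anti-seizure medications, one- vs two-stage surgery) with a random
intercept per patient, fitted by REML with Satterthwaite degrees of
freedom and Bonferroni correction for 6 comparisons. A per-patient random
stage slope is available by option. The epileptogenicity (or SOZ) model is
a binomial logistic mixed model of channel status on the biomarker value
plus the same covariates and random intercept, Bonferroni-corrected for 40
comparisons, reporting per-unit odds ratios. Epoch-level rows are the
default input; stage-minute labels ("Sev3_2") select single epochs and
bare stage names average a channel's analysis epochs.

Numerical decisions that matter in practice: both models are fitted on a
standardized response/predictor internally and back-transformed (t, z, df
and p are scale-invariant; this stabilizes optimization when TE values are
of order 10⁻³), the optimizer is bobyqa, and covariates constant within
the fitted subset are dropped automatically (with few patients the
patient-level covariate block can saturate — four patients support at most
four patient-level parameters — in which case lme4 reports a singular
Hessian; the package classifies singular random effects and
singular-Hessian reports as boundary conditions rather than convergence
failures, because the channel-level terms of interest remain well
determined). If the logistic fit fails outright it is retried with
nAGQ = 0, then with the patient-level covariates dropped (they are
redundant with the patient random intercept for identification); the
reduction is flagged on the result. Quasi-complete separation — common
when a biomarker separates classes strongly in a small cohort — yields
finite standardized estimates but astronomically large per-unit odds
ratios; signs and p-values remain interpretable and the convergence flag
records the condition.

Cohen's d follows the per-patient-per-epoch definition — |mean of class
sites − mean of other sites| / SD of all the patient-epoch's sites —
averaged over patients and epochs within a stage. The subtraction
predictor is mean(resected) − mean(retained) per patient, optionally fed
to an ordinary logistic fit against seizure outcome. The log-transform
variant uses `log(value + ε)` with ε = half the smallest positive value
per biomarker, applied only when zeros are present, so the transform is
monotone and defined without distorting strictly positive biomarkers.

Hotspots are channels at least 3 SD above the SWS reference mean
(boundary included, following the "at least" definition); the reference
is the pooled normative-channel statistic, matching group-level map
construction, with per-channel referencing available. All unordered
hotspot pairs are exported as a CSV edge list for external tractography.

## The synthetic cohort generator

The generator emulates the statistical structure of the study rather than
its biophysics. Each channel carries Brownian (1/f²) background noise
(15 µV SD), a continuous delta oscillation at a channel-specific frequency
drawn from 3–4 Hz (50 µV, with 2-s slow-wave burst excursions and Brownian
phase diffusion of 0.5 rad²/s giving the rhythm a ~0.1 Hz physiological
linewidth — a zero-linewidth carrier would render circular-shift
surrogates blind to genuine coupling, since shifting a perfectly periodic
phase merely rotates the mean vector), and
50–150 ms broadband HFO bursts — band-limited 80–300 Hz noise under a Hann
envelope, not pure tones — whose amplitude is scaled by
`1 + κ·cos(delta phase)`. Directed edges (20% of ordered pairs) propagate
bursts one hop at a one-bin lag with a stage- and class-dependent
transmission probability. Sampling is 1000 Hz; the default schedule is the
study's 5-min stages, with SWS appended for the two-stage fraction
(11/19); roughly 30% of channels are epileptogenic, matching the cohort's
resected fraction.

The published account gives the direction but not the magnitude of the
effects, so the gain tables are free parameters chosen once: κ rises from
0.10 (controls, class-independent so baselines are well defined) to 0.40
(normative) / 0.70 (epileptogenic) at Sev4; HFO burst rates from 1.0/s to
2.2/3.0 per second; HFO transmission from 0.15 to 0.50/0.80; delta
transmission *falls* for epileptogenic channels (0.40 at control to
0.70/0.15 at Sev4), encoding the double dissociation. These values were
fixed after a pilot that checked only internal consistency — that injected
bursts clear the z = 2 binarization threshold and that class tables
validate — and are validated as a whole by recovery properties
(monotonicity of measured MI in κ, edge directionality, stage-slope sign),
not by matching any published magnitude.

What the generator does not emulate: spike morphology and other
non-sinusoidal waveform features, volume conduction and reference
artifacts, non-stationary anaesthetic depth within a stage, electrode
geometry, and any biophysical (GABAergic) mechanism. Passing tests
therefore demonstrate that the estimators and models recover effects of
the kind and direction encoded — not that real recordings would show
effects of any particular size.

## Problem sizes in the test and acceptance runs

Simulation-backed checks use deliberately compact designs: end-to-end
property tests run ten cohorts of 4 patients × 8 channels with 90-s stages
(one analysis epoch per stage, a 90-s control baseline); null-calibration
runs use 12-channel single-patient cohorts (≥ 200 independent pairs) and
100 30-s uncoupled signals with 200 surrogates each; mixed-model coverage
uses 200 replicates of 8 patients × 10 channels × 10 stages, and logistic
recovery 12 patients × 125 channels (~1500 sites). These sizes are the
package's choices for fast, repeatable verification; the mixed-model
small-cohort caveats above are a direct consequence and disappear at
study-scale patient counts.

## Known limitations

- Per-epoch delta EC rests on 29 bins; treat single-epoch delta values as
  noisy and prefer stage averages.
- The plug-in TE is biased upward at small bin counts; comparisons should
  stay within a fixed epoch length.
- MI's positive sampling floor means raw MI values from sparse-burst
  channels should not be compared across very different usable-data
  lengths; the surrogate z is the calibrated alternative.
- Automated artifact masking is a threshold rule; pathological rhythmic
  artifacts below 6 robust SDs pass through.
- Electrode localization, cortical-surface interpolation and tractography
  itself are out of scope; the package stops at the hotspot edge list.
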