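---
title: "Models and methods behind nfalpha"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nfalpha}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`nfalpha` simulates and analyses a closed-loop EEG neurofeedback experiment
for upregulating positive emotion, together with the complete offline
analysis a simultaneous EEG--fMRI study of that design requires. This
vignette explains the models, the parameters that matter, what the
synthetic-data generators do and do not emulate, and the numerical and
design choices that were genuinely open.

## The paradigm

The experiment is a block design: 10 runs of 130 s, each composed of a 20-s
Rest block, a 40-s View block (passively viewing pictures tied to positive
autobiographical memories) and a 60-s Upregulation block (actively
increasing positive emotion with feedback). The three named blocks sum to
120 s; the package closes the remaining 10 s of each run with a `Buffer`
segment (instructions/transition) that is excluded from every analysis.
This preserves the totals the design fixes -- 1300 s and, at TR = 2 s,
650 BOLD volumes -- without altering any analysed block. What actually
occupies those 10 s in the original experiment is not stated anywhere we
could find; the Buffer is a stand-in, not a claim.

All intervals are half-open `[start, end)` and 0-based, and boundaries are
floored to the sample grid, so segmentation is unambiguous at both
250 samples/s (EEG) and 0.5 samples/s (BOLD).

## The feedback signal

Frontal alpha asymmetry is the difference of natural-log alpha-band
(8--12 Hz) power between the right (F4) and left (F3) frontal electrodes,

$$A = \ln P_{F4} - \ln P_{F3},$$

computed in 2-s windows advancing every 1 s (50% overlap). Higher values
index relatively stronger left-hemisphere activation, the approach-related
state under the approach--withdrawal model. Band power is the rectangular
sum of FFT periodogram bins whose centres fall in the band: a 2-s window is
too short for Welch sub-averaging, and the periodogram sum satisfies the
Parseval check exactly (a unit sinusoid in band carries power 0.5).

During an Upregulation block the displayed bar is the window asymmetry
minus the mean asymmetry of the *preceding View block* (the baseline),
averaged over the current and up to two previous windows. The bar is blue
when it maintains or exceeds the previous bar, red otherwise; ties count as
success, and the first bar of a block is blue. Two readings of the display
rule were possible -- compare raw windows or compare smoothed bars; the
smoothed-bar comparison is implemented, because the smoothed bar *is* the
displayed quantity. Feedback is causal: the update at time *t* uses only
samples up to *t*, which the tests verify by corrupting the future.

Sham feedback, shown to the control group, is a bounded Gaussian random
walk (step SD 0.2, reflected at ±2), independent of any EEG. The dynamics
are unconstrained by the design beyond "randomly generated"; the defaults
were chosen to visually resemble real traces. Independence is verified
statistically over full 10-block traces (590 updates): at 59 samples per
block a null correlation with an autocorrelated walk exceeds 0.2 too often
for a per-block bound to be meaningful.

## Synthetic data: what is emulated

**EEG.** Each channel is pink (1/f) background noise plus an independent
band-limited alpha component. The experimental profile multiplies the F4
alpha *power* by `exp(asym_effect)` during Upregulation samples, so the
planted asymmetry increment is `asym_effect` (default 0.3) on the log-power
scale; the control profile plants nothing. Defaults (alpha RMS 3, pink SD 2
in arbitrary microvolt-like units) keep the in-band background small so the
log-power estimator recovers the planted effect with a bias well below the
Monte-Carlo tolerance; this is an SNR a clean frontal alpha rhythm
plausibly has, chosen once and not revisited. An ECG channel carries
R peaks at jittered R--R intervals (default 70 bpm, 50-ms jitter) with the
true peak times stored for oracle tests. An optional periodic
gradient-like artifact (fixed template, configurable amplitude) emulates
what moving-average template subtraction removes. The generator does not
emulate electrode topography beyond F3/F4, ballistocardiogram residuals,
eye blinks, or real scanner physics -- so a green recovery test establishes
that the estimators are correct, not that artifact handling on real
recordings would be.

**ROI-level BOLD.** Per-ROI series are
`baseline * (1 + signal/100) + noise`. The signal is a linear combination
of HRF-convolved block boxcars (canonical double-gamma HRF: response peak
6 s, undershoot 16 s, ratio 6 -- the conventional parameterization, since
only "the" HRF is named by the design). The combination's amplitudes are
calibrated by solving a 3x3 linear system so that the *ratio-of-means
percent-signal-change estimator itself* (with the first-4-s Upregulation
trim) returns exactly the requested `psc_up_view` / `psc_up_rest` on
noiseless data. This makes "planting a PSC" well defined despite
haemodynamic carry-over between blocks. Defaults come from the published
ROI table (38 regions, 19 bilateral pairs; the four right-hemisphere
regions without a reported effect carry 0). Noise is multivariate AR(1)
Gaussian (coefficient 0.3), with innovation correlation `base_corr`
(default exchangeable 0.2) everywhere except Upregulation volumes, where
`delta_r` increments (default +0.3) are added on the planted edge list --
the reported limbic/prefrontal connectivity gains. Non-positive-definite
matrices are repaired by nearest-PD projection and re-checked.

**Voxel-level BOLD.** Small 4-D grids of white noise around baseline with
HRF-convolved Upregulation signal planted in specified voxel clusters;
fixtures for the GLM and cluster-correction tests. There is no R NIfTI
reader in the supported environment, so volumes live as arrays with a
plain-text serialization; the analysis code is container-agnostic.

**Psychometrics.** Paired before/after scores from a bivariate normal with
equal SDs and pair correlation 0.7, shifted so the population pooled-SD
effect size equals the planted `d`. Generating means/SDs default to the
published scale summaries.

**Cohorts.** 18 experimental + 14 control subjects by default: 18 is the
analysed experimental sample implied by every printed statistic (t(17),
180 run-blocks), although 20 were enrolled; 14 likewise (df 13 paired,
df 318 between groups on run-blocks). Both are parameters. Per-subject
seeds derive deterministically from a master seed; EEG and ROI data are
regenerated on demand from those seeds, so a full cohort never has to sit
in memory and every accessor is bit-reproducible.

## Offline statistics

Block-level analysis units are run-blocks: the mean window asymmetry per
subject x run x block, 180 per condition for the default experimental
group. The omnibus test across Rest/View/Upregulation is labelled
repeated-measures in the source analysis but its printed error df (537 =
540 − 3) is that of a pooled one-way ANOVA; the package implements both and
uses the pooled one-way as the default "reproduction mode". Between-group
comparisons are pooled-variance two-sample t tests on run-block
(Up − View) and (Up − Rest) differences (df 318), FDR-corrected with the
Benjamini--Hochberg step-up procedure at q = 0.05 (the step-up variant is a
choice; only "FDR" is specified). Normality screening uses the
one-sample Kolmogorov--Smirnov statistic against a normal with estimated
moments; its p value is the asymptotic Kolmogorov tail and is treated as a
screen, not a precise test.

Whether the between-group tests should use run-block or subject-mean units
was open; df = 318 is only consistent with run-block units, which is the
default.

**fMRI.** Preprocessing: discrete-cosine high-pass (cutoff 0.005 Hz,
idempotent projection) and separable Gaussian smoothing (FWHM in voxel
units, sigma = FWHM/2.3548, symmetric padding so total intensity is exactly
conserved). The GLM has three HRF-convolved task regressors, six motion
confounds (all-zero columns are dropped -- synthetic data have no motion)
and an intercept; OLS with t contrasts for Up>View and Up>Rest. When the
residual variance is zero at rounding level the contrast t is flagged
±Inf (explained signal) or 0 (no signal) rather than returning numerical
garbage. Cluster correction forms clusters at voxel p = 0.01
(26-connectivity) and compares extents against a permutation null of
maximum cluster size obtained by randomly permuting the task-regressor
rows in time. Random permutation, not circular shifting: the multi-run
design is periodic, so circular shifts realign the regressor with itself.
This substitution for closed-form Gaussian-random-field correction is
deliberate -- GRF smoothness estimation is underdetermined on toy grids,
while the permutation null gives exact finite-sample control for the white
noise the generator produces (it would need block permutation under
autocorrelated noise). ROI percent signal change is
`100 * (mean(Up') − mean(ref)) / mean(ref)` over activated voxels, where
Up' drops the first two volumes (4 s) of every Upregulation block to
remove the haemodynamic tail of the preceding View block.

**Connectivity.** Zero-lag Pearson correlation per unordered ROI pair per
block per run (the operative description; "cross-correlation" in the
source's wording is read as its zero-lag case), with the same Upregulation
trim. Correlations are Fisher z-transformed before averaging and testing
(variance stabilization; the choice was open). Per edge: a paired t on
z(Up) − z(View) over the experimental run-blocks (df 179), a pooled
two-sample t of those differences between groups (df 318), and BH-FDR at
q = 0.05 within each 703-edge family. An edge enters the differential
network only when significant in *both* families -- the conjunction
reading of "significant between conditions and between groups"; sequential
filtering was the alternative and would be slightly more liberal. Edges
undefined in a segment (zero variance) are excluded for that unit, never
imputed. Empty networks are valid results.

**HRV.** R peaks are detected by band-passing the ECG to 5--20 Hz,
squaring the derivative, smoothing, thresholding and grouping events with
a 250-ms refractory period. SDNN and RMSSD summarize each block (the HRV
measure is unnamed in the source; these are the two standard time-domain
summaries), and a per-subject one-way ANOVA compares R--R intervals across
blocks.

**Effect sizes.** `cohens_d_pooled` is
`(m2 − m1) / sqrt((s1^2 + s2^2)/2)`. Its printed-precision mode *truncates
toward zero* at the printed number of decimals: truncation, not rounding,
reproduces all ten published scale-level values from their printed
means/SDs (e.g. −1.2766 printed as −1.27, −0.0586 as −0.058), so it is the
reproduction convention; full precision is kept internally.

## Numerical choices

- All EEG filters are zero-phase FFT masks (no IIR designs): exact
  stopbands, exact linear phase, appropriate for finite recordings.
- Downsampling low-passes at 80% of the target Nyquist before decimation.
- Fisher z clips |r| at 1 − 1e−12 before atanh.
- BH-FDR uses the monotone step-up adjustment; it is tested against a
  brute-force subset oracle for m ≤ 12.
- Degenerate cells (zero variance where a denominator needs it) raise
  errors naming the cell, except where an identity-data result is well
  defined (identical before/after scores give d = 0 and no rejection).

## What a green test establishes -- and limitations

The acceptance suite establishes (a) that every printed design count,
degrees of freedom and scale-level effect size is reproduced exactly from
printed inputs, and (b) that on data generated under the package's own
stated world, the estimators recover what was planted at nominal error
rates. It cannot establish anything about the unreleased recordings: the
group-level EEG/fMRI results of the original study are not reproducible
without them. Known limitations: no slice-timing/motion correction, no
MR-physics or artifact realism beyond the periodic template, no anatomical
atlases (ROI labels are user-supplied or synthetic), no directed or
dynamic connectivity, and the classical GRF correction is replaced by a
permutation scheme valid for white noise.
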