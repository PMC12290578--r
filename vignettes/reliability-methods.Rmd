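---
title: "Methods: simulating and quantifying test-retest reliability of evoked spinal cord responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying test-retest reliability of evoked spinal cord responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinalrel)
```

## The problem

Event-related spinal cord fMRI of brief noxious heat stimuli produces weak,
noisy BOLD responses in the dorsal horn, contaminated by cardiac and
respiratory pulsation, drift, and draining-vein signal spread. Whether such
responses are *reliable* — whether a participant who responds strongly today
responds strongly tomorrow — is quantified by measuring each participant in
two sessions and computing the intraclass correlation ICC(3,1) of the
response amplitude, alongside the spatial overlap (Dice coefficient) of the
activation patterns. The same question applies to the peripheral autonomic
responses that accompany each stimulus: the transient shortening of the
heart period (HPR), the skin conductance response (SCR), and the pupil
dilation response (PDR).

`spinalrel` implements this entire analysis chain and, because real
two-session datasets are expensive, pairs it with a synthetic-study
generator whose ground truth is known exactly. Every stage of the analysis
can therefore be validated: the GLM against injected amplitudes, the
nuisance model against injected artifacts, and the ICC estimator against
the variance components that generated the data.

## The generative model

A study configuration (`study_config()`) fixes the design: by default 40
participants, 2 sessions, 20 trials of 1-s stimuli per run with a 10–12 s
jittered intertrial interval, 160 volumes at TR 1.8 s (288 s per run), and
16 axial slices of 1 x 1 x 5 mm voxels. The first onset is placed at 10 s
and schedules are rejected unless every trial's `[-1, +10]` s epoch fits in
the run.

The evoked amplitude of participant $i$ in session $s$ is

$$A_{is} = \mu + b_i + w_{is}, \qquad
  b_i \sim N(0, \sigma_b^2), \quad w_{is} \sim N(0, \sigma_w^2),$$

so the *true* consistency ICC of the amplitude is
$\sigma_b^2 / (\sigma_b^2 + \sigma_w^2)$. The defaults
($\mu = 1\%$ signal change, $\sigma_b = 0.3\%$, $\sigma_w = 0.16\%$, hence
true ICC $\approx 0.78$) describe a population with substantial stable
trait variance; acceptance tests re-estimate these components at other
settings. Autonomic amplitudes (HPR $-40$ ms, SCR $0.5\,\mu S$, PDR $0.3$
a.u. by default) share the same *relative* variance structure but are drawn
independently per measure.

The BOLD grid is a synthetic stand-in for the C6 vertebral neighborhood:
a circular cord with four quadrants split at the in-plane midlines, four
gray-matter horn blobs, an in-plane dilation ring (6 voxels by default)
standing in for draining-vein territory, a one-voxel dorsal-surface vein
shell whose amplitude is `vein_gain` (default 2) times the dorsal-horn
amplitude, and a fluid (CSF) ring with amplified cardiac pulsation. The
fluid ring deliberately excludes the vein shell so that the CSF nuisance
regressor cannot absorb evoked venous signal. The slice stack is divided
into four contiguous segmental levels labelled C5–C8; the responding horn
occupies the left dorsal horn on C6 only. Voxel time series combine:

* the HRF-convolved stimulus regressor scaled by $A_{is}$ (sampled at
  volume onsets, matching the first-level design convention),
* a global linear-plus-cosine drift,
* cardiac and respiratory components with voxel-random weights, whose
  phases derive from the simulated R-peak train and respiration trace and
  are sampled at each slice's acquisition time (ascending slices, evenly
  spaced within the TR — the acquisition order is our choice, since only
  *some* order is needed for slice-wise phase regressors),
* AR(1) Gaussian noise scaled to marginal SD `noise_sd` (the residual
  autocorrelation model is likewise a package choice; lag-1 coefficient
  0.2 by default).

Physiology is simulated at 100 Hz: R-peaks are integrated from a continuous
interbeat-interval function carrying a Gaussian evoked dip (peak 3 s
post-onset, chosen inside the 0–8 s search window) plus per-beat jitter;
skin conductance superposes a canonical SCR kernel — a peak-normalized
gamma density peaking at ~3.1 s with a slow decay, parameters exposed in
the configuration — with spontaneous low-frequency fluctuations; the pupil
uses a gamma-shaped dilation kernel peaking at 1.5 s with inserted blink
gaps; respiration is a slowly frequency-modulated sinusoid.

What the generator does *not* emulate: subject motion, geometric
distortion, signal dropout, template registration error, multi-echo
acquisition, or non-Gaussian noise. Passing tests therefore demonstrate
the correctness and calibration of the *analysis*, not robustness to every
artifact of real cord data.

## Response extraction

Autonomic responses follow fixed extraction rules. Interbeat intervals are
assigned to the *following* R-peak, interpolated to 10 Hz, and band-pass
filtered (second-order Butterworth, 0.01–0.5 Hz). All filters run
forward–backward (zero phase), so latencies are undistorted while the
effective order doubles; traces are reflection-padded before filtering so
edge transients do not leak into the first trials. HPR is the minimum of
the baseline-corrected epoch over (0, 8] s, with the baseline the mean IBI
over the 5 s before onset; SCR (down-sampled to 100 Hz, 1 Hz low-pass) is
the peak over (0, 8] s relative to the sample at onset; PDR (blink samples
±100 ms removed and linearly interpolated, 100 Hz, 4 Hz low-pass) is the
peak over (0, 4] s. Window bounds are half-open, a "peak" is the maximum
sample, and ties resolve to the earliest sample. Baselines use a single
onset sample for SCR/PDR (an average would also be defensible; the single
sample is the simpler reading of "corrected to stimulus onset") and a 5-s
pre-stimulus average for HPR. Trials whose epochs leave the recording, or
pupil epochs more than half interpolated, are dropped with a warning.
Tonic state is summarized by heart rate, RMSSD
($\sqrt{\mathrm{mean}(\Delta IBI^2)}$), and spontaneous electrodermal
fluctuation (area under the absolute residual after regressing the
SCR-kernel-convolved onsets out of the skin conductance trace).

## Noise model and first-level GLM

Cardiac phase grows linearly from 0 to $2\pi$ between successive R-peaks;
respiratory phase uses the amplitude-histogram method (empirical CDF of
the trace, signed by the derivative). Each slice receives 32 Fourier
nuisance regressors — sine and cosine of cardiac and respiratory harmonics
1–4 plus all products of first- and second-harmonic terms — and one CSF
column (mean of the top-5% variance voxels in the fluid mask,
standardized): 33 columns per slice. The exact harmonic allocation is not
canonical; 4 + 4 + 2x2 products is the common convention that yields 32 and
is configurable. Outlier volumes are flagged where dVARS or refRMS
(reference = temporal mean image, intensities mean-scaled first) exceed
their own mean + 3 SD, and enter the design as unit spike regressors.

The first-level design contains the double-gamma-HRF-convolved task
regressor (peak delay 6 s, undershoot delay 16 s, dispersions 1, ratio 6 —
the widely used canonical shape, exposed as parameters), its temporal
derivative, the slice-wise nuisance block, optional motion and
contralateral-horn columns, an intercept, and a cosine drift basis
implementing high-pass filtering at 100 s (a projection equivalent for the
task estimate to filtering data and regressors; running-line filters used
by some packages differ slightly in their pass band). Identically zero
columns (e.g., an empty event subset) are tolerated; genuine collinearity
raises an error naming the aliased columns. Estimation is ordinary least
squares per voxel — no prewhitening; the simulator's AR(1) noise lets the
consequences of that choice be measured rather than assumed — with
$t = \beta/\mathrm{se}$ converted to $z$ through the t distribution at the
residual degrees of freedom using log-scale tail probabilities for
numerical stability. Spatial smoothing, when requested, is a separable
Gaussian specified in millimeters (2 mm FWHM default in the field;
edge-preserving variants are out of scope).

Group inference uses one-sample sign-flipping permutation tests:
family-wise error corrected p-values come from the permutation
distribution of the maximum statistic over the mask, all $2^n$ flips are
enumerated when feasible, and the identity permutation is always included
so $p \ge 1/n_\text{perm}$. Day-wise significance masks combine by
voxel-wise conjunction (logical AND).

## ROI metrics, overlap, reliability

ROI amplitude metrics are the mean, the peak, and the mean of the top 10%
of values (count `ceiling(0.1 n)`; for a 502-voxel ROI that is 51 voxels),
computed for both β and z maps in four masks: target horn, target dilated
quadrant, control horn, control dilated quadrant. Spatial agreement uses
the Dice coefficient $2 V_\text{overlap} / (V_1 + V_2)$ — written here
with the division that the overlap convention requires — at the individual
level on $|z| \ge 1.96$ maps (participants lacking suprathreshold voxels
on either day are flagged and excluded from group averages) and at the
group level on uncorrected p maps at liberal thresholds. Spatial
specificity counts suprathreshold voxels ($p < 0.001$ uncorrected, strict
inequality) per segment, quadrant and horn.

Reliability is ICC(3,1), the two-way mixed-effects single-measure
consistency form:

$$\mathrm{ICC}(3,1) = \frac{BMS - EMS}{BMS + (k - 1)\,EMS},$$

with BMS and EMS the between-participant and error mean squares of the
participants x sessions table and $k$ the number of sessions. Negative
estimates are reported as computed, 95% confidence intervals use the
Shrout–Fleiss F interval, participants with any missing session are
dropped, and estimates are labelled with Cicchetti's bands — poor
($< 0.4$), fair ($[0.4, 0.6)$), good ($[0.6, 0.75)$), excellent
($\ge 0.75$); band edges are lower-inclusive. Split-half reliability
(odd/even or early/late trials) refits the GLM with one regressor per trial
subset, extracts metrics per subset, computes ICC between subsets per day,
and averages the day-wise point estimates (confidence intervals are
reported per day; averaging before interval construction would require a
joint model we deliberately avoid). Cross-measure and quality-control
correlations are Pearson correlations with one-tailed p-values in the
expected direction — negative for HPR, where stronger nociceptive responses
mean *more negative* heart-period changes.

## Numerical choices and problem sizes

Degenerate inputs follow explicit rules: fewer than 2 R-peaks, empty
masks, constant respiration, all-identical ICC tables, and zero-variance
paired differences raise errors; a paired test on identical sessions
returns $t = 0, p = 1$; Dice of two empty masks is 0 with a flag. All
intervals are half-open `[start, end)`; time is seconds from run start;
trial indices are 1-based.

The packaged validation runs at sizes a laptop handles in minutes, chosen
once as the smallest scales at which the statistical guarantees are
informative: ICC oracle agreement on 5x2 and 40x2 tables, parameter
recovery and CI coverage with 500 replications at $n = 40, k = 2$,
family-wise error calibration with 500 null studies of 20 participants on
a 16 x 16 x 8 grid with 1000 flips, amplitude recovery over 200 noisy
simulations, autonomic recovery over 100 seeded runs, and an end-to-end
contrast at $n = 12$ in which $\sigma_w = 0$ with near-zero noise must
rate every signal-carrying ROI metric "excellent" and $\sigma_b = 0$ must
rate them all "poor". The control-region metrics are excluded from that
last contrast by design: they carry no participant-level signal, so their
ICC estimates fluctuate around zero in both arms and categorize as "poor"
regardless of the variance components under test.

## Known limitations

The generator's uniform baseline and voxel-independent noise make tSNR
spatially homogeneous, which real cord data are not; the evoked response
is uniform within the target horn, so the top-10% metric differs from the
mean only through noise; z-score metrics become unstable as noise
approaches zero (the standard error in the denominator shrinks faster than
rank orderings stabilize); and OLS with AR(1) errors yields mildly
optimistic standard errors at the default lag-1 coefficient of 0.2 — the
permutation group inference does not rely on them. Multi-run sessions are
supported by analyzing runs separately and averaging maps, not by a
dedicated concatenation stage.
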