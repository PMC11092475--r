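---
title: "Localizing the auditory and visual thalamus: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing the auditory and visual thalamus: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`thalamoloc` derives participant-specific functional regions of interest
(fROIs) for the medial and lateral geniculate nuclei (MGN, LGN) — the
thalamic relay nuclei for audition and vision — from a clustered-sparse
sensory localizer fMRI task, and validates them with resting-state
functional connectivity (RSFC). This vignette explains the model behind
each stage, the parameters that matter, and the design decisions taken
where the method left genuine freedom. Everything here is computed by the
package's test suite or `scripts/acceptance.R`; no empirical claim below
goes beyond what those runs check.

## The localizer task and its timing model

The task alternates 12-second trials of auditory stimulation (nine 900 ms
instrumental-music segments, each followed by 100 ms of silence, i.e. a
9 s block) and visual stimulation (a reversing checkerboard) in a seeded
pseudorandom order: one leading fixation trial, then 8 auditory and 8
visual trials per run. BOLD volumes are *not* acquired during stimulation.
Instead a cluster of 3 volumes is acquired at the end of each trial
(clustered-sparse temporal acquisition), so scanner noise never overlaps
the stimuli and the hemodynamic response is sampled at or near its peak.

With a cluster of $k$ volumes at repetition time $TR$, the two silent gap
periods flanking the 9 s stimulation block split the remainder of the
trial equally:

$$\text{gap} = \tfrac{1}{2}\left(12 - 9 - k \cdot TR\right).$$

At $TR = 0.85$ s this gives a 225 ms gap and a 2.55 s cluster; at
$TR = 0.80$ s, a 300 ms gap and a 2.40 s cluster. `compute_trial_timing()`
implements exactly this arithmetic and refuses infeasible parameter sets.

Design decisions: the "pseudorandom" condition order is an unconstrained
seeded permutation (a maximum same-condition run length is available as an
option but off by default), and the fixation trial carries an acquisition
cluster like every other trial — run volume counts (17 trials x 3 volumes
= 51) require it.

## The sparse-design GLM

Because acquisition is not continuous, condition regressors cannot be
convolved with an HRF; they are 0/1 indicators over the acquired volumes
of each trial's condition, modelling the response as a plateau sampled at
its peak. Each run contributes 19 columns — intercept, auditory, visual,
6 motion parameters and their squares, WM and CSF compartment signals, and
indicators for the second and third volume of each cluster — assembled
block-diagonally across runs. The cluster-volume indicators absorb
T1-relaxation effects: the sparse scheme never reaches steady-state
magnetization, so later volumes in a cluster sit on a systematically lower
baseline. A regression test verifies that omitting these columns biases
the condition betas while including them restores exact recovery on
noise-free data.

Estimation is per-voxel ordinary least squares with an explicit
rank check that names collinear columns. WM/CSF nuisance series are
mean-centred per run (the convention adopted where the method statement is
silent). The participant-level contrast is the per-run auditory-minus-
visual beta difference averaged across runs.

## Search regions, coactivation, and fROI extraction

Cortical search masks are per-hemisphere unions of BA 41/42-style labels
(auditory cortex, AC) and BA 17/18-style labels (visual cortex, VC),
dilated once. Within each, the contrast map is thresholded to the most
extreme 10% of in-mask voxels (upper tail for AC, lower for VC; the
fraction is a count over in-mask voxels, with ties broken by value then
linear index), components under 10 voxels are discarded, and the component
holding the largest-magnitude surviving value supplies the cortical
reference time series (hemisphere means averaged unweighted across
hemispheres, from smoothed data).

Thalamic search regions (TSRs) start from the segmented nucleus: MGN
dilated 3 times (segmentations of MGN run small), LGN once. Voxels of
surrounding structures are subtracted — cortical grey matter,
parahippocampal WM and hippocampus as-is; mediodorsal nucleus, insular WM,
choroid plexus, pulvinar, putamen and pallidum dilated once — then the
posterior-most two occupied slices are removed, and (MGN only) voxels
superior to the inferior-most pulvinar slice. Every rule logs the voxels
it removed. Rules are applied in that order; the pulvinar reference is the
undilated label. The literal superior-trim rule can empty a hemisphere on
unusual geometry, which surfaces as an explicit TSR-construction error
rather than a silent empty mask.

Coactivation between each TSR voxel and the AC or VC reference is a
Pearson partial correlation controlling for WM, CSF, global grey-matter
signal, TSR-local WM (WM at Chebyshev distance 1–5 voxels from the TSR —
the reading of "between 1 and 5 voxels in any direction"), the
cluster-volume indicators, and per-run intercepts. The adaptive threshold
keeps the top $\lceil f N \rceil$ voxels per hemisphere where
$f = \min(1, \text{numerator}/\bar N)$, $\bar N$ the mean of the two
hemisphere TSR sizes, with numerators 32 (MGN) and 20 (LGN) — so the
survivor count is roughly constant across participants. Voxels surviving
both the AC and VC maps of one TSR are removed from both, and the largest
remaining 18-connected cluster is the fROI. Note the stated threshold rule
selects ~32/~20 voxels per hemisphere, below reported median fROI sizes of
40–50 voxels; the rule is implemented as stated and alternative
interpretations are left to configuration.

QC is an automated surrogate for consensus visual review: flags for empty
fROIs, an LGN inferior or medial to its ipsilateral MGN, left/right size
ratios beyond 3 (a default, not a calibrated value), and MGN–LGN overlap.

Morphology conventions: dilation and erosion use the full 3x3x3
(26-connectivity) structuring element; cluster contiguity is
18-connectivity (the dominant fMRI convention; configurable). Compartment
masks for WM/CSF nuisance extraction are eroded up to three times, each
erosion applied only if it would leave at least two voxels. Internally the
package uses R-native 1-based voxel indexing; all world coordinates go
through the NIfTI affine with its 0-based voxel convention, so affines
mean the same thing they do elsewhere.

## Resting-state post-processing and connectivity

Rest runs are mode-1000 normalized (scaled by the modal in-brain intensity
estimated from a 100-bin histogram), linearly detrended and mean-centred.
Censoring combines any precomputed motion-based mask (LPF-FD threshold
0.07587 mm and GEV-DV parameter 3.105 are consumed as parameters; their
optimization is external) with eye-closure censoring: closures longer than
3 s are censored, as are gaps under 30 s between two such closures.
Retained segments shorter than 8 s are discarded, runs under 90 s dropped,
and participants with fewer than 2 runs or under 300 s excluded — with
reasons reported, never silently.

Band-pass filtering is a second-order zero-phase Butterworth (0.009–0.08
Hz) applied after linear interpolation of censored points (edges held at
the nearest retained value); the first and last $\lceil 22/TR \rceil$
volumes are discarded (26 at TR 0.85 s, 28 at 0.80 s), then censored
volumes are dropped. Partial correlations are computed over retained
volumes only.

The RSFC nuisance set has 28 columns: band-pass-filtered motion
parameters, their squares, their backward-difference derivatives (first
element 0 — a convention choice), the squares of the derivatives, and WM
and CSF signals each with its derivative. Squares and derivatives are
taken after filtering; WM/CSF are unfiltered by default (configurable), as
the method statement specifies filtering only for the motion parameters.

ROI-pair connectivity averages the four left/right seed-by-target partial
correlations into one run-level estimate, then averages over kept runs.
Selectivity across a cohort uses one-tailed paired t-tests of MGN-AC >
MGN-VC, MGN-AC > LGN-AC, LGN-VC > LGN-AC and LGN-VC > MGN-VC, with
Benjamini–Hochberg FDR correction across the four (the step-up variant,
where the citation leaves the variant implicit).

## The phantom: what it emulates and what it does not

The phantom generates labeled anatomy on a 48^3 grid of 2 mm voxels (the
BOLD resolution) in a +x=right/+y=anterior/+z=superior frame: per
hemisphere, boxes for MGN and LGN (40 voxels each, matching typical
functionally defined geniculate sizes) with the LGN lateral and superior
to the MGN, pulvinar superior/posterior to both, mediodorsal nucleus,
putamen, pallidum, hippocampus, choroid plexus, insular and
parahippocampal WM around them, AC and VC surrogate parcels, a cortical
grey-matter shell, interior WM, and a ventricular CSF block.

Task runs place a plateau response at acquisition (no HRF convolution,
matching the unconvolved design): each volume is baseline x T1-decay
(defaults 1, 0.97, 0.95 across the cluster — nonzero so the
cluster-volume regressors are exercised) plus the condition amplitude plus
white noise. Defaults emulate typical 3 T effect sizes: ~1000 baseline
(mode-1000 scale), 2% signal change in responsive thalamic nuclei, 3% in
sensory cortex, 1% noise.

Rest runs plant band-limited latent signals shared between MGN and AC and
between LGN and VC. The Cholesky-style mixing is applied to the *realized*
series — each idiosyncratic component is orthogonalized in-sample against
the shared latent before mixing — so the sample correlation of every
planted pair equals its target exactly. This matters because band-limited
series at these lengths carry few effective degrees of freedom (about 12%
of the nominal sample size for the 0.009–0.08 Hz band), and mixing raw
draws would scatter the realized correlation around the target by ±0.05
even at 10,000 volumes, making recovery checks tests of generator luck
rather than pipeline fidelity. On top of the latents the generator adds
band-limited WM, CSF and global signals and white voxel noise. The global
amplitude default (1.5, vs 10 for planted ROI signals) is deliberately
modest: the 28-column nuisance set contains no global-signal regressor, so
an unmodeled global component inflates every ROI pair; the default keeps
that inflation within the generator's own stated recovery tolerances while
still exercising the nuisance regression.

For cohort-scale statistical studies (hundreds of cohorts), the
generator's cohort mode (`simulate_rest_cohort`) draws the eight ROI mean
series per participant directly from the same latent model without
materializing 4D volumes; runs default to 400 volumes (~5.7 min at TR
0.85 s, matching realistic run lengths).

The phantom does not emulate susceptibility distortion, multiband
reconstruction artifacts, physiological noise, spatially varying
autocorrelation, or real segmentation error. Passing recovery tests
therefore shows the pipeline's logic and numerics are sound under the
stated signal model — not that it is robust to all properties of real
scans.

## Problem sizes and numerical choices

The recovery checks use the default 4-run, 48^3 task phantom (Dice of each
fROI against its planted nucleus ≥ 0.6), a single 10,000-volume 32^3 rest
run for connectivity recovery (±0.05), and 500 null cohorts of 20
participants for type-I calibration of the selectivity tests (rejection
within 2 standard errors of 5%). Degenerate cases are handled explicitly:
constant series after residualization give a flagged coactivation of 0,
ties in thresholding resolve by value then linear voxel index, empty
thresholded maps yield flagged empty fROIs, and both-empty Dice is defined
as 0 with a warning.

## Known limitations

The TSR superior-trim rule is implemented literally and can be aggressive
when the pulvinar sits low. The adaptive-threshold interpretation (a kept
*fraction* of in-TSR voxels) yields fROIs near the numerator size, smaller
than reported median fROI sizes; both the numerators and the
interpretation are configurable. Motion traces in the phantom are
plausible random walks but the BOLD data are not actually displaced, so
motion regressors are exercised only as nuisance columns, and the LPF-FD /
GEV-DV metrics themselves are consumed, not computed.
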