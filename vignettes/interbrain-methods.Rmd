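---
title: "Inter-brain coherence from dyadic fNIRS: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-brain coherence from dyadic fNIRS: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`interbrain` analyses two-person (hyperscanning) fNIRS experiments in which
dyads co-watch short naturalistic videos before and after a face-to-face
conversation. This vignette describes the models the package implements,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical decisions taken
where the underlying methods leave room.

## The analysis problem

Each member of a dyad wears a continuous-wave NIRS cap (7 sources and 7
detectors per hemisphere, 19 channels per hemisphere at 3 cm separation,
three wavelengths: 780/805/830 nm, sampled at 8.33 Hz) while the pair
watches a 2-minute video (phase 1), converses for about 20 minutes
(phase 2), and watches a second 2-minute video (phase 3). The scientific
quantity is *inter-brain coherence*: time-frequency squared coherence
between the two participants' hemodynamic signals at matched cortical
sites, summarised per frequency band, and contrasted between real dyads
and *pseudo-dyads* (re-pairings of participants from different sessions
matched on episode order). Two measures feed inference:

* `cowatch1` — band coherence while co-watching the first video;
* `change` — band coherence while co-watching the second video minus the
  first, i.e. the conversation-induced change.

## Preprocessing chain

The order is fixed: optical density, wavelet motion correction, band-pass,
modified Beer-Lambert law, CBSI.

**Optical density.** `OD(t) = -log(I(t)/mean(I))` per channel and
wavelength. The temporal mean (not the first sample) is the reference
level — the standard convention, and the one that makes OD invariant to
detector gain.

**Wavelet motion correction** (`motion_correct_wavelet`). Each series is
decomposed with a Daubechies-5 DWT to its maximum dyadic depth; detail
coefficients outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` of their level's
distribution are zeroed and the series reconstructed. Numerical points
that matter:

* Records are padded to a dyadic length with a smooth cosine bridge from
  the last to the first sample, so the periodic extension is continuous
  and boundary transients are not mistaken for artifacts.
* Fence statistics use only the data-region coefficients of each level;
  including the low-amplitude pad would shrink the IQR and flag
  legitimate signal wholesale.
* At levels with fewer than 30 data coefficients the quartiles are too
  unstable to define outliers (and a narrowband hemodynamic signal
  concentrates exactly there), so the fence is widened fourfold; only
  gross outliers — persistent step shifts reach tens of standard
  deviations at those levels — are removed.

This correction, like the published method it follows, suppresses spikes
well (the suite bounds the residual of a 10-SD spike on a smooth
background at a tenth of its amplitude) but cannot remove artifact energy
that is not an outlier at in-band scales; the consequences for
parameter-recovery power are discussed below.

**Band-pass** (`bandpass_filter`). 5th-order Butterworth, 0.01-0.4 Hz,
applied forward and backward (`signal::filtfilt`) for zero phase — any
filter lag would bias coherence phase. Series are demeaned and
mirror-padded before filtering; DC rejection is exact and verified to
1e-6.

**Modified Beer-Lambert law** (`od_to_concentration`). The 3-wavelength
system is solved per sample by least squares with a fixed extinction
table (Gratzer/Kollias compilation, documented in
`extinction_coefficients()`), 3 cm separation and DPF 6 at all
wavelengths. The absolute micromolar scale is only as good as these
constants, but every downstream quantity (coherence) is
amplitude-invariant, so their exact source does not affect results.

**CBSI** (`cbsi`). The activation signal is
`x = (HbO - alpha HbR)/2` with `alpha = sd(HbO)/sd(HbR)`, exploiting the
physiological anti-correlation of the chromophores; `x` is invariant to
rescaling HbR, and channels with zero HbR variance are flagged degenerate
and excluded.

**Channel quality** (`channel_quality`) replaces the visual screening a
human would do with three deterministic gates: cardiac-band spectral SNR,
saturation/flat-line detection, and a first-difference jump count. The
SNR statistic (peak power in 0.5-2 Hz over the median neighbouring-band
power) has a noise floor of 10-12 dB even for channels with no cardiac
component, because the numerator is a maximum over many periodogram bins;
channels with a real heartbeat measure above 30 dB. The default threshold
(18 dB) sits between the two regimes.

## Probe geometry and ROI allocation

Optode registrations are validated against the cap's neighbour graph:
each optode must lie between 2.5 and 3.5 cm (inclusive) from every
neighbour, the tolerance band around the nominal 3 cm spacing. Channel
MNI positions are optode midpoints; channels formed by a mis-located
optode fall back to the cohort's mean position for that channel, and a
participant with more than half their optodes mis-located (or no
registration) takes cohort means throughout. Cohort means average only
directly measured (midpoint-provenance) positions — the conservative
reading when some participants are themselves partly fallback.

Channels are allocated to eight ROIs (DLPF, vPM, TPJ, SPL, both
hemispheres; `roi_table()`) by a mutual-nearest rule within a 2 cm
radius: every channel proposes to its nearest eligible ROI; when two
channels compete, the nearer wins and the loser proposes to its next
nearest ROI with a free slot, iterating to a fixed point (deferred
acceptance). Because both sides rank by the same distance, the result is
the unique stable matching for generic positions; ties break by lower
channel id, then ROI table order, making allocation fully deterministic.
The test suite checks the algorithm against exhaustive enumeration of all
rule-respecting assignments on small toys.

## Wavelet transform coherence

`wtc()` implements the analytic Morlet transform (centre frequency 6)
over dyadic scales, 12 voices per octave, smallest scale `2/fs`, with the
standard coherence smoothing: a Gaussian in time whose SD equals the
scale, and a 0.6-octave boxcar across scales. Squared coherence is the
smoothed cross-spectrum magnitude squared over the product of smoothed
auto-spectra. Two properties are worth stating:

* both smoothing kernels are non-negative, so `r2` is guaranteed inside
  `[0, 1]` by Cauchy-Schwarz (the suite also checks this on random
  inputs);
* without smoothing `r2` would be identically 1 — the suite asserts
  independent noise does *not* return 1, guarding the classic
  implementation error.

The cone of influence is the e-folding time of the Morlet
(`sqrt(2) * scale`); `band_average()` excludes edge-affected cells by
default and reports the excluded fraction. For the low band (30-60 s
periods) on a 2-minute trial most of the plane is edge-affected — this is
geometry, not a defect — so low-band summaries rest on few effective
samples. Band intervals are half-open `[lo, hi)` so the three bands tile
0.02-0.2 Hz without double counting; frequencies outside that range are
never summarised (slow noise below, non-hemodynamic rates above).

FFT lengths are the next power of two above the trial length; circular
wrap-around at large scales falls inside the COI-excluded region.
Exact numerical agreement with any particular proprietary WTC routine is
not a goal; the estimator follows the standard published formulation.

## Pseudo-dyads and permutation inference

Pseudo-dyads are all ordered cross-pairings of role-A and role-B
participants within groups of real dyads sharing the same experimental
features (episode order by default): a group of size `k` yields
`k (k - 1)` pseudo-dyads. The permutation test computes a pooled-variance
two-sample t between real and pseudo values, then shuffles the
real/pseudo labels (preserving group sizes) `n_perm` times;
`p = (1 + #{|t*| >= |t_obs|})/(1 + n_perm)`, two-sided, never exactly
zero. Effect size is Cohen's d with a normal-approximation 95% CI. Design
notes:

* two-sided p with the +1 correction is the faithful reading of "tested
  whether the true statistic differed";
* the pooled statistic is the default (a Welch option exists);
* pseudo values share participants, so they are not fully exchangeable
  with real values; the label permutation mirrors the published procedure
  anyway, and the type-I calibration of the whole construction is
  measured empirically in the acceptance suite rather than assumed;
* a full grid is 8 ROIs x 3 bands; at 10,000 permutations that is
  240,000 label draws per measure, tracked by an execution counter
  (`permutation_draws()`).

`paired_t_within_real()` provides the within-real paired t across the two
co-watching phases (df = n dyads - 1), and `adjust_pvalues()` exposes
Bonferroni and Benjamini-Hochberg corrections for grid-level reporting.

## The synthetic-data generator

`simulate_session()` builds dyadic recordings from a forward model whose
ground truth is known, so every stage has a falsifiable target:

* per ROI and band, a dyad-shared latent, an episode-order-group
  stimulus latent and a private latent, all unit-variance Gaussian series
  band-limited by a steep (order-16) Butterworth magnitude so injected
  coupling stays confined to its analysis band; they mix as
  `x = c_d shared + c_s stimulus + sqrt(1 - c_d^2 - c_s^2) private`,
  with phase-dependent coefficients, so expected coherence rises
  monotonically with the coupling coefficient;
* HbO in each designated ROI channel is the equal-weight sum of its three
  band latents (0.5 uM scale); HbR is `-0.3 HbO` plus 10% independent
  band-limited noise, giving CBSI realistic structure; non-designated
  channels carry private broadband signals;
* concentrations run through the extinction-coefficient forward model to
  optical density, then to intensities with baseline level, a ~1.1 Hz
  cardiac oscillation (0.02 OD), slow drift (0.01 OD below 0.005 Hz),
  0.5% multiplicative white noise, and motion artifacts: Poisson events
  (0.5/min/channel) split between Gaussian spikes (5-8 SD, width under
  2 s) and step shifts (2-5 SD), identical across a channel's
  wavelengths, with the event list kept as ground truth;
* optode MNI positions get per-optode isotropic Gaussian jitter (SD 8 mm,
  truncated at 15 mm), reproducing realistic probe-location variability
  while keeping most channels allocatable; real-space positions get
  0.5 mm digitiser noise.

Defaults mirror the acquisition conditions the pipeline targets (27
dyads, 8.33 Hz, 120/1200/120 s phases, counterbalanced episode order, 19
channels per hemisphere). Coupling defaults to zero everywhere: the
default cohort is fully null, and scenarios inject coupling explicitly
via `coupling_spec()`. All randomness derives from one integer seed;
equal configurations are bit-identical.

What the generator does **not** emulate: systemic physiology shared
within a dyad (breathing alignment, autonomic coupling), superficial
scalp hemodynamics, spatially correlated motion (events are independent
across channels), subject-specific optical properties, or any behaviour
in the conversation phase. Passing tests therefore demonstrate that the
pipeline recovers the modelled class of band-limited neural coupling
against realistic instrument noise — not that real co-watching data
contains such coupling.

### Artifact residuals bound recovery power

The artifact model deliberately stresses the published correction. Two
residual classes survive it by construction: the in-band (0.03-0.1 Hz)
component of a 0.2-1.5 s spike sits near the coefficient noise level at
in-band wavelet scales — below any outlier fence — and the sub-0.03 Hz
content of a persistent step cannot be separated from slow signal on a
short record. The surviving residuals both depress the mean band
coherence reachable at full coupling and inflate its between-session
spread. This is the main reason single-cell parameter recovery at small
cohort sizes is noise-limited: the recovery experiment in the acceptance
suite measures exactly this, and at its stated scale (8 dyads, one
injected cell against 23 null cells) the injected cell does not dominate
the grid reliably. The suite reports that outcome rather than relaxing
the experiment.

## Problem sizes in the test suite

Tests run the full pipeline at reduced scale so the suite stays fast
while exercising every stage: the reduced 13-channel-per-hemisphere cap
(same construction, fewer columns), 120 s video phases with a shortened
conversation phase (the conversation signal carries no coherence
measure), cohorts of 4-8 dyads, and 200-1000 permutations per cell.
Monte-Carlo checks (coupling monotonicity, type-I calibration, parameter
recovery) use 20-42 replicates with seeds derived from fixed masters.
These sizes are the package's choices for a balanced, reproducible suite;
the full-scale defaults remain what `sim_config()` and
`pipeline_config()` construct.

## Known limitations

* Coherence estimates from 2-minute trials have few effective degrees of
  freedom, especially in the low band; per-dyad band values are noisy by
  nature and the package reports COI-excluded fractions so users can see
  how thin the support is.
* The permutation construction treats pseudo-dyad values as exchangeable
  with real values although pseudo values share participants; its
  empirical type-I error is measured in the suite, but dependence-aware
  inference (e.g. mixed models over participant effects) is out of scope.
* The wavelet correction inherits the published method's blindness to
  non-outlying artifact energy; no spline/PCA hybrid correction is
  provided.
* Absolute concentration scale depends on tabulated extinction
  coefficients and a fixed DPF of 6; only scale-invariant downstream
  quantities should be interpreted.
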