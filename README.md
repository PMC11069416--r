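# interbrain

Analysis of dyadic (hyperscanning) fNIRS experiments in which two people
co-watch naturalistic videos before and after a face-to-face
conversation. The package carries a recording from raw three-wavelength
optical intensities all the way to inter-brain statistics:

1. **Preprocessing** — optical density, wavelet-based motion-artifact
   correction (Daubechies-5, per-level IQR fences), zero-phase 5th-order
   Butterworth band-pass (0.01–0.4 Hz), modified Beer–Lambert law
   (3 cm separation, DPF 6), and the correlation-based signal improvement
   (CBSI) activation signal `x = (HbO − α·HbR)/2`, `α = σ(HbO)/σ(HbR)`,
   with automated channel-quality gates (cardiac-band SNR, saturation,
   jump count).
2. **Probe geometry** — validation of optode registrations (2.5–3.5 cm
   neighbour distances), channel MNI positions as optode midpoints with
   cohort-mean fallbacks, and deterministic mutual-nearest allocation of
   channels to eight ROIs (DLPF, vPM, TPJ, SPL × hemisphere) within a
   2 cm radius.
3. **Coherence** — Morlet wavelet transform coherence (ω₀ = 6, 12
   voices/octave, Gaussian-in-time and 0.6-octave-in-scale smoothing,
   cone-of-influence handling), summarised over three period bands:
   high (0.1–0.2 Hz), medium (0.03–0.1 Hz), low (0.02–0.03 Hz).
4. **Inference** — pseudo-dyads (all ordered cross-pairings within
   episode-order groups), pooled-t label-permutation tests per
   (ROI, band) cell with Cohen's d and 95% CI, a within-real paired t
   across co-watching phases, and optional multiple-comparison
   adjustment.
5. **Synthetic data** — a generator of dyadic sessions with known
   band-limited inter-brain coupling (`x = c·shared + √(1−c²)·private`),
   cardiac/drift/noise/motion-artifact nuisance structure and probe
   jitter, so every stage of the pipeline can be validated against
   ground truth.

The two inference measures mirror the co-watching paradigm: coherence
while co-watching the first video, and the conversation-induced change
(second video minus first), each contrasted between real and pseudo
dyads.

## A worked example

```r
library(interbrain)

cfg <- pipeline_config(
  sim = sim_config(n_dyads = 8, phase_durations = c(120, 60, 120),
                   n_channels_per_hemisphere = 13, seed = 1,
                   coupling = coupling_spec(phase = "video2", band = "medium",
                                            roi = "TPJ_R", coupling = 1.0)),
  n_perm = 2000, seed = 1)
run <- run_full(cfg)
run
#> <ib_run> 8 real + 24 pseudo dyads, 2000 permutations per cell
#>   cowatch1: min p = 0.07846 at DLPF_R/high
#>   change: min p = 0.01149 at TPJ_R/medium

dplyr::filter(tidy(run$results$change), roi == "TPJ_R")
#>     band real_mean pseudo_mean observed_diff     t      p effect_size
#> 1   high   -0.0331     -0.0411       0.00801 0.150 0.8906      0.0611
#> 2 medium    0.1061     -0.0206       0.12671 2.701 0.0115      1.1026
#> 3    low    0.0411     -0.0384       0.07940 0.509 0.6052      0.2080
```

Eight dyads co-watched two 2-minute videos around a conversation phase;
dyad-level coupling was injected only into the right temporo-parietal
junction, medium band, during the second video. The conversation-induced
`change` contrast recovers exactly that cell as the grid's minimum-p
entry: real dyads' medium-band TPJ-R coherence rose by +0.13
squared-coherence units relative to pseudo dyads (t = 2.7, permutation
p = 0.011, Cohen's d = 1.10), while all other cells behave like null
draws. The co-watching grid (`cowatch1`), where nothing was injected,
shows no cell below p = 0.078.

`glance()`, `tidy()`, `autoplot()` work on the fitted objects
(`permutation_result`, `permutation_grid`, `coherence_spectrogram`), and
`plot_band_coherence()` draws the real-vs-pseudo box plots.

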