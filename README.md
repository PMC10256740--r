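# rnptrack

Quantification of RNP granule transport, anchoring, and subcellular mRNA
localization from fluorescence microscopy and compartment-fractionation
data.

RNA-binding proteins move their mRNA cargo by two opposing activities:
kinesin-dependent transport of RNP granules along microtubules and
anchoring of granules at membranes. Dissecting these activities requires a
chain of quantitative readouts — single-particle tracking, mean-squared
displacement (MSD) diffusion estimation, kymograph co-transport analysis,
centrosome-recruitment scoring, and neurite/soma RNA localization
statistics. `rnptrack` implements that chain end to end for R users, with a
synthetic-data generator so every estimator can be validated by parameter
recovery against known ground truth.

## The statistics at the core

* **Track dynamics.** For a track r(t): MSD(kΔt) = ⟨|r(t+kΔt) − r(t)|²⟩
  over overlapping windows, k = 1…7; the diffusion coefficient is the OLS
  slope of MSD vs lag over 4 (2-D convention, MSD = 4Dτ; the raw-slope
  convention is selectable); velocity = path length / elapsed time; maximum
  distance = farthest excursion from the track start. Tracks shorter than
  21 frames (2 s at 10 frames/s) are discarded.
* **Co-transport.** Processive runs are maximal monotone excursions ≥ 2 µm
  of the track projected on its principal axis; a run is co-transported if
  a partner-channel track stays within 0.5 µm for at least half of its
  frames.
* **Recruitment.** Centrosome enrichment E = log₂(mean intensity in the
  centrosome mask / mean intensity over the whole cell); masked Pearson and
  Manders coefficients for colocalization.
* **Localization.** After pairwise cyclic-loess normalization, the
  localization ratio is L = log₂(neurite/soma) per gene; ΔL between
  conditions is binned by CLIP tags/kb of UTR with rank-sum tests against
  the zero-density bin; gene-set overlaps are scored as fold enrichment
  over independence with Fisher's exact test; FISH spot distances are
  normalized per neurite with per-cell 95th percentiles; qPCR membrane
  association uses 2^−ΔΔCt.

## Worked example

Simulate directed granule transport at 10 frames/s, render a noise-free
movie, track it, and recover the dynamics:

```r
library(rnptrack)

acq   <- acquisition_spec(nx = 160, ny = 160, n_frames = 60,
                          noise = "none", seed = 21)
truth <- simulate_tracks(motion_model("brownian", D = 0.004), acq, 9,
                         start = "grid", start_margin = 2)
movie <- render_movie(truth, acq)
spots  <- detect_spots(movie)                       # LoG + sub-pixel fit
tracks <- filter_tracks(link_spots(spots, 0.5, 0.1), 21)
length(unique(tracks$tracks$track_id))
#> [1] 9
summarize_dynamics(tracks)$ensemble
#>   n_tracks D_um2_per_s   log10_D  d_max_um velocity_um_per_s
#> 1        9 0.004478005 -2.348915 0.3131055         0.3605286
```

All nine tracks are recovered (positions agree with the ground truth to
well under half a pixel RMS), and the ensemble median MSD-slope estimate
sits near the generative D = 0.004 µm²/s; the apparent velocity of a purely
diffusive track reflects step noise, not transport, which is why processive
runs are called separately. The numbered drivers under `analysis/`
(`01_granule_motility.R` … `07_fish_and_qpcr.R`) walk through each stage of
the pipeline the same way and write their tables under `results/`.

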