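---
title: "Quantifying RNP granule transport, anchoring, and mRNA localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RNP granule transport, anchoring, and mRNA localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnptrack)
```

# Scope

RNA-binding proteins distribute their mRNA cargo through two opposing
activities: kinesin-dependent transport of RNP granules along microtubules,
and anchoring of granules at membranes. `rnptrack` implements the
quantitative readouts used to dissect these activities — single-particle
tracking statistics, kymograph co-transport analysis, centrosome-recruitment
scoring, and neurite/soma mRNA localization statistics — together with a
synthetic-data generator that produces inputs with known ground truth, so
every estimator in the package is validated by parameter recovery rather
than by eye.

# Motion models and the synthetic generator

`motion_model()` describes one granule class:

* `stationary` — anchored granules.
* `brownian` — free diffusion; per-axis steps are N(0, 2 D Δt).
* `directed` — processive transport at a per-track constant speed.
* `confined` — Brownian motion radially reflected inside a disc of
  `corral_radius` about the anchor point. This is the simplest model whose
  MSD saturates, which is the behaviour that distinguishes anchored from
  freely diffusing reporters.
* `switching` — alternation between a diffusive and a directed state with
  exponential dwell times (`switch_rates`, per second), for granules that
  pause between processive runs.

Acquisition defaults follow the live-imaging regime used for granule
dynamics: 10 frames/s for 60 s (`frame_interval = 0.1` s, `n_frames = 600`),
0.1 µm pixels, and a PSF sigma of 0.18 µm consistent with a ~0.5 µm
diffraction-limited granule. Movies rendered by `render_movie()` place an
isotropic Gaussian per spot over a constant background with Poisson shot
noise by default; spot amplitude and background are not taken from any
instrument — they are chosen so that detection operates at a clearly
resolvable signal-to-noise ratio, which is what estimator validation needs.

Two generator choices deserve explanation:

* **Per-track speeds are drawn from a zero-truncated normal whose mean is
  calibrated.** Velocity summaries are reported as a mean ± SEM over n
  tracks. To use those numbers as generative ground truth we draw per-track
  speeds from a truncated-at-zero normal with SD = SEM·√n and solve (by
  `uniroot`) for the parent mean such that the *truncated* distribution's
  mean equals the reported mean. Without the calibration, truncation would
  inflate the generative mean above the reported value and every recovery
  comparison would inherit that bias.
* **Reflecting boundaries.** Tracks are folded back at the field edges so
  rendered movies never lose particles, avoiding censoring bias in
  end-to-end recovery tests. Reflection preserves step lengths, so velocity
  statistics are unaffected; where exact unbounded excursions matter
  (straight-run distance recovery) `boundary = "none"` disables folding.

# Tracking pipeline

`detect_spots()` follows the classic small-particle protocol: rolling-ball
background correction (grayscale opening with a disc of radius 3 px — the
flat-disc form of the rolling ball, adequate at radii this small), a
scale-normalized Laplacian-of-Gaussian filter at σ = diameter/(2√2) for the
~0.5 µm granule diameter, strict 8-neighbour local maxima, and per-axis
quadratic sub-pixel refinement clamped to ±0.5 px. The automatic quality
cutoff is an Otsu threshold on the movie-wide distribution of local-maximum
responses, applied only when that distribution is genuinely bimodal (mean of
the lower class below half the mean of the upper class). In noise-free
renders every local maximum is a true spot and an unconditional Otsu cut
would discard half of them.

`link_spots()` joins mutually nearest neighbours between consecutive frames
within `max_displacement`, with no gap closing, splitting or merging; a spot
missing for one frame therefore splits its track. Determinism is guaranteed
by sorting spots by (frame, y, x) and breaking distance ties toward the
lower index. `filter_tracks()` retains tracks of at least 21 points,
implementing the "> 20 frames (2 s)" track-length threshold at 10 frames/s.

# Dynamics statistics

`msd()` uses all overlapping pairs at lags 1…7 frames (the protocol's
"up to lag time 7"). `diffusion_coefficient()` fits ordinary least squares
with a free intercept — the intercept absorbs static localization error and
is discarded — and by default reports slope/4, the 2-D Brownian convention
(MSD = 4Dτ). Because the source protocol describes the coefficient as the
slope itself, `convention = "slope"` reports the raw slope; all recovery
tests use the default. A negative fitted slope is clamped to zero and
flagged, and zero/clamped estimates are excluded from log10 D summaries and
counted separately.

Velocity is total path length divided by elapsed time. The protocol sentence
describing this measurement inverts the ratio ("dividing total time by total
distance"), but the reported units (µm/s) identify distance/time as the
intended quantity, which is what `track_velocity()` computes.
`max_distance()` is the farthest excursion from the track start.

`compare_groups()` is a two-tailed Mann–Whitney U test that enumerates all
assignments exactly (correct under ties) when n₁+n₂ ≤ 12 and otherwise uses
the normal approximation with tie correction; the exact two-tailed p is the
permutation probability of a U at least as far from its null mean as
observed.

# Co-transport

Kymographs resample each frame along a polyline at one-pixel steps with
bilinear interpolation, averaging across the ROI width. Processive runs are
maximal monotone excursions of the track projected onto its first principal
component (motion in neurites is effectively one-dimensional), with a
default threshold of 2 µm — the working definition of a long processive
movement. Because any strict reversal ends a run, heavy localization noise
fragments runs; tracks fed to the run caller should come from the filtered
linker output, whose sub-pixel errors are an order of magnitude below
per-frame transport steps. The co-transport criterion — a partner track
within `max_gap = 0.5` µm for at least half of a run's frames — quantifies
"overlapping in both channels"; both constants are exposed because any
specific choice is a convention, and the fraction is reported over reference
tracks that have at least one run.

# Recruitment scoring

The centrosome enrichment score is E = log2(mean intensity in the centrosome
mask / mean intensity over the whole-cell mask), with the cell mask
including the centrosome pixels — "whole cell" is read literally. E is
invariant to multiplicative gain but not to additive offsets, so scores must
be computed on consistently processed intensities; an optional
background-subtraction step is deliberately left to the caller.
`make_cell_image()` inverts the score exactly: given masks and a target E it
solves for the two intensity levels so that the constructed image scores E
to machine precision, which turns every reported enrichment value into a
round-trip test of the scorer. Masked Pearson and Manders coefficients
operate on 2-D or 3-D arrays restricted to a mask; Manders thresholds
default to 0 because no threshold convention is assumed.

# Localization statistics

Counts are normalized by pairwise cyclic loess on log2(count + 0.5)
(`limma::normalizeCyclicLoess`, span 0.7, 3 iterations), and the
localization ratio is L = mean log2 neurite − mean log2 soma per condition,
with ΔL the change versus the control. The expression filter keeps genes
whose mean normalized log2 expression exceeds 1 in both compartments of all
conditions; the threshold is configurable and recorded.

A point worth making explicit: global normalization cannot distinguish a
broad biological localization shift from a sequencing-depth difference — it
redistributes part of any real shift onto unaffected genes. For that reason
`clip_density_shift()` reports bin medians relative to the zero-CLIP-density
bin, which carries no binding-dependent effect and acts as the internal
reference; the uncentred medians are kept alongside. Default bins are
{0, (0, q50], (q50, q75], > q75} tags/kb computed on the positive densities;
edges are configurable since no canonical bin set exists. Significance per
bin is a two-tailed Wilcoxon rank-sum against the zero-density bin, and the
SEM of the bin median comes from a bootstrap.

`mislocalized_set()` uses a default shift threshold of 0.25 log2 units
(configurable, carried in the output) and `overlap_enrichment()` computes
fold enrichment against the independence expectation |A||B|/N with a
two-tailed Fisher's exact test. FISH spot distances are normalized per
assigned neurite — a fraction of that neurite's total length, which bounds
values by 1 (a cell-wide sum would not) — and per-cell 95th percentiles are
computed only for cells with at least 150 assigned spots. qPCR membrane
enrichment is the standard 2^−ΔΔCt with the cytosolic housekeeping gene as
reference, averaged over replicates.

# Synthetic count tables

`simulate_fractionation_counts()` draws negative-binomial counts with a
shared dispersion (0.05) for one soma and one neurite sample per condition —
single-replicate fractionation, as in the experiment it emulates, so
statistics are across genes, not replicates. Per-gene CLIP densities come
from a zero-inflated gamma (40% zeros), baseline log2(neurite/soma) ratios
from N(0, 0.5), and genes above the density threshold receive the effect
shift in perturbed neurite samples. Sequencing depth is scaled from the
control composition, so unaffected genes keep identical expected counts
across conditions and the depth consequence of the perturbation is left for
the normalization step to absorb — the situation the pipeline faces with
real data.

# Problem sizes and numerical conventions

Recovery analyses use the sizes stated with each result: velocity and
distance recoveries use the reported track counts (36, 71, 50); diffusion
recovery uses several hundred 600-frame tracks; the CLIP-density recovery
uses ~3,400 genes so the top bin holds ~500 genes; the null-uniformity check
uses 1,000 simulated tables of 400 genes. Pixel centres sit at integer pixel
coordinates with the origin at top-left, x rightward, y downward, and all
public outputs are in physical units with unit-suffixed column names
(`x_um`, `tau_s`, `D_um2_per_s`). Quantiles use the linear-interpolation
definition (R type 7). All generators are deterministic given their seed;
derived stages (rendering noise, bootstraps) use named sub-seeds of the
global seed.

# What the synthetic data does and does not show

The generator reproduces the statistical structure the estimators assume:
Gaussian spots over uniform background, ideal NB counts with a shared
dispersion, spots exactly on neurite polylines. Real movies have
heterogeneous backgrounds, photobleaching, focus drift and overlapping
granules; real count tables have gene-specific dispersions and composition
effects beyond a single global shift. Passing recovery tests therefore
demonstrates correctness of the estimators under their stated assumptions,
not robustness to every artefact of real microscopy or sequencing. Two
further limitations: all imaging is 2-D (no volumes, no nuclear foci), and
the linker performs no gap closing, so blinking fluorophores fragment
tracks — by design, since the downstream length filter then discards the
fragments rather than fabricating bridges.
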