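---
title: "Methods: nanocluster bracelets, null models, and enrichment quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nanocluster bracelets, null models, and enrichment quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synbracelet)
```

## The analytical problem

At glutamatergic synapses, scaffold proteins organize into subsynaptic
nanodomains. `synbracelet` quantifies one particular architecture: a
central PSD marker (PSD-95 or Homer1) forming a disc-like core, with
peripheral proteins (the MAGUK MPP2 and the adhesion molecule
SynCAM 1) arranged as a ring of small nanoclusters — a bracelet — at
the PSD edge, and, in a subset of spines, co-clustering of MPP2 with
GABA-A receptor subunits. Establishing such an architecture
quantitatively requires several independent measurements, each with
its own statistical machinery, and this package implements all of
them against synthetic data with known ground truth.

## dSTORM branch: localization tables and nanoclusters

Single-molecule localization data arrive as tables of detections with
a per-detection precision (Thompson estimate, nm). Two quality
conventions are fixed up front:

* **Precision filter.** Localizations with precision *worse than*
  20 nm are excluded; the boundary value 20 nm is kept
  (`uncertainty <= max_uncertainty`). The filter is idempotent.
* **Rendering.** Each localization contributes a unit-mass isotropic
  Gaussian of constant width. "Width" is interpreted as FWHM
  (20 nm → σ ≈ 8.49 nm); a σ-interpretation is selectable. Pixels are
  half-open bins `[lo, hi)`, y grows downward.

Nanoclusters are detected with DBSCAN at ε = 20 nm and a minimum of 5
points, *counting the point itself* in its ε-neighbourhood (the
original-algorithm convention; implementations differ, so it is
documented and tested). Border points reachable from several clusters
are assigned to the cluster of the earliest core point in input
order, which makes labelling deterministic; the whole partition is
tested against an exhaustive density-reachability closure computed by
an independent code path.

Ring diameters are estimated by an algebraic (Kåsa) least-squares
circle fit to cluster centroids. The traditional alternative —
manual line-tool measurements averaged per synapse — cannot be
automated faithfully, so recovery is assessed in distribution: on synthetic bracelets at the
default geometry the fitted diameters scatter tightly around the
generating values (the acceptance script reports mean and SD over 100
synapses). For the *central filled disc* a circle fit does not apply;
the package uses the quantile identity of a uniform disc (median
radial distance = R/√2), which is robust to the sparse background
localizations that surround a synapse.

Bracelet classification is a heuristic score, validated only against
synthetic truth: score = (fraction of 8 angular sectors occupied by
peripheral cluster centroids) × (1 − central-void violation). The
violation term is the fraction of centroids inside half the
90th-percentile radius, scaled by the 25% expected for a uniform
filled disc and capped at 1. A clean ring scores near 1, a filled or
collapsed arrangement near 0; the default decision threshold is 0.5.
Under the generator's conditions the dominant signal is simpler
still: non-bracelet synapses place peripheral localizations uniformly
in a disc, at densities DBSCAN does not cluster, so they typically
produce no peripheral clusters at all and score 0.

## 3D branch: segmentation and object geometry

Stacks are `c(ny, nx, nz)` arrays with anisotropic voxels (default
40 × 40 × 125 nm); the world coordinate of a voxel is
`(index − 0.5) × voxel_size`. Peripheral channels are segmented by
Gaussian filtering (physical-unit sigma, anisotropy-corrected),
percentile background subtraction, a histogram threshold, and
26-connected labelling. Where two histogram methods are combined, the
package takes the *larger* of Otsu's and Yen's thresholds
(conservative foreground); this combination rule is a design choice
and is configurable. Thresholds are histogram-based, so segmentation
is invariant under intensity rescaling (tested).

PSD anchors are found by a blob finder: the stack is converted to
robust z-units (median/MAD of the raw stack), smoothed at a scale set
by the expected blob diameter (σ = diameter/4), and local maxima
above `blob_threshold` (default 4.5 z-units) become seeds; a
marker-controlled watershed floods the smoothed z-image over the
half-threshold mask, merging basins whose saddle lies within
`blob_watershed_level` (default 6.7) of the lower peak. The two
numeric defaults mirror a commercial tool's settings; they are mapped
to h-depth and robust z-units, kept configurable, and nothing in the
acceptance checks depends on their exact values. The z-scoring order
matters: z-units are defined on the raw stack (so noise has unit
scale) and smoothing then suppresses noise while preserving
blob-scale structure.

Object geometry: volume = voxel count × voxel volume; surface area
from exposed voxel faces (each face weighted by its physical area, so
anisotropy is handled); sphericity ψ = π^(1/3)(6V)^(2/3)/A;
equivalent-sphere radius r = (3V/4π)^(1/3). Face counting is exact
for axis-aligned boxes (a digitized cube gives the closed form
(π/6)^(1/3) ≈ 0.806) but, like any Manhattan-area estimator, it
converges to 1.5× the true area on smooth surfaces, so the sphericity
of a finely digitized sphere approaches 2/3 rather than 1. That is a
property of the chosen estimator, not a bug; the 0.4 filter floor
sits far below it at every resolution, which is what the filter
needs. Filters use strict `>` on both sphericity and volume. The
volume floor is adopted as 0.005 µm³ by default, with a 0.0005 µm³
reading selectable (the two are easily conflated in print). Synapses are assembled by attaching, per channel, the
nearest partner object within the distance cutoff; where a 2–2.5 µm
range is quoted without per-channel assignment, the permissive
2.5 µm end is the default for all channels.

## Radial profiles and nearest-neighbour statistics

Radial profiles bin voxels by anisotropy-corrected Euclidean distance
from each anchor into 50-nm shells (bin width is not dictated by the
protocol; 50 nm is the package default), take the mean intensity per
shell, average over anchors, and min-max normalize per image; shells
that extend past the stack border for an anchor are excluded for that
anchor. Nearest-neighbour distances are directional (A→B is not B→A);
surface mode uses `max(0, centre distance − r₁ − r₂)` under the
sphere model or exact voxel-surface distances when voxel sets are
available. Surface NN ≤ centre NN always.

Two null models are provided:

* **CSR in a simplified postsynapse.** Species A is placed uniformly
  within, species B uniformly on the surface of, a 0.8-µm sphere,
  with object counts and radii taken from the corresponding
  segmentation; 10 simulation rounds per synapse. The envelope
  definition deserves care: a mean ± 1.96·SEM band is a confidence
  band on the *null mean* and will reject a single observed
  realisation about half the time even when the data are drawn from
  the null. The package therefore defaults to a t-based prediction
  band across simulation rounds, mean ± t₀.₉₇₅,ₙ₋₁ · sd · √(1+1/n) —
  the band within which one new realisation falls with the nominal
  probability — and also exports the SEM band and per-bin min/max.
  Calibration is tested by drawing the "observed" data from the null
  itself: coverage must reach at least 90% of bins.
* **Toroidal shift.** One channel's cluster centres are translated by
  a 20-nm vector in one random direction per image, wrapping at the
  field bounds. Only the magnitude is a fixed convention; the
  one-direction-per-image choice is the package's, seed-controlled.
  For cluster pairs planted at 10-nm offsets the first histogram bin
  (0–15 nm) of the null falls below the observed count — the
  co-clustering signature.

Histograms aggregate in two levels: mean within experiment, then
mean ± SEM across experiments, matching the "n images from N
independent experiments" bookkeeping; with a single experiment the
SEM is flagged undefined. Whether null simulations are pooled before
or after histogramming is a genuinely open choice; the package
histograms per synapse and averages (pooled-after), and the per-round
matrix is attached for the other reading.

## Confocal spine branch

MAP2 maximum projections are thresholded (Otsu), blurred, re-binarized
at half maximum and thinned (Zhang–Suen) to a 1-pixel skeleton, in
that order, even though thinning the pre-blur binary would also be
defensible. Thinning erodes each bar end by about half
the bar width, which the tests bound explicitly. Puncta are detected
per channel by a 1.5-px mean filter, a histogram threshold
(Otsu/Yen/Moments per channel, default Otsu), a 1.5-px Gaussian blur,
and local maxima above the threshold with a prominence floor
(default 3× the MAD of the blurred image, standing in for a GUI
"noise tolerance"). Two robustness guards are deliberate design
choices: the threshold is computed on the image clipped at
median + 30 MAD, because a few saturated or overlapping puncta
otherwise stretch the histogram and pull the threshold above ordinary
spot peaks; and if the chosen threshold keeps more than 25% of the
image, the channel is declared non-punctate and no maxima are
reported (this is what happens on a channel containing only noise —
Otsu then merely splits the background mode). Homer puncta farther
than 2 µm from the skeleton are discarded; a spine is triple-positive
when at least one MPP2 and one GABA-A punctum lie within 0.5 µm of
the Homer punctum (an average spine-head radius); a punctum may serve
several spines. The reported fraction is triple-positives over Homer
puncta, per image.

## Proteomics enrichment branch

Peptide tables carry raw heavy/light ratios; protein ratios are
intensity-weighted peptide averages. Replicates use inverted isotope
labels, so replicate B's raw ratios are stored inverted and flipped
during orientation; after orientation, a ratio > 1 always means
PSD-95-side enrichment. Ratios are normalized by the same-replicate
GST ratio, making GST exactly 1 in every replicate. Filters: present
in both replicates, ≥ 2 peptides per replicate, geometric SD
(`exp(sd(log ratios))`, n−1 denominator) strictly below 2, exclusion
list removed. The geometric SD is computed across the two oriented,
normalized replicate ratios by default (a peptide-level option
exists; either population is a defensible reading). Quadrants: both ratios > 1 → PSD-95-enriched; both < 1 →
MPP2-enriched; otherwise unassigned. Fold enrichment on the MPP2 side
uses the weaker replicate (`min(1/r_A, 1/r_B)`) — the conservative
reading of "enriched in both replicates" — and selection at the
7-fold threshold is strict, so exactly 7.0-fold is excluded. One
subtlety: because weighted *arithmetic* averaging precedes
orientation, label-swap symmetry is exact only for noise-free peptide
tables (the arithmetic mean of inverted ratios is the inverse of the
harmonic mean); the symmetry test runs at zero peptide noise.

## What the synthetic generators emulate — and what they do not

The generators encode the study conditions as defaults: a 448-nm
central disc, peripheral rings of 894 nm (SynCAM1-like) and 791 nm
(MPP2-like) with 6 satellite clusters each (σ = 40 nm, 50
localizations), precision draws of 10 ± 4 nm applied as positional
jitter and recorded per row, 5 background localizations/µm², and a
65% bracelet prevalence; non-bracelet synapses place the peripheral
species uniformly in a disc (the alternative morphology is not
described anywhere, so uniformity is the package's choice). Voxel
scenes render the central channel as a uniform *ball* of the disc
diameter — so the 3D radial shell profile is flat inside the disc
radius and halves at its edge, the geometric form of "signal drops at
the PSD border" that the profile test asserts — plus peripheral
satellite blobs on a randomly oriented ring plane and a vGlut1 blob
adjacent to the centre. Confocal scenes alternate spine sides along
the dendrite so neighbouring spines' partner puncta cannot fall into
each other's co-occurrence radius, and keep shaft puncta away from
spines; planted co-occurrence counts are exact
(`round(fraction × n)`). Peptide tables plant 7 GABA-A subunits at
10–16-fold MPP2-side enrichment, 4 strong PSD-95-side interactors,
≈180 near-unity background proteins (truncated below 5-fold so noise
cannot cross the 7-fold line), and filter-failing proteins (single
replicate, or a planted inter-replicate bias that pushes the
geometric SD above 2).

Passing tests on these scenes demonstrates parameter recovery under
the stated geometry and noise — not performance on real specimens.
Real data add blinking/multiple-counting artefacts, antibody
linkage error, drift residuals, heterogeneous cluster shapes and
densities, out-of-focus light, and spot crowding that the generators
deliberately omit; the bracelet score in particular is validated only
against synthetic truth and should be treated as a screening
heuristic on real images. Master seeds derive per-entity streams
(seed + entity index), so enlarging a simulated dataset never
perturbs earlier entities.

## Problem sizes and tolerances

The test and acceptance workloads are sized for interactive use:
DBSCAN oracle equivalence on 200 instances of ≤ 300 points; diameter
recovery on 100 synapses per species (5% tolerance on the mean);
prevalence on 200 synapses (±7 points); CSR calibration with 50
synapses × 10 rounds (≥ 90% of bins in the 95% envelope); 10⁴
singleton CSR draws against an independently coded sampler (1%);
radial profiles from 4 synapses in a 128 × 128 × 20 stack (half-max
within one 50-nm bin of the 224-nm disc radius); spine-fraction grids
of 10 images × 20 spines per condition (±0.05). Numerical guards:
histogram thresholds return `NA` on constant input (segmenting warns
and returns no objects; profiles warn and return an all-zero
profile); circle fits flag fewer than 3 or collinear supports as
undefined; empty NN target sets are errors; empty Homer sets yield an
undefined, flagged fraction.

## Known limitations

* The bracelet score is a 2D heuristic; strongly tilted rings in 3D
  data should be fitted in their plane first (the voxel branch
  estimates rings from 3D satellite centroids instead).
* Face-count surface areas overestimate smooth surfaces by up to
  1.5×; sphericity values are therefore comparable within this
  pipeline but not across packages using mesh-based areas.
* The watershed operates on smoothed z-scores; very dim anchors below
  ~4.5 robust z-units are not seeded.
* DBSCAN is quadratic in localization count per channel; tables
  beyond ~10⁴ points per synapse should be tiled.
* The proteomics branch starts from peptide-level ratio tables;
  spectral processing and identification are upstream and out of
  scope.
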