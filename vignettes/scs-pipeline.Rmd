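---
title: "Quantifying memory B cell traffic at the subcapsular sinus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying memory B cell traffic at the subcapsular sinus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Germinal-center-derived memory B cells accumulate under the capsule of the
draining lymph node, crawl along the subcapsular sinus (SCS), scan the
CD169^+^ macrophages that line its floor, and either recycle back into the
parenchyma or leave the node. Intravital two-photon microscopy captures
this as multi-channel z-stacks acquired every 30-40 s, roughly a dozen
4-µm-spaced z-planes deep. Turning those movies into per-movie statements
like "the fraction of tracks leaving the SCS dropped in
chemokine-scavenger-deficient nodes" requires an automated chain of
detection, tracking, sinus segmentation and geometric track classification,
plus (for calcium reporter experiments) a ratiometric FRET analysis with a
principled definition of "macrophage-contacting". `scstrack` implements
that chain end to end, together with a ground-truthed synthetic-movie
generator, so every stage is testable without microscope data — the
original imaging recordings are not publicly deposited.

## Pipeline model

**Detection.** Cells appear as diffraction-blurred blobs of radius about
10 µm. A frame is filtered with a scale-normalized anisotropic
Laplacian-of-Gaussian: the Gaussian scale is $\sigma = r/\sqrt{3}$ µm
(the scale at which the 3D LoG response to a ball of radius $r$ peaks),
converted per axis into voxel units, so 4-µm z-spacing and 1-2-µm xy
pixels are handled consistently. The response is $-\sigma^2 \nabla^2
(G_\sigma * I)$, so bright blobs give positive peaks whose height scales
linearly with amplitude. Detections are strict 26-neighbourhood local
maxima above a quality threshold; maxima closer than one radius merge,
keeping the higher response. Positions are reported at voxel centres in
physical µm — no sub-voxel refinement, which matches the ≤ 1 voxel
localization requirement downstream.

**Tracking.** Frame-to-frame linking is a linear assignment problem in the
Jaqaman style: costs are squared Euclidean distances, links beyond the cap
(default 20 µm) are forbidden, and every unlinked detection pays the cap
squared. The same construction closes gaps globally between tracklet ends
and later tracklet starts whose frame difference is at most the gap
interval (default 2 frames, i.e. at most one missing frame) and whose
distance is within the gap cap (20 µm). Tracks with fewer than 5
detections are discarded. The assignment solver is an exact
$O(n^3)$ shortest-augmenting-path method, and the test suite checks it
against exhaustive enumeration on hundreds of small random instances.

**Sinus segmentation.** The mask is built from per-voxel 4-class
probability maps (inner wall, lumen, outer wall, background), whether
produced externally or by the package's optional random-forest pixel
classifier over a multi-scale feature bank (smoothed intensity, gradient
magnitude, Laplacian, Hessian eigenvalues). Post-processing follows a
fixed chain: 3-frame temporal rolling mean (shrunken windows at the
sequence ends, so no data is invented), per-voxel argmax with a fixed tie
priority (inner wall > lumen > outer wall > background), retention of the
largest 26-connected component per non-background class, merging of the
three sinus classes, and 3D hole filling. Distance to the mask is an exact
anisotropic Euclidean distance transform in physical µm. Every non-mask
voxel is labelled *parenchymal* or *extranodal* by whether its nearest
inner-wall voxel is closer than its nearest outer-wall voxel — a
deterministic, testable realization of "which side of the sinus is this
point on" (ties go to parenchymal; a frame missing one wall class entirely
falls back to the other side's label).

**Track classification.** Only a track's first and last detection matter.
With margin $m$ (default 5 µm): *entering* = start parenchymal at
distance ≥ m and end inside; *leaving* = start inside and end at distance
≥ m on either side (the entering rule is deliberately asymmetric — an
extranodal start cannot "enter from the follicle", but a leaving cell may
exit through the ceiling); *internal* = both endpoints inside; everything
else is *non_interacting*, so per-movie fractions always sum to one.
States are evaluated at the voxel nearest the detection, against the
frame-matched mask. Movies are first cropped to a consistent window
(13 z-slices × 32 time points by default) so fractions are comparable;
tracks left with fewer than the minimum detections are dropped and
counted. Conditions are compared by an unpaired t test (pooled variance by
default, one- or two-tailed) on per-movie fractions.

**FRET contact analysis.** Observed channels are linearly unmixed
(`true = M^{-1} observed`, clipped at zero) to remove bleed-through; the
relative FRET ratio is acceptor gain over total donor + acceptor emission
after per-channel instrument corrections, a monotone calcium readout in
[0, 1] for troponin-based indicators. Contact with sinus macrophages is
quantified as the mean macrophage-channel intensity over each cell mask
(colocalization intensity). The histogram of nonzero colocalization
intensities decays to a plateau of never-contacting cells; the package
fits $A_1 e^{-x/\tau_1} + A_2 e^{-x/\tau_2}$ to the decaying flank (all
bins after the mode), estimates the plateau either as the median of the
top-decile-x tail bins (default) or as a free additive constant, and takes
the threshold where the fitted decay crosses the plateau (bracketing +
bisection to 1e-6 relative). Cells at exactly zero colocalization form the
(−) group, cells above threshold the (+) group; the interval in between is
left out of the comparison, mirroring how contact groups are defined in
intravital calcium studies.

## The synthetic generator

The generator is first-class, tested code; its defaults are the study
conditions every benchmark runs under.

* **Geometry.** A paraboloid shell near the shallow z-face — outer wall
  (4 µm), lumen (8 µm), inner wall (4 µm) — with curvature
  5 × 10⁻⁴ µm⁻¹ and a seeded ~1 µm roughness field. This reproduces the
  floor/ceiling topology and leaves ≥ 20 µm of parenchyma for approach
  trajectories. Default volume: 32 frames × 13 z × 256 × 256 at
  (4, 1, 1) µm voxels, i.e. the analysis crop of the real acquisitions.
* **Motion.** Persistent random walks of fixed per-frame step
  `speed × frame_interval` (defaults 6 µm/min, 35 s — a plausible
  lymphocyte speed; the papers this models do not report SCS crawling
  speeds, so it stays configurable). Fates are enforced by waypoint
  biasing plus rejection: each realized track is re-classified against the
  true geometry with the package's own rules and regenerated on
  disagreement, so planted labels are exact by construction. Simulated
  cells travel mid-sinus rather than hugging the endothelium (a ~2 µm
  standoff), which also keeps endpoint states robust to voxel rounding.
* **Rendering.** Cells are anisotropic Gaussian blobs
  (σ = 10/√3 µm, the scale the detector expects), evaluated over a ±4σ
  support; macrophages are static blobs at anchors lining the floor; FRET
  donor/acceptor amplitudes split a constant total by
  $r = r_{min} + (r_{max} - r_{min}) \cdot \text{calcium}$ (defaults 0.2 /
  0.7). Noise is Poisson shot noise at a configurable photon scale plus
  Gaussian read noise over a constant background.
* **Not emulated:** optical PSF structure beyond Gaussian blur, tissue
  drift, photobleaching, intensity heterogeneity between cells, cell shape.
  Passing benchmarks therefore demonstrate the correctness of the
  geometric and statistical machinery under known conditions, not
  performance on arbitrary real recordings.

## Numerical choices

* Volumes are `(t, c, z, y, x)` arrays; voxel `(i)` has its centre at
  `(i − 1) × voxel_size` µm; all distances are physical µm.
* Filtering uses symmetric reflect padding; detections on the outermost
  voxel layer are kept but flagged, because excluding borders in a
  13-slice stack would discard too much volume.
* Plateau maxima in detection and size ties in component retention are
  broken toward the smallest linear voxel index; assignment ties are
  resolved deterministically by the solver's fixed scan order; spots are
  canonically ordered before linking, making the whole chain invariant to
  input permutation and bit-reproducible under a fixed seed.
* The printed quality threshold of the original tracking tool (15) is
  treated as instrument-specific: LoG quality units depend on intensity
  normalization, so the package default (10, calibrated on synthetic
  blobs of amplitude ~50 where the theoretical peak response is ~0.53 ×
  amplitude) is a configuration value, and 15 can be supplied for parity.
* "Fewer than 5 frames" is interpreted as fewer than 5 detections (not
  spanned frames); the gap interval of two frames admits end-start frame
  differences of 1 or 2, reproducing the common tracking-tool semantics.
* The biexponential fit uses 12 deterministic (τ₁, τ₂) initializations on
  a geometric grid of the fitted span with non-negativity bounds,
  reporting τ₁ < τ₂; degenerate single-exponential data are handled by
  letting A₂ → 0 (with a log-linear fallback when the plateau swamps the
  decay), and a decay that never reaches the plateau reports "no
  crossing" rather than a number.
* The reference plateau/threshold pair printed for the original data
  (9509 counts, 717 AU) depends on an unpublished histogram and binning
  and is therefore reproduced in *procedure*, not in value.

## Benchmarks the suite runs

Problem sizes were chosen to exercise each guarantee at desk scale:
200 random instances for the assignment-vs-enumeration check; 500 planted
blobs at SNR ≈ 6.5 for detection (recall, precision ≥ 0.95, RMSE ≤ 1
voxel); 20 noise seeds for segmentation fidelity (Jaccard 1 clean, ≥ 0.9
at 10% label noise) plus exact distance checks against brute force on
16³ volumes; 10 movies × 20 planted tracks for end-to-end fate recovery
(≥ 90%); 10 + 10 movies at leaving-fate proportions 0.30 vs 0.05 for the
condition contrast (one-tailed p < 0.01); a 3 × 3 (τ-ratio ×
plateau-fraction) grid of Poisson histograms for threshold recovery
(≤ 10% error); and 5 seeds × 100 cells for the contact-group FRET effect
(p < 0.01). `scripts/acceptance.R` recomputes all of these from scratch
for any seed.

## Limitations

Real probability maps come from an interactively trained classifier whose
exact feature bank and forest are not reproduced here; the built-in
classifier is a functional stand-in with the same contract. Track
merging/splitting, motion models, sub-voxel localization, dwell-time
analytics and absolute calcium calibration are out of scope. Segmentation
masks derived at down-sampled xy resolution are nearest-neighbour
up-sampled before distance computation, so mask boundaries carry the block
quantization of the down-sampling factor.
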