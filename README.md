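# scstrack

Quantification of germinal-center-derived memory B cells interacting with
the lymph-node **subcapsular sinus (SCS)** in intravital two-photon
time-lapse volumes, for immunologists analyzing B-cell traffic at the
capsule: where cells cross the sinus floor, what fraction of tracks enter,
leave or stay within the sinus, and whether cells in contact with CD169⁺
sinus macrophages show elevated calcium.

The pipeline:

1. **Detection** — per-frame 3D cell detection as strict local maxima of a
   scale-normalized anisotropic Laplacian-of-Gaussian response,
   $-\sigma^2\nabla^2(G_\sigma * I)$ with $\sigma = r/\sqrt{3}$ for blob
   radius $r$ (10 µm).
2. **Tracking** — linear-assignment-problem linking with squared-distance
   costs, a no-link price of $d_{max}^2$ (caps 20 µm frame-to-frame and
   20 µm / 2 frames for gap closing), then discarding tracks with fewer
   than 5 detections. The solver is exact and verified against exhaustive
   enumeration.
3. **Sinus segmentation** — from 4-class voxel probability maps (inner
   wall / lumen / outer wall / background): 3-frame temporal rolling mean,
   per-voxel argmax, largest 26-connected component per class, class
   merging, 3D hole filling, anisotropic Euclidean distance fields and
   parenchymal/extranodal sidedness.
4. **Track classification** — with margin $m = 5$ µm: *entering* tracks
   start ≥ m in the parenchyma and end inside the sinus, *leaving* tracks
   start inside and end ≥ m away, *internal* tracks start and end inside;
   per-movie fractions are compared across conditions by unpaired t tests.
5. **FRET contact analysis** — linear spectral unmixing, relative FRET
   ratio $g\,A/(b\,D + g\,A)$, macrophage colocalization intensity per
   cell, and a contact threshold at the crossing of a biexponential decay
   $A_1 e^{-x/\tau_1} + A_2 e^{-x/\tau_2}$ fitted to the colocalization
   histogram with its plateau.

A ground-truthed synthetic-movie generator (curved sinus shell,
persistent-random-walk cells with planted fates, macrophage anchors, FRET
channel pair, Poisson + Gaussian noise) makes every stage testable without
microscope data.

## Worked example

Simulate a movie with 20 cells of known fate, run the full chain, and
summarize:

```r
library(scstrack)

geometry <- generate_scs_geometry(shape = c(13, 128, 128),
                                  voxel_size = c(4, 2, 2), seed = 1)
truth <- simulate_tracks(geometry,
  n_per_fate = c(entering = 5, leaving = 5, internal = 5, parenchymal = 5),
  n_frames = 16, min_spacing = 22, seed = 2)
movie <- render_movie(geometry, truth, noise = noise_model(1, 2, 5),
                      seed = 3)
movie
#> <scs_movie> 16 frames x 1 channels x (13 z, 128 y, 128 x) voxels
#>   voxel size (z,y,x): 4 x 2 x 2 um; frame interval: 35s
#>   channels: cells

spots  <- detect_spots(movie, channel = "cells", radius = 10,
                       quality_threshold = 10)          # 320 detections
tracks <- track_spots(spots, max_link_dist = 20, max_gap_dist = 20,
                      max_gap_frames = 2, min_length = 5) # 20 tracks

maps    <- probability_maps_from_geometry(geometry, n_frames = 16,
                                          label_noise = 0.05, factor = 2,
                                          seed = 4)
regions <- build_scs_mask(assign_classes(
  smooth_probability_maps(maps, window = 3)))
classes   <- classify_tracks(tracks, regions, min_outside_dist = 5)
fractions <- summarize_fractions(classes)
fractions[, c("n_tracks", "frac_entering", "frac_leaving",
              "frac_internal", "frac_non_interacting")]
#>   n_tracks frac_entering frac_leaving frac_internal frac_non_interacting
#> 1       20          0.25         0.25          0.25                 0.25
```

All 20 planted tracks are recovered and every one receives its planted
label: the 5 entering, 5 leaving, 5 internal and 5 non-interacting cells
come back as fractions of 0.25 each. `compare_conditions()` then tests a
label's per-movie fraction between two groups of movies, and the FRET
module (`unmix()`, `cell_records()`, `fit_decay_threshold()`,
`assign_groups()`) covers the calcium/contact analysis.

`run_pipeline(default_config(), "out/")` executes the whole chain from a
single YAML-serializable configuration and writes every intermediate
artifact (CSV/TIFF) plus a JSON summary; `inst/cli/scstrack.R` exposes the
stages as shell subcommands (`simulate`, `detect`, `track`, `segment`,
`classify`, `compare`, `fret`, `run`).

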