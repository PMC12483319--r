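---
title: "Methods: segmentation and morphometry of synaptic ultrastructure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation and morphometry of synaptic ultrastructure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synrec)
```

# Overview

`synrec` reconstructs presynaptic ultrastructure from electron tomograms:
semantic networks predict per-voxel foreground and boundary probabilities
for a structure class, structure-specific postprocessing turns those maps
into instance or binary segmentations, and a morphometry layer measures
what neuroscientists actually report -- vesicle diameters, distances to the
active zone, ribbon or presynaptic density, vesicle pools, and
area-normalised vesicle counts. A mean-teacher adaptation routine transfers
a trained network to a new imaging condition without annotations. Because
annotated tomograms are large and hard to ship, the package carries a
phantom generator that renders vesicle/organelle scenes with exact
ground-truth labels; all quantitative claims in the test suite are made on
these phantoms.

# Data model

A `syn_volume` is a 2D or 3D intensity array with a per-axis voxel size in
nm, axis order (z, y, x) so the anisotropic depth axis of tomograms is
always first. A `syn_labels` is a congruent non-negative integer array
(0 = background). A `syn_maps` holds per-voxel probabilities in [0, 1]:
`foreground`, `boundary`, and optionally a normalised `boundary_distance`
channel used by the compartment variant. MRC2014 files carry their voxel
size in the header; HDF5 datasets carry it in a `voxel_size` attribute;
TIFF has no portable 3D spacing tag, so reading TIFF requires an explicit
voxel size -- the package never invents a default, because every downstream
measurement is in nm.

# The phantom generator

`generate_phantom()` renders the content the segmentation stack targets:

* **Vesicles** -- non-overlapping spheres with radii drawn uniformly from
  8-15 nm at a 1.554 nm voxel size, rendered as a dark membrane ring
  (~3 nm) around a lumen slightly darker than the background. Placement is
  sequential rejection sampling with a retry cap, so a given spec is
  reproducible bit for bit. The defaults mirror the fixture scale used
  throughout the tests; at this voxel size, vesicles of the canonical
  30-50 nm kind (radii 15-25 nm) pack too densely to place a hundred
  non-touching instances in a 128 voxel cube, which is why the phantom
  population sits at the small end of the physiological range.
* **Structures** -- an active-zone slab two voxels thick on a membrane
  plane, stacked compartments separated by that membrane, a dense ribbon
  ellipsoid with a small presynaptic density block between ribbon and
  membrane, and an ellipsoidal mitochondrion with rim/lumen contrast.
* **Corruptions** -- `apply_domain_shift()` applies Gaussian blur, additive
  Gaussian noise scaled by the data range, and a gamma contrast change;
  the zero spec is exactly the identity. An optional anisotropic blur
  along z emulates the missing-wedge elongation and is off by default:
  the postprocessing does not model it, so leaving it on by default would
  conflate two effects in every downstream test.

What the phantoms do *not* emulate: tilt-series projection and
reconstruction artefacts, spatially correlated noise, crowded cytoplasmic
texture, partial or ambiguous membranes. Passing tests on phantoms
therefore demonstrate the correctness of the algorithms -- geometry
recovery, closed-loop identity, metric equivalence -- not the full
difficulty of segmenting real tomograms.

`render_oracle_maps()` converts any label volume into idealised network
output (foreground mask, rim-of-instance boundary). Its `rim_width` is a
Chebyshev radius; the default 1 matches the 1-voxel rim used as the
boundary training target, so the oracle and the learned targets agree by
construction.

# Networks

`build_unet()` constructs the standard encoder/decoder with skip
connections: four levels, 32 initial features doubling per level
(32/64/128/256), two 3^d convolutions + ReLU per level, max-pool
downsampling, nearest-neighbour upsampling, sigmoid outputs. In 3D the
first pooling is in-plane only (factors (1, 2, 2)) because tomograms are
shallow along z and blurred by the missing wedge. The implementation is
dense linear algebra: convolutions are im2col gathers multiplied through
BLAS, with hand-derived adjoints for every op; the full backward pass is
validated against numerical differentiation in the test suite.

Training (`train_supervised()`) minimises the negative Dice coefficient
(a perfect prediction scores exactly -1) with AdamW at an initial learning
rate of 1e-4 (betas 0.9/0.999, weight decay 0.01), halving the rate when
the validation loss fails to improve for five consecutive epochs, and
returns the weights of the best validation epoch. Targets are derived from
instance labels: binary foreground, 1-voxel instance rim as boundary, and
optionally the boundary distance normalised by a 10-voxel cap. Validation
splits by volume (default 10%), never by patch, to avoid leakage between
overlapping patches. Inputs are z-scored; at prediction time the z-scoring
is global per volume so that tiled and untiled prediction agree.

`predict_tiled()` pads the volume by reflection once, processes overlapping
windows and keeps only each tile's interior. With a halo at least the
network's one-sided receptive field the stitching is exactly seamless; for
the four-level network the residual seam difference decays roughly
geometrically with the halo.

**Desk-scale problem sizes.** The reference recipe trains for 100,000
iterations on hundreds of tomograms; nothing at that scale is
reproducible on a laptop, and the package does not try. The smoke
configuration used by the tests and the acceptance script trains the full
4-level/32-feature 2D network for 600 iterations on ten 96x96 phantoms
(patch 64x64), which reaches a held-out detection F1 above 0.9 after
watershed postprocessing. This problem size was chosen as the smallest at
which the full pipeline demonstrably converges.

# Postprocessing

`distance_watershed_instances()` implements the five-step distance-seeded
watershed: EDT of the thresholded-boundary complement; seeds = connected
components where that distance exceeds `seed_distance`; heightmap =
distance to the nearest seed; mask = thresholded foreground; seeded
watershed of the heightmap within the mask. Because seeds come from the
distance transform rather than from boundary closure, approximately
spherical objects are recovered even when their predicted boundary has
holes. Presets: vesicles (0.5, 8), mitochondria (0.25, 6). These
pixel-unit thresholds apply at the model's working resolution and
presuppose the production object scale -- vesicles of 30-50 nm diameter at
~1.5 nm voxels have interior radii of 10-16 voxels, comfortably above the
8-voxel seed threshold. Phantom-scale fixtures (radii 8-15 nm) use a
proportionally scaled seed distance of 4; an object whose interior EDT
never exceeds the seed distance produces no seed and is not segmented,
which is the intended behaviour, not an error.

Watershed determinism: components and seeds are labelled in raster order,
flooding uses face connectivity with a priority queue ordered by
(height, insertion order), so results are reproducible across runs.

`segment_active_zone()` thresholds at 0.5 and removes components strictly
smaller than 500 voxels. `segment_compartments()` runs a per-slice seeded
watershed on the distance to the predicted boundary, then merges 2D
fragments across z: fragments overlapping in adjacent slices get an edge
weighted `overlap/min(size) - 0.5`, and the signed graph is partitioned by
greedy additive edge contraction. An exact multicut solver is out of
scope; the greedy contraction is deterministic (ties broken on sorted
keys) and agrees with any exact solution whenever the optimum is
unambiguous, which is what the tests assert. `filter_ribbon_structures()`
keeps the ribbon candidate with the most vesicles within 80 nm (the
ribbon-association distance, exposed as a parameter) and the density
candidate closest to that ribbon.

# Domain adaptation

`adapt_model()` implements mean-teacher self-training: teacher and student
start as copies of the pretrained network; per iteration the teacher
predicts on a target patch without gradients; a confidence mask keeps
voxels with probability strictly above t_c = 0.75 or below 1 - t_c,
channelwise; the student predicts on an augmented copy of the same patch
(Gaussian blur with bandwidth drawn from [0, 2.5] voxels, additive noise
drawn from [0, 15%] of the data range) and is updated by the
negative-Dice loss against the teacher's continuous probabilities,
restricted to the mask; the teacher then tracks the student by
`w_t <- alpha w_t + (1 - alpha) w_s` with alpha = 0.999. The adapted
teacher is returned. Pseudo-labels stay continuous (no binarisation), and
masking is channelwise -- the only shape-consistent reading when the model
has several output channels.

A note on the augmentation asymmetry. Consistency training admits two
assignments of the clean and corrupted views. Giving the teacher the
clean view and the student the corrupted one -- the direction implemented
here, and the one the mean-teacher literature converged on -- computes
pseudo-labels from the most reliable input and asks the student to
reproduce them under corruption; on blur-shifted phantoms this improves
held-out detection F1 monotonically with adaptation iterations. The
opposite assignment computes pseudo-labels from the corrupted view:
measured on the same phantoms it erodes the boundary channel (the teacher
is confidently wrong exactly where blur erased the rims), collapses the
student to a single merged instance per image within 150 iterations, and
drags the teacher down with it. The package therefore ships only the
clean-teacher direction.

Self-training amplifies whatever the source model believes, so it can only
help when the initial target-domain predictions are mostly right; when
they are confidently wrong the procedure degrades them further, and no
loss curve reveals this. `adaptation_report()` quantifies one observable
symptom (instance-count drift between source and adapted models), but
visual inspection of adapted segmentations remains mandatory before using
them for measurements.

# Morphometry

All vesicle-structure distances are surface-to-surface: the minimum over
the vesicle's voxels of the EDT of the structure, with per-axis (possibly
anisotropic) voxel sampling, in nm. A vesicle overlapping the structure is
at distance 0. Centre-based distances are not offered.

Diameters are inscribed-sphere diameters from the interior EDT, reported
as `2 max(EDT) + 0.5 voxel`. The half-voxel term corrects the sub-voxel
offset between the continuous inscribed-sphere centre and the nearest
voxel centre, which biases the raw maximum low; the corrected estimator
recovers analytic sphere diameters (radii 4-20 voxels, off-grid centres)
to better than 0.8 voxel, where the uncorrected convention errs by up to
two voxels. For touching instances, rim voxels between two different
labels are added to the EDT reference set, an approximation exact to one
voxel that avoids one full EDT per object.

Pool assignment uses inclusive thresholds ("within X nm" reads as
inclusive) with precedence docked > membrane-proximal > ribbon-associated:
docked within 100 nm of the presynaptic density and 2 nm of the membrane,
membrane-proximal within 100 nm and 50 nm, ribbon-associated within 80 nm
of the ribbon. The 2 nm docked threshold is the upper edge of the 0-2 nm
distance bin at the 1.554 nm voxel size: a docked vesicle has no
measurable gap, so its measured distance falls in that first bin.

Surface areas come from an iso-0.5 mesh of the (Gaussian-smoothed, sigma
1 voxel) mask, extracted by marching tetrahedra -- six tetrahedra per grid
cell with linearly interpolated crossings, a marching-cubes-family scheme
without ambiguous cases -- and summing triangle areas under the per-axis
voxel scaling. Without smoothing the iso-surface follows the voxel
staircase and overestimates curved areas; with it, a radius-20-voxel
sphere is recovered to well under 5%. Mesh-derived areas are
convention-sensitive (smoothing, iso-level), so the occupancy
normalisation `binned_az_occupancy()` accepts an externally measured area
instead of forcing the mesh value. Counts are normalised to vesicles per
0.01 um^2 over half-open bins [e_i, e_{i+1}).

# Evaluation metrics

`matched_f1()` matches instance pairs with IoU strictly above the
threshold ("overlap larger than 50%" read literally; at exactly 0.5 two
candidates could tie) and reports `2TP / (2TP + FP + FN)`; at thresholds
of at least 0.5 the matching is unique. `best_dice()` averages, over
ground-truth objects, the best Dice against any predicted object; the
published score is named symmetric but described one-directionally, so
both the directional (default) and min-symmetrised variants are provided.
`surface_dice()` skeletonises both masks (thin sheet-like masks, at most
two voxels of interior depth, are their own skeleton; thicker masks keep
the EDT ridge) and takes the harmonic mean of skeleton precision and
recall at a tolerance of 1 voxel by default. Aggregation over volumes
reports the mean, with SD attached only for five or more items.

# Numerical choices and degenerate inputs

* EDT is the exact two-pass lower-envelope transform with per-axis
  spacing; an empty reference set yields infinite distances, which
  callers either reject (empty structures are an error naming the
  structure) or substitute (no boundary anywhere).
* Connected components use the full (8/26) neighbourhood; watershed
  flooding uses face connectivity; ties break on insertion order.
* An all-background probability map yields an empty segmentation, not an
  error; an empty candidate mask in ribbon filtering yields empty outputs
  with a warning.
* Compartment ties in `restrict_to_compartment()` and vesicle-count ties
  in ribbon filtering resolve to the lower label id.
* Label resampling is nearest-neighbour only, so resampling can never
  invent ids.

# Limitations

The networks here are trained at smoke scale on phantoms; they are a
validated implementation of the training and adaptation machinery, not
pretrained segmentation models for real tomograms. Mean-teacher
adaptation inherits the failure mode discussed above. The multicut step
is a greedy approximation. Phantom realism is deliberately limited to
what the downstream algorithms consume (membrane contrast, geometry,
noise level); none of the acquisition physics is simulated.
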