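---
title: "Cohort image projects and pipeline execution: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort image projects and pipeline execution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxpipe)
```

## The problem this package addresses

Multi-parametric imaging studies accumulate hundreds of subjects, each
visited several times, each visit producing many scans in heterogeneous
formats and geometries. Analyzing such a cohort means applying the same
chain of operations to every session while respecting the within-subject
time structure, keeping track of what was computed from what, and being
able to hand the whole project to a colleague. voxpipe implements this as
three connected layers:

1. **A project store**: a directory with fixed sub-folders (`Raw_data`,
   `Derived_data`, `ROI_data`, `Tmp`, `Saved_Pipelines`) and a flat TSV
   database with one row per scan or ROI. A row carries only tags —
   subject, timepoint, sequence name, group, type, status — plus a
   relative path, so the table alone describes the project and the
   directory is movable between machines.
2. **A pipeline engine**: a pipeline is an ordered list of *modules*
   (declared computations with a parameter schema). Adding a module to a
   pipeline immediately expands it into *jobs* — one per (subject,
   timepoint) session matched by its selector parameters — and declares
   one *virtual* database entry per output. Virtual entries are selectable
   by later modules before anything has run, which is how modules chain.
3. **A module library** of the standard operations (smoothing,
   thresholding, ROI masking, reslicing, brain extraction, CT
   preprocessing, local entropy, region growth, CSV/HTML export), each
   also callable as a plain R function on `scan_volume` objects.

## Data model

A `scan_volume` is an array (3D to 5D), a 4×4 affine mapping 0-based voxel
indices to world millimetres (RAS+), and the JSON sidecar metadata. ROIs
are binary 3D masks with their own affine. The affine is stored in the
NIfTI sform only: the quaternion form cannot represent shears and
renormalizes scales, so round-tripping through it would silently alter
non-axial geometries.

Entry status maps to the database color code: raw data are blue, derived
data green, ROI data pink, and virtual (declared but not yet computed)
files yellow. Module compliance uses red (selectors match nothing in this
database), orange (outputs of a previous execution exist on disk), and
green.

### Uniqueness and naming

The database key is (subject, timepoint, sequence name, type). Register
collisions are errors rather than auto-suffixed duplicates so that a
pipeline applied twice produces the same job set. On-disk names are
reconstructed from tags (`<subject>_<timepoint>_<sequence>.nii.gz`), which
is why renaming a tag value also renames files; a rename that would
collide two keys is rejected atomically. Module outputs are named
`<input sequence>_<extension string>`.

## Execution semantics

`execute()` supports two modes with identical outputs:

* **single**: all jobs of module 1, then all of module 2, and so on — the
  mode to use when developing a module;
* **multi**: a process-based worker pool (`parallel::mcparallel`) runs up
  to `workers` jobs concurrently; a job becomes eligible when all of its
  parents in the job dependency graph are finished. There is an edge from
  job A to job B exactly when an output entry of A is an input of B; the
  graph is acyclic by construction because a module can only select
  entries that existed when it was added.

Every job computes into `Tmp/jobs/<job id>/`. Only on success are its
files promoted into `Derived_data`/`ROI_data` and the database row flipped
from virtual to derived/roi — always in the parent process, so a crashed
worker or a killed run leaves no partial files in the final folders and
nothing half-registered in the database. A failed job marks exactly its
transitive descendants skipped. Jobs whose outputs already exist on disk
with a matching provenance record are re-run only with `overwrite = TRUE`;
otherwise they are skipped and their files kept, and downstream jobs still
run against those files.

Modules that produce cohort-level files rather than images (the CSV
statistics export, the HTML report) write one fragment per job; a
`finalize` hook assembles the fragments in the parent after the module's
jobs complete, ordered by job id, so the result is identical regardless of
worker scheduling. "Identical outputs" between modes is defined on the
decompressed NIfTI streams and on sidecars with execution timestamps set
aside: gzip headers embed a file modification time and provenance records
embed wall-clock time, which no scheduler can reproduce.

## Provenance

Each executed job appends one history record to the JSON sidecar of every
output: module id, full parameter map, input and output filenames
(relative to the project root), timestamp, and engine version. Records are
append-only. `trace_to_raw()` walks records through the input files'
sidecars until it reaches files with empty history (raw data), returning
both a tree (fan-in modules have several parents) and a flat raw-first
chain; a missing intermediate sidecar truncates the chain and is flagged
rather than raising. Because the records carry the complete parameter map,
re-running a module from a recorded chain reproduces byte-identical
outputs for deterministic modules — this is tested.

## Numerical choices in the module library

* **Gaussian smoothing** — the filter size parameter is the Gaussian
  *standard deviation*, by default in millimetres and converted per axis
  through the voxel sizes (a `unit = "voxel"` flag bypasses the
  conversion). Some descriptions of such filters say "variance"; sigma in
  mm is the convention every neuroimaging toolkit exposes, so that is the
  documented meaning here. Convolution is separable with symmetric
  (half-sample) reflection at the borders, which conserves total mass;
  kernels are truncated at 4 sigma. 2D mode never mixes across slices, and
  4D/5D volumes are smoothed volume by volume.
* **Thresholding** is strict (`>` for "above", `<` for "below"); masks are
  written as uint8.
* **Reslicing** maps each reference-grid voxel through the composed affine
  and samples the source (trilinear or nearest; ROIs always nearest so
  masks stay binary). Fractional coordinates within 1e-7 of a grid point
  are snapped, so reslicing an image onto its own grid is exact at every
  voxel. Out-of-field voxels are NaN for float data and 0 for integer data
  and masks.
* **Local entropy** — per voxel, the Shannon entropy in bits of the
  histogram over a square (2D) or cubic (3D) window of side `2r+1`, with
  equal-width bins spanning the global finite intensity range of the
  input. Neighbours outside the image and non-finite voxels are excluded;
  values are bounded by log2(bins). Defaults (r = 3, bins = 32, 2D) are
  this package's convention. The implementation computes one box-sum per
  bin via separable banded matrix products, which is exactly the naive
  per-voxel histogram (property-tested against it at 1e-10) but runs
  orders of magnitude faster in R.
* **Brain extraction** is a deliberately simple intensity/morphology
  method: Otsu threshold, largest 26-connected component, morphological
  closing with a metric ball (radius in mm, default 2), hole fill. It is a
  stand-in with the standard contract (one connected, hole-free mask) and
  is labelled "simplified"; it is not a published skull-stripping
  algorithm.
* **CT preprocessing** follows the published recipe values for head CT
  (window 0–100 HU, sigma 1 mm). One subtlety is documented here because
  it is easy to get wrong: if the image is clamped to the window first,
  the sub-zero tissue/bone gap collapses to the window floor and Gaussian
  smoothing reconnects brain and skull, after which no threshold can
  separate them. The mask branch therefore combines the strict in-window
  test on the *original* HU values (which excludes bone and air outright)
  with a strict `> 0` threshold on the Gaussian-filtered original image,
  then keeps the largest component and fills holes. The clamped image is
  returned alongside as the clipped scan. The optional "resize" stage is
  isotropic 1 mm resampling through the reslicer.
* **Region growth** (the ROI drawing helper): a candidate voxel on the
  region boundary joins when its intensity is within `k` (default 2.5)
  region standard deviations of the region mean and it touches the region
  with at least `m` (default 2) neighbours. Two bootstrap rules make the
  textbook rule actually grow: the tolerance has a floor of 2% of the
  image intensity range (a single-voxel region has zero variance), and
  the neighbour count uses the 26-neighbourhood — a face-adjacent
  candidate of a *convex* region has exactly one face neighbour, so a
  face-only count of 2 freezes any smooth region (we verified the freeze
  empirically at ~80 voxels on an ellipsoid phantom).
* **ROI statistics** use the population standard deviation (divisor N).
  ROI volume is `n_voxels × |det| ` of the 3×3 affine block. Voxel indices
  are 0-based throughout the API; world coordinates are mm RAS+.
  Cross-scan value displays interpolate trilinearly.

## Conversion

The converter normalizes everything to a compressed NIfTI plus JSON
sidecar pair. Which source fields are collected is driven by a YAML
mapping (one rule per sidecar key: dialect, source address, unit
conversion); the shipped default covers Modality, EchoTime,
RepetitionTime, FlipAngle, AcquisitionDateTime, SeriesDescription and
SliceThickness from their standard DICOM tags. Times stay in milliseconds
(the DICOM native unit), so default conversion factors are 1.

DICOM support covers classic single-frame, explicit-VR little-endian
files — written by hand here because no R DICOM parser is part of this
package's dependency set, and validated against an independent Python
reader in the tests. Slices are sorted by the projection of
ImagePositionPatient onto the slice normal; the affine is built from
ImageOrientationPatient/PixelSpacing and converted from LPS to RAS+.
Mixed series in one directory and irregular slice spacing are errors.
Vendor formats beyond DICOM/NIfTI are reachable through
`register_dialect()`, a hook that accepts a reader returning array, affine
and metadata; none is bundled.

## Synthetic cohorts and what passing tests do (and do not) show

All tests run on generated data: ellipsoid "brain" phantoms with a bright
shell and a dark gap, Hounsfield-valued head phantoms (air −1000, skull
≈ 1000, brain 40 ± noise, and a sub-zero gap between brain and skull),
intensity ramps, checkerboards and gamma-variate 4D perfusion series.
Generation is seed-deterministic and each generator returns its ground
truth (the true mask, the noiseless time-course), which is what the
segmentation and statistics tests score against.

Default cohort sizes mirror the studies the package replays: a
preclinical project of 2 subjects × 3 timepoints × 10 sequences with one
brain ROI per session, and a clinical CT patient with 3 timepoints. The
scaled load test uses 45 subjects with uneven visit counts (20×3 + 25×2 =
110 sessions, 9 scans each, 990 scans) and an 18-module chain — 1,980
jobs — with volumes of 12×12×6 voxels so the whole run completes in a few
minutes; the point of that test is scheduler correctness (job counts,
dependency handling, cross-mode identity), which does not depend on voxel
count.

These phantoms establish correctness of the machinery, not clinical
performance: the brain extractor meeting Dice ≥ 0.95 on an ellipsoid
phantom says nothing about real skull-stripping accuracy, and the CT
phantom's clean intensity modes are far kinder than real CT. The phantom's
brain–skull gap is a separability device, not anatomy.

## Known limitations

* Single-frame DICOM only; no enhanced multi-frame, no DICOM-RT, no
  anonymization.
* The worker pool is fork-based (Unix); on systems without fork the multi
  mode would need a PSOCK backend. No cluster submission.
* Pipeline iteration is per (subject, timepoint); modules needing all
  timepoints of a subject at once declare per-subject arity, but no such
  module ships in the builtin library — longitudinal comparison is
  offered at the library level (`longitudinal_compare()`).
* No concurrent multi-user locking on the project database.
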