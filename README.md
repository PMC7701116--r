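# voxpipe

A headless, scriptable system for managing **cohorts of medical images**
and for designing and executing **processing pipelines** over them, in R.

Imaging studies routinely hold hundreds of subjects, each imaged at
several timepoints, each visit producing many scans (3D, 4D, even 5D) in
mixed formats and geometries. voxpipe targets the people who have to
analyse such cohorts reproducibly — imaging scientists and analysts in
preclinical MRI and clinical CT/MR studies — and gives them:

* **a project store**: an on-disk project (fixed sub-folders `Raw_data`,
  `Derived_data`, `ROI_data`, `Tmp`, `Saved_Pipelines`) entirely described
  by a flat, diffable TSV database of tags — subject, timepoint, sequence
  name, group, type (Scan/ROI), status — with relative paths, so a whole
  project can be moved or shared as one directory;
* **a converter** to the canonical NIfTI + JSON sidecar pair, from
  single-frame DICOM series (geometry rebuilt from
  ImageOrientation/ImagePosition/PixelSpacing in RAS+) and from
  NIfTI, with BIDS tree import and a YAML-editable metadata mapping;
* **a pipeline engine**: a pipeline is a list of parameterized *modules*;
  adding a module creates one *job* per (subject, timepoint) session and
  declares *virtual* database entries for its outputs, which later
  modules can select before anything has run. Execution is either
  sequential ("single") or dependency-aware parallel ("multi", a worker
  pool honouring the job DAG), with all outputs staged in `Tmp` and
  promoted only on success — both modes produce identical images;
* **a module library** (13 declared modules: Gaussian smoothing,
  thresholding, ROI masking, affine reslicing, simplified brain
  extraction, CT clip/filter/brain-extraction, local Shannon entropy
  maps, seeded region growth, CSV statistics export, HTML report, file
  deletion, and a commented template for writing your own — dropped as an
  R file into a Modules folder and picked up by the next discovery);
* **first-order ROI statistics** (mean, population SD, median, extrema,
  voxel count, volume in mm³), histograms, 4D voxel time-courses, paired
  scan values, world-coordinate sampling across resolutions, and
  longitudinal comparison;
* **provenance**: every output's JSON sidecar accumulates one history
  record per module execution (module id, full parameters, input/output
  files, timestamp), and `trace_to_raw()` reconstructs the whole chain
  back to raw data;
* **synthetic fixtures**: seed-deterministic phantom generators
  (ellipsoid brain, Hounsfield head, ramps, checkerboards, gamma-variate
  perfusion) and whole registered cohorts with ground truth, so every
  feature is testable offline.

Key formal pieces: voxel indices map to world mm through the NIfTI 4×4
affine **A** (RAS+), `world = A · (i, j, k, 1)ᵀ` with 0-based indices;
ROI volume is `n_voxels · |det A₃ₓ₃|`; the local entropy map computes per
voxel `H = −Σ_b p_b log₂ p_b` over an equal-width histogram of the
`(2r+1)`-sided neighbourhood, bounded by `log₂(bins)`; the job graph has
an edge A→B iff an output entry of A is an input of B, and is acyclic by
construction.

## Worked example

A small preclinical-style study: 2 subjects × 3 timepoints × 10 sequences
plus one brain ROI per session, processed by a 4-module pipeline (brain
extraction → ROI masking → smoothing → statistics export):

```r
library(voxpipe)

spec    <- cohort_spec(n_subjects = 2, timepoints = 3, sequences = 10, seed = 42)
project <- make_cohort(spec, "study")
project
#> <vox_project> /tmp/readme_demo/study
#>   66 entries (raw: 60, roi: 6)

lib <- discover_modules()
pl  <- new_pipeline(project)
pl  <- add_module(pl, lib$specs$Module_Brain_Extract, list(sequence = "Seq01"))
pl  <- add_module(pl, lib$specs$Module_Mask_ROI,
                  list(sequence = "Seq01", roi = "Seq01_brain"))
pl  <- add_module(pl, lib$specs$Module_Smooth,
                  list(sequence = "Seq01_masked", size = 1))
pl  <- add_module(pl, lib$specs$Module_Export_Stats,
                  list(sequence = "Seq01_masked_smooth", roi = "Seq01_brain"))
pl
#> <vox_pipeline> 4 module(s), 24 job(s)
#>   1. Module_Brain_Extract     [green] 6 job(s)
#>   2. Module_Mask_ROI          [green] 6 job(s)
#>   3. Module_Smooth            [green] 6 job(s)
#>   4. Module_Export_Stats      [green] 6 job(s)

res <- execute(pl, mode = "multi", workers = 4)
res$report
#> <vox_execution_report> mode=multi workers=4: 24 done, 0 failed, 0 skipped

head(read.csv("study/Derived_data/roi_stats.csv"), 3)
#>   subject timepoint  mean   std median    min   max n_voxels volume_mm3
#> 1     S01        T0 50.96 26.72  39.63 12.213 100.5     2344       2344
#> 2     S01        T1 50.96 26.76  39.53 12.276 100.5     2344       2344
#> 3     S01        T2 50.75 26.78  39.39  5.151 100.4     2359       2359
```

Each job is one pipeline occurrence per session: 6 sessions × 4 modules
= 24 jobs, all green (compliant, not yet executed) before the run. The
CSV has one row per session; `mean`/`std` are the first-order statistics
of the smoothed, brain-masked scan inside the extracted brain ROI, and
`volume_mm3` is the ROI volume (here 1 mm isotropic voxels, so it equals
the voxel count). Every derived file knows where it came from:

```r
entry <- filter_database(res$project, sequence = "Seq01_masked_smooth",
                         subject = "S01", timepoint = "T0")
cat(file_history_report(res$project, entry[1, ]), sep = "\n")
#> Provenance of S01_T0_Seq01_masked_smooth.nii.gz (3 processing steps):
#>   1. Module_Brain_Extract [2026-09-26T03:46:16.706Z]
#>      parameters: sequence=Seq01, closing_radius=2, extension=brain
#>      inputs:  Raw_data/S01_T0_Seq01.nii.gz
#>      outputs: ROI_data/S01_T0_Seq01_brain.nii.gz
#>   ...
```

The same workflow is scriptable from a shell through the bundled launcher
(`inst/cli/voxpipe`): `init`, `import dicom|nifti|bids`, `db
list|filter|rename|delete` (with `--json` machine output), `pipeline
new|add|run --mode multi --workers N`, `stats`, `history`, and `fixtures
make`. See `?run_cli`.

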