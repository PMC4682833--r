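# spiolocate

Voxel-wise localization and quantification of SPIO-labeled cells in
multi-echo gradient-echo MRI.

Cells loaded with superparamagnetic iron oxide (SPIO) nanoparticles can be
tracked in vivo with MRI: the particles shorten T2\*, darken the magnitude
image, and imprint a dipole pattern on the phase. Any one of those cues is
ambiguous — air, bone and partial-volume voxels mimic them — so `spiolocate`
combines them. From a baseline (pre-injection) and a contrast scan, each
acquired at several echo times, it extracts a 13-channel feature vector per
voxel:

* **magnitude features** — per-echo signal intensity ρ, a volume of interest
  from spatial fuzzy c-means clustering, per-echo baseline-subtracted
  intensity change |Δρ|, and the R2\* map from a weighted log-linear fit of
  S(TE) = S₀·exp(−R2\*·TE);
* **phase features** — per-echo unwrapped, baseline-subtracted phase φ (3D
  best-pair-first region-merging unwrapping), an unreliable-phase indicator
  from extrapolating phase to TE = 0, a band-passed short-range perturbation
  map *s*, and a perturbation-propagation map *p* (growth rate of |s| with
  echo time).

A C-support-vector classifier with RBF kernel
k(x_i, x_j) = exp(−γ‖x_i − x_j‖²), trained on a labeled 15% subsample of
phantom voxels with (C, γ) self-tuned by five-fold cross-validation,
classifies every voxel as *containing* / *not containing* labeled cells.
R2\* in positive voxels is converted to iron oxide concentration (µM Fe₂O₃)
through a linear calibration R2\* = a + b·c fit on phantom inlays of known
concentration.

A physics-based simulator stands in for the scanner: agarose block phantoms
with five cylindrical inlays in a 2:1 dilution series from 480 down to 30
labeled cells/mm³ (313 → 19 µM Fe₂O₃), imaged with a 3-echo FLASH-type
protocol (TE = 2.54/3.78/11.34 ms, TR = 200 ms, flip 25°, 4.7 T, 0.4 mm
voxels), with mono-exponential T2\* decay, Fourier-domain dipole
susceptibility phase, and seeded Rician noise — plus full ground truth for
training and scoring. Datasets read and write as per-echo NIfTI pairs with a
YAML manifest (ANALYZE 7.5 is readable), so real scanner exports plug into
the same pipeline.

## Worked example

Simulate the default block phantom, run the full pipeline (register →
extract → train → classify → quantify → evaluate), and print the report:

```r
library(spiolocate)

cfg <- default_run_config()   # seed 1, paper-block phantom, 5% noise
out <- run_full_pipeline(cfg)
print(out$report)
```

```
<evaluation_report>
 inlay concentration sensitivity specificity volume_ratio detected_mean
     1           313      0.9958      0.9908       1.0097        285.02
     2           156      1.0000      0.9925       1.0115        156.88
     3            78      1.0000      0.9893       1.0158         78.95
     4            38      0.9759      0.9795       1.0051         38.33
     5            19      0.7601      0.9552       0.8263         23.04
 detected_sd   tp  fp   tn   fn
      152.14 5035  71 7633   21
       38.79 5056  60 7908    0
       24.35 5056  85 7883    0
       18.47 4934 163 7805  122
       15.08 3843 345 7359 1213
mean sensitivity 0.946, mean specificity 0.981, mean volume ratio 0.974
global specificity 0.9673, halo fraction 0.092
```

Each row is one inlay of the dilution series: sensitivity and specificity
are voxel rates inside the inlay plus a 3-voxel background shell,
`volume_ratio` compares detected to true inlay volume, and `detected_mean ±
detected_sd` is the R2\*-derived concentration over detected voxels (to be
read against the `concentration` column). The pattern mirrors the phantom
study: detection is essentially perfect down to 38 µM, the 19 µM inlay
(about 2 labeled cells per 0.4 mm voxel, ~180 pg iron) is the hardest,
mid-range concentrations are recovered to within a few percent, and the
highest concentration is underestimated because its signal at the longest
echo drops below the noise floor and the R2\* fit falls back to the first
two echoes.

`run_transfer_experiment()` performs the stricter version: train on one
phantom, apply the frozen model and calibration to an independently
simulated phantom, and report both.

A thin command-line wrapper is installed at
`inst/cli/spiolocate.R` (`simulate`, `run`, `evaluate` subcommands) for
shell use; the R API above is the primary interface.

## Package layout

* `R/` — simulator (`phantom.R`, `simulate.R`), I/O and configuration,
  feature extraction (`magnitude.R`, `phase.R`), registration, classifier
  (`svm.R`), evaluation, pipeline orchestration
* `src/` — Rcpp kernels: region-merging phase unwrapping, 3D connected
  components, binary dilation
* `vignettes/spiolocate-methods.Rmd` — the models, their assumptions, all
  tunable parameters, and the design decisions
* `tests/testthat/` — unit, property and acceptance suites with
  programmatically generated fixtures
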