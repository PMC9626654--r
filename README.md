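# rflesion

Morphometry and volumetry of radiofrequency (RF) ablation lesions in
myocardium, with a synthetic-phantom validation pipeline.

RF ablation creates volumes of coagulative necrosis whose size determines
whether an arrhythmia substrate is eliminated. Ex vivo studies measure
these lesions two ways — on high-field MRI stacks of the fixed heart and
on photographed gross-pathology slices — and quantify each lesion by four
landmark dimensions and a volume:

* **A** — maximum depth, from the catheter contact point on the
  endocardium to the lesion apex (mm);
* **B** — maximum width, reached at depth **C** (mm);
* **C** — depth of the maximum diameter (mm);
* **D** — estuary, the surface opening indented by the catheter (mm);
* volume, either from the closed formula

  $$LV = 0.75\,\pi\,(B/2)^2\,(A-C)\;-\;0.25\,\pi\,(D/2)^2\,(A-2C)\quad[\mathrm{mm}^3],$$

  or directly by Cavalieri slice summation ("point-by-point": outline the
  lesion on every slice, sum area × thickness).

`rflesion` implements the full chain for anyone who needs to measure
lesions from labelled 3D masks (NIfTI or multi-page TIFF) — detection,
dimension measurement in full-3D or observer-style best-slice mode, the
three volume estimators, and the paired multilevel statistics of a
method/observer comparison — and, because real lesions have no known
ground truth, a phantom generator that builds lesion solids with *exact*
dimensions and volume, renders MRI-like stacks (dark border zone, noise,
ghost lesions) and thick-slice pathology sections, and runs the entire
study end to end with emulated observers. The package reproduces, on
synthetic data, the central empirical finding of such comparisons: the
dimension formula systematically underestimates the volume of real
(irregular) lesions — direct slice summation gives roughly twice the
formula volume — while the two imaging routes agree on the dimensions
themselves.

## Worked example

Build a phantom with known truth, rasterize it at 0.2 mm, measure it, and
compare the volume estimators:

```r
library(rflesion)
set.seed(42)

spec <- lesion_spec(1, A = 9.0, B = 11.1, C = 4.8, D = 2.0)
spec
#> <lesion_spec #1> A=9.00 B=11.10 C=4.80 D=2.00 mm, V=573.7 mm^3, perturbation: none

scene <- rasterize_scene(wall_model(16, c(24, 24)), list(spec), spacing = 0.2)
rec <- measure_lesion(scene$mask, surface_ref(), mode = "full3d")
round(rec[, c("A", "B", "C", "D")], 2)
#>   A     B   C    D
#> 1 9 11.29 4.8 2.18

c(V_true         = spec$V_true,
  V_formula      = formula_volume(rec$A, rec$B, rec$C, rec$D),
  V_pointbypoint = as.numeric(pointbypoint_volume(scene$mask, axis = "z")),
  V_voxel        = voxel_volume(scene$mask))
#>         V_true      V_formula V_pointbypoint        V_voxel
#>       573.7400       315.8358       574.0160       574.0160
```

All four dimensions come back within 1.5 voxels of the truth. The
point-by-point (Cavalieri) volume matches the voxel reference exactly and
sits within 0.05% of the analytic truth, while the formula — which
assumes a regular ovoid — underestimates this lesion by ~45%: the
discrepancy the package is built to quantify.

The full synthetic study (99 lesions, 10 hearts, two modalities, two
observers × three repeats) runs in seconds and writes CSV tables, a
markdown report shaped like a method-comparison table, and a checksummed
manifest:

```r
res <- run_pipeline(pipeline_config(), "report", seed = 1)
res$comparisons$method_A          # paired method contrast for depth
res$comparisons$recognition      # chi-square on recognition counts
```

A thin command-line wrapper with subcommands
`simulate | measure | volumize | compare | run` ships at
`system.file("cli", "rflesion.R", package = "rflesion")`, and a fully
documented cohort configuration example at
`system.file("extdata", "cohort-example.yaml", package = "rflesion")`.

## Documentation

The methods vignette (`vignettes/lesion-morphometry.Rmd`) describes the
lesion model and its rationale, the acquisition emulations, every
measurement convention (voxel-centre semantics, extent corrections,
tie-breaking), the statistical design and its balanced-case closed form,
the default cohort, and the package's known limitations.
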