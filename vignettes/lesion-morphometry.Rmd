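---
title: "Measuring radiofrequency ablation lesions: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring radiofrequency ablation lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rflesion)
```

## Why a synthetic validation package

Radiofrequency (RF) ablation creates volumes of coagulative necrosis in
myocardium, and assessing an ablation strategy means measuring those
lesions: their depth, width, surface opening, and volume. In ex vivo
studies two measurement routes coexist - high-field MRI of the fixed heart,
and gross pathology inspection of hand-cut tissue slices - and a natural
question is whether they agree, both with each other and across observers.

Real studies cannot answer how *accurate* either route is, because the
true lesion geometry is unknown. `rflesion` closes that gap with
phantoms: parametric lesion solids whose dimensions and volume are exact
by construction, pushed through emulations of both acquisition routes and
through the same measurement and statistical chain an observer study
would use. Everything downstream of the phantom - detection, dimension
measurement, the three volume estimators, the paired multilevel
comparison - is production code that works on any labelled lesion mask,
not only on synthetic ones.

## The lesion model

A lesion is defined by the four landmark dimensions used in lesion
morphometry (all in mm):

* **A** - maximum depth, from the catheter contact point on the
  endocardium to the lesion apex;
* **B** - maximum width, attained at depth **C**;
* **C** - depth of the maximum diameter;
* **D** - estuary: the surface opening left by catheter pressure.

The solid is a body of revolution about the depth axis with radius
profile

$$
r(z) = \begin{cases}
\dfrac{D}{2} + \left(r_e(h) - \dfrac{D}{2}\right)
 \left(\dfrac{1-\cos(\pi z/h)}{2}\right)^{3}, & 0 \le z \le h,\\[6pt]
r_e(z) = \dfrac{B}{2}\sqrt{1 - \left(\dfrac{C - z}{C}\right)^{2}},
 & h < z \le C,\\[6pt]
\dfrac{B}{2}\sqrt{1 - \left(\dfrac{z - C}{A - C}\right)^{2}},
 & C < z \le A,
\end{cases}
$$

with a *neck depth* $h = \min(1, C/2)$ mm. The body and cap are quarter
ellipses - the classic ovoid of an RF lesion, and the shape the closed
volume formula (below) was conceived for. The neck is the package's own
addition: a real lesion opens to the surface through a narrow indentation
pressed by the catheter tip, and modelling that opening with an ellipse
would give the profile a vertical tangent at the surface, so that a voxel
half a layer below the surface would already be almost twice as wide as
the estuary. No mask-based estimator could then recover `D` at
realistic voxel sizes. The sixth-order cosine easing starts flat - the
radius stays at $D/2$ to fourth order in $z$ - which keeps the surface
layer of any reasonable rasterization at the estuary radius while joining
the ellipse smoothly in under a millimetre. By construction
$r(0) = D/2$, $r(C) = B/2$ is the unique maximum, and $r(A) = 0$.

Ground-truth volume is computed by adaptive quadrature of
$\pi r(z)^2$ over the three smooth pieces (relative tolerance $10^{-9}$),
and verified in the test suite against independent brute-force
voxelization.

### Irregular lesions

High-power ablation can rupture tissue ("steam pop"), producing
irregular, poorly bounded lesions. `perturb_steam_pop()` multiplies the
radius field by a smooth positive azimuthal modulation
$1 + a\,\sin(\pi z/A)\,s(\theta)$, where $s$ averages `n_lobes`
raised-cosine bumps at seeded random azimuths. The depth taper vanishes
at the surface and the apex, so the rupture spreads laterally: `A` and
`D` are unchanged while `B`, `C` and the volume are recomputed from the
perturbed solid (caliper width over azimuths; 2D quadrature over depth
and azimuth for the volume, again checked against voxelization). Fused
lesion pairs are built by placing a partner solid at a lateral offset;
the rasterized label map keeps the two identities while their binary
union forms a single connected blob.

## Acquisition emulation

**MRI-like stacks.** `render_mri()` paints the necrotic core, a dark
border-zone rim (the exact Euclidean dilation of the core by
`border_width` mm, minus the core), and background myocardium at three
intensity levels, and adds Gaussian noise. Two modelling choices are
deliberate simplifications. First, ex vivo proton-density images at high
field have high SNR, so additive Gaussian noise is used rather than a
Rician magnitude model; the noise enters through one argument and is easy
to swap. Second, the literature describes the *border zone* as dark but
does not pin down the core-to-myocardium contrast; the defaults (core
0.9, myocardium 0.55, border 0.15) are chosen for detectability, not
radiometric fidelity, and lesions below a configurable depth are rendered
nearly isointense to emulate the small "ghost" lesions that go
unrecognized in practice. The default grid is 1.0 mm slices with a
100/256 mm in-plane pixel (a 100 mm field of view on a 256 matrix).

Detection (`detect_lesions()`) thresholds the absolute contrast against
the volume median, takes 26-connected components, and drops components
below a minimum volume. Because lesion size is always measured on the
necrotic core only - the border zone is excluded by convention - the
pipeline restricts detected components to their bright side before
measuring.

**Pathology-like sectioning.** `emulate_patho()` cuts the volume into
half-open slabs `[kt, (k+1)t)` of thickness 3-5 mm and exposes each
slab's *proximal* cut face (a real knife cut exposes one face; the distal
face of a slab is the proximal face of the next). The first and last
slabs may be thinner; the face images carry the mm-per-pixel calibration
a photographed 1-cm caliper would provide. In the pipeline the cut
positions are *aimed*: the prosector slices through the visible lesion
with a uniform error of half an MRI slice thickness (`cut_aim`, default
±0.5 mm), and - because a knife cut is a continuous plane, not a raster
artefact - the face raster is aligned so that a layer centre sits exactly
at the aimed plane. The face offset from the lesion centre is then
*exactly* U(−0.5, 0.5) mm, the same distribution as the MRI slice offset
(1-mm slices cannot be aimed, so the best slice sits uniformly within
half a slice of the lesion centre). This choice is load-bearing for the
statistical design: any mismatch between the two modalities' offset
distributions turns into a systematic method effect, because chord
truncation at the apex and estuary is convex in the offset. During
development, letting the face position quantize to the 0.39-mm pixel
grid on top of the aim - a slightly heavier-tailed offset distribution
of equal variance - was enough to bias the depth contrast by 15 µm and
inflate its false-positive rate at n = 99. With identical offset
distributions the pipeline's no-method-effect null is true by
construction, which is exactly the condition under which its statistical
stage is validated. Both modalities also share the same in-plane pixel
size for the same reason.

## Measurement conventions

All measurements use the voxel-centre convention (a voxel's centre sits
half a spacing from its corner) with extent corrections that make
axis-aligned shapes exact:

* **Depth A** - largest signed voxel-centre depth below the endocardial
  plane, plus half a voxel.
* **Width B** - per constant-depth layer, the maximum caliper (Feret)
  diameter over voxel centres (computed on the convex hull) plus one
  in-plane voxel; `B` is the maximum over layers. The one-voxel
  correction is a constant, not a direction projection: a constant keeps
  the per-layer width monotone under set inclusion, which the `C`
  estimator depends on.
* **Depth of the maximum diameter C** - the layer attaining `B`. On a
  voxel grid several adjacent layers near a flat maximum tie *exactly*;
  ties are resolved by a deterministic chain: largest cross-section area
  first (area grows pixel by pixel, so it is a much finer monotone
  statistic), then the mean layer-centre depth of the remaining run. On a
  lesion uniformly wide over a depth range this places `C` mid-range.
* **Estuary D** - caliper extent of the lesion's cross-section within the
  voxel layer containing the endocardial plane; 0 with a
  `reaches_surface = FALSE` flag if the lesion does not reach it.

Two modes expose these definitions. `full3d` measures the whole mask.
`slice2d` emulates the observer: it selects the slice (perpendicular to a
lateral axis) with the largest lesion cross-section - "the slice where
the lesion reaches its maximum parameters" - and applies the same
definitions to that 2D section, where layers reduce to rows.
`measure_patho_stack()` does the same on the best thick-slice face.
Inconsistent results (an observer's `C > A` or `D > B` after noise) are
flagged, never rejected.

On 50 seeded phantoms rasterized at 0.2 mm, each dimension is recovered
within 1.5 voxels (measured maxima: A 0.10, B 0.20, C 0.26, D 0.19 mm).
One caveat is worth stating plainly: the `full3d` and `slice2d`
estimators have *different* discretization biases - the 2D Feret plus one
voxel reads about one voxel wider than a 1D row extent - so on a
symmetric lesion the two modes agree only to about two voxels in `B`,
`C`, `D` (depth agrees exactly), even though each mode individually is
within 1.5 voxels of the truth. Per-mode accuracy, not cross-mode
agreement, is the meaningful figure of merit.

## Volume estimators

Three estimators, by design of very different character:

* `formula_volume()` - the closed formula from the four dimensions,
  $LV = 0.75\pi (B/2)^2 (A - C) - 0.25\pi (D/2)^2 (A - 2C)$,
  read with $B/2$ and $D/2$ (dimensional analysis: mm³). $A - 2C$ may be
  negative, in which case the second term adds volume; a negative total
  (possible only for inconsistent inputs with $D > B$) is returned
  unclamped with a warning.
* `pointbypoint_volume()` - Cavalieri slice summation: cross-section area
  times thickness, summed over slices. Polygon outlines (the observer's
  route; shoelace areas, self-intersection rejected) and mask sections
  (pixel counts) are both supported; in mask mode at native slicing it
  reproduces `voxel_volume()` to the last bit.
* `voxel_volume()` - voxel count times voxel volume, the digital
  reference.

The formula assumes a regular ovoid and systematically underestimates the
ovoid-with-neck family: over the default cohort's dimension range the
relative error is typically ~45% (supremum 0.94 at the corner of the
valid region, where $C \to A$), so direct slice summation exceeds the
formula volume by a factor of ~1.6-1.7 on irregular steam-pop cohorts.
Reproducing the *direction and rough size* of that discrepancy - direct
volumes about twice the formula volumes - is one of the package's
acceptance properties; the exact factor depends on the lesion mix and is
not asserted.

## The statistical stage

Measurement tables are compared with the paired multilevel design of
repeated-measures method studies: fixed main effects for method, observer
and repeat (no interactions), a random intercept per lesion. For a
two-level factor `compare_factor()` reports the fitted mixed-model
contrast (`lme4`), which in a complete balanced design equals the mean of
per-lesion paired differences, and takes its p-value from the exact
paired t-test on lesion-level means with `n - 1` degrees of freedom - so
the balanced case is pinned to a closed form regardless of fitting
machinery, and the test suite asserts that equivalence to 1e-6. Lesions
missing a level (e.g. unrecognized on one method) are dropped pairwise.
The three-level repeat factor uses a within-lesion repeated-measures
ANOVA. Recognition rates are compared with an uncorrected Pearson
chi-square on the 2×2 table (Yates correction behind a flag); a
degenerate table (nothing missed by either method) returns
$\chi^2 = 0$, p = 1. Type-I error of the method contrast is verified by
simulation to sit in [0.02, 0.09] at $\alpha = 0.05$ over 200 null
cohorts.

## The default cohort, and what passing tests do not show

The default `pipeline_config()` draws 99 lesions across 10 hearts with
dimension targets (mean ± SD, mm) depth 9.0 ± 2.8, width 11.1 ± 2.8,
depth-of-width 4.8 ± 1.6, estuary 2.0 ± 0.9, truncated to mutually
consistent ranges; 15% of lesions carry a steam-pop perturbation
(amplitude 0.5, 3 lobes). Observer emulation adds per-dimension repeat
noise (0.15-0.3 mm) and opposite per-observer biases sized to produce a
~1.1 mm inter-observer width gap - the classic pattern of significant
inter-observer but negligible intra-observer differences - while leaving
the method contrast null. Lesions shallower than 4.5 mm render as ghosts
and go unrecognized on MRI.

Problem sizes in the test suite are chosen to keep the full run at a few
minutes on one core: 50 phantoms at 0.2 mm for recovery, 20 at 0.4 mm
for Cavalieri consistency, 200 null cohorts of 30 lesions for
calibration, and two full 99-lesion pipeline runs for the null pattern
and byte-level determinism.

The generator emulates the *geometry and sampling* of an ex vivo study,
not its physics. It does not model curved ventricular anatomy or
trabeculation (the wall is a flat slab), MR pulse-sequence physics or
Rician noise, formaldehyde shrinkage, registration between the MRI and
pathology frames, or observer outlining behaviour beyond additive
noise and bias. Passing tests therefore demonstrate that the measurement
chain is correct and calibrated on masks whose truth is known - they do
not certify accuracy on real scans, where segmentation and border-zone
delineation dominate the error budget.

## Reproducibility notes

Every random stage (cohort draw, grid alignment, rendering noise, cut
aiming, observer noise) derives from one integer seed through local RNG
scopes; `run_pipeline()` with a fixed seed is byte-identical across
reruns, and the manifest records per-table checksums. NIfTI round trips
are exact (masks as `int32`, images as `double`, spacing in the header);
TIFF pages are 32-bit with a power-of-two scale in a YAML sidecar, exact
for labels (re-rounded on read) and ~1e-9 relative for grayscale. A
volume file without spacing metadata is an error, never a silent 1-mm
default.
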