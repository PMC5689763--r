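---
title: "Methods: quantifying NSC biodistribution and tumor coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying NSC biodistribution and tumor coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nscoverage)
```

This vignette documents the models, the parameter choices and the
numerical conventions behind `nscoverage`, and is explicit about the
places where a design decision had to be made because the underlying
assay tradition leaves it open.

## The measurement problem

Enzyme/prodrug neural-stem-cell (NSC) therapy depends on geometry: a
secreted activating enzyme reaches only tumor tissue within some tens of
micrometres of each carrier cell. The assay quantified here images each
brain as pairs of consecutive 10 µm sections — an iron stain (Prussian
blue, pararosaniline counterstain) marking the NSCs on one slide, a DAB
immunostain (hematoxylin counterstain) marking tumor cells on the next —
with one pair analyzed per 200 µm of depth. From those pairs the
pipeline estimates, per section and per brain: NSC counts, tumor areas
and volumes, the tumor fraction within a radius of action of the NSCs,
and the spatial clustering of the NSCs.

## Stain separation

Chromagen staining is multiplicative in transmitted light, so analysis
happens in optical density, $OD = -\log_{10}(I/I_0)$ per RGB channel.
Two conventions are fixed here: intensities are floored at 1 before the
logarithm (a saturated-black pixel maps to finite density rather than
infinity) and densities are clipped below at zero (pixels brighter than
the background carry no absorbance). $I_0$ is the blank-slide white
point, a scanner property supplied by the user (default 255).

Color deconvolution solves, per pixel, $OD = M c$, where the columns of
$M$ are unit RGB absorbance vectors of the stains. With two stains the
basis is completed channel-wise by the residual vector
$v_{3,i} = \sqrt{\max(0, 1 - v_{1,i}^2 - v_{2,i}^2)}$ (the convention of
the standard plugin implementation of the algorithm). Raw concentrations
are kept unclipped; negativity is resolved only at mask building, where
pixels at or above a concentration threshold form the mask and
8-connected components below a minimum size are dropped. 8-connectivity
is the natural choice for blob-like cell profiles and is stated so the
component counts are reproducible.

For hematoxylin/DAB the published absorbance basis is shipped as a
preset. No published basis exists for Prussian blue/pararosaniline; the
preset for that pair is the vector pair used by the package's own
synthetic renderer and should be replaced by measured vectors for real
slides. The default segmentation threshold is a fixed concentration
cutoff of 0.3 with an optional Otsu mode (`threshold = "otsu"`); the
assay tradition does not state a thresholding rule, so this is a
declared default, not an inference. The Otsu implementation cuts at the
midpoint of the between-class-variance plateau, which is well defined
for the strongly bimodal channels deconvolution produces.

## Counting, coverage, and their conventions

**Counting.** The primary count is the marked-pixel ratio: marked area
divided by the mean single-cell area. The default mean area, 64 µm²,
corresponds to a 9 µm diameter cell, mid-range for 8–10 µm NSCs, and is
configurable; counts are kept as reals so the downstream extrapolation
stays linear. Resolved-cell detection (one centroid per 8-connected
component within an area band, default 20–400 µm²) supplies the
coordinates used by the spatial statistics. Touching cells are not
split; on the phantoms this matters little because overlap is sparse,
and it is listed as a limitation for dense real clusters.

**Coordinates.** Pixel indices are 0-based; $x$ is the column and $y$
the row times the pixel size; distances are measured between pixel
centers. These statements make the brute-force oracle unambiguous.

**Coverage.** A tumor pixel is covered at radius $r$ when its distance
to the nearest NSC-positive pixel is $\le r$ (zero where the masks
overlap). The implementation computes the exact squared Euclidean
distance transform of the NSC mask (the two-pass lower-envelope
algorithm, in C++) and thresholds it against the squared radius in pixel
units. Both sides of that comparison are exact — squared lattice
distances are integers — so the result equals per-pixel brute-force
enumeration *exactly*, and the test suite asserts identity, not
tolerance, on random mask pairs. Measuring from the nearest NSC *pixel*
realizes the "from the edge of each marked area" construction at the
renderer's resolution, because the marked area is itself made of pixels.
The two stains sit on consecutive sections; the pipeline assumes the
pair is co-registered and offers only a known rigid offset
(`offsetPx`) — estimating registration is out of scope.

**Theoretical maximum and efficiency.** The assay tradition compares
observed coverage to a "homogeneous distribution" maximum without
stating a formula. The definition adopted here is non-overlapping disks
fully inside the tumor: $\min(100, 100\,n\,\pi (r + r_{cell})^2 / A)$,
with $r_{cell} = 4.5$ µm by default (cell edge to cell center). It is an
upper bound for any arrangement of $n$ cells, which is exactly what an
efficiency denominator needs; efficiency is observed/maximum and can
exceed 1 only through the 100% cap, in which case a warning is raised.

**Degenerate inputs.** An empty NSC mask gives 0% coverage (sections are
evaluated whether or not NSCs are present); an empty tumor mask leaves
coverage undefined and errors, as do zero tumor area for the theoretical
maximum and zero denominator for efficiency.

## Serial-section stereology

One analyzed section represents its 200 µm interval. Volume is the
rectangular Cavalieri sum $V = \sum_i A_i \, \Delta$ with no
end-correction — the direct formalization of "extrapolating over the
spacing" — and NSC totals multiply each section count by
$\Delta / t = 200/10 = 20$. Whether the original assay counted one or
both sections of each slide is not stated; the factor is therefore
explicit in `SamplingScheme` and configurable. Whole-tumor coverage is
the area-weighted mean of per-section coverages: this is the estimand
the per-section construction defines (the package deliberately does
*not* compute 3-D sphere-union coverage, a different and larger
quantity, listed as a non-goal). Unit conversions (µm³ to mm³) live in
one helper so every stored quantity has a declared unit.

## Clustering index

Clusters are connected components of the graph joining NSC pairs at
pairwise distance $\le$ the clustering radius (default 50 µm) — single
linkage, chosen because the index is defined solely through pairwise
distances and a radius, and any density-based alternative would import
parameters the definition does not contain. Ties at exactly the radius
count as connected, for determinism. The index is
$CI = 1 - k/N$; it is 0 at complete dispersion and reaches its maximum
$1 - 1/N$ when all $N$ cells form one cluster (the verbal gloss "CI = 1
for a single cluster" is an idealization of that limit; the formula is
taken as authoritative). $CI$ is non-decreasing in the radius, which the
suite tests as a property.

## Diffusion model

The tortuosity-adjusted coefficient is $D^* = D/\lambda^2$; for a 60 kDa
carboxylesterase, $D = 4.3\times10^{-7}$ cm²/s and $\lambda = 2.25$ give
$D^* = 8.5\times10^{-8}$ cm²/s (two significant figures). The
steady-state profile from a non-depleting source with first-order
elimination $k_e$ is $C/C_0 = \exp\{-x\sqrt{k_e/D^*}\}$. Distances are
in µm and rates in s⁻¹; $D^*$ is converted internally by the exact
factor $10^8$ µm²/cm². $k_e$ has no established value and is therefore a
required input (or derived from a half-life, $k_e = \ln 2 / t_{1/2}$),
never silently defaulted.

One documented discrepancy: with this closed form, a profile at 50% at
25 µm forces exactly 25% at 50 µm (since $C(2x) = C(x)^2$), whereas the
assay literature quotes "24% at 50 µm"; the $k_e$ behind that figure is
not recoverable. The formula is implemented as stated and the
discrepancy is documented rather than patched.

## The phantom generator

`generatePhantom()` emulates the study's imaging so the pipeline can be
validated without animal data. Its defaults are the package's declared
study conditions:

* **Field and sampling** — 512×512 px at 1 µm/px; 12 analyzed depths
  200 µm apart; 10 µm slabs. Desk-scale rather than the original
  15 000² whole-slide scans, while preserving the sampling scheme.
* **Tumor** — an ellipsoid (semi-axes 200 × 160 × 900 µm) whose margin
  radius is modulated by low-order angular Fourier modes (modes 2–5,
  amplitude 0.08 of the radius, normalized to unit sup-norm so the
  amplitude is an exact bound). The analytic volume follows by
  quadrature; a fine-depth voxelization cross-checks it.
* **NSCs** — 10 000 retained of 20 000 administered (retention 0.5,
  the order of magnitude reported for intracerebral delivery at small
  doses), placed as 40% uniform interior points, 40% Thomas-process
  clusters (parents uniform, mean 8 offspring, 25 µm isotropic spread)
  and 20% edge-rim points within 40 µm of the margin — the mixture
  mirrors the qualitative observation that NSCs sit in clusters and
  near the tumor edge. The implied density, ≈ 8×10⁴ NSCs/mm³, sits in
  the 10⁴–10⁵ band typical of the assay. The Thomas process was chosen
  because its two knobs (parents, offspring spread) are directly
  interpretable.
* **Rendering** — cells become disks of radius 4.5 µm; per pixel
  $OD = \sum_s c_s v_s$ (target chromagen on objects, counterstain
  0.25 everywhere), $I = 255 \cdot 10^{-OD}$ plus Gaussian noise
  (sd 2 intensity levels), clipped to [0, 255] and left unquantized so
  that the noise-free round trip through deconvolution is exact to
  machine precision. Writing to PNG quantizes, and is tested
  separately.

Ground truth is computed by routes independent of the pipeline where it
matters: true coverage by stamping lattice disks around NSC pixels
(disk-union oracle) rather than by the distance transform, and volume
both analytically and by voxelization. Truth whole-tumor coverage is the
area-weighted aggregate at the sampled depths — i.e. the estimand the
per-section method defines, so that pipeline-vs-truth comparisons
measure pipeline error, not estimand mismatch.

What the phantoms do **not** emulate: brain anatomy and texture
(cortex/white-matter contrast), scanner artifacts, section tearing and
folding, registration error between consecutive sections, stain
variability between slides, and dense NSC clumps that merge into single
connected components. Passing the phantom suite therefore demonstrates
correctness of the measurement chain under the stated forward model, not
robustness to every pathology of real slides.

## Validation design and problem sizes

The suite's heavier checks use sizes chosen to be statistically
informative while keeping a full run in tens of seconds: the recovery
check runs the default 512×512 × 12-section phantom end to end (NSC
total within 15%, volume within 5% of the analytic value, per-section
coverage within 2 points of the oracle); oracle-equivalence uses 20
random mask pairs up to 256×256; the clustering sweep uses 30
single-section phantoms at 2 µm/px over a ~0.55 mm² tumor profile with
~30 in-slab cells, sweeping the Thomas spread from 3 to 150 µm —
dimensions at which a dispersed pattern is genuinely dispersed relative
to the 50 µm clustering radius, and the homogeneous-placement maximum is
not capped. The dose-response check holds geometry fixed and couples the
doses by nested subsampling of one point pattern, so monotonicity of
coverage in dose is isolated from sampling noise.

Two statistics caveats are deliberate and noted in report headers: raw
p-values are reported with no multiple-testing correction (matching the
assay tradition), and regressions are computed on linear values — log
axes in displays are presentation only.

## Known limitations

* No watershed splitting of touching cells; pixel-ratio counting is the
  robust estimator in dense regions.
* No registration estimation between consecutive sections (rigid offset
  hook only).
* No whole-slide pyramidal formats; inputs are flat PNG/TIFF.
* No stain-vector estimation from data (e.g. Macenko); vectors are
  supplied or taken from presets.
* The diffusion model is the 1-D steady-state closed form — no
  geometry, binding, or prodrug-conversion kinetics.
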