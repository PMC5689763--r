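# nscoverage

Quantification of neural stem cell (NSC) biodistribution and tumor
coverage in two-stain serial histology.

Tumor-tropic NSCs engineered to secrete a prodrug-activating enzyme
(e.g. a carboxylesterase converting CPT-11 to SN-38) kill tumor cells at
a distance: the enzyme diffuses away from each carrier cell, so every
tumor cell within a *radius of action* of an NSC is reachable by the
activated drug (the bystander effect). Whether such a therapy can work
therefore turns on a spatial question — after intracerebral or
intravenous administration, **where do the NSCs end up relative to the
tumor, and what fraction of the tumor do they put within reach?**

The experimental readout is pairs of consecutive 10 µm brain sections,
scanned at ~1 µm/pixel: one slide stains iron-loaded NSCs (Prussian blue,
pararosaniline counterstain), the next stains tumor cells
(anti-eGFP/DAB, hematoxylin counterstain), with one pair analyzed every
200 µm of depth. This package implements the complete quantitative
pipeline for such stacks, plus a seeded synthetic-histology generator
that makes every stage testable against exact ground truth.

## What it computes

* **Stain separation** — Beer–Lambert optical density
  (OD = −log₁₀(I/I₀)) and Ruifrok–Johnston color deconvolution: per
  pixel, solve OD = M·c where the columns of M are unit stain-absorbance
  vectors, giving one concentration channel per chromagen
  (`rgbToOD()`, `deconvolveStains()`, `segmentStain()`).
* **Cell quantification** — NSC counts by the marked-pixel ratio
  (marked area / mean single-cell area), resolved-cell centroids by
  8-connected components, tumor areas (`countCellsPixelRatio()`,
  `detectCells()`, `tumorArea()`).
* **Coverage mapping** — percent of tumor pixels whose Euclidean
  distance to the nearest NSC pixel is ≤ r (r = 25 or 50 µm), via an
  exact distance transform that provably matches brute-force
  enumeration; plus the homogeneous-placement theoretical maximum
  min(100, 100·n·π(r + r_cell)²/A) and the efficiency observed/maximum
  (`coverageFraction()`, `theoreticalMaxCoverage()`,
  `coverageEfficiency()`).
* **Volumetry** — Cavalieri tumor volume V = Σ Aᵢ·Δ (Δ = 200 µm),
  whole-tumor NSC totals by ×(Δ/t) slab extrapolation, NSC density per
  mm³, area-weighted whole-tumor coverage (`cavalieriVolume()`,
  `extrapolateCounts()`, `nscDensity()`, `wholeTumorCoverage()`).
* **Spatial statistics** — pairwise Euclidean distances, single-linkage
  clusters at a 50 µm clustering radius, and the clustering index
  CI = 1 − (clusters/NSCs), 0 = fully dispersed
  (`pairwiseDistances()`, `clusterPoints()`, `clusteringIndex()`).
* **Diffusion model** — tortuosity-adjusted diffusion coefficient
  D\* = D/λ² (λ = 2.25 for a 60 kDa enzyme in brain) and the
  steady-state profile C/C₀ = exp{−x·√(kₑ/D\*)}
  (`effectiveDiffusion()`, `relativeConcentration()`).
* **Cohort statistics** — OLS r², Spearman rank correlation, Welch
  unequal-variance t test, and the orchestration that turns image pairs
  (or phantoms) into per-section CSVs, per-brain JSONs and a cohort
  table (`runPipeline()`, `runPhantomCohort()`, `cohortStats()`).

## Worked example

A fully synthetic brain with known truth, through the whole pipeline:

```r
library(nscoverage)

spec <- phantomSpec(seed = 1L)        # 512x512 px, 12 depths, 10k NSCs
ph   <- generatePhantom(spec)         # images + exact ground truth
an   <- analyzePhantom(ph, spec)      # deconvolve, segment, measure

an$sections[5, c("depth_um", "nsc_count", "tumor_area_um2",
                 "cov_25um", "cov_50um", "clustering_index")]
#>  depth_um nsc_count tumor_area_um2 cov_25um cov_50um clustering_index
#>       800     68.77          89487    82.56     99.5           0.9677

t(round(an$brain[, c("tumor_volume_mm3", "total_nsc_count",
                     "pct_at_tumor", "nsc_density_per_mm3",
                     "cov_25um", "cov_50um")], 3))
#> tumor_volume_mm3        0.120
#> total_nsc_count      9674.062
#> pct_at_tumor           48.370
#> nsc_density_per_mm3 80287.207
#> cov_25um               83.976
#> cov_50um               99.286
```

Section 5 (800 µm deep) holds ≈ 69 NSC-equivalents of Prussian blue
signal in a 0.089 mm² tumor profile; 82.6% of that profile lies within
25 µm of an NSC. Across the stack, the Cavalieri volume is 0.120 mm³,
the extrapolated NSC total 9 674 (the generator placed 10 000 — a 3.3%
recovery error), i.e. 48.4% of the administered dose at the tumor at a
density of 8.0 × 10⁴ NSCs/mm³.

The diffusion side of the argument:

```r
dstar <- effectiveDiffusion(4.3e-7, 2.25)   # 8.49e-08 cm^2/s
ke <- (log(2) / 25)^2 * dstar * 1e8         # half-distance at 25 um
relativeConcentration(c(25, 50), ke, dstar)
#> [1] 0.50 0.25
```

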