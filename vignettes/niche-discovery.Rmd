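---
title: "Spatial neighborhood profiling and niche discovery: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial neighborhood profiling and niche discovery: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spatialniche)
```

## The problem

Multiplexed immunofluorescence (mIF) of tumor sections yields a marked
point pattern: every segmented cell has a position (in µm) and a set of
marker intensities. In ER-negative breast cancer, the spatial arrangement
of tumor NOS2 (iNOS) and COX2 expression relative to CD8+ T cells carries
prognostic information: diffuse CD8+ infiltration into the tumor core
accompanies survival, whereas CD8-excluded, COX2-expressing immune deserts
and NOS2+COX2+ inflamed margins with stroma-restricted CD8+ T cells
accompany poor outcome. `spatialniche` implements the full analysis chain
that turns such cell tables into outcome-associated cellular niches, plus
a synthetic tissue generator that makes every stage testable with known
ground truth.

## Phenotype quantization

Each marker intensity is cut into negative / weak / moderate / strong
levels by three thresholds. Boundaries are lower-inclusive (a value equal
to a threshold belongs to the upper level); positivity sets are
upward-closed so that raising an intensity can never lower a call. A cell's
phenotype is the 3-bit code `4*CD8 + 2*NOS2 + COX2`, giving eight classes.
Default positivity: CD8+ at any signal (lineage marker), NOS2+ and COX2+
at moderate-or-above (enzyme expression level). Whether strong COX2 cells
belong in the COX2+ census is genuinely ambiguous in visual-scoring
practice; both behaviors are available through the rule's positivity sets.
The NOS2 level is retained per cell even when NOS2 is negative, because
strong-NOS2 ("NOS2s") ratio analyses need it.

Published studies quantize visually; numeric thresholds are not printed.
The reproducible default (`derive_rule()`) places thresholds at the 0.5 /
0.75 / 0.9 quantiles of the pooled per-marker intensity distribution;
`canonical_rule()` (thresholds 1/2/3) matches the generator's intensity
model so that zero-noise simulations round-trip exactly.

## Neighborhood census

For every cell, the census counts neighbors of each phenotype in annuli
0–25, 25–50, 50–100, 100–150 and 150–200 µm and divides by the exact
annulus area, giving a 40-value descriptor in cells/mm². Conventions that
must be fixed for exactness, and are:

* intervals are half-open `[lo, hi)`; a neighbor at exactly 25 µm falls
  in the 25–50 annulus;
* the focal cell is excluded;
* densities are per annulus, not per cumulative disk (consistent with
  density-versus-distance profiles);
* censuses never mix cells from different samples.

The production implementation uses a fixed-radius spatial pair search
(`spatstat.geom::closepairs`); an exhaustive all-pairs oracle
(`census_oracle()`) with the same contract exists purely for validation,
and the suite checks element-wise agreement to 1e-9 on hundreds of random
instances. Cells whose 200 µm disk crosses the tissue bounds can be kept,
flagged (default) or excluded; exclusion reproduces the common practice of
annotating away edge effects, flagging preserves cell counts.

## Embedding and group contrast

The censuses of all cells are reduced to 2D with UMAP (`uwot`), with
neighbor count 30, minimum distance 0.1, Euclidean metric and a fixed
seed; these are defaults of this package, not claims about any published
configuration. By default the pipeline embeds per-bin neighbor *counts*
(density × annulus area) rather than raw densities: the innermost annulus
is ~100× smaller than the outermost, so a single neighbor there moves the
density by ~509 cells/mm², and a Euclidean metric on raw densities is
dominated by that quantization noise — in practice it fractures one
homogeneous niche into count-0 and count-1 islands. Count scaling
equalizes Poisson noise across annuli (variance ≈ mean count). Mean, SEM
and ratio profiles are always reported as unscaled densities.

Deceased and alive cells are histogrammed on a shared 100×100 grid over
the joint embedding extent, each group normalized to sum 1, and contrasted
as `log10((f_deceased + ε)/(f_alive + ε))` with pseudofrequency
`ε = 1/max(group size)`. Bins with log-ratio above +0.01 are
deceased-prevalent, below −0.01 alive-prevalent; the selection is
group-restricted (deceased cells from deceased-prevalent bins, and vice
versa). The log base is a package decision (only "log-ratio" is standard
terminology); the ±0.01 threshold is kept on the log10 scale.

## Niche discovery

Within each prevalent cell set, k-means (k-means++ initialisation, 10
restarts, best within-cluster sum of squares) is run for k = 2…10 in the
2D embedding, and the k minimising the Davies–Bouldin index

\[ DB = \frac{1}{k}\sum_i \max_{j \ne i} \frac{S_i + S_j}{d(c_i, c_j)} \]

is selected, ties broken toward smaller k. Clusters are named by
descending size (D1…Dk for deceased-derived niches, A1…Ak for alive).
Cluster summaries are the arithmetic mean ± SEM of the 40 census values
over member cells; niche contrasts are element-wise ratios of mean
profiles, with a small documented denominator floor (10⁻⁶ cells/mm² in
the pipeline) guarding empty entries.

## Survival analysis

Per-sample covariates are ratios of marker-positive to CD8+ cell counts
(NOS2s/CD8 uses strong-NOS2 cells only), or of gene expression
(NOS2/CD8A, COX2/CD8A) for expression cohorts. Ratios are dichotomized at
the median with ties assigned to "low" (a convention the published
analyses leave unstated). Five-year analyses administratively censor
events after the horizon rather than dropping them. Kaplan–Meier curves
and the pooled log-rank tabulation come from the `survival` package; the
Mantel–Haenszel hazard ratio is assembled as
`HR = (O_high/E_high)/(O_low/E_low)` with `se(log HR) = 1/√V` from the
log-rank variance, oriented so HR > 1 means the high-ratio stratum fares
worse. This O/E-ratio estimator is well calibrated when event fractions
are moderate, but is biased toward the null when nearly all subjects in
both strata have events — a known property, which is why the survival
simulator defaults to a clinically realistic 0.04 events/year baseline
hazard; at saturated follow-up no log-rank-derived estimator recovers
large hazard ratios unattenuated.

## The synthetic tissue generator

The generator emulates the study conditions rather than any particular
image. Geometry: a 3000×3000 µm field (origin bottom-left, y-up,
coordinates in µm), a central tumor-core disk of radius 800 µm and a
500 µm margin annulus; the remainder is stroma. Cells are homogeneous
Poisson per region × phenotype, plus Thomas-type (Poisson parents,
Gaussian offspring) clusters for edge satellites and stromal lymphoid
aggregates. Three archetypes:

* **immune_desert** (deceased): a CD8−NOS2−COX2+ dominated core
  (495 cells/mm², ~5× the background phenotype), no CD8+ cells inside the
  core or within the 50 µm gap beyond the tumor edge;
* **inflamed_margin** (deceased): a CD8−NOS2+COX2+ inflamed-edge zone in
  the margin plus Thomas satellites (12 parents, mean 3 offspring,
  σ = 30 µm) hugging the edge; CD8+ cells stroma-restricted to a dense
  band 50–100 µm beyond the tumor edge (1000 cells/mm²), with lymphoid
  aggregates 500–1000 µm out;
* **fully_inflamed** (alive): diffuse CD8+NOS2−COX2− infiltration
  (340 cells/mm²) across core, margin and stroma.

Intensity calibration of the planted niche is analytic: the alive
background CD8−NOS2+COX2+ intensity is 25 cells/mm²; the deceased margin
carries 250 cells/mm² so that the realized local density within 25 µm of
a margin cell — after ~5% annulus-boundary losses and the satellite
offspring field — is ~250 cells/mm², a 10-fold excess. The margin is
deliberately wider (500 µm) than the 200 µm census radius: when the zone
is narrower than the neighborhood scale, cells straddling the boundary
dominate any cluster that captures the zone and bias its mean profile
downward, which no longer measures the planted contrast. Absolute cell
counts (~5,000 per sample; ~50,000 per 5+5 cohort) are chosen for
single-CPU tractability, not to match any study's totals.

Marker intensities are drawn as level means (0.5/1.5/2.5/3.5, i.e. midway
between the canonical 1/2/3 thresholds) plus Gaussian noise (sd 0.15 by
default), so quantization by `canonical_rule()` is exactly invertible at
zero noise and ~99.9% faithful at the default. What the generator does
*not* emulate: segmentation errors, intensity spillover between
neighboring cells, staining batch effects, irregular (non-disk) tumor
geometry, holes and tears, or marker co-expression correlations beyond
those implied by the phenotype codes. Passing tests therefore demonstrate
correctness of the computational chain under idealized marked-Poisson
tissue, not robustness to real mIF artefacts.

Determinism: every sample is driven by a single integer seed; cohorts
derive per-sample seeds from the master seed by a fixed counter recurrence
(`(48271*master + 104729*i) mod 2^31−1`), so a master seed reproduces a
cohort byte-for-byte.

## Problem sizes and runtime choices

The test and acceptance runs use 5 deceased + 5 alive samples of roughly
5,000 cells each (~50,000 censuses, one UMAP of 50,000×40, adaptive
k-means over k = 2…10 with 10 restarts), 20 random 500–1,000-cell
instances for index-vs-oracle validation, 500 null replicates for
log-rank calibration and 200 simulated cohorts of n = 600 for
hazard-ratio recovery. These sizes make the whole chain reproducible on a
single CPU in minutes while keeping Monte-Carlo error well inside the
stated tolerances.

## Known limitations

* UMAP coordinates, and hence cluster shapes, are seed- and
  version-dependent; all downstream statements in this package are made
  about quantities that are stable under that variation (mean profiles,
  ratios, prevalence), never about embedding geometry itself.
* The Davies–Bouldin criterion prefers compact isotropic clusters; on
  manifold-shaped embeddings it can oversplit. Selected k should be read
  as "number of distinguishable neighborhood families", not anatomy.
* The O/E hazard-ratio estimator attenuates large effects under saturated
  follow-up (see above); Cox regression is deliberately out of scope.
* Region-composition statistics assign boundary cells as inside and
  resolve overlapping annotations by a fixed, documented priority order
  (lymphoid_aggregate > satellite > edges > large_tumor_nest >
  tumor_core > immune_desert > stroma); alternative conventions change
  percentages at the margin level only.
* Whether cross-type gap distances should be measured cell-to-cell or
  boundary-to-boundary is unspecified in the field; cell-to-cell is
  implemented.
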