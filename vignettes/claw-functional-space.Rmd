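---
title: "Quantifying claw function: stress intervals, functional triangles, and shape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying claw function: stress intervals, functional triangles, and shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the method

Claws (unguals) are among the most function-laden skeletal elements: the
same basic organ digs, hooks vegetation, or pierces prey depending on its
shape. `clawfsa` quantifies how well one claw shape serves each of those
three canonical functions, and how divergent its performance is across
them, using only mesh geometry and linear elasticity.

The pipeline is:

1. **Standardise** — meshes are uniformly scaled to a common surface area
   (`scale_to_surface_area()`), so stress levels compare shape, not size.
2. **Simulate** — three load scenarios are solved on each claw
   (`assign_scenario_loads()` + `solve_linear_elastic()`): scratch-digging
   (force on the ventral tip surface), hook-and-pull (force spread along
   the whole ventral surface), and piercing (proximally directed axial
   force at the tip). Each applies a 200 N total force to a mesh with the
   articular surface fixed, with elastic, isotropic, homogeneous bone
   (E = 20.49 GPa, Poisson 0.40). Units are mm / N / MPa throughout.
3. **Quantify** — each solution's von Mises stress field is reduced to an
   interval vector (`compute_interval_vectors()`): the percentage of
   model volume in each of 50 linear stress ranges, after trimming the
   top 2% of volume by stress to suppress constraint-point artefacts.
4. **Ordinate** — all interval vectors are log-transformed, standardised,
   and jointly ordinated by PCA (`ordinate()`) into a functional space.
5. **Condense** — each specimen's three scenario points form a functional
   triangle (`functional_triangles()`): the area measures functional
   divergence, the centroid the average performance, the signed sides the
   pairwise contrasts.
6. **Relate** — shape ratios (L/W, L/D, D/W), morphospace projection
   against a reference table (`morphospace_project()`), and OLS
   regressions (`regress_ols()`) connect function to form and size.

## The finite-element solver

The solver uses linear 4-node tetrahedra with **node-based strain
smoothing**: element strains are volume-averaged onto nodes before the
stiffness integration (one strain sample per node, weighted by the nodal
volume). The formulation reproduces any uniform-strain state exactly (it
passes the patch test to machine precision) and largely removes the
bending over-stiffness that plain constant-strain tetrahedra show at
practical mesh resolutions: on the 100 × 10 × 10 mm cantilever benchmark
at 40 × 8 × 8 hex-split resolution, plain constant-strain tets
under-predict the Euler–Bernoulli tip deflection by about 15%, while the
smoothed formulation lands within about 2.4% (and within about 4% on the
root-fiber bending stress, measured by extrapolating the top-fiber nodal
axial stress to the clamped plane, which avoids the clamped-corner
singularity). Plain constant-strain tets remain available via
`formulation = "cst"` for comparison.

Other solver choices:

* **Constraints.** All translations of every articular node are fixed —
  the simplest well-posed reading of "constrained on the articulation
  surface", and common practice in claw FE work. Roller (single-axis)
  constraints are supported for verification problems only.
* **Load directions.** The ventral scenarios push along each loaded
  facet's inward (dorsal-pointing) normal — a substrate-reaction model —
  with per-facet magnitude proportional to facet area; the assembled
  force is rescaled so the vector resultant is exactly the requested
  total (200 N by default). Piercing applies the force at tip nodes along
  the claw axis's distal tangent, negated (a proximally directed strike
  reaction).
* **Tip region.** The distal 5% of the axial parametric coordinate
  (configurable via `tip_fraction`). A boundary facet belongs to the tip
  when its *maximum* nodal coordinate reaches the threshold; the maximum
  (rather than the mean) keeps the tip set non-empty on coarse meshes.
* **Linear algebra.** One sparse symmetric factorisation per solve
  (`Matrix`); no iterative-solver tuning is exposed.

The solver's physics is verified by construction-independent properties:
rotation equivariance of the von Mises field, exact linearity in the
applied force, and the geometric scaling law vm ∝ s⁻² for a uniform
scale s at fixed force.

## The intervals method, exactly

For a field with element stresses $\sigma_e$ and volumes $v_e$:

* **Trim.** Elements are removed in descending stress order while the
  removed volume stays ≤ `trim_fraction` × total volume — whole elements,
  never exceeding the fraction. Default 0.02, configurable within the
  accepted 1–5% range.
* **Bin.** Fifty linear intervals on [0, U], where U is the pooled
  post-trim maximum across the batch (a shared bound is what makes
  vectors comparable across specimens and scenarios). Interval $i$
  accumulates volume of elements with stress in $[E_i, E_{i+1})$, last
  interval closed. Percentages are relative to the *original* pre-trim
  volume, so `sum(pct) + trimmed_pct = 100` always.
* **Transform.** $\log(p + c)$ with $c = 0.01$ percentage points. Empty
  intervals are common, so the offset is required; the transform-then-
  standardise order is used because standardising first would produce
  non-positive values that cannot be logged.
* **Ordinate.** Columns with zero variance are dropped; the rest are
  standardised to unit variance (correlation PCA) and decomposed.
  Component signs are fixed deterministically: PC1 is oriented to
  correlate non-negatively with the simulations' volume-weighted mean
  stress, so "higher stress" is always to the right and the low-stress
  region is quadrant II; PC2 onward get their largest-magnitude loading
  set positive. This makes quadrant semantics reproducible across runs
  and platforms.

Fifty intervals suffice: on 30-field synthetic batches the pairwise
score-distance matrices from 50- and 100-interval ordinations correlate
above 0.99 (this is re-measured by `scripts/acceptance.R`).

## Functional triangles and signs

The triangle is pure Euclidean geometry on the (PC1, PC2) scores: area by
the shoelace formula, centroid as vertex mean, sides as distances. The
three sides are directed vectors — "hook-and-pull to piercing",
"scratch-digging to piercing", "scratch-digging to hook-and-pull" — and a
side is **positive when its terminal scenario sits in a higher
volume-weighted mean stress field than its initial scenario** (higher
stress = worse suited), negative when lower, zero within a 1e-9 MPa
tolerance. "Higher stress field" is operationalised as the
volume-weighted mean von Mises stress of the underlying simulation,
because the PC1 position, while stress-correlated, is
ordination-dependent.

Two conventions deserve a note. First, published descriptions of this
sign rule are not internally consistent: prose summaries sometimes read
the sign the opposite way (negative = initial function lower-stressed).
This package implements the definitional rule above verbatim; with a
cohort whose digging stress is a multiple of its piercing stress, the
"scratch-digging to piercing" side is therefore *negative* (terminal
piercing vertex in the lower-stress field). Second, quadrant labels use
the half-open rule (0 counts as positive), so points exactly on an axis
classify deterministically; real ordinations never place one there.

## The morphometric layer

`measure_claw()` defines L, D, W as extents along the principal axes of
the node scatter: L along the first axis, D along whichever remaining
axis has the larger |z|-component (ties toward +z), W along the last.
For a curved claw L is thus a chord-like extent, not an arc length —
the convention is stated here because no universal one exists for
fossils. Volume uses the divergence theorem over the oriented boundary;
open surfaces yield `NA` volume with a warning but still return extents
and ratios.

`morphospace_project()` fits a covariance PCA to the log-transformed
ratio table of a reference sample and projects study claws as
supplementary points, leaving the reference scores untouched.
`divergence_metrics()` measures morphological divergence as the distance
from a designated baseline specimen in the first two morphospace
components — the baseline is an explicit argument because no operational
definition is standard — and reports functional divergence as both the
triangle area and a chosen signed side. Regressions default to log base
10 for size variables (configurable), and `p` comes from the two-sided
slope t-test on n − 2 degrees of freedom.

## The synthetic generator

`generate_claw_mesh()` sweeps an elliptical cross-section along a
circular arc that curves ventrally, tapering to a point as
$(1-u)^{p}$. Its purpose is to stand in for CT-derived fossil meshes in
tests: it spans curvature (0–180°) and depth/width gradients with exact,
seeded reproducibility. Cells of the swept lattice (wedges, hexes, and
the collapsed apex slab) are tetrahedralised through shared face-centre
and cell-centre nodes, which guarantees a watertight boundary for every
cell shape without diagonal bookkeeping; inverted or folded geometry is
a generation error, not a silent repair. Ring vertices sit at an
area-preserving radius (the inscribed polygon has exactly the ellipse's
area), so a straight cone's discretised volume matches $\pi r^2 L/3$
essentially exactly rather than carrying the usual inscribed-polygon
deficit.

Default shape (decided once, as a realistic robust digging-type ungual:
deep relative to length, moderately curved): length 50 mm, arc 60°, base
depth 20 mm, base width 10 mm (D/W = 2), taper exponent 1.2. The
parameter set takes `length_mm` as the primary size input and derives
the arc radius as length/arc; surface noise is expressed at the base
cross-section and tapers with the claw, which keeps arbitrary seeds from
folding the tip.

`generate_stress_field()` draws i.i.d. per-element stresses (lognormal,
gamma, or constant) so that distributional ground truth is exact — e.g.
a lognormal field's volume-weighted mean converges to
$\exp(\mu + \sigma^2/2)$. Spatial realism, when needed, comes from the
FE solver instead; the two sources are deliberately separate.
`make_benchmark_cohort()` combines both: claws spanning D/W and
curvature gradients, with per-scenario stress scales following stated
rules (a base mean, a digging multiplier, a pulling multiplier, an
optional stress gradient along the cohort), and a manifest recording all
ground truth.

What the synthetic data do *not* emulate: real CT segmentation noise,
taxon-specific geometry, keratin sheaths, or spatial stress correlation
in the i.i.d. fields. Passing tests therefore demonstrate that the
pipeline recovers known truths under controlled conditions, not that any
particular fossil result is correct.

## Problem sizes and numerical tolerances

The test-suite and acceptance computations use: the 40 × 8 × 8 cantilever
(15,360 tets) for the beam benchmark; claws at 8–32 axial segments
(≈ 700–19,000 tets) elsewhere; 30 × 2,000-element fields for interval
stability; 100 seeded replicates for the sign-recovery and separation
rates; 1,000 random triangles for the geometry oracle. Tolerances are
stated per property: machine-precision identities (volume conservation,
patch test, triangle oracles) at 1e-9–1e-12, physics invariances at
1e-6–1e-9 relative, discretisation-limited comparisons at 2–10%.

## Known limitations

* Absolute stress levels depend on the element formulation and mesh
  density; comparisons across studies should rely on the interval-vector
  ordination, which is scale-shared, rather than raw MPa values.
* The solver is linear and static: no contact, plasticity, keratin
  layering, or dynamic loading.
* Triangles are defined for exactly three scenarios; convex hulls of
  more simulations are out of scope.
* `measure_claw()`'s principal-axis convention can re-identify axes on
  near-isotropic shapes; it is intended for elongate claw-like meshes.
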