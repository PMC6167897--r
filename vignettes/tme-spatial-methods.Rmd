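---
title: "Quantitative spatial analysis of the PD-1/PD-L1 axis in the Merkel cell carcinoma TME"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative spatial analysis of the PD-1/PD-L1 axis in the Merkel cell carcinoma TME}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcctme)
```

## The problem

Merkel cell carcinoma (MCC) responds to PD-1 blockade in roughly half of
patients, but the standard predictive biomarker — a pathologist's binary
PD-L1 call at the 1% threshold — does not separate responders from
non-responders in this disease. The analysis implemented here asks a finer
question of the same tissue: *how many* PD-1+ and PD-L1+ cells are present
per unit area of tumor microenvironment (TME), *where* they sit relative to
the tumor–stroma interface, and *how often* the receptor and its ligand are
close enough (within 20 μm, roughly one to two cell diameters) to plausibly
interact. The package computes these quantities from segmented cell tables
and pathologist boundary annotations, and links them to response labels with
rank-based cohort statistics.

The package consumes outputs of upstream image-analysis software (cell
positions in μm with binary marker-positivity flags); segmentation,
spectral unmixing and positivity thresholding are explicitly out of scope.

## Region model

The tissue is partitioned relative to the annotated tumor boundary:

* **IT (intratumoral)** — inside the tumor polygon union, minus exclusions;
* **PT (peritumoral)** — outside the tumor but within the band width
  (default **100 μm**) of the boundary, minus exclusions, clipped to the
  tissue polygon when one is supplied;
* **EXCLUDED** — acellular/necrotic polygons, removed from both cell counts
  and area denominators;
* **OUTSIDE** — everything else (never analyzed).

Densities are counts over region area (cells/mm²); the **TOTAL** region is
the pooled IT ∪ PT region — pooled counts over pooled area, not a mean of
the two densities. Bands around nearby tumor nodules merge by construction
because the band is defined by Euclidean distance to the tumor union, so no
area is double-counted. Interior holes of annular tumors receive a band by
the same rule; nothing in the source material settles this case, and the
distance-based definition is the convention this package adopts.

Two deliberate tie-break rules make labels deterministic: a cell exactly on
the tumor border is IT (the tumor is a closed set), and a cell exactly on
the outer band edge is PT.

### Numerical implementation

No polygon-buffering geometry engine is used. Cell labels are assigned with
exact point-in-polygon and point-to-segment geometry, so a label never
depends on raster resolution. Region *areas* are measured on a raster: the
tumor union is scanline-rasterized and an exact Euclidean distance transform
gives every outside pixel's distance to the tumor, from which the band area
follows by counting pixels. For a 1000 × 1000 μm square tumor with a 100 μm
band the analytic band area is \(P w + \pi w^2 = 0.43142\ \mathrm{mm^2}\);
at the default 1 μm resolution the raster measurement agrees to about 0.1%
(the tests enforce < 1%). The error scales like the pixel size times the
boundary length over the band area, so the cohort simulations use a 3 μm
raster (≈ 0.5% area error, far below the Poisson noise of the cell counts)
to keep a 25-specimen cohort under a few seconds.

## Proximity metrics

`count_within_radius()` counts source cells (e.g. PD-1+) having **at least
one** target cell (e.g. PD-L1+) within the radius — each source counted
once, however many targets are near. Conventions:

* radius default **20 μm** with **strict** `<` comparison (the inclusive
  `≤` variant is a flag, since the two conventions appear side by side in
  the descriptive literature on this metric);
* distances are centroid-to-centroid by default; a `surface` mode subtracts
  the two cell radii (floored at zero) when the tables carry radii — the
  difference is bounded by the sum of the radii;
* the density denominator is the **total TME area** (IT + PT);
* when source and target are the same physical section, a cell is never its
  own neighbour (id-matched self-pair exclusion), so PD-1/PD-L1
  double-positive cells cannot trivially count themselves.

The engine is a uniform-grid spatial index in C++ returning exact
nearest-neighbour distances; the test suite proves exact equality against
an exhaustive \(O(n^2)\) scan on hundreds of random instances, and the
within-radius count is definitionally `sum(nn_distance < r)`, which is also
tested as a cross-operation invariant.

## Serial-section registration

PD-1 and PD-L1 are typically stained on consecutive 4 μm sections, so
cross-marker proximity requires aligning the sections first. The supported
contract is landmark-based: matched fiducial pairs, least-squares fit of a
rigid (orthogonal Procrustes via SVD, reflections disallowed), similarity,
or affine model, with the achieved RMSE reported. A residual above 20 μm —
the proximity radius — triggers a warning, because within-radius counts
across sections are then unreliable. Automatic feature matching is out of
scope; the synthetic generator emits landmarks with configurable noise so
the whole chain is testable end to end.

## Statistics

* **Mann–Whitney U** (two-sided) for group comparisons: exact enumeration
  when the pooled sample is ≤ 16 without ties, otherwise the normal
  approximation with tie and continuity corrections (`stats::wilcox.test`
  conventions; the tests validate against a from-scratch enumeration
  oracle).
* **Chi-square** for PD-L1 positivity fractions and score gradients.
* **Quartile stratification** by rank with ties to the lower quartile —
  deterministic on the 16–26 specimen cohorts this targets.
* **Density-adjusted proximity**: the published analysis "controlled for"
  the marginal PD-1+ and PD-L1+ densities without stating the method. This
  package residualizes the proximity density on the *ranks* of the two
  marginal densities (robust to the heavy right skew of density data) and
  compares residuals between groups; the output labels the method
  explicitly as this interpretation. Simulations in the test suite show the
  procedure has ≥ 80% power at n = 12 + 12 when proximity carries genuine
  independent signal, and a uniform p-value under label permutation.
* No multiple-testing correction by default (matching the reported
  unadjusted p-values); a Benjamini–Hochberg helper exists.

## The synthetic TME generator

No patient data accompany the study this pipeline re-implements, so the
generator is the test bed. It emulates:

* a blob tumor (radial Fourier perturbation of a disk, star-shaped hence
  simple by construction; mean radius 350 μm, roughness 0.15, one optional
  necrotic exclusion in 25% of specimens);
* tumor cells as homogeneous Poisson at 2,500 cells/mm² inside the tumor;
* an immune infiltrate as inhomogeneous Poisson with intensity
  \(\lambda(d) = \lambda_0 e^{-d/\tau}\) in the distance \(d\) to the
  interface on both sides (\(\tau\) = 75 μm), realized by thinning a
  homogeneous proposal — exact and simple to test;
* lineages drawn per immune cell (CD8 0.45, CD4 0.35, CD20 0.08, CD68 0.12;
  FoxP3 in 22% of CD4 cells, matching the reported Treg share of the
  CD4+PD-1+ pool when PD-1 is drawn independently within CD4 cells; a rare
  NKp46 marker at ~1 cell/mm² for completeness);
* **adaptive PD-L1**: \(P(\text{PD-L1+}) = \mathrm{logit}^{-1}(\alpha +
  \beta k)\) with \(k\) the cell's PD-1+ neighbour count within 20 μm —
  ligand spatially coupled to attack; **constitutive PD-L1**: Bernoulli on
  tumor cells, independent of infiltrate. This is the distinction the
  proximity metric exists to detect, and the tests verify that at *matched
  marginal densities* adaptive specimens show systematically higher
  proximity density.

Calibration is solved, not searched: given per-specimen target densities,
\(\lambda_0\) follows from the intensity integral over the TME raster,
the PD-1 probability from the realized lymphoid count, and the adaptive
intercept \(\alpha\) by root-finding on the realized neighbour counts — so
cohort medians match their targets in expectation by construction, with no
rejection sampling. Targets for the cohort presets are drawn per specimen
from log-normal distributions centred on the published cohort medians
(responder-like: PD-1 70.7, PD-L1 855.4 cells/mm²; non-responder-like: 6.7
and 245.0), with log-scale spreads (0.5–1.0) chosen once so the simulated
ranges echo the published ranges; CD8 targets are drawn from overlapping
distributions (medians 264 vs 216.6, log-sd 0.9) in both groups, so CD8
does *not* separate groups — the study's key negative finding. Responder
specimens use the adaptive program, non-responders the constitutive one.

Determinism: every specimen draws from a stream seeded by (cohort seed,
specimen index); geometry, cells and sectioning use offset sub-seeds so
each stage is individually reproducible. Identical seeds give bit-identical
output tables.

What the generator does **not** emulate: cell-shape and segmentation error,
staining artifacts, intensity distributions (flags are generated directly),
spatial clustering of tumor cells beyond the blob geometry, 3D tissue
context, and inter-marker registration error beyond a rigid transform with
Gaussian jitter. Passing tests therefore demonstrate the pipeline's
correctness and the detectability of the adaptive-vs-constitutive contrast
under the stated point-process model — not performance on real slides.

## Problem sizes and runtime choices

The simulated specimen is ~0.4 mm² of tumor with ~1,500–3,000 cells — on
the order of the smallest contiguous tumor deposits (~1 mm²) such analyses
accept, sized to keep a 100-seed cohort study in the test suite to a few
minutes. Oracle comparisons run up to n = 2,000 cells
per side against exhaustive scans; the cohort-structure checks use 100
cohorts of 17 + 8 specimens. The acceptance script reruns the cohort
analysis at the study size (17 vs 8) plus a 30-replicate power estimate.

## Known limitations

* The PT band is distance-defined, so partitions are serialized as the
  generating geometry plus band width rather than as band polygons.
* Pathologist PD-L1 scores here derive from cell flags; the original scores
  came from visual assessment of stain, which may diverge from cell-level
  counts when staining is diffuse.
* The high-power-field area for multiplex summaries defaults to 0.335 mm²
  (a common 20× field size); the source material does not state one.
* The density-adjustment method is one defensible reading of an
  underspecified analysis; conclusions drawn from it should be labelled
  accordingly, as the output does.
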