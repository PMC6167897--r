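# mcctme

Quantitative spatial analysis of the PD-1/PD-L1 axis in the Merkel cell
carcinoma (MCC) tumor microenvironment (TME), as an R package plus a set of
analysis drivers.

## The problem

MCC responds to PD-1 blockade in about half of patients, but the standard
biomarker — a pathologist's binary PD-L1 call at the 1% threshold — does not
predict who. Finer, spatially resolved measurements do carry signal: the
density of PD-1+ and PD-L1+ cells per mm² of TME, and in particular how many
PD-1+ cells have a PD-L1+ cell within 20 μm — close enough for the receptor
and its ligand to interact. That proximity count distinguishes *adaptive*
PD-L1 expression (induced locally by immune attack, hence spatially
juxtaposed with infiltrating lymphocytes) from *constitutive* expression
(tumor-intrinsic, independent of infiltrate), which looks identical in a
binary PD-L1 call but does not indicate an endogenous antitumor response.

The package implements the full measurement chain on segmented cell tables
(one row per cell: x/y in μm, binary marker flags) and pathologist boundary
annotations:

* **Regions** — partition tissue into intratumoral (IT) and peritumoral
  (PT, 100 μm band beyond the tumor–stroma interface) regions with
  necrotic/acellular exclusions; densities are counts over region area,
  with the *total* TME = IT ∪ PT.
* **Registration** — rigid/similarity/affine landmark alignment of serial
  sections (orthogonal Procrustes), so markers stained on consecutive
  slides can be co-analyzed.
* **Proximity** — `count_within_radius(PD1, PDL1, radius = 20)`: the number
  of source cells with ≥ 1 target cell within the radius (strict `<`,
  counted once per source), normalized by total TME area; plus
  nearest-neighbour distances and the transposed metric.
* **Densities and scores** — per-region marker densities, PD-L1 positive
  tissue-area fraction from masks, pathologist-style PD-L1 bins
  (<1%, 1%, 2–4%, 5–9%, 10–19%, … ; positive at ≥ 1%).
* **Phenotyping** — priority-gated lineage calls (tumor/NSE, CD8 T, Treg =
  CD4+FoxP3+, CD4 T, B cell, macrophage), hot-spot field selection, PD-1
  co-expression summaries.
* **Cohort statistics** — two-sided Mann–Whitney (exact when enumerable),
  chi-square, rank quartile stratification, and a rank-residualization
  "density-adjusted" proximity comparison.
* **Synthetic TME generator** — seeded specimens with interface-enriched
  infiltrates and adaptive vs constitutive PD-L1 programs, calibrated to
  published cohort medians, so the whole pipeline is testable without any
  patient data (none are publicly deposited).

## Worked example

```r
library(mcctme)

# one synthetic responder-like specimen, calibrated to the cohort medians
sp <- simulate_specimen(sim_params(seed = 7, necrosis_prob = 1,
                                   pd1_target_density  = 70.7,
                                   pdl1_target_density = 855.4,
                                   cd8_target_density  = 264,
                                   pdl1_mode = "adaptive"))
print(sp$partition)
#> region_partition: band 100 um | IT 0.3846 mm^2, PT 0.2668 mm^2,
#>   total 0.6513 mm^2, excluded 0.0086 mm^2

density_table(sp$cells, sp$partition, c("PD1", "CD8", "PDL1"), "TOTAL")
#>    marker count   density
#>       PD1    37  56.80606   # cells/mm^2 over the total TME
#>       CD8   187 287.10088
#>      PDL1   540 829.06136

pd1  <- marker_positive(sp$cells, "PD1")
pdl1 <- marker_positive(sp$cells, "PDL1")
count_within_radius(pd1, pdl1, radius = 20,
                    area_mm2 = sp$partition$total_area_mm2)
#> proximity_result: 30 / 37 source cells with a target within < 20 um
#>   (density 46.06 /mm^2 over 0.651 mm^2)
```

The proximity density (~46 PD-1+ cells/mm² with a PD-L1+ neighbour) is the
biomarker: under the constitutive PD-L1 program at the same marginal
densities it drops several-fold, which is exactly what the cohort tests
exploit.

The numbered scripts under `analysis/` run the complete study workflow —
`01_simulate_cohort.R` (17 responder-like vs 8 non-responder-like specimens
through the full pipeline), `02_regions_and_densities.R`,
`03_registration_and_proximity.R`, `04_phenotyping.R`,
`05_cohort_statistics.R` — each writing its tables under `results/` and
printing what it found. On the default seed the cohort comparison gives
median PD-1+ densities of 58.1 (R) vs 9.1 (NR) cells/mm² (p = 1.4e-4),
PD-L1+ 860.3 vs 216.3 (p = 1.7e-4), proximity 45.5 vs 0.8 (p = 8.2e-5),
while CD8+ density does not separate the groups (p = 0.58) — every
responder sits in the top PD-1 quartile's responder fraction of 1.0 and no
responder in the bottom quartile.

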