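# hexiz

Spatial indicators of tumor biology from digital-pathology cell detections,
computed on randomized hexagonal grids.

Two biomarker families motivated by breast-cancer prognosis research are
implemented end-to-end:

- **Ki67 intratumoral heterogeneity (ITH).** Tumor-cell detections are
  subsampled by a dense hexagonal grid (side 262.5 μm at 0.5 μm/pixel);
  hexagons with fewer than 50 cells are discarded; per-hexagon Ki67
  positivity percentages are ranked into 10 intervals (0–10%, >10–20%, …);
  a symmetric co-occurrence matrix *P* over adjacent hexagons yields
  Haralick texture indicators, with entropy
  *H = −Σᵢⱼ pᵢⱼ ln pᵢⱼ* as the headline biomarker
  (0 = spatially uniform, ln 100 ≈ 4.61 = maximal heterogeneity).
- **CD8 immunogradient.** A finer grid (side 65 μm) carries per-hexagon
  tissue-class area fractions from a tumor/stroma/background label map.
  Hexagons with abrupt tumor-fraction changes along a grid axis form the
  tumor edge (rank 0); remaining hexagons get signed ranks by hexagonal
  distance (tumor side +, stroma side −), and the nine-rank interface zone
  (−4…+4) yields eight indicators: mean/SD of CD8⁺ density (cells/mm² of
  analyzed tissue) in the stroma, edge and tumor aspects, the immunodrop
  *ID = D̄(−1)/D̄(+1)*, and the center of mass
  *CM = Σ r·D̄ᵣ / Σ D̄ᵣ* of the density profile.

A survival layer provides optimal-cutoff dichotomization (log-rank scan),
a univariate screen, multivariable Cox regression with Harrell's C, and a
combined prognostic score (CPBS) summing binary poor-prognosis indicators
into low / intermediate / high risk groups (maximum score 4 for the
ER+HER2− model, 3 for the TNBC model).

Because matched slide/outcome data of this kind are not publicly
deposited, the package ships synthetic generators for tissue label maps,
cell tables (Poisson point processes with a controllable CD8 drop factor κ
and Ki67 patch mosaic), and proportional-hazards survival cohorts — every
stage of the pipeline is testable without any download.

## Worked example

Simulate a tumor–stroma slide with a twofold CD8 density drop at the
boundary, then compute all indicators:

```r
library(hexiz)

tissue <- generate_tissue_map(tissue_scenario(
  2600, 3900, list(type = "half_plane", boundary_x_px = 1300)))
cells <- generate_cells(tissue, cell_scenario(
  tumor_cell_density_mm2 = 2000, ki67_base = 0.3,
  cd8_lambda_s_mm2 = 800, cd8_kappa = 2, cd8_decay_um = 4000, seed = 11))

res <- run_slide(cells, tissue, analysis_config(grid_seed = 42),
                 run_qc = FALSE)  # small demo slide; QC expects >= 6 mm^2
res
#> slide_result
#>   tumor content: 1.27 mm^2 (QC fail)
#>   Ki67: entropy 1.376 over 12 hexagons (global 30.5%)
#>   CD8: m_S 811, m_TE 609, m_T 392 cells/mm^2, ID 2.29, CM -0.79
```

The Ki67 positivity is spatially uniform here, so entropy is low; the CD8
profile recovers the simulated gradient: stromal density ≈ the generating
800 cells/mm², a drop across the edge with ID ≈ 2 (the generator's κ), and
a negative center of mass (stroma-concentrated infiltrate).

The numbered drivers under `analysis/` run the full study on synthetic
data: `01_simulate_slides.R` (slide generation), `02_slide_indicators.R`
(per-slide indicators and interface-zone export), `03_parameter_recovery.R`
(κ and patchiness recovery over 20 seeds), `04_cohort_models.R`
(252-patient simulated cohort: screen → Cox → CPBS → Kaplan–Meier export).
Outputs land under `results/`.

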