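#!/usr/bin/env Rscript
# Simulate the synthetic slides used throughout the analysis: a half-plane
# tumor-stroma slide with a CD8 gradient (drop factor 2), plus two all-tumor
# slides with spatially uniform and patchy Ki67 positivity at the same
# global positivity rate. Writes label-map PNGs and cell-table CSVs.

suppressPackageStartupMessages(library(hexiz))
out <- "results/slides"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# tumor on the right half; 1.3 x 1.95 mm at 0.5 um/px
tm_grad <- generate_tissue_map(tissue_scenario(
  2600, 3900, list(type = "half_plane", boundary_x_px = 1300)))
cells_grad <- generate_cells(tm_grad, cell_scenario(
  tumor_cell_density_mm2 = 2000, ki67_base = 0.3,
  cd8_lambda_s_mm2 = 800, cd8_kappa = 2, cd8_decay_um = 4000, seed = 11))
write_tissue_map(tm_grad, file.path(out, "gradient_tissue.png"))
write_cell_table(cells_grad, file.path(out, "gradient_cells.csv"))
message(sprintf("gradient slide: %d cells (%d CD8+), tumor %.2f mm^2",
                nrow(cells_grad), sum(cells_grad$marker == "cd8"),
                tumor_area_mm2(tm_grad)))

# all-tumor slides for the Ki67 heterogeneity arm, 2.25 x 2.25 mm
tm_ki <- generate_tissue_map(tissue_scenario(
  4500, 4500, list(type = "uniform", class = "tumor")))
write_tissue_map(tm_ki, file.path(out, "ki67_tissue.png"))
for (kind in c("uniform", "patchy")) {
  spread <- if (kind == "uniform") 0 else 0.3
  cells <- generate_cells(tm_ki, cell_scenario(
    tumor_cell_density_mm2 = 2000, ki67_base = 0.3, ki67_patch_um = 400,
    ki67_patch_spread = spread, cd8_lambda_s_mm2 = 0, seed = 12))
  write_cell_table(cells, file.path(out, paste0("ki67_", kind, "_cells.csv")))
  message(sprintf("ki67 %s slide: %d tumor cells, %.1f%% positive",
                  kind, nrow(cells), 100 * mean(cells$positive)))
}
message("slides written to ", out)
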