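# colonymap

Multi-scale image analysis of pluripotent stem cell colonies in R.

Human pluripotent stem cells grow as spatially patterned colonies, and a
cell's position in that structure — loosely attached at the periphery, in
the outermost cell layer, or inside a dense patch — covaries with its cell
cycle state and pluripotency marker expression. Imaging whole colonies at
single-cell resolution means acquiring a grid of overlapping microscope
fields; `colonymap` turns per-field segmentations of such a grid into one
seamless *virtual slide* and quantifies each cell in its spatial context.
It is written for imaging groups doing colony-resolved image cytometry and
smFISH transcript counting, and for anyone who needs a fully synthetic,
ground-truthed benchmark of such a pipeline.

The package provides:

* **Virtual slide construction** — per-field label matrices are merged by
  overlap consensus: two instances of one object (footprints overlapping in
  region coordinates, centroids within one cell diameter) are resolved by
  keeping the larger; raw pixels are never stitched. With field overlap
  ≥ 2 × the maximum cell diameter, every cell is wholly contained in at
  least one field, so the merged map is seamless.
* **Segmentation and features** — colony masks by Gaussian blur + Otsu
  threshold on the mosaic; nuclei by local-background thresholding and a
  distance-transform watershed; per-cell area, perimeter, eccentricity,
  integrated/mean intensities; per-colony geometry including the maximum
  edge distance used for small/medium/large classes (<150 / 150–300 /
  >300 µm).
* **Spatial context** — distance from the colony edge via the Euclidean
  distance transform (0 outside any colony), cell layers in bands of one
  cell diameter, equal-count distance bins, and 250 × 192 µm density
  windows classed low/mixed/high.
* **Gating with bootstrap CIs** — 2N/4N DNA gates from a two-component
  mixture on log integrated DNA (fit on EdU-negative cells), S/M marker
  thresholds at mixture antimodes, precedence S > M > G1/G2, and percentile
  bootstrap confidence intervals for subpopulation frequencies
  (B multinomial resamples per bin).
* **smFISH** — 3-D spot detection (per-plane top-hat, Laplacian of
  Gaussian, 26-connectivity maxima) scored by a curvature × intensity
  statistic; per-field detection thresholds `S = [s_xy]` equalized by
  minimizing the margin-count error
  `E(S) = Σ (f_r(s_xy) − f_l(s_x+1,y))^p + (f_b(s_xy) − f_t(s_x,y+1))^p`
  over adjacent field pairs (p = 2, or 1 for robustness); nuclei expanded
  into cell territories; margin duplicates merged so every molecule is
  counted once.
* **Synthetic truth** — `generate_colony_scene()` and
  `generate_smfish_stack()` build colony scenes and z-stack regions with
  known cells, phases, marker states and spot positions, including
  per-field gain/background effects and an across-region gain gradient.

## Worked example

Simulate a three-colony scene, image it as a 3 × 3 grid of overlapping
fields, and run the full analysis:

```r
library(colonymap)

cfg <- pipeline_config(
  seed  = 1,
  scene = scene_params(n_colonies = 3, cells_per_colony = 300,
                       scene_w_um = 900, scene_h_um = 900,
                       colony_radius_um = 140),
  grid  = list(nx = 3, ny = 3, field_w = 340, field_h = 340, overlap = 60),
  layers = list(cell_diameter_um = 12),
  gating = list(B = 1000, seed = 1))
res <- run_pipeline(cfg, output_dir = "out")

nrow(res$cells)               # 921 cells in 3 colonies
table(res$cells$phase)
#>   G1            S           G2            M unclassified
#>  374          291          208           46            2

subset(res$layer_freqs, phase %in% c("G1", "G2"))
#>      layer phase   n freq ci_lo ci_hi
#>  periphery    G1  26 0.88  0.73  1.00
#>     layer1    G1 176 0.34  0.27  0.41
#>     layer2    G1 158 0.34  0.27  0.42
#>     layer3    G1 144 0.40  0.32  0.48
#>   interior    G1 415 0.43  0.39  0.48
#>  periphery    G2  26 0.00  0.00  0.00
#>     layer1    G2 176 0.31  0.24  0.39
#>     layer2    G2 158 0.33  0.26  0.40
#>     layer3    G2 144 0.19  0.12  0.26
#>   interior    G2 415 0.18  0.14  0.22
```

The peripheral population (distance-from-edge 0) is strongly G1-enriched
(0.88 with 95% CI 0.73–1.00, against 0.34–0.43 in the colony proper), and
G2 cells are enriched in the outer cell layers (0.31–0.33) relative to the
third layer and interior (0.18–0.19) — the spatial pattern the generator
plants. The planted first-layer G2 enrichment partly smears into the second
layer because the measured edge distance carries a few micrometres of
boundary error; the truth-based acceptance tests resolve the layer-exact
ordering. `out/` receives `cells.csv`, `colonies.csv`, `windows.csv`,
`bin_freqs.csv`, `layer_freqs.csv`, 16-bit label TIFFs and a
`parameters.txt` log of every threshold actually used.

## Package layout

```
R/                  implementation (scene generator, virtual slide,
                    segmentation, context, gating, smFISH, pipeline)
tests/testthat/     unit, property and acceptance tests
scripts/acceptance.R   standalone acceptance computation
vignettes/          methods and design notes
inst/cli/colonymap.R   command-line front end
```
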