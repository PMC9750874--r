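# imdassay

Spatial single-cell analysis of intratumor microdevice drug assays.

An implantable microdevice (a 5.5 mm × 750 µm cylinder with up to 18
surface reservoirs) releases nanoliter doses of different drugs into
spatially separate regions of a living tumor. Sections through each
reservoir are stained by multiplexed chromogenic immunohistochemistry
(mIHC), and the local drug response is read out as changes in
tumor-microenvironment composition and organization with distance from
the drug source. `imdassay` implements the computational pipeline for
that assay, for labs running microdevice or comparable local-perturbation
experiments:

* **imaging** — Ruifrok–Johnston stain deconvolution of the hematoxylin
  round; AEC chromogen extraction as the CMYK yellow channel
  (`K = 1 − max(r,g,b)`, `Y = (1 − b − K)/(1 − K)`); seeded-watershed
  nuclear segmentation; per-cell mean intensities scaled to [0, 1] by the
  image dtype maximum; feature-based (ICP/Kabsch) round co-registration.
* **phenotyping** — hierarchical gating of the cell table into the 17
  standard cell types defined over the 13-marker baseline panel (Epcam,
  CD45, CD31, αSMA, CD3, CD4, CD8, CD11b, F4/80, CSF1R, CD11c, Ly6G,
  MHC-II), plus translatable polygon gates, control-derived thresholds,
  and extended phenotype refinements.
* **spatial statistics** — everything in a well-centered frame (drug
  source at `(0,0)`, release along +y): distance-based clustering as
  single-linkage connected components at `d_max` with a `min_cells`
  floor (defaults 50 µm / 10 cells); assay-region selection (nearest
  3,000–5,000 cells above the well, control matched within ±300);
  relative-abundance profiles with Gaussian + moving-average smoothing;
  seeded circular ROI sampling (175 µm); pairwise proximity statistics
  (proportion of pairs < 50 µm).
* **enrichment** — paired one-tailed t-tests of per-type percentages
  (assay > control) across reservoir replicates with the published noise
  floor (≥12 cells and ≥0.75%), and heatmap-ready matrices.
* **synthetic data** — a ground-truthed scene generator (Poisson
  background, exponential recruitment gradients, planted clusters,
  per-marker Beta intensity mixtures) and a chromogenic image renderer,
  so every stage is testable without animal data.

## Worked example

A synthetic reservoir with a dendritic-cell recruitment gradient and three
planted pericyte microclusters, analyzed end to end:

```r
library(imdassay)

sc <- scene_config(
  gradients = list(list(label = "dendritic cell",
                        amplitude = 1e-3, decay_length = 150)),
  planted_clusters = list(list(label = "pericyte", n_clusters = 3,
                               cells_per_cluster = 15, spread_sd = 8)),
  seed = 1)
scene <- generate_scene(sc)
scene
#> Synthetic scene: 5117 cells, arena [-600, 600] x [-300, 900] um, seed 1
#>   1 gradients, 1 planted cluster groups

tree <- load_gating_config()
tree
#> Gating tree 'standard-17': 17 leaf cell types over 13 markers
#>   provenance: reconstructed
scene$cells$label <- classify_cells(scene$cells, tree)

per <- scene$cells[scene$cells$label == "pericyte", ]
cluster_by_distance(per[, c("x_um", "y_um")], d_max = 50, min_cells = 10)
#> Distance clusters (d_max = 50 um, min 10 cells): 3 cluster(s), 34.3% of 134 cells assigned
#>   sizes: 16, 14, 16

pairs <- lapply(1:3, function(r) {
  sc$seed <- r
  s <- generate_scene(sc)
  s$cells$label <- classify_cells(s$cells, tree)
  assay   <- suppressWarnings(select_assay_region(s$cells, n_target = 1500))
  control <- select_control_region(s$cells, n_target = 1500,
                                   exclude_ids = assay$cell_id)
  region_pair(assay, control, reservoir_id = r)
})
et <- paired_enrichment_test(pairs)
et[et$type %in% c("dendritic cell", "antigen-presenting neutrophil",
                  "neutrophil", "tumor (Epcam+)", "pericyte"), ]
#> Paired enrichment over 3 replicates (one-tailed greater, alpha = 0.05; floor: count >= 12 & 0.75%)
#>                           type pct_assay pct_control mean_diff      t p_value
#>                 dendritic cell     11.16        6.78      4.38  9.813 0.00511
#>  antigen-presenting neutrophil      0.20        0.13      0.07  1.000      NA
#>                     neutrophil      6.71        6.67      0.04  0.070 0.47500
#>                 tumor (Epcam+)     48.22       50.60     -2.38 -3.452 0.96300
#>                       pericyte      3.20        3.07      0.13  0.405 0.36200
#>       status significant
#>           ok        TRUE
#>  below_floor       FALSE
#>           ok       FALSE
#>           ok       FALSE
#>           ok       FALSE
```

The three planted clusters are recovered exactly (sizes 16/14/16: the 45
planted cells plus a handful of background pericytes falling inside
them). The paired test flags only the planted dendritic-cell recruitment
(11.2% near the well vs 6.8% in the distant control, p = 0.005); the
antigen-presenting-neutrophil row shows the noise floor masking a type
with ~3 cells per region, and tumor cells are (correctly) not "enriched"
— their share is diluted by the recruited DCs, and the one-tailed test
looks for enrichment only.

`run_pipeline()` chains the same stages from a YAML config and writes
CSV/JSON artifacts with config-hash provenance;
`inst/scripts/run_pipeline.R` is a shell wrapper around it.

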