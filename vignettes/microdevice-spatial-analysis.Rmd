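---
title: "Methods: spatial single-cell analysis of microdevice drug assays"
author: "imdassay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial single-cell analysis of microdevice drug assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imdassay)
```

## The assay

An implantable microdevice (IMD) is a 5.5 mm x 750 µm resin cylinder whose
outer surface carries up to 18 reservoirs, each packed with a drug in a PEG
carrier. Implanted into a tumor, every reservoir releases its drug by
passive diffusion into a spatially separate region of tissue, so one
implant assays many treatments at once. Sections cut orthogonal to the
device through each reservoir are stained by multiplexed chromogenic
immunohistochemistry (iterative stain/scan/strip rounds with an AEC
chromogen plus a hematoxylin nuclear round), and the local response of the
tumor microenvironment (TME) is read out as changes in cell composition
and organization with distance from the drug source.

This package implements the computational side of that assay end to end —
image rounds to single-cell tables, tables to cell types, cell types to
spatial statistics and paired enrichment calls — together with a
ground-truthed synthetic-scene generator so that every stage can be
validated without animal data.

A note on the device geometry default: the manufacturing protocol gives
5.5 mm length while a summary figure text gives 5 mm; `device_geometry()`
follows the manufacturing value (5,500 µm).

## Coordinate frame and dose calibration

All spatial statistics work in a well-centered frame: the drug source at
`(0, 0)`, the release direction along +y, units micrometers
(`well_frame()`, `to_well_frame()`; a proper rigid transform, verified to
preserve pairwise distances to 1e-6 µm). Profiles, assay-region selection
and the synthetic generator default to the release half-plane (y > 0).

Reservoir loads are calibrated to emulate systemic exposure: doses of
0–1, 1–2, 2–4 and >4 mg/kg map to 20, 25, 30 and 40% drug in PEG
(`dose_to_peg_fraction()`). The printed bands are ambiguous at shared
endpoints; we resolve them lower-inclusive/upper-exclusive, with 4 mg/kg
assigned to the 30% band because the last band is strictly ">4". The
mapping is a monotone step function and the band table is config data, so
a different convention can be supplied.

## The synthetic scene generator

`generate_scene()` draws the statistical structure the analysis assumes:

* a homogeneous Poisson background of typed cells. The default density,
  3.5e-3 cells/µm², is chosen so an assay-region-sized half-window above
  the well holds 3,000–5,000 cells, matching the protocol's stated
  per-region totals; observed densities are not published, so this is a
  documented assumption.
* drug-recruited cells from an inhomogeneous Poisson process with
  intensity `A exp(-d/L)` (`d` = distance to the well), sampled by
  thinning; `A` is the intensity at the well (cells/µm²) and `L` the
  decay length (µm).
* planted compact clusters: parent centers with Gaussian offspring at
  `spread_sd`. Centers are kept `min_separation` (default 200 µm) apart so
  planted microcultures are spatially distinct, mirroring the separate
  cell aggregates the assay reports.
* per-marker intensities from a two-component Beta mixture per cell type:
  negative component Beta(3, 19) (mode 0.1) and positive component
  Beta(15, 7) (mode 0.7), clipped to [0, 1]. The modes follow what
  chromogenic mean intensities look like after 0–1 scaling; the
  concentrations are chosen so the two populations separate cleanly at a
  mid-range gating threshold, i.e. the generator emulates usable staining,
  not marginal staining. Signature markers are positive with probability
  0.98, off-signature markers 0.02.

`generate_null_scene()` strips gradients and planted clusters, emulating a
pure-PEG negative-control region; it drives the false-cluster and
type-I-error calibrations below. Scenes are seed-deterministic
(`identical()` outputs for identical config + seed) and do not perturb the
caller's RNG stream.

What the generator does **not** emulate: tissue texture and folds, uneven
staining, section-to-section registration error, cell-shape variation
(nuclei render as Gaussian blobs), or biologically structured marker
co-expression beyond the type signatures. Passing recovery tests therefore
demonstrate that the pipeline's inference is correct for data satisfying
its own model assumptions — they do not certify performance on real
tissue, where the QC steps (deformed-region exclusion, control tissues)
carry that weight.

`render_chromogenic()` turns a scene into image rounds: nuclear optical
density accumulates as Gaussian blobs and converts to RGB transmittance
through Beer–Lambert with the standard hematoxylin absorption vector, so
the rendered images invert exactly under stain deconvolution; AEC rounds
tint each cell in proportion to its marker intensity with a red-brown
absorption vector. A ground-truth label mask (labels = scene `cell_id`s)
and the list of optically overlapping cells are returned. A blank margin
(default 3 nucleus radii) surrounds the arena so edge cells render
completely.

## Imaging

* **Stain separation.** `deconvolve_stains()` inverts the Ruifrok–Johnston
  model: per-pixel OD = −log10(I) projected through the inverse stain
  matrix (default hematoxylin/eosin/residual vectors). Hematoxylin OD
  seeds nuclear segmentation.
* **AEC extraction.** `extract_aec_yellow()` is the CMYK yellow channel:
  `K = 1 − max(r, g, b)`, `Y = (1 − b − K)/(1 − K)` (0 where `K = 1`), a
  total function with range [0, 1]; gray pixels map to 0.
* **Segmentation.** Otsu threshold (the protocol names only "standard
  image processing steps"; Otsu is the field default), morphological
  opening for noise removal, then a seeded watershed. Seeds are local
  maxima of the Gaussian-smoothed in-mask intensity with a configurable
  minimum separation, and labels grow from seeds by intensity-guided
  propagation. We seed from intensity rather than the distance transform
  because a touching nucleus pair often has a single distance-transform
  ridge (one seed) while its intensity profile keeps two maxima; on
  rendered scenes this halves the count error. Objects under `min_area`
  are dropped and labels renumbered in raster order, making results
  deterministic.
* **Measurement.** `measure_cells()` reports per-cell mean intensity over
  the mask footprint scaled by the channel's fixed dtype maximum (255 for
  8-bit), never per-image min–max: cross-image comparability is what
  gating needs. Centroids are reported in the well frame.
* **Registration.** `register_rounds()` detects nuclear-scale blob
  features, matches them by iterative closest point, and estimates a rigid
  transform (Kabsch), escalating to affine when the rigid residual exceeds
  1 px equivalent tolerance; transforms and residuals are returned for
  audit, and too few matched features or a large residual is a hard error
  naming the round.
* **Coverage.** `binary_coverage()` binarizes a channel inside a region
  and returns the covered fraction — the death-marker (CC3-style) readout.
  The binarization threshold is biologically assay-specific and therefore
  a required parameter.

Validation regime: count recovery is verified on rendered scenes at
5e-4 cells/µm². At the full 3.5e-3 tissue density roughly a tenth of the
rendered nuclei sit closer than the optical blob width; they are
unresolvable by construction (the generator reports them as overlapping),
so count recovery there measures the render model, not the segmenter.

## Hierarchical gating

`classify_cells()` walks an ordered gate hierarchy root-down; the first
matching child wins, and every cell gets exactly one leaf label (or the
reserved `"unclassified"`). Positivity is intensity strictly greater than
the threshold. Gates are 1-D thresholds, boolean combinations, or simple
polygon gates on a marker pair that translate rigidly around a central
vertex (`translate_gate()`), the mechanism used to port gates across
staining batches.

The shipped tree (`load_gating_config()`) reconstructs the 17 standard
TME cell types over the 13-marker baseline panel (Epcam, CD45, CD31,
αSMA, CD3, CD4, CD8, CD11b, F4/80, CSF1R, CD11c, Ly6G, MHC-II; spelled
column-safe as `aSMA`, `F480`, `MHCII`). The published leaf table is not
available as data, so the composition is reconstructed from the lineage
gates the text documents — T cells split by CD4/CD8, macrophages split
2x2 by CSF1R x MHC-II, neutrophils split by MHC-II, DCs on CD11c (ahead
of the CD45 branch, since phagocytic DCs present Epcam+CD45−),
endothelial/pericyte on CD31 x αSMA, fibroblast, mesenchymal — padded to
exactly 17 leaves. The 17/13 cardinalities are authoritative; the
composition is config data (`provenance: reconstructed`) users can
replace. The mesenchymal leaf requires lineage negativity plus weak
signal (>0.2) on at least one panel marker, so an all-zero artifact row
falls to `"unclassified"` rather than being called a cell type.

Extended phenotypes (`classify_extended()`) are strict refinements: e.g.
antigen-presenting neutrophils (Ly6G+MHC-II+) are a subset of standard
neutrophils. The cancer-stem-cell pattern ships verbatim as
Epcam−CD45+PyMT+Ki67−Sox9+; CD45+ in a tumor-compartment phenotype is
likely a typographical slip for CD45−, so an explicit `csc_alt` with
CD45− ships alongside and the user chooses — nothing is silently fixed.

`threshold_from_control()` reproduces the positive-control workflow: Otsu
on the control's intensity histogram, a manual override hook, and a
mode-count guard that flags controls with no separable positive
population (threshold then sits just above the data).

## Spatial statistics

* **Distance clustering.** "Each cell clusters with its closest neighbor
  if closer than the threshold, and clusters within the threshold merge"
  is formalized as the connected components of the graph joining pairs at
  Euclidean distance ≤ `d_max` (single-linkage) — the only reading
  consistent with merging. Components with ≥ `min_cells` members are
  clusters; defaults (50 µm, 10 cells) are the treatment-specific
  calibration, with documented per-readout overrides (30 µm proliferating
  tumor, 75 µm endothelial/pericyte, 150 µm PD-L1). Implementation is a
  bucket grid + union–find (near-linear at tissue densities); the test
  suite pins it to a dense O(n²) oracle.
* **Assay region.** The first `n_target` cells above the well,
  nearest-first, after excluding deformed-tissue cells; 3,000–5,000 is
  the standard window and other targets warn. The matched control region
  is taken farthest-first and pairs are valid when totals agree within
  300 cells.
* **Profiles.** Per distance bin (radial distance to the well; the
  release half-plane by default), relative abundance = series count /
  bin total, then Gaussian blur and a centered moving average (50 µm or
  100 µm windows, per the two published smoothing settings). "Signal not
  scaled" we read as: no per-series normalization after smoothing — the y
  axis stays a per-bin fraction. The Gaussian sigma is unspecified in the
  protocol; it defaults to one bin width and is exposed. Empty bins are
  `NA` gaps, never zeros, and smoothing renormalizes over observed bins.
  Pre-smoothing fractions across exclusive types sum to 1 per bin.
* **ROIs and proximity.** `sample_rois()` draws seeded uniform circle
  centers in the region eroded by the ROI radius (default diameter
  175 µm). `pairwise_proximity()` computes all |A|·|B| pair distances,
  their histogram, and the proportion strictly below the cutoff
  (default 50 µm, the distance at which the cluster calibration says
  cells interact); it is symmetric in the two sets.
* **Zones.** Proximal/border/distal hotspot labels are derived from
  config-driven distance bands and convex hulls of selected cluster sets
  (`hull_area_um2` in cluster results); the original description is
  verbal, so the concrete rule here is a documented choice.

## Paired enrichment

For each cell type, per-reservoir composition differences
`d_i = %assay_i − %control_i` are tested with a paired one-tailed t-test
(`t = mean(d)/(sd(d)/sqrt(n))`, df = n−1, alternative assay > control).
Enrichment is the published direction; depletion sits behind a flag. A
noise floor masks types whose mean assay count is below 12 cells or mean
assay proportion below 0.75%: both printed constants are honored even
though they are mutually inconsistent at the stated totals (0.75% of
3,000–5,000 cells is 22–37, not 12), and the floor is configurable. A
masked type reports `p = NA` (status `below_floor`) and is never flagged
significant; zero-variance differences report `NA` with status
`degenerate` rather than a fabricated zero. No multiple-testing
correction is applied by default, matching the per-type reporting;
Benjamini–Hochberg is available as an option.

## Calibration and validation choices

The test suite and `scripts/acceptance.R` recompute, at fixed problem
sizes chosen to keep the full run in a few minutes:

* clustering equals the brute-force oracle on 100 random instances of up
  to 200 points;
* on 100 null scenes at the study density (3.5e-3 cells/µm², clustering a
  2% minority type, ~70 cells/mm²), the calibrated parameters (10 cells,
  50 µm) produce zero clusters in ≥95% of seeds while the lax parameters
  (5 cells, 100 µm) produce ≥1 spurious cluster in ≥50% — the
  negative-control contrast that motivated the published calibration;
* over 500 null triplicate experiments (disjoint 800-cell assay/control
  regions from 2 x 2 mm null scenes), the fraction of types flagged at
  α = 0.05 falls inside the 95% binomial envelope around 0.05, and power
  over a three-point recruitment-amplitude grid (0, 2e-4, 8e-4 cells/µm²
  at 150 µm decay) increases monotonically;
* planted gradients are recovered within 20% of the true decay length
  from >3,000 recruited cells (Poisson annulus regression with log-area
  offset); planted clusters are recovered with mean adjusted Rand index
  ≥ 0.9 under the construction regime (3 clusters x 15 cells, 8 µm
  spread, sparse same-type background); rendered-image cell counts are
  recovered within 5% at the imaging validation density; AEC extraction
  matches its closed-form formula exactly per pixel.

## Numerical conventions and degenerate inputs

Threshold positivity is strictly greater-than. Cluster ids are numbered
by first member in input order; the partition is permutation-invariant.
Otsu thresholds are computed on fixed-range 256-bin histograms. Empty
point sets cluster to an empty result; empty images segment to an empty
mask; empty regions, empty cell sets, and constant-intensity controls are
errors, as are self-intersecting polygons, singular stain matrices, and
gating configs with duplicate leaves or unknown markers. All randomness
(scenes, ROI sampling, display palettes) is seeded, and seeded helpers
restore the caller's RNG state.

## Known limitations

Registration assumes mostly-overlapping rounds with shared nuclear
features and small transforms; it is not a general mosaicking tool.
Profile distance is radial; a drawn profile-line variant is a possible
extension. The annulus decay fit assumes annuli inside the observation
window (no edge correction). The gating tree composition is a
reconstruction, and real antibody panels will want their own tree and
thresholds from control tissue. No spatial statistics beyond the assay's
own (no Ripley's K, no permutation-based neighborhood enrichment) are
provided by design.
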