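# Default hierarchical gating tree: 17 standard tumor-microenvironment cell
# types defined over the 13-marker baseline discovery panel.
#
# The exact published leaf composition is not available as machine-readable
# data; this hierarchy is RECONSTRUCTED from the marker biology and the
# documented lineage gates (tumor Epcam+CD45-; CD3 T cells with CD4/CD8
# subsets; CD11b+F4/80+ macrophages split by CSF1R x MHC-II; Ly6G+
# neutrophils split by MHC-II; CD11c+ DCs; CD31+ endothelium split by aSMA
# into endothelial/pericyte; aSMA+ fibroblasts; lineage-negative
# mesenchymal cells). The 17-leaf / 13-marker cardinalities are the
# authoritative constraint; replace this file to use a different taxonomy.
#
# Evaluation: nodes root-down, first matching child wins. Positivity is
# intensity strictly greater than the threshold. "otherwise" matches any
# cell reaching that node. Cells matching no leaf are "unclassified".
meta:
  name: standard-17
  provenance: reconstructed
  markers: [Epcam, CD45, CD31, aSMA, CD3, CD4, CD8, CD11b, F480, CSF1R, CD11c, Ly6G, MHCII]
thresholds:
  default: 0.4
tree:
  # T cells and DCs gate on their defining markers ahead of the
  # pan-leukocyte branch: DCs in particular may present as Epcam+CD45-
  # (phagocytic) and must not require CD45.
  - gate: {marker: CD3, side: above}
    children:
      - label: CD8 T cell
        gate: {marker: CD8, side: above}
      - label: CD4 T cell
        gate: {marker: CD4, side: above}
      - label: double-negative T cell
        gate: {type: otherwise}
  - label: dendritic cell
    gate: {marker: CD11c, side: above}
  - gate: {marker: CD45, side: above}
    children:
      - gate: {marker: Ly6G, side: above}
        children:
          - label: antigen-presenting neutrophil
            gate: {marker: MHCII, side: above}
          - label: neutrophil
            gate: {type: otherwise}
      - gate:
          type: all
          conditions:
            - {marker: CD11b, side: above}
            - {marker: F480, side: above}
        children:
          - label: CSF1R+ MHC-II- macrophage
            gate:
              type: all
              conditions:
                - {marker: CSF1R, side: above}
                - {marker: MHCII, side: below}
          - label: CSF1R+ MHC-II+ macrophage
            gate:
              type: all
              conditions:
                - {marker: CSF1R, side: above}
                - {marker: MHCII, side: above}
          - label: antigen-presenting macrophage
            gate: {marker: MHCII, side: above}
          - label: CSF1R- MHC-II- macrophage
            gate: {type: otherwise}
      - label: immature myeloid
        gate: {marker: CD11b, side: above}
      - label: leukocyte (other)
        gate: {type: otherwise}
  - label: tumor (Epcam+)
    gate: {marker: Epcam, side: above}
  - gate: {marker: CD31, side: above}
    children:
      - label: pericyte
        gate: {marker: aSMA, side: above}
      - label: endothelial
        gate: {type: otherwise}
  - label: fibroblast
    gate: {marker: aSMA, side: above}
  # lineage-negative nucleated stromal cells; the weak pan-panel floor (0.2)
  # keeps signal-free rows (artefacts) in the reserved "unclassified" class
  - label: mesenchymal
    gate:
      type: any
      conditions:
        - {marker: Epcam,  side: above, threshold: 0.2}
        - {marker: CD45,   side: above, threshold: 0.2}
        - {marker: CD31,   side: above, threshold: 0.2}
        - {marker: aSMA,   side: above, threshold: 0.2}
        - {marker: CD3,    side: above, threshold: 0.2}
        - {marker: CD4,    side: above, threshold: 0.2}
        - {marker: CD8,    side: above, threshold: 0.2}
        - {marker: CD11b,  side: above, threshold: 0.2}
        - {marker: F480,   side: above, threshold: 0.2}
        - {marker: CSF1R,  side: above, threshold: 0.2}
        - {marker: CD11c,  side: above, threshold: 0.2}
        - {marker: Ly6G,   side: above, threshold: 0.2}
        - {marker: MHCII,  side: above, threshold: 0.2}
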