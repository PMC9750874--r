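# Extended phenotype definitions refining the standard taxonomy with
# extended-readout markers. `within` restricts a phenotype to members of the
# named standard class(es), making it a strict refinement.
#
# Note on `csc`: the published cancer-stem-cell pattern reads
# Epcam-CD45+PyMT+Ki67-Sox9+, in which CD45+ is biologically surprising for
# a tumor-compartment phenotype and is likely a typographical slip for
# CD45-. The pattern is kept verbatim here; `csc_alt` carries the CD45-
# alternate. Choose explicitly; nothing is silently corrected.
phenotypes:
  antigen-presenting neutrophil:
    within: [neutrophil, antigen-presenting neutrophil]
    pattern:
      - {marker: Ly6G, positive: true}
      - {marker: MHCII, positive: true}
  phagocytic DC:
    within: [dendritic cell]
    pattern:
      - {marker: CD11c, positive: true}
      - {marker: Epcam, positive: true}
      - {marker: CD45, positive: false}
  less-differentiated macrophage:
    within: [CSF1R+ MHC-II- macrophage, CSF1R+ MHC-II+ macrophage,
             antigen-presenting macrophage, CSF1R- MHC-II- macrophage]
    pattern:
      - {marker: CD45, positive: false}
  csc:
    pattern:
      - {marker: Epcam, positive: false}
      - {marker: CD45, positive: true}
      - {marker: PyMT, positive: true}
      - {marker: Ki67, positive: false}
      - {marker: Sox9, positive: true}
  csc_alt:
    pattern:
      - {marker: Epcam, positive: false}
      - {marker: CD45, positive: false}
      - {marker: PyMT, positive: true}
      - {marker: Ki67, positive: false}
      - {marker: Sox9, positive: true}
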