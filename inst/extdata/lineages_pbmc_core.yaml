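# Sign-based population definitions for healthy PBMC, encoding the
# conventional marker logic of the major immune lineages and their
# well-established subsets. Clauses are incremental with respect to the
# parent population; sibling order encodes gating priority (first match).
# Levels: pos/neg are relative to the per-antigen primary cutoff,
# high/low to the per-antigen secondary cutoff.
profile: pbmc_core
populations:
  - name: "CD45+ leukocytes"
    parent: ~
    positive: {CD45: pos}
    negative: {CD235ab: neg, CD61: neg}
  - name: "T cells"
    parent: "CD45+ leukocytes"
    positive: {CD3: pos}
  - name: "gd T cells"
    parent: "T cells"
    positive: {TCRgd: pos}
  - name: "NKT cells"
    parent: "T cells"
    positive: {TCRVa24-Ja18: pos}
    negative: {TCRgd: neg}
  - name: "CD4 T cells"
    parent: "T cells"
    positive: {CD4: pos}
    negative: {CD8a: neg, TCRgd: neg, TCRVa24-Ja18: neg}
  - name: "Treg"
    parent: "CD4 T cells"
    positive: {CD25: high, FoxP3: pos}
    negative: {CD127: low}
  - name: "CD4 T naive"
    parent: "CD4 T cells"
    positive: {CD45RA: pos, CCR7: pos}
  - name: "CD4 T central memory"
    parent: "CD4 T cells"
    positive: {CCR7: pos}
    negative: {CD45RA: neg}
  - name: "CD4 T effector memory"
    parent: "CD4 T cells"
    negative: {CD45RA: neg, CCR7: neg}
  - name: "CD4 T effector"
    parent: "CD4 T cells"
    positive: {CD45RA: pos}
    negative: {CCR7: neg}
  - name: "CD8 T cells"
    parent: "T cells"
    positive: {CD8a: pos}
    negative: {CD4: neg, TCRgd: neg, TCRVa24-Ja18: neg}
  - name: "CD8 T naive"
    parent: "CD8 T cells"
    positive: {CD45RA: pos, CCR7: pos}
  - name: "CD8 T central memory"
    parent: "CD8 T cells"
    positive: {CCR7: pos}
    negative: {CD45RA: neg}
  - name: "CD8 T effector memory"
    parent: "CD8 T cells"
    negative: {CD45RA: neg, CCR7: neg}
  - name: "CD8 T effector"
    parent: "CD8 T cells"
    positive: {CD45RA: pos}
    negative: {CCR7: neg}
  - name: "B cells"
    parent: "CD45+ leukocytes"
    positive: {CD19: pos, HLA-DR: pos}
    negative: {CD3: neg}
  - name: "Plasmablasts"
    parent: "B cells"
    positive: {CD38: high, CD27: pos}
  - name: "CD27+ B cells"
    parent: "B cells"
    positive: {CD27: pos}
  - name: "CD27- B cells"
    parent: "B cells"
    negative: {CD27: neg}
  - name: "NK cells"
    parent: "CD45+ leukocytes"
    positive: {CD56: pos}
    negative: {CD3: neg, CD19: neg, CD14: neg}
  - name: "CD56high CD16- NK cells"
    parent: "NK cells"
    positive: {CD56: high}
    negative: {CD16: neg}
  - name: "CD56low CD16+ NK cells"
    parent: "NK cells"
    positive: {CD16: pos}
  - name: "Monocytes"
    parent: "CD45+ leukocytes"
    positive: {CD14: pos, CD33: pos, CD11b: pos}
    negative: {CD3: neg, CD19: neg}
  - name: "Classical monocytes"
    parent: "Monocytes"
    negative: {CD16: neg}
  - name: "Intermediate monocytes"
    parent: "Monocytes"
    positive: {CD16: pos, CD14: high}
  - name: "Non-classical monocytes"
    parent: "Monocytes"
    positive: {CD16: pos}
    negative: {CD14: low}
  - name: "pDC"
    parent: "CD45+ leukocytes"
    positive: {CD123: pos, HLA-DR: pos}
    negative: {CD3: neg, CD19: neg, CD14: neg, CD11c: neg}
  - name: "cDC"
    parent: "CD45+ leukocytes"
    positive: {CD11c: pos, HLA-DR: pos}
    negative: {CD3: neg, CD19: neg, CD14: neg, CD123: neg}
  - name: "Basophils"
    parent: "CD45+ leukocytes"
    positive: {FceRI: pos, CD123: pos}
    negative: {HLA-DR: neg, CD3: neg, CD19: neg, CD14: neg}
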