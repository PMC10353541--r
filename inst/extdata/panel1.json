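{
  "panel_id": 1,
  "name": "Immunophenotyping Panel 1 (lymphocyte panel)",
  "activation_markers": ["CD25", "CD154"],
  "channels": [
    {"marker": "CD8a", "fluorophore": "FITC"},
    {"marker": "CD4", "fluorophore": "PE"},
    {"marker": "CD19", "fluorophore": "PE-Cy7"},
    {"marker": "CCR4", "fluorophore": "APC"},
    {"marker": "CD45RA", "fluorophore": "AF700"},
    {"marker": "TCRgd", "fluorophore": "APC-Fire750"},
    {"marker": "CD45", "fluorophore": "PacBlue"},
    {"marker": "Viability", "fluorophore": "ZombieAqua"},
    {"marker": "CD3", "fluorophore": "BV570"},
    {"marker": "CD25", "fluorophore": "BV650"},
    {"marker": "CD154", "fluorophore": "BV711"},
    {"marker": "CD127", "fluorophore": "BV785"}
  ],
  "gates": [
    {"id": "main", "parent": null, "kind": "scatter-region",
     "channels": ["FSC-A", "SSC-A"], "threshold_source": "auto", "polarity": "inclusive"},
    {"id": "singlet", "parent": "main", "kind": "singlet",
     "channels": ["FSC-A", "FSC-H"], "threshold_source": "auto", "polarity": "inclusive"},
    {"id": "viability", "parent": "singlet", "kind": "viability-exclusion",
     "channels": ["Viability-ZombieAqua"], "threshold_source": "auto", "polarity": "exclusive"},
    {"id": "cd45_pos", "parent": "viability", "kind": "threshold-positive",
     "channels": ["CD45-PacBlue"], "threshold_source": "isotype-quantile", "polarity": "inclusive"},
    {"id": "cd19_pos", "parent": "cd45_pos", "kind": "threshold-positive",
     "channels": ["CD19-PE-Cy7"], "threshold_source": "isotype-quantile", "polarity": "inclusive"},
    {"id": "cd3_pos", "parent": "cd45_pos", "kind": "threshold-positive",
     "channels": ["CD3-BV570"], "threshold_source": "isotype-quantile", "polarity": "inclusive"},
    {"id": "cd8_pos", "parent": "cd3_pos", "kind": "threshold-positive",
     "channels": ["CD8a-FITC"], "threshold_source": "isotype-quantile", "polarity": "inclusive"},
    {"id": "cd8pos_cd4_neg", "parent": "cd8_pos", "kind": "threshold-negative",
     "channels": ["CD4-PE"], "threshold_source": "isotype-quantile", "polarity": "inclusive"},
    {"id": "cd45ra_pos", "parent": "cd8pos_cd4_neg", "kind": "threshold-positive",
     "channels": ["CD45RA-AF700"], "threshold_source": "isotype-quantile", "polarity": "inclusive"},
    {"id": "cd4_pos", "parent": "cd3_pos", "kind": "threshold-positive",
     "channels": ["CD4-PE"], "threshold_source": "isotype-quantile", "polarity": "inclusive"},
    {"id": "cd4pos_cd8_neg", "parent": "cd4_pos", "kind": "threshold-negative",
     "channels": ["CD8a-FITC"], "threshold_source": "isotype-quantile", "polarity": "inclusive"},
    {"id": "ccr4_pos", "parent": "cd4pos_cd8_neg", "kind": "threshold-positive",
     "channels": ["CCR4-APC"], "threshold_source": "isotype-quantile", "polarity": "inclusive"},
    {"id": "cd25_pos", "parent": "ccr4_pos", "kind": "threshold-positive",
     "channels": ["CD25-BV650"], "threshold_source": "isotype-quantile", "polarity": "inclusive"},
    {"id": "cd127_lo", "parent": "cd25_pos", "kind": "threshold-low",
     "channels": ["CD127-BV785"], "threshold_source": "isotype-quantile", "polarity": "inclusive"},
    {"id": "cd8_neg", "parent": "cd3_pos", "kind": "threshold-negative",
     "channels": ["CD8a-FITC"], "threshold_source": "isotype-quantile", "polarity": "inclusive"},
    {"id": "dn_cd4_neg", "parent": "cd8_neg", "kind": "threshold-negative",
     "channels": ["CD4-PE"], "threshold_source": "isotype-quantile", "polarity": "inclusive"},
    {"id": "tcrgd_pos", "parent": "dn_cd4_neg", "kind": "threshold-positive",
     "channels": ["TCRgd-APC-Fire750"], "threshold_source": "isotype-quantile", "polarity": "inclusive"}
  ],
  "populations": [
    {"name": "B cells",
     "path": ["main", "singlet", "viability", "cd45_pos", "cd19_pos"],
     "activation_markers": ["CD25", "CD154"]},
    {"name": "T cells",
     "path": ["main", "singlet", "viability", "cd45_pos", "cd3_pos"],
     "activation_markers": []},
    {"name": "Cytotoxic T cells",
     "path": ["main", "singlet", "viability", "cd45_pos", "cd3_pos", "cd8_pos", "cd8pos_cd4_neg"],
     "activation_markers": ["CD25", "CD154"]},
    {"name": "Naive cytotoxic T cells",
     "path": ["main", "singlet", "viability", "cd45_pos", "cd3_pos", "cd8_pos", "cd8pos_cd4_neg", "cd45ra_pos"],
     "activation_markers": []},
    {"name": "CD4 T cells",
     "path": ["main", "singlet", "viability", "cd45_pos", "cd3_pos", "cd4_pos", "cd4pos_cd8_neg"],
     "activation_markers": ["CD25", "CD154"]},
    {"name": "Regulatory T cells",
     "path": ["main", "singlet", "viability", "cd45_pos", "cd3_pos", "cd4_pos", "cd4pos_cd8_neg", "ccr4_pos", "cd25_pos", "cd127_lo"],
     "activation_markers": []},
    {"name": "gd T cells",
     "path": ["main", "singlet", "viability", "cd45_pos", "cd3_pos", "cd8_neg", "dn_cd4_neg", "tcrgd_pos"],
     "activation_markers": []}
  ]
}
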