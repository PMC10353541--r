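{
  "panel_id": 2,
  "name": "Immunophenotyping Panel 2 (monocyte, DC, NK panel)",
  "activation_markers": ["CD54", "CD69"],
  "channels": [
    {"marker": "CD56", "fluorophore": "FITC"},
    {"marker": "CD14", "fluorophore": "PE"},
    {"marker": "CD19", "fluorophore": "PE-Cy7"},
    {"marker": "CD123", "fluorophore": "APC"},
    {"marker": "CD54", "fluorophore": "AF700"},
    {"marker": "CD20", "fluorophore": "APC-Fire750"},
    {"marker": "CD45", "fluorophore": "PacBlue"},
    {"marker": "Viability", "fluorophore": "ZombieAqua"},
    {"marker": "CD3", "fluorophore": "BV570"},
    {"marker": "CD69", "fluorophore": "BV650"},
    {"marker": "CD11c", "fluorophore": "BV785"}
  ],
  "gates": [
    {"id": "main", "parent": null, "kind": "scatter-region",
     "channels": ["FSC-A", "SSC-A"], "threshold_source": "auto", "polarity": "inclusive"},
    {"id": "mono_scatter", "parent": "main", "kind": "scatter-region",
     "channels": ["FSC-A", "SSC-A"], "threshold_source": "auto", "polarity": "inclusive",
     "branch": "monocyte"},
    {"id": "lymph_scatter", "parent": "main", "kind": "scatter-region",
     "channels": ["FSC-A", "SSC-A"], "threshold_source": "auto", "polarity": "inclusive",
     "branch": "lymphocyte"},
    {"id": "mono_singlet", "parent": "mono_scatter", "kind": "singlet",
     "channels": ["FSC-A", "FSC-H"], "threshold_source": "auto", "polarity": "inclusive"},
    {"id": "mono_viability", "parent": "mono_singlet", "kind": "viability-exclusion",
     "channels": ["Viability-ZombieAqua"], "threshold_source": "auto", "polarity": "exclusive"},
    {"id": "mono_cd45_pos", "parent": "mono_viability", "kind": "threshold-positive",
     "channels": ["CD45-PacBlue"], "threshold_source": "isotype-quantile", "polarity": "inclusive"},
    {"id": "mono_cd3_neg", "parent": "mono_cd45_pos", "kind": "threshold-negative",
     "channels": ["CD3-BV570"], "threshold_source": "isotype-quantile", "polarity": "inclusive"},
    {"id": "mono_cd19_neg", "parent": "mono_cd3_neg", "kind": "threshold-negative",
     "channels": ["CD19-PE-Cy7"], "threshold_source": "isotype-quantile", "polarity": "inclusive"},
    {"id": "cd14_pos", "parent": "mono_cd19_neg", "kind": "threshold-positive",
     "channels": ["CD14-PE"], "threshold_source": "isotype-quantile", "polarity": "inclusive"},
    {"id": "lymph_singlet", "parent": "lymph_scatter", "kind": "singlet",
     "channels": ["FSC-A", "FSC-H"], "threshold_source": "auto", "polarity": "inclusive"},
    {"id": "lymph_viability", "parent": "lymph_singlet", "kind": "viability-exclusion",
     "channels": ["Viability-ZombieAqua"], "threshold_source": "auto", "polarity": "exclusive"},
    {"id": "lymph_cd45_pos", "parent": "lymph_viability", "kind": "threshold-positive",
     "channels": ["CD45-PacBlue"], "threshold_source": "isotype-quantile", "polarity": "inclusive"},
    {"id": "lymph_cd3_neg", "parent": "lymph_cd45_pos", "kind": "threshold-negative",
     "channels": ["CD3-BV570"], "threshold_source": "isotype-quantile", "polarity": "inclusive"},
    {"id": "l_cd19_neg", "parent": "lymph_cd3_neg", "kind": "threshold-negative",
     "channels": ["CD19-PE-Cy7"], "threshold_source": "isotype-quantile", "polarity": "inclusive"},
    {"id": "l_cd14_neg", "parent": "l_cd19_neg", "kind": "threshold-negative",
     "channels": ["CD14-PE"], "threshold_source": "isotype-quantile", "polarity": "inclusive"},
    {"id": "cd20_neg", "parent": "l_cd14_neg", "kind": "threshold-negative",
     "channels": ["CD20-APC-Fire750"], "threshold_source": "isotype-quantile", "polarity": "inclusive"},
    {"id": "cd123_pos", "parent": "cd20_neg", "kind": "threshold-positive",
     "channels": ["CD123-APC"], "threshold_source": "isotype-quantile", "polarity": "inclusive"},
    {"id": "cd11c_pos", "parent": "cd20_neg", "kind": "threshold-positive",
     "channels": ["CD11c-BV785"], "threshold_source": "isotype-quantile", "polarity": "inclusive"},
    {"id": "cd56_pos", "parent": "cd20_neg", "kind": "threshold-positive",
     "channels": ["CD56-FITC"], "threshold_source": "isotype-quantile", "polarity": "inclusive"},
    {"id": "lymph_cd3_pos", "parent": "lymph_cd45_pos", "kind": "threshold-positive",
     "channels": ["CD3-BV570"], "threshold_source": "isotype-quantile", "polarity": "inclusive"},
    {"id": "nkt_cd56_pos", "parent": "lymph_cd3_pos", "kind": "threshold-positive",
     "channels": ["CD56-FITC"], "threshold_source": "isotype-quantile", "polarity": "inclusive"}
  ],
  "populations": [
    {"name": "Monocytes",
     "path": ["main", "mono_scatter", "mono_singlet", "mono_viability", "mono_cd45_pos", "mono_cd3_neg", "mono_cd19_neg", "cd14_pos"],
     "activation_markers": ["CD54", "CD69"]},
    {"name": "pDC",
     "path": ["main", "lymph_scatter", "lymph_singlet", "lymph_viability", "lymph_cd45_pos", "lymph_cd3_neg", "l_cd19_neg", "l_cd14_neg", "cd20_neg", "cd123_pos"],
     "activation_markers": ["CD54", "CD69"]},
    {"name": "mDC",
     "path": ["main", "lymph_scatter", "lymph_singlet", "lymph_viability", "lymph_cd45_pos", "lymph_cd3_neg", "l_cd19_neg", "l_cd14_neg", "cd20_neg", "cd11c_pos"],
     "activation_markers": ["CD54", "CD69"]},
    {"name": "NK cells",
     "path": ["main", "lymph_scatter", "lymph_singlet", "lymph_viability", "lymph_cd45_pos", "lymph_cd3_neg", "l_cd19_neg", "l_cd14_neg", "cd20_neg", "cd56_pos"],
     "activation_markers": ["CD54", "CD69"]},
    {"name": "NKT cells",
     "path": ["main", "lymph_scatter", "lymph_singlet", "lymph_viability", "lymph_cd45_pos", "lymph_cd3_pos", "nkt_cd56_pos"],
     "activation_markers": []}
  ]
}
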