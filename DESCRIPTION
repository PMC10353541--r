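Package: immunogate
Title: Hierarchical Gating and Statistics for PBMC Immunophenotyping Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for multicolor flow-cytometry
    immunophenotyping of human peripheral blood mononuclear cells (PBMC).
    Ships two declarative antibody panels (a lymphocyte panel and a
    monocyte/dendritic-cell/NK panel) with their hierarchical gate trees,
    executes isotype-referenced threshold gating with activation quadrants,
    and derives stimulation indices of gate percentages and geometric mean
    fluorescence intensities. Control-sample computations cover spillover
    estimation from single stains, linear compensation, stain-index antibody
    titration, and an intrinsic-fluorescence interference screen for test
    articles such as nanoparticle formulations. The statistics layer provides
    negative-control reproducibility analysis (Pearson correlation with
    complete-linkage clustering), paired t-tests against vehicle or
    unstimulated references, and an exhaustive donor-label-swap permutation
    correction with a pooled null. A synthetic-cohort simulator with known
    ground truth makes every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
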