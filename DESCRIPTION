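Package: langnet
Title: Lesion-Modulated Language-Network Functional Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for studying how focal brain lesions (gliomas)
    reorganise resting-state functional connectivity within the language
    network. Provides a self-contained statistics kernel (t tests, one-way and
    two-level repeated-measures ANOVA, Tukey HSD, Pearson chi-square and
    correlation, Benjamini-Hochberg FDR), a synthetic-cohort generator
    encoding a core-periphery lesion model over the ten canonical language
    modules, lesion-mask utilities (tumor volume, overlap maps, subsystem
    assignment), desk-scale group spatial ICA with template-based component
    selection and sphere-ROI construction, edge-wise Fisher-z connectivity
    with hemispheric mean-network-connectivity indices, and the group-level
    inference layer (edge-wise reduction tests with FDR, direct/indirect edge
    typology, mNC ANOVAs, ipsi/contralesional analyses, tumor-volume
    correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    signal,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
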