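Package: fiberlink
Title: Linking Fiber-Pathway Tractography, Brain Gene Expression and
    Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for integrating diffusion-MRI fiber
    tractography with spatially registered brain gene-expression samples
    and a protein-protein interaction (PPI) network. Provides a synthetic
    phantom generator (label volumes, multi-fiber orientation fields with
    crossing regions, scattered expression samples with planted effects,
    and designed PPI graphs), probabilistic streamline tractography over
    a two-population orientation field, selection of expression samples
    inside pathway masks with per-probe z-score normalization and
    per-pathway average z-scores, interaction-count filtering of disease
    genes, and tier classification of the PPI neighborhood around a seed
    protein. All tabular results are tibbles; volumes are read and
    written as NIfTI.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
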