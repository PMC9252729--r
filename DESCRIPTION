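Package: omegafeat
Title: Feature Engineering for Biological Sequences, Structures and Ligands
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes named descriptor sets for protein, DNA and RNA sequences
    (composition, autocorrelation, sequence-order, pseudo compositions, reduced
    alphabets, residue-level encodings), protein structures (shell
    microenvironments, secondary-structure shells, half-sphere exposure,
    residue depth, residue contact-network indices) and small-molecule ligands
    (constitutional, topological, connectivity, shape, electrotopological,
    information-theoretic, Burden, pharmacophore, autocorrelation, charge,
    property and surface-area descriptors plus fingerprints). Feature matrices
    are tibbles that flow into a feature-analysis layer (normalization, ten
    clustering algorithms, three dimensionality reductions) and ggplot2-based
    visualisations, with export to CSV, TSV, SVM-light and ARFF.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    generics,
    jsonlite,
    ggplot2,
    igraph,
    mclust,
    kernlab,
    MASS,
    Biostrings,
    bio3d,
    ChemmineR,
    ChemmineOB,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
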