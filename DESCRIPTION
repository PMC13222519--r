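Package: residuekit
Title: Noncanonical Amino-Acid Residue Templates for Structure Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies amino-acid-like small molecules as peptide-embeddable
    alpha/beta/gamma residue monomers, maps them onto a Chemical Component
    Dictionary style reference library by full or connectivity-layer InChIKey
    matching, ranks reference components by Morgan-fingerprint similarity under
    four coefficients, builds named 3D residue topologies with CCD-style atom
    names, exports AlphaFold3-compatible residue definitions (CSV) and job
    specifications (JSON), and validates predicted structures with geometric
    band checks, peptide-bond omega-dihedral banding, RMSD with optional
    least-squares superposition, and chirality-parity agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    tibble,
    dplyr,
    purrr,
    tidyr,
    stringr,
    rlang,
    ggplot2,
    generics,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
SystemRequirements: Open Babel (obabel on PATH); Python 3 with RDKit
    (python on PATH) for the default conformer engine.
Config/testthat/edition: 3
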