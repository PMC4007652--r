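Package: phosphoconform
Title: Structural Accessibility Analysis of Protein Phosphorylation Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies protein phosphorylation sites into allowed and
    disallowed regions of phosphoconformation from their structural
    accessibility. Computes relative solvent accessible surface area
    (rSASA) of the octapeptide surrounding a phosphosite by Shrake-Rupley
    sphere sampling normalised to extended Gly-X-Gly tripeptide reference
    areas, assigns secondary structure, estimates residue depth, and
    rescues apparently buried sites via oligomer-interface removal,
    alternate structures, kinase consensus motifs, and conformer ensembles
    sampled along the low-frequency normal modes of a C-alpha elastic
    network model. Includes a synthetic-structure generator that plants
    ground-truth site categories so the whole pipeline is testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    bio3d,
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
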