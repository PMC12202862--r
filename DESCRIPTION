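Package: rsalor
Title: Mutational Effect Prediction from Residue Conservation and Solvent Accessibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised prediction of single-site and additive multi-site
    mutational effects in proteins. Computes a log-odd ratio (LOR) of weighted,
    regularized amino-acid frequencies from a multiple sequence alignment and
    scales it by the mutated residue's relative solvent accessibility (RSA)
    derived from a 3D structure via a deterministic Shrake-Rupley solvent
    accessible surface area calculation. Includes MSA curation (deduplication,
    twilight-zone identity filtering), inverse-cluster-size sequence weighting,
    structure-to-alignment residue mapping tolerant of missing residues and
    homologous templates, RSA-rescaling of external predictor scores, and
    seed-deterministic generators of synthetic alignments and structures for
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    parallel,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
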