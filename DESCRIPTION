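Package: ciliapep
Title: Discovery and Analysis of Cilia-Derived Amidated Signaling Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying peptidergic signaling through ciliary
    ectosomes in Chlamydomonas reinhardtii. Implements rule-based discovery
    of prepropeptide cleavage and C-terminal amidation sites in protein
    sequences, in-silico precursor processing to amidated peptides, peptide
    mass and fragment-ion arithmetic including the Gly-loss + amide
    modification, spectral-count normalization and replicate-presence
    filtering, an amidated-peptide evidence screen over peptide-spectrum
    matches, pairwise-alignment distances with rooted UPGMA clustering, and
    quantitative chemotaxis statistics (chemotaxis index, slice profiles,
    population center of mass, Rayleigh endpoint test). Synthetic-data
    generators reproduce the statistical structure of every input so the
    whole workflow runs without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
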