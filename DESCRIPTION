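Package: acidtrace
Title: Evolution of Clustered-Acidic C-Terminal Domains in a Protein Family
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative analysis of protein domain architecture across a gene
    family, built around the Dbx homeodomain transcription factors. Implements a
    sliding-window scanner for clustered acidic (Asp/Glu) C-terminal domains,
    reference-anchored projection of domain coordinates through a family
    alignment with ClustalX-style column conservation, per-domain relative
    solvent accessibility summaries with nonparametric comparison, and
    Fitch/Dollo parsimony machinery that weighs an ancestral-gain-plus-losses
    scenario against convergent gains on a species tree. A sequence-family
    simulator with known gain/loss ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
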