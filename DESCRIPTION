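Package: ganokey
Title: Identification and Barcode-Locus Resolution for Laccate Ganoderma of the United States
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the taxonomy of the laccate (varnished) Ganoderma
    species of the United States: a data-driven dichotomous identification
    key over morphological, host and geographic characters; basidiospore
    morphometrics (spore shape index and Q-ratio); collection tallies;
    desk-scale multilocus phylogenetics (supermatrix concatenation,
    pairwise distances, neighbor joining, nonparametric bootstrap,
    outgroup rooting, congruence screening); and a barcode-locus scoring
    scheme that ranks candidate loci by the number and cumulative
    bootstrap support of well-supported terminal species clades. A
    synthetic-data generator produces species-structured alignments,
    spore measurements and character profiles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    datasets,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
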