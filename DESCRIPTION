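Package: titeseq
Title: Sort-Seq Binding Titration Simulation and Dissociation Constant Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for massively parallel binding-titration (Tite-Seq style)
    experiments on yeast-displayed antibody libraries. Simulates FACS
    sort-seq experiments across an antigen concentration ladder (log-normal
    single-cell fluorescence around an equilibrium binding isotherm, gated
    sorting, post-sort recovery bottleneck, multinomial sequencing), infers
    absolute dissociation constants and surface-expression scores from
    binned read counts by maximum likelihood, processes paired-end amplicon
    reads into variant count tables, and provides downstream
    sequence-affinity landscape analyses (position-specific affinity
    matrices, per-position sensitivity statistics, additive multi-mutant
    prediction, enrichment diagnostics) and structural correlates from
    crystal-structure coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    S4Vectors,
    bio3d,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
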