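Package: slocusevo
Title: Origin, Loss, and Regain of S-RNase-Based Self-Incompatibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of type-1 (S-RNase/SLF)
    gametophytic self-incompatibility. Models pollination under
    collaborative non-self recognition and competitive interaction in
    transgenic self-crosses, infers a transgene's detoxification
    specificity from progeny genotype counts, implements the
    detoxification-probability closed forms (Pn = 1 - (1 - PR)^n and
    style-acceptance rates), annotates type-1 S-/S-like loci from
    classified gene tables via linkage-window clustering of T2 RNase
    anchors and F-box genes, classifies species histories into SI
    loss/regain routes, and reconstructs marginal posterior ancestral
    states of SI traits on dated trees under an F81-type model, with a
    forward simulator for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
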