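Package: polyforge
Title: Incipient Diploidization Analysis for Young Allopolyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissect the earliest stages of diploidization in a young
    allotetraploid genome: coverage-depth partition of subgenomes, de novo
    mutation calling from four-way orthologous alignments with 96-trinucleotide
    context spectra, detection of homeologous exchanges (4:0 segmental, 2:2
    balanced, 3:1 nonreciprocal) from depth dichotomy, comparative gene
    curation (pseudogene and deletion classification), Nei-Gojobori synonymous
    divergence with molecular dating, and homeolog expression bias. A bundled
    synthetic allotetraploid generator emits genomes, alignments, depth tracks,
    gene models, expression tables and complete truth sets so that every stage
    of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    Biostrings,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
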