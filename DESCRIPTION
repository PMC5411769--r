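Package: hingeasm
Title: Hinge-Aided Overlap-Layout-Consensus Assembly of Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An overlap-layout-consensus assembler for long error-prone reads
    that aims for maximal repeat resolution. Repeats are annotated on reads from
    sharp gradients in pile-o-gram alignment counts, their bridging status is
    spread globally by a contagion procedure that leaves exactly one in-hinge
    and one out-hinge per unbridged repeat, and a hinge-aided greedy layout
    builds a sparse overlap graph in which only unbridged repeats are collapsed,
    de Bruijn style. Uniquely traversable repeat loops are untangled subject to
    a plasmid-length gate, and contigs are polished by majority vote. Includes a
    simulator for circular bacterial-like genomes with configurable repeat
    structure and full ground truth, PAF input/output, and GFA output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    data.table,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: minimap2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
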