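Package: dbgcycles
Title: Eulerian and Hamiltonian Cycle Machinery for Edge-Centric de Bruijn Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying genome assembly with edge-centric de Bruijn
    graphs built from the k-mer spectrum of a read set. Implements the
    spectrum and closure operations on k-mer sets, de Bruijn and overlap
    graph construction, deterministic Eulerian cycle finding (Hierholzer),
    exhaustive enumeration and BEST-theorem counting of Eulerian cycles,
    the label-preserving bijection between Eulerian cycles of the order-k
    graph and Hamiltonian cycles of the order-(k+1) graph of the closure,
    spelling of cycles into circular genome reconstructions, unitig
    compaction, a seeded simulator of circular genomes with planted repeats
    and idealized (error-free, fully tiling) read sets, and a small command
    line interface. Graphs export to GFA1 and Graphviz DOT.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
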