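# dbgcycles

Eulerian and Hamiltonian cycle machinery for edge-centric de Bruijn graphs,
for teaching and studying the combinatorics of genome assembly from k-mers.

Given reads `R` (FASTA/FASTQ, gzipped or plain, or a plain k-mer list) and an
order `k`, the package computes the k-spectrum `sp^k(R)` — the *set* of
distinct k-mers in the reads — and builds the edge-centric de Bruijn graph
`dBG^k(S)`: vertices are the (k−1)-mers of `S`, and each k-mer `x ∈ S` is an
edge from `pre_{k−1}(x)` to `suf_{k−1}(x)`. A circular genome consistent
with the data is an Eulerian cycle of this graph.

The package's core is the correspondence between the two classical cycle
problems. With `closure(S)` = all (k+1)-mers whose k-prefix and k-suffix both
lie in `S`, the vertex set of `G2 = dBG^{k+1}(closure(S))` is exactly `S`,
and a cyclic k-mer sequence is an Eulerian cycle of `G1 = dBG^k(S)` **iff**
it is a Hamiltonian cycle of `G2` — the same sequence, reinterpreted. So a
Hamiltonian cycle of `G2` is found in `O(|S|)` time by running Hierholzer's
algorithm on `G1`, NP-hardness of general Hamiltonicity notwithstanding.
And because graphs with repeats admit *several* Eulerian cycles — several
genomes, all fully consistent with the same reads — the package also
enumerates and counts them (exhaustive backtracking, cross-checked against
the exact BEST-theorem count), and computes the unambiguous output an
assembler actually reports: unitigs, the maximal non-branching paths.

## Worked example

The minimal two-read example, `R = {TATTA, TAATA}` with `k = 3`:

```r
library(dbgcycles)

fx <- example_fixture()
S <- spectrum(fx$reads, fx$k)
S$kmers
#> [1] "AAT" "ATA" "ATT" "TAA" "TAT" "TTA"

G1 <- build_dbg(S)
G1
#> DeBruijnGraph (edge-centric): order k = 3, 4 vertices, 6 edges

cyc <- enumerate_eulerian_cycles(G1)
length(cyc)
#> [1] 2
sapply(cyc, function(C) spell(rotate_cycle(C, "ATT"))$linearized)
#> [1] "ATTAATAT" "ATTATAAT"
```

Two Eulerian cycles, two circular genomes (written with the wraparound
convention: the last 2 characters repeat the first 2). The data alone cannot
decide between them. On the Hamiltonian side:

```r
G2 <- build_closure_graph(S)      # order-4 graph of the 10-element closure
setequal(G2$vertices, S$kmers)
#> [1] TRUE
length(brute_force_hamiltonian(G2))
#> [1] 2
count_eulerian_cycles(G1)
#> [1] 2

unitigs(G1)
#> UnitigSet: 4 unitigs
#> Unitig: ATA (1 edges)
#> Unitig: ATTA (2 edges)
#> Unitig: TAAT (2 edges)
#> Unitig: TAT (1 edges)
```

Same count by three independent routes (enumeration, brute-force
Hamiltonian search, BEST theorem), and the four unitigs are the substrings
common to both reconstructions.

## Command line

```sh
exec/dbgcycles build     --reads inst/extdata/example_reads.fasta -k 3 --out out/
exec/dbgcycles assemble  --reads inst/extdata/example_reads.fasta -k 3 --out out/ --mode hamilton
exec/dbgcycles enumerate --reads inst/extdata/example_reads.fasta -k 3 --out out/
exec/dbgcycles simulate  --scenario scenario.txt --out out/
```

Every command writes a JSON report; `assemble --mode euler` and
`--mode hamilton` are guaranteed to write byte-identical FASTA. Exit codes:
0 success, 2 usage error, 3 non-Eulerian input (with a printed diagnosis),
4 enumeration overflow. Graphs export as GFA1 (segments = k-mer edge labels,
links = shared (k−1)-mer vertices) and Graphviz DOT.

A seeded simulator (`sim_scenario()`, `simulate_genome()`,
`simulate_reads()`) generates random circular genomes with planted exact
repeats and idealized, error-free read sets that tile every rotation start,
so the read spectrum provably equals the genome spectrum.

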