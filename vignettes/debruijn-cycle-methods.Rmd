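---
title: "Eulerian and Hamiltonian cycles in edge-centric de Bruijn graphs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eulerian and Hamiltonian cycles in edge-centric de Bruijn graphs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbgcycles)
```

## The model

dbgcycles works in the idealized, single-stranded model of genome assembly
from k-mers. The input is a set of reads `R` over `{A,C,G,T}`; the object of
study is its **k-spectrum** `sp^k(R)`, the *set* of distinct k-mers occurring
in the reads. Multiplicities are deliberately not tracked: a k-mer seen once
and a k-mer seen ten times are the same element of the spectrum. All
downstream statements are statements about this set.

The **edge-centric de Bruijn graph** of order k of a k-mer set `S`,
`build_dbg(S)`, has the (k−1)-mers of `S` as vertices and one edge per
k-mer, running from its (k−1)-prefix to its (k−1)-suffix. Vertices are
induced from edges, so no isolated vertices exist. Under the idealized
assumptions realized by the simulator (below), a circular genome corresponds
to an Eulerian cycle of this graph: a cyclic edge sequence using every k-mer
exactly once.

The **closure** of `S` is the set of all (k+1)-mers whose k-prefix and
k-suffix both lie in `S` — every (k+1)-mer constructible from `S`, including
ones absent from any read. The order-(k+1) graph of the closure,
`build_closure_graph(S)`, has vertex set exactly `S` whenever `S` is the
spectrum of reads all longer than k (each k-mer of a read extends to a
(k+1)-mer of the same read, whose affixes are again in `S`). The closure
graph is the line digraph of the order-k graph restricted to constructible
edges, which is the structural reason for the central correspondence:

**A cyclic k-mer sequence is an Eulerian cycle of `build_dbg(S)` if and only
if it is a Hamiltonian cycle of `build_closure_graph(S)`.** Both conditions
say the same thing: the sequence contains each element of `S` exactly once
and consecutive elements overlap in k−1 characters. `euler_to_hamilton()`
and `hamilton_to_euler()` are therefore identities on label sequences, and
`hamiltonian_cycle()` finds a Hamiltonian cycle of the closure graph in time
linear in `|S|` by running Hierholzer's algorithm on the order-k graph —
even though Hamiltonicity is NP-hard on general digraphs. The package
surfaces this as a user-visible guarantee: `cmd_assemble()` in `euler` and
`hamilton` mode writes byte-identical FASTA.

The consequence for assembly practice is the multiplicity of cycles: whenever
the graph admits two or more Eulerian cycles, the same read set is fully
consistent with two or more distinct circular genomes, so picking one cycle
is arbitrary. `unitigs()` computes the unambiguous alternative — the maximal
non-branching paths, which occur in *every* reconstruction.

## Cycle conventions

Cycles are cyclic objects. Two cycles are considered equal when one is a
rotation of the other; reversal is *not* quotiented out, because the graphs
are directed. The canonical form of a cycle is the lexicographically least
rotation of its label sequence; since labels within a cycle are distinct
(set semantics), that is simply the rotation starting at the smallest label.
For circular *strings* (reconstructions, circular unitigs), where characters
do repeat, the canonical form is computed with Booth's linear-time
least-rotation algorithm (`canonical_rotation()`).

A cycle of n edges is spelled (`spell()`) as a **linearized** string of
n + k − 1 characters: the first label followed by the last character of each
subsequent label. Its final k−1 characters automatically repeat the first
k−1 — the wraparound convention for writing a circular string of length n.
The circular sequence proper is the first n characters. The linearization
origin is the cycle's first label; `rotate_cycle()` selects any other
origin, which is how the package reproduces a published spelling exactly.

## Algorithms and numerical choices

* **Hierholzer** (`eulerian_cycle()`): iterative stack-based sub-tour
  splicing, O(m). Determinism without randomness: start at the
  lexicographically smallest vertex and always consume the smallest-label
  unused out-edge. The edge-visit counter is returned as an attribute so
  tests can assert one visit per edge exactly.
* **Exhaustive enumeration** (`enumerate_eulerian_cycles()`): backtracking
  with the first edge pinned to the globally smallest label. Every Eulerian
  cycle contains that edge exactly once, so each rotation class is generated
  exactly once and arrives already in canonical form. Counts grow
  factorially; a `limit` (default 10000) turns runaway enumeration into an
  explicit overflow error carrying the partial results, never silent
  truncation.
* **BEST-theorem counting** (`count_eulerian_cycles()`): the number of
  Eulerian cycles up to rotation equals the number of arborescences toward
  an arbitrary root times the product of (out-degree − 1) factorials. For
  Eulerian digraphs in-degrees equal out-degrees, so the arborescence count
  is independent of root and orientation; it is the determinant of the
  reduced out-degree Laplacian (self-loops cancel). The determinant uses
  Bareiss fraction-free elimination on integer-valued doubles: every
  intermediate quantity is an integer, so results are exact as long as
  intermediates stay below 2^53 — far beyond the graph sizes that can be
  enumerated or stored here.
* **Brute-force Hamiltonian search** (`brute_force_hamiltonian()`):
  exponential backtracking pinned to the smallest vertex, used as the
  independent second route when verifying the correspondence. It refuses
  graphs above a vertex cap (default 15) unless the cap is raised
  explicitly, since its only intended use is on small instances.
* **Unitig compaction** (`unitigs()`): maximal paths whose internal vertices
  have in-degree = out-degree = 1, found edge-linearly by walking forward
  from every edge leaving a branching vertex; leftover edges form simple
  cycles of 1/1 vertices and are emitted as circular unitigs with
  canonicalized rotation. The standard maximal-non-branching-path definition
  is used. Containment of a unitig in a reconstruction is checked in the
  *circular* sense (`in_circular()`): a unitig may straddle the arbitrary
  linearization origin of a cycle, so substring checks against one fixed
  linearization would be origin-dependent.

Degenerate inputs are handled explicitly: order k = 1 graphs are rejected
(vertices would be empty strings); a single self-overlapping k-mer such as
`AA` yields a one-vertex self-loop graph whose unique cycle spells the
one-character circular genome `A`; an empty closure (no k-mer chains onto
any other) is an error at graph construction, not an empty graph.

## The simulator and what it does (not) emulate

`simulate_genome()` draws a uniform random circular genome and plants each
requested repeat as exact copies at random non-overlapping positions
(placement is restarted bounded-many times when tight packings fragment the
free space). `simulate_reads()` emits one error-free read per rotation start
— full tiling — which *guarantees* that the read spectrum equals the
genome's spectrum at every order up to the read length. That guarantee is
the precondition of every theorem-level property test; a coverage-sampled
read mode would only weaken it. A single seeded RNG stream per scenario,
isolated from the session's RNG state, makes every output byte-reproducible.

Two modeling notes that matter when interpreting test results:

* Because spectra are sets, a genome whose k-mers are *not* all distinct
  collapses edges, and the collapsed graph is generally unbalanced. In
  particular a maximal repeat of length ≥ k with distinct flanking
  characters makes the repeat's boundary (k−1)-mer have two in-edges but one
  out-edge: the graph has **no** Eulerian cycle at order k. Fig-1-style
  ambiguity — several Eulerian cycles, several genomes — instead comes from
  repeated *vertices*, i.e. repeats of length k−1 in distinct contexts,
  interleaved around the circle. The ambiguity scenarios plant two repeat
  pairs of length k−1 accordingly, and the property suites treat
  non-Eulerian draws as zero-cycle cases on both sides of the
  correspondence (the bijection holds vacuously there).
* The model is single-stranded, error-free and circular. Nothing here
  speaks to reverse complements, sequencing errors, linear chromosomes or
  coverage variation; passing tests validate the combinatorics, not
  real-data robustness.

## Problem sizes used in the test suite

The correspondence suite runs 200 seeded scenarios with k drawn from 2–6 and
genome lengths 8–40, capped at `min(40, 4^(k-1) + 6)` per k: at small k the
graphs approach the complete de Bruijn graph, whose cycle counts explode
factorially, and the point of the suite is *double-sided exhaustive*
verification, which needs enumerable instances on both routes. About half
the scenarios plant repeats. Oracle agreement between the BEST count and
enumeration uses 50 random Eulerian graphs with at most 10 edges; the
Hierholzer validity check runs on a 100,000-edge graph (k = 31, where a
random circular genome has distinct k-mers with overwhelming probability).

## Known limitations

* Eulerian *paths* (linear genomes) are out of scope; everything is cyclic.
* k-mer multiplicities are not modeled, so the package cannot represent the
  multigraph in which long repeats retain balanced degrees.
* `count_eulerian_cycles()` is exact only while Bareiss intermediates stay
  below 2^53; it does not switch to arbitrary-precision arithmetic.
* The overlap graph stores one arc (the maximal overlap) per ordered read
  pair, and a read never overlaps itself; alternative conventions exist.
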