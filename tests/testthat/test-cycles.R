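fixture_S <- function() spectrum(c("TATTA", "TAATA"), 3)

test_that("Eulerian diagnosis separates balance and strong connectivity", {
  expect_true(diagnose_eulerian(build_dbg(fixture_S()))$is_eulerian)

  d <- diagnose_eulerian(build_dbg(kmer_spectrum("AC")))
  expect_false(d$is_eulerian)
  expect_identical(nrow(d$unbalanced_vertices), 2L)

  # balanced but disconnected: two 2-cycles over disjoint alphabets
  d2 <- diagnose_eulerian(build_dbg(kmer_spectrum(c("AC", "CA", "GT", "TG"))))
  expect_identical(nrow(d2$unbalanced_vertices), 0L)
  expect_false(d2$connected)
  expect_false(d2$is_eulerian)
})

test_that("diagnosis agrees with igraph's Eulerian-cycle test on random graphs", {
  set.seed(101)
  for (rep in 1:30) {
    S <- spectrum(random_genome(sample(6:25, 1)), sample(2:4, 1))
    G <- build_dbg(S)
    ig <- igraph::graph_from_data_frame(G$edges[, c("source", "target")],
                                        vertices = G$vertices)
    expect_identical(diagnose_eulerian(G)$is_eulerian,
                     igraph::has_eulerian_cycle(ig))
  }
})

test_that("Hierholzer returns a valid, deterministic Eulerian cycle and consumes each edge once", {
  G <- build_dbg(fixture_S())
  C <- eulerian_cycle(G)
  expect_true(is_eulerian_cycle_of(C, G))
  expect_identical(attr(C, "edge_visits"), nrow(G$edges))
  expect_identical(C$labels, eulerian_cycle(G)$labels)
  # its spelling is one of the two printed circular genomes
  expect_true(canonical_rotation(spell(C)$circular_seq) %in%
                c(canonical_rotation("ATTAAT"), canonical_rotation("ATTATA")))

  C1 <- eulerian_cycle(build_dbg(kmer_spectrum("AA")))
  expect_identical(C1$labels, "AA")

  err <- tryCatch(eulerian_cycle(build_dbg(kmer_spectrum("AC"))),
                  dbg_not_eulerian_error = function(e) e)
  expect_s3_class(err$diagnosis, "EulerianDiagnosis")

  sp <- distinct_kmer_spectrum(77L, n_range = 400:500, k = 12L)
  G500 <- build_dbg(sp$S)
  C500 <- eulerian_cycle(G500)
  expect_true(is_eulerian_cycle_of(C500, G500))
  expect_identical(attr(C500, "edge_visits"), nrow(G500$edges))
})

test_that("exhaustive enumeration finds exactly the worked example's two cycles", {
  G <- build_dbg(fixture_S())
  cyc <- enumerate_eulerian_cycles(G)
  expect_length(cyc, 2)
  for (C in cyc) expect_true(is_eulerian_cycle_of(C, G))
  # canonical forms are distinct
  expect_length(unique(vapply(cyc, function(C)
    paste(C$labels, collapse = "|"), character(1))), 2)
  # a simple cycle has exactly one Eulerian cycle
  expect_length(enumerate_eulerian_cycles(build_dbg(kmer_spectrum(c("AC", "CG", "GA")))), 1)
  # the deterministic Hierholzer cycle appears among the enumerated ones
  key <- paste(canonicalize_cycle(eulerian_cycle(G))$labels, collapse = "|")
  expect_true(key %in% vapply(cyc, function(C)
    paste(canonicalize_cycle(C)$labels, collapse = "|"), character(1)))
})

test_that("enumeration overflow raises an explicit error carrying partial results", {
  G <- build_dbg(fixture_S())
  err <- tryCatch(enumerate_eulerian_cycles(G, limit = 1),
                  dbg_overflow_error = function(e) e)
  expect_s3_class(err, "dbg_overflow_error")
  expect_identical(err$limit, 1)
  expect_length(err$partial, 1)
})

test_that("the BEST-theorem count matches exhaustive enumeration on random Eulerian graphs", {
  expect_identical(count_eulerian_cycles(build_dbg(fixture_S())), 2)
  expect_identical(count_eulerian_cycles(build_dbg(kmer_spectrum(c("AC", "CG", "GA")))), 1)
  n_checked <- 0
  seed <- 1L
  while (n_checked < 50) {
    sp <- distinct_kmer_spectrum(seed, n_range = 4:10, k = 3L)
    seed <- sp$seed + 1L
    G <- build_dbg(sp$S)
    expect_identical(count_eulerian_cycles(G),
                     as.numeric(length(enumerate_eulerian_cycles(G))))
    n_checked <- n_checked + 1
  }
})

test_that("the Euler->Hamilton map is the identity on labels and lands on valid Hamiltonian cycles", {
  S <- fixture_S()
  G1 <- build_dbg(S)
  G2 <- build_closure_graph(S)
  C1 <- eulerian_cycle(G1)
  H <- euler_to_hamilton(C1)
  expect_identical(H$labels, C1$labels)
  expect_identical(H$order, C1$order + 1L)
  expect_true(is_hamiltonian_cycle_of(H, G2))
  back <- hamilton_to_euler(H, S)
  expect_identical(back$labels, C1$labels)
  expect_true(is_eulerian_cycle_of(back, G1))

  # single-vertex case
  H1 <- euler_to_hamilton(eulerian_cycle(build_dbg(kmer_spectrum("AA"))))
  expect_true(is_hamiltonian_cycle_of(H1, build_closure_graph(kmer_spectrum("AA"))))

  # invalid inputs are rejected
  expect_error(hamilton_to_euler(vertex_cycle("TAT", order = 4L), S),
               class = "dbg_validation_error")
  expect_error(euler_to_hamilton(edge_cycle(c("AAA", "AAA"), 3)),
               class = "dbg_validation_error")  # duplicated edge label
  expect_error(edge_cycle(c("ATT", "TAT"), 3), class = "dbg_validation_error")
})

test_that("round-trip identity holds across 100 simulated spectra", {
  for (seed in 1:100) {
    sc <- random_scenario(seed)
    S <- scenario_spectrum(sc)
    G1 <- build_dbg(S)
    if (!diagnose_eulerian(G1)$is_eulerian) next
    C1 <- eulerian_cycle(G1)
    H <- euler_to_hamilton(C1)
    expect_true(is_hamiltonian_cycle_of(H, build_closure_graph(S)))
    expect_identical(hamilton_to_euler(H, S)$labels, C1$labels)
  }
})

test_that("hamiltonian_cycle() runs the linear-time route end to end", {
  S <- fixture_S()
  H <- hamiltonian_cycle(S)
  expect_true(is_hamiltonian_cycle_of(H, build_closure_graph(S)))
  expect_identical(hamiltonian_cycle(kmer_spectrum("AA"))$labels, "AA")
})

test_that("brute-force Hamiltonian search matches hand counts and respects its cap", {
  S <- fixture_S()
  ham <- brute_force_hamiltonian(build_closure_graph(S))
  expect_length(ham, 2)
  # complete digraph on 3 vertices has 2 directed Hamiltonian cycles
  og <- build_overlap_graph(c("ACA", "CAC", "ACAC"), 1)
  expect_identical(nrow(og$arcs), 6L)
  expect_length(brute_force_hamiltonian(og), 2)
  # cap refusal
  sp <- distinct_kmer_spectrum(7L, n_range = 20:25, k = 4L)
  expect_error(brute_force_hamiltonian(build_dbg(sp$S), cap = 15),
               class = "dbg_cap_error")
})

test_that("cycle serialization carries the ordered labels and order", {
  C <- eulerian_cycle(build_dbg(fixture_S()))
  obj <- jsonlite::fromJSON(cycle_json(C))
  expect_identical(obj$order, 3L)
  expect_identical(obj$labels, C$labels)
})
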