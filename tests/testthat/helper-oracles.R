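# Independent oracles and generators shared across the test files. Each
# oracle deliberately uses a different algorithm than the package code path
# it checks.

ALPH <- c("A", "C", "G", "T")

test_path_tmp <- function(name) file.path(tempdir(), name)

random_genome <- function(n) paste(sample(ALPH, n, replace = TRUE), collapse = "")

# wraparound linearization of a circular string for order k
circ_lin <- function(g, k) paste0(g, substr(g, 1L, k - 1L))

# spectrum by an explicit per-position loop over the character vector
oracle_spectrum <- function(strings, k) {
  out <- character(0)
  for (s in strings) {
    chars <- strsplit(s, "")[[1]]
    for (i in seq_len(length(chars) - k + 1L)) {
      out <- c(out, paste(chars[i:(i + k - 1L)], collapse = ""))
    }
  }
  sort(unique(out))
}

# closure by brute force over every candidate (k+1)-mer of the alphabet
oracle_closure <- function(kmers, k) {
  cand <- kmers[1]
  grids <- rep(list(ALPH), k + 1L)
  all_y <- do.call(paste0, expand.grid(grids, stringsAsFactors = FALSE))
  keep <- substr(all_y, 1L, k) %in% kmers & substr(all_y, 2L, k + 1L) %in% kmers
  sort(unique(all_y[keep]))
}

# maximal suffix/prefix overlap by scanning lengths upward
oracle_overlaps <- function(reads, min_o) {
  reads <- sort(unique(reads))
  res <- data.frame(from = character(0), to = character(0),
                    overlap = integer(0), stringsAsFactors = FALSE)
  for (x in reads) for (y in reads) {
    if (x == y) next
    best <- 0L
    for (o in seq_len(min(nchar(x), nchar(y)))) {
      if (substr(x, nchar(x) - o + 1L, nchar(x)) == substr(y, 1L, o)) best <- o
    }
    if (best >= min_o)
      res <- rbind(res, data.frame(from = x, to = y, overlap = best,
                                   stringsAsFactors = FALSE))
  }
  res
}

# least rotation by materializing every rotation
oracle_least_rotation <- function(s) {
  n <- nchar(s)
  rots <- vapply(0:(n - 1L), function(j)
    paste0(substr(s, j + 1L, n), substr(s, 1L, j)), character(1))
  sort(rots)[1]
}

# a seeded random simulation scenario spanning k in 2..6; genome lengths are
# capped per k so exhaustive enumeration on both graph orders stays fast
random_scenario <- function(seed) {
  set.seed(seed)
  k <- sample(2:6, 1)
  n_max <- min(40L, 4L^(k - 1L) + 6L)
  n <- sample(8:n_max, 1)
  rs <- list()
  if (seed %% 2 == 0 && k >= 3 && 4 * (k - 1) < n - 2)
    rs <- list(c(k - 1, 2), c(k - 1, 2))
  rl <- sample((k + 1):min(n, k + 6), 1)
  sim_scenario(n, read_length = rl, k = k, seed = seed + 9000L,
               repeat_spec = rs)
}

scenario_spectrum <- function(sc) {
  spectrum(simulate_reads(simulate_genome(sc), sc), sc$k)
}

# a random spectrum from a circular genome whose k-mers are all distinct
# (such graphs are Eulerian by construction); deterministic given seed0
distinct_kmer_spectrum <- function(seed0, n_range = 4:10, k = 3L) {
  seed <- seed0
  repeat {
    set.seed(seed)
    n <- if (length(n_range) == 1L) n_range else sample(n_range, 1)
    g <- random_genome(n)
    S <- spectrum(circ_lin(g, k), k)
    if (length(S$kmers) == n) return(list(S = S, genome = g, seed = seed))
    seed <- seed + 1000L
  }
}

# checks that a unitig is a maximal non-branching path of G
oracle_unitig_ok <- function(u, G) {
  v <- G$vertices
  e <- G$edges
  in_deg <- table(factor(e$target, levels = v))
  out_deg <- table(factor(e$source, levels = v))
  is_through <- function(x) in_deg[[x]] == 1L && out_deg[[x]] == 1L
  lab <- u$edge_labels
  k <- G$order
  # path consecutiveness
  if (length(lab) > 1) {
    for (i in seq_len(length(lab) - 1L)) {
      if (substr(lab[i], 2L, k) != substr(lab[i + 1L], 1L, k - 1L)) return(FALSE)
    }
  }
  srcs <- substr(lab, 1L, k - 1L)
  tgts <- substr(lab, 2L, k)
  if (u$circular) {
    # every vertex on the cycle must be 1/1
    return(all(vapply(srcs, is_through, logical(1))))
  }
  internal <- if (length(lab) > 1) tgts[-length(tgts)] else character(0)
  if (!all(vapply(internal, is_through, logical(1)))) return(FALSE)
  # maximality: endpoints must be branching (else the path could extend)
  if (is_through(srcs[1])) return(FALSE)
  if (is_through(tgts[length(tgts)])) return(FALSE)
  TRUE
}
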