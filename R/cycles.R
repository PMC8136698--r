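# Cycle machinery: Eulerian diagnosis, deterministic Hierholzer, exhaustive
# enumeration, BEST-theorem counting, the Euler<->Hamilton bijection, and a
# brute-force Hamiltonian search used as an oracle.

#' Construct an edge cycle (cyclic sequence of k-mer edge labels)
#'
#' Validates the defining invariant: consecutive labels (cyclically) overlap
#' in their last/first k-1 characters.
#'
#' @param labels Character vector of k-mers, read as a cyclic sequence.
#' @param order The order k of the host graph (= label length).
#' @return An object of class `EdgeCycle`.
#' @export
edge_cycle <- function(labels, order) {
  order <- as.integer(order)
  check_cycle_labels(labels, order, "EdgeCycle")
  structure(list(labels = unname(labels), order = order), class = "EdgeCycle")
}

#' Construct a vertex cycle (cyclic sequence of vertex labels)
#'
#' For a de Bruijn graph of order k+1 the vertices are k-mers, so a vertex
#' cycle stores k-mer labels and `order` = k+1 (the host graph's order).
#' Consecutive labels must overlap in k-1 characters, exactly as for edge
#' cycles — this shared invariant is what makes the Euler/Hamilton bijection
#' an identity on label sequences.
#'
#' @param labels Character vector of (order-1)-mers, cyclic.
#' @param order Order of the host graph (`NA` for overlap graphs).
#' @return An object of class `VertexCycle`.
#' @export
vertex_cycle <- function(labels, order) {
  order <- as.integer(order)
  if (!is.na(order)) check_cycle_labels(labels, order - 1L, "VertexCycle")
  structure(list(labels = unname(labels), order = order), class = "VertexCycle")
}

# labels are len-length strings whose cyclic (len-1)-overlaps must chain.
check_cycle_labels <- function(labels, len, what) {
  if (length(labels) == 0)
    dbg_stop(sprintf("%s must be nonempty", what), "dbg_validation_error")
  if (any(nchar(labels) != len))
    dbg_stop(sprintf("%s labels must all have length %d", what, len),
             "dbg_validation_error")
  nxt <- c(labels[-1], labels[1])
  bad <- substr(labels, 2L, len) != substr(nxt, 1L, len - 1L)
  if (any(bad))
    dbg_stop(sprintf("%s overlap invariant violated at position %d",
                     what, which(bad)[1]), "dbg_validation_error")
  invisible(TRUE)
}

#' @export
print.EdgeCycle <- function(x, ...) {
  cat(sprintf("EdgeCycle: %d edges (k = %d): %s\n", length(x$labels), x$order,
              paste(utils::head(x$labels, 8), collapse = " -> ")))
  invisible(x)
}

#' @export
print.VertexCycle <- function(x, ...) {
  cat(sprintf("VertexCycle: %d vertices (host order %s): %s\n",
              length(x$labels), x$order,
              paste(utils::head(x$labels, 8), collapse = " -> ")))
  invisible(x)
}

#' Rotation-canonical form of a cycle
#'
#' Cycles are compared up to rotation of their label sequence (never
#' reversal: the graphs are directed). Because labels within one cycle are
#' distinct, the lexicographically least rotation simply starts at the
#' smallest label.
#'
#' @param C An `EdgeCycle` or `VertexCycle`.
#' @return The same object rotated to canonical form.
#' @export
canonicalize_cycle <- function(C) {
  C$labels <- least_vector_rotation(C$labels)
  C
}

#' Rotate a cycle to start at a given label
#'
#' Cycles are cyclic objects; this picks the linearization origin. Useful to
#' reproduce a published spelling exactly.
#'
#' @param C An `EdgeCycle` or `VertexCycle`.
#' @param to_label A label contained in the cycle.
#' @return The same cycle rotated so `to_label` comes first.
#' @export
rotate_cycle <- function(C, to_label) {
  i <- match(to_label, C$labels)
  if (is.na(i))
    dbg_stop(sprintf("label %s is not in the cycle", to_label),
             "dbg_param_error")
  n <- length(C$labels)
  if (i > 1L) C$labels <- C$labels[c(i:n, 1:(i - 1L))]
  C
}

least_vector_rotation <- function(labels) {
  n <- length(labels)
  if (n <= 1L) return(labels)
  cand <- which(labels == min(labels))
  off <- 1L
  while (length(cand) > 1L && off < n) {
    vals <- labels[((cand - 1L + off) %% n) + 1L]
    cand <- cand[vals == min(vals)]
    off <- off + 1L
  }
  i <- cand[1]
  if (i == 1L) labels else labels[c(i:n, 1:(i - 1L))]
}

cycle_key <- function(labels) paste(labels, collapse = "|")

# ---------------------------------------------------------------------------
# Diagnosis

#' Check the Eulerian-cycle preconditions of a de Bruijn graph
#'
#' A nonempty digraph has an Eulerian cycle iff every vertex is balanced
#' (in-degree = out-degree) and the graph is strongly connected on its
#' non-isolated vertices (isolated vertices cannot exist here by
#' construction). Strong connectivity is computed with igraph.
#'
#' @param G A `DeBruijnGraph`.
#' @return An object of class `EulerianDiagnosis`: fields `is_eulerian`,
#'   `unbalanced_vertices` (data frame `vertex`, `in_degree`, `out_degree`)
#'   and `connected`.
#' @export
diagnose_eulerian <- function(G) {
  v <- G$vertices
  e <- G$edges
  out_deg <- tabulate(match(e$source, v), nbins = length(v))
  in_deg <- tabulate(match(e$target, v), nbins = length(v))
  unb <- data.frame(vertex = v, in_degree = in_deg, out_degree = out_deg,
                    stringsAsFactors = FALSE)[in_deg != out_deg, , drop = FALSE]
  rownames(unb) <- NULL
  ig <- igraph::graph_from_data_frame(e[, c("source", "target")],
                                      directed = TRUE, vertices = v)
  connected <- igraph::is_connected(ig, mode = "strong")
  structure(list(is_eulerian = nrow(unb) == 0 && connected,
                 unbalanced_vertices = unb, connected = connected),
            class = "EulerianDiagnosis")
}

#' @export
print.EulerianDiagnosis <- function(x, ...) {
  cat(sprintf("EulerianDiagnosis: is_eulerian = %s (balanced: %s, strongly connected: %s)\n",
              x$is_eulerian, nrow(x$unbalanced_vertices) == 0, x$connected))
  if (nrow(x$unbalanced_vertices)) print(utils::head(x$unbalanced_vertices, 10))
  invisible(x)
}

require_eulerian <- function(G) {
  d <- diagnose_eulerian(G)
  if (!d$is_eulerian)
    dbg_stop(paste0("graph is not Eulerian (",
                    nrow(d$unbalanced_vertices), " unbalanced vertices; ",
                    "strongly connected: ", d$connected, ")"),
             "dbg_not_eulerian_error", diagnosis = d)
  d
}

# Internal indexed view used by all traversals: integer source/target per
# edge, CSR-style adjacency over edges sorted by (source, label).
graph_index <- function(G) {
  v <- G$vertices
  labels <- G$edges$label               # sorted lexicographically
  src <- match(G$edges$source, v)
  tgt <- match(G$edges$target, v)
  ord <- order(src)                     # stable: keeps label order per source
  counts <- tabulate(src, nbins = length(v))
  starts <- cumsum(c(1L, counts))
  list(nv = length(v), m = length(labels), labels = labels,
       src = src, tgt = tgt, adj = ord, starts = starts)
}

# ---------------------------------------------------------------------------
# Hierholzer

#' Find one Eulerian cycle deterministically (Hierholzer's algorithm)
#'
#' Runs in time linear in the number of edges. Determinism: the traversal
#' starts at the lexicographically smallest vertex, always consumes the
#' unused out-edge with the smallest label, and splices sub-tours in the
#' standard stack-based fashion. Each edge is consumed exactly once; the
#' visit count is recorded in the `"edge_visits"` attribute of the result.
#'
#' @param G A `DeBruijnGraph` satisfying [diagnose_eulerian()].
#' @return An `EdgeCycle` covering every edge exactly once.
#' @examples
#' eulerian_cycle(build_dbg(spectrum(c("TATTA", "TAATA"), 3)))
#' @export
eulerian_cycle <- function(G) {
  require_eulerian(G)
  gi <- graph_index(G)
  m <- gi$m
  ptr <- gi$starts[seq_len(gi$nv)]
  stack_v <- integer(m + 1L)
  stack_e <- integer(m + 1L)
  top <- 1L
  stack_v[1L] <- 1L                     # vertices sorted: 1 is lex smallest
  stack_e[1L] <- 0L
  circuit <- integer(m)
  ci <- 0L
  visits <- 0L
  while (top > 0L) {
    vtx <- stack_v[top]
    if (ptr[vtx] < gi$starts[vtx + 1L]) {
      e <- gi$adj[ptr[vtx]]
      ptr[vtx] <- ptr[vtx] + 1L
      visits <- visits + 1L
      top <- top + 1L
      stack_v[top] <- gi$tgt[e]
      stack_e[top] <- e
    } else {
      if (stack_e[top] > 0L) {
        ci <- ci + 1L
        circuit[ci] <- stack_e[top]
      }
      top <- top - 1L
    }
  }
  if (ci != m || visits != m)
    dbg_stop("internal error: Hierholzer did not consume every edge once",
             "dbg_validation_error")
  out <- edge_cycle(gi$labels[rev(circuit)], order = G$order)
  attr(out, "edge_visits") <- visits
  out
}

#' Is C an Eulerian cycle of G? / a Hamiltonian cycle of G?
#'
#' Independent validators used throughout the tests: they re-check the
#' consecutive-overlap invariant and exact coverage (each edge label once for
#' Eulerian; each vertex once for Hamiltonian) directly against the graph.
#'
#' @param C An `EdgeCycle` (Eulerian check) or `VertexCycle` (Hamiltonian).
#' @param G The host graph (`DeBruijnGraph`; Hamiltonian check also accepts
#'   `OverlapGraph`).
#' @return `TRUE` or `FALSE`.
#' @export
is_eulerian_cycle_of <- function(C, G) {
  if (!inherits(C, "EdgeCycle")) return(FALSE)
  if (length(C$labels) != nrow(G$edges)) return(FALSE)
  if (anyDuplicated(C$labels) > 0) return(FALSE)
  if (!setequal(C$labels, G$edges$label)) return(FALSE)
  k <- G$order
  nxt <- c(C$labels[-1], C$labels[1])
  all(substr(C$labels, 2L, k) == substr(nxt, 1L, k - 1L))
}

#' @rdname is_eulerian_cycle_of
#' @export
is_hamiltonian_cycle_of <- function(C, G) {
  if (!inherits(C, "VertexCycle")) return(FALSE)
  v <- G$vertices
  if (length(C$labels) != length(v)) return(FALSE)
  if (anyDuplicated(C$labels) > 0) return(FALSE)
  if (!setequal(C$labels, v)) return(FALSE)
  has_arc <- graph_arc_lookup(G)
  nxt <- c(C$labels[-1], C$labels[1])
  all(has_arc(C$labels, nxt))
}

graph_arc_lookup <- function(G) {
  pairs <- if (inherits(G, "OverlapGraph")) {
    paste(G$arcs$from, G$arcs$to, sep = "\r")
  } else {
    paste(G$edges$source, G$edges$target, sep = "\r")
  }
  function(from, to) paste(from, to, sep = "\r") %in% pairs
}

# ---------------------------------------------------------------------------
# Enumeration and counting

#' Enumerate all Eulerian cycles of a small graph
#'
#' Exhaustive backtracking. The first edge of the trail is pinned to the
#' lexicographically smallest edge label, which every Eulerian cycle contains
#' exactly once — so each cycle (up to rotation) is generated exactly once
#' and is already in canonical least-rotation form. Counts grow factorially;
#' if more than `limit` cycles are found an overflow error is raised carrying
#' the partial results in its `partial` field.
#'
#' @param G A `DeBruijnGraph` satisfying [diagnose_eulerian()].
#' @param limit Abort threshold on the number of cycles (default 10000).
#' @return List of rotation-canonical `EdgeCycle` objects.
#' @examples
#' length(enumerate_eulerian_cycles(build_dbg(spectrum(c("TATTA", "TAATA"), 3))))
#' @export
enumerate_eulerian_cycles <- function(G, limit = 10000L) {
  require_eulerian(G)
  if (limit < 1L) dbg_stop("limit must be >= 1", "dbg_param_error")
  gi <- graph_index(G)
  m <- gi$m
  adj <- split(gi$adj, gi$src[gi$adj])   # per-vertex edge ids, label-sorted
  adj_full <- rep(list(integer(0)), gi$nv)
  adj_full[as.integer(names(adj))] <- adj
  used <- logical(m)
  path <- integer(m)
  res <- vector("list", 0L)
  nfound <- 0L
  start_v <- gi$src[1L]
  used[1L] <- TRUE
  path[1L] <- 1L
  recurse <- function(v, depth) {
    if (depth > m) {
      if (v == start_v) {
        if (nfound >= limit)
          dbg_stop(sprintf("more than %d Eulerian cycles; enumeration aborted",
                           limit),
                   "dbg_overflow_error", partial = res, limit = limit)
        nfound <<- nfound + 1L
        res[[nfound]] <<- edge_cycle(gi$labels[path], order = G$order)
      }
      return(invisible(NULL))
    }
    for (e in adj_full[[v]]) {
      if (!used[e]) {
        used[e] <<- TRUE
        path[depth] <<- e
        recurse(gi$tgt[e], depth + 1L)
        used[e] <<- FALSE
      }
    }
    invisible(NULL)
  }
  recurse(gi$tgt[1L], 2L)
  res
}

#' Count Eulerian cycles exactly via the BEST theorem
#'
#' The number of Eulerian cycles (up to rotation of the edge sequence) of a
#' connected balanced digraph equals `t_w(v) * prod((d_out(u) - 1)!)`, where
#' `t_w(v)` is the number of arborescences oriented toward an arbitrary root
#' v, computed as the determinant of the reduced out-degree Laplacian
#' (matrix-tree theorem; in a balanced digraph the count is root- and
#' orientation-independent). The determinant is evaluated with Bareiss
#' fraction-free elimination, which stays on integers throughout (exact while
#' intermediate values remain below 2^53).
#'
#' @param G A `DeBruijnGraph` satisfying [diagnose_eulerian()].
#' @return The exact count as a numeric scalar.
#' @examples
#' count_eulerian_cycles(build_dbg(spectrum(c("TATTA", "TAATA"), 3)))
#' @export
count_eulerian_cycles <- function(G) {
  require_eulerian(G)
  v <- G$vertices
  nv <- length(v)
  e <- G$edges
  A <- matrix(0, nv, nv)
  si <- match(e$source, v)
  ti <- match(e$target, v)
  for (i in seq_along(si)) A[si[i], ti[i]] <- A[si[i], ti[i]] + 1
  out_deg <- rowSums(A)
  L <- diag(out_deg, nv, nv) - A        # self-loops cancel on the diagonal
  arbo <- det_bareiss(L[-1L, -1L, drop = FALSE])
  arbo * prod(factorial(out_deg - 1))
}

# Fraction-free (Bareiss) determinant of an integer matrix held in doubles.
det_bareiss <- function(M) {
  n <- nrow(M)
  if (n == 0L) return(1)
  sign <- 1
  prev <- 1
  for (p in seq_len(n - 1L)) {
    if (M[p, p] == 0) {
      swap <- which(M[(p + 1L):n, p] != 0)
      if (length(swap) == 0) return(0)
      r <- p + swap[1]
      tmp <- M[p, ]; M[p, ] <- M[r, ]; M[r, ] <- tmp
      sign <- -sign
    }
    for (i in (p + 1L):n) {
      for (j in (p + 1L):n) {
        M[i, j] <- (M[i, j] * M[p, p] - M[i, p] * M[p, j]) / prev
      }
      M[i, p] <- 0
    }
    prev <- M[p, p]
  }
  sign * M[n, n]
}

# ---------------------------------------------------------------------------
# The bijection

#' Map an Eulerian cycle to the corresponding Hamiltonian cycle
#'
#' The correspondence is the identity on label sequences: the k-mer edge
#' labels of an Eulerian cycle in the order-k graph of S, read in order, are
#' exactly the vertex labels of a Hamiltonian cycle in the order-(k+1) graph
#' of closure(S), and vice versa. `hamilton_to_euler()` validates its input
#' against `build_closure_graph(S)` before reinterpreting it.
#'
#' @param C1 A valid `EdgeCycle` (Eulerian in some order-k graph).
#' @param C2 A `VertexCycle`, Hamiltonian in `build_closure_graph(S)`.
#' @param S The underlying [kmer_spectrum()].
#' @return A `VertexCycle` (resp. `EdgeCycle`) with the identical label
#'   sequence.
#' @export
euler_to_hamilton <- function(C1) {
  if (!inherits(C1, "EdgeCycle"))
    dbg_stop("C1 must be an EdgeCycle", "dbg_validation_error")
  if (anyDuplicated(C1$labels) > 0)
    dbg_stop("edge labels of an Eulerian cycle must be distinct",
             "dbg_validation_error")
  check_cycle_labels(C1$labels, C1$order, "EdgeCycle")
  vertex_cycle(C1$labels, order = C1$order + 1L)
}

#' @rdname euler_to_hamilton
#' @export
hamilton_to_euler <- function(C2, S) {
  if (!inherits(C2, "VertexCycle"))
    dbg_stop("C2 must be a VertexCycle", "dbg_validation_error")
  S <- as_kmer_spectrum(S)
  G2 <- build_closure_graph(S)
  if (!is_hamiltonian_cycle_of(C2, G2))
    dbg_stop("C2 is not a Hamiltonian cycle of the closure graph of S",
             "dbg_validation_error")
  edge_cycle(C2$labels, order = S$k)
}

#' Find a Hamiltonian cycle of the closure graph in linear time
#'
#' Exploits the bijection: computes an Eulerian cycle of `build_dbg(S)` with
#' Hierholzer's algorithm and reinterprets its edge-label sequence as the
#' vertex sequence of a Hamiltonian cycle of `build_closure_graph(S)` —
#' overall linear in `|S|`, despite Hamiltonicity being NP-hard in general
#' graphs.
#'
#' @param S A [kmer_spectrum()] obtained from reads of minimum length > k.
#' @return A `VertexCycle`, Hamiltonian in `build_closure_graph(S)`.
#' @examples
#' hamiltonian_cycle(spectrum(c("TATTA", "TAATA"), 3))
#' @export
hamiltonian_cycle <- function(S) {
  S <- as_kmer_spectrum(S)
  euler_to_hamilton(eulerian_cycle(build_dbg(S)))
}

#' Enumerate Hamiltonian cycles by brute-force backtracking
#'
#' Exponential-time oracle for small graphs; refuses more than `cap` vertices
#' unless the cap is raised explicitly. The path is pinned to start at the
#' lexicographically smallest vertex, which each Hamiltonian cycle visits
#' exactly once, so every cycle (up to rotation) appears once and in
#' canonical form. Works on de Bruijn graphs and overlap graphs.
#'
#' @param G A `DeBruijnGraph` or `OverlapGraph`.
#' @param limit Abort threshold on the number of cycles.
#' @param cap Maximum vertex count accepted (default 15).
#' @return List of rotation-canonical `VertexCycle` objects.
#' @export
brute_force_hamiltonian <- function(G, limit = 10000L, cap = 15L) {
  v <- G$vertices
  nv <- length(v)
  if (nv > cap)
    dbg_stop(sprintf("%d vertices exceeds the brute-force cap of %d (raise `cap` to override)",
                     nv, cap), "dbg_cap_error")
  host_order <- if (inherits(G, "DeBruijnGraph")) G$order else NA_integer_
  pairs <- if (inherits(G, "OverlapGraph")) {
    data.frame(from = G$arcs$from, to = G$arcs$to, stringsAsFactors = FALSE)
  } else {
    data.frame(from = G$edges$source, to = G$edges$target,
               stringsAsFactors = FALSE)
  }
  pairs <- unique(pairs)
  fi <- match(pairs$from, v)
  ti <- match(pairs$to, v)
  adj <- rep(list(integer(0)), nv)
  ord <- order(fi, ti)
  sp <- split(ti[ord], fi[ord])
  adj[as.integer(names(sp))] <- sp
  has_arc <- matrix(FALSE, nv, nv)
  has_arc[cbind(fi, ti)] <- TRUE
  visited <- logical(nv)
  path <- integer(nv)
  res <- vector("list", 0L)
  nfound <- 0L
  visited[1L] <- TRUE
  path[1L] <- 1L
  recurse <- function(u, depth) {
    if (depth > nv) {
      if (has_arc[u, 1L]) {
        if (nfound >= limit)
          dbg_stop(sprintf("more than %d Hamiltonian cycles; enumeration aborted",
                           limit),
                   "dbg_overflow_error", partial = res, limit = limit)
        nfound <<- nfound + 1L
        res[[nfound]] <<- vertex_cycle(v[path], order = host_order)
      }
      return(invisible(NULL))
    }
    for (w in adj[[u]]) {
      if (!visited[w]) {
        visited[w] <<- TRUE
        path[depth] <<- w
        recurse(w, depth + 1L)
        visited[w] <<- FALSE
      }
    }
    invisible(NULL)
  }
  if (nv == 1L) {
    if (has_arc[1L, 1L]) res <- list(vertex_cycle(v, order = host_order))
    return(res)
  }
  recurse(1L, 2L)
  res
}

#' Serialize a cycle to JSON (ordered labels plus order)
#'
#' @param C An `EdgeCycle` or `VertexCycle`.
#' @return A JSON string.
#' @export
cycle_json <- function(C) {
  as.character(jsonlite::toJSON(
    list(type = class(C)[1], order = C$order, labels = C$labels),
    auto_unbox = TRUE
  ))
}
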