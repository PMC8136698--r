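# Spelling cycles into circular genome reconstructions, canonical rotations
# of circular strings, and unitig compaction.

#' Spell an edge cycle into a circular genome reconstruction
#'
#' The linearized form of a cycle of n k-mer edges is the first label
#' followed by the last character of each subsequent label: n + k - 1
#' characters whose final k - 1 characters repeat the first k - 1 (the
#' wraparound convention for writing a circular string). The circular
#' sequence proper is the first n characters; rotating the cycle rotates it
#' correspondingly.
#'
#' @param C A valid `EdgeCycle`.
#' @return An object of class `Reconstruction` with fields `circular_seq`,
#'   `linearized`, `k`, `n` and `source_cycle`.
#' @examples
#' G <- build_dbg(spectrum(c("TATTA", "TAATA"), 3))
#' spell(eulerian_cycle(G))
#' @export
spell <- function(C) {
  if (!inherits(C, "EdgeCycle"))
    dbg_stop("spell() expects an EdgeCycle", "dbg_validation_error")
  labels <- C$labels
  k <- C$order
  check_cycle_labels(labels, k, "EdgeCycle")
  n <- length(labels)
  linearized <- paste0(labels[1],
                       paste(substr(labels[-1], k, k), collapse = ""))
  structure(
    list(circular_seq = substr(linearized, 1L, n),
         linearized = linearized, k = k, n = n, source_cycle = C),
    class = "Reconstruction"
  )
}

#' @export
print.Reconstruction <- function(x, ...) {
  cat(sprintf("Reconstruction: circular genome of length %d (k = %d)\n",
              x$n, x$k))
  cat(sprintf("  linearized (n + k - 1 = %d chars): %s\n",
              nchar(x$linearized), x$linearized))
  invisible(x)
}

#' Lexicographically least rotation of a string
#'
#' Canonical form for comparing circular sequences, computed with Booth's
#' linear-time least-rotation algorithm. Idempotent.
#'
#' @param s A single non-empty string.
#' @return The smallest rotation of `s`.
#' @examples
#' canonical_rotation("ATTAAT") # "AATATT"
#' @export
canonical_rotation <- function(s) {
  if (length(s) != 1L || is.na(s) || nchar(s) == 0)
    dbg_stop("s must be a single non-empty string", "dbg_param_error")
  j <- booth_least_rotation(utf8ToInt(s))
  rotate_string(s, j)
}

# 0-based index of the least rotation (Booth's algorithm).
booth_least_rotation <- function(v) {
  n <- length(v)
  if (n == 1L) return(0L)
  s <- c(v, v)
  f <- rep(-1L, 2L * n)                 # failure function, 0-based values
  lr <- 0L                              # least-rotation candidate, 0-based
  for (j in 1L:(2L * n - 1L)) {         # 0-based position j, s[j + 1] in R
    sj <- s[j + 1L]
    i <- f[j - lr]                      # f is 0-indexed via offset: f[idx0+1]
    while (i != -1L && sj != s[lr + i + 2L]) {
      if (sj < s[lr + i + 2L]) lr <- j - i - 1L
      i <- f[i + 1L]
    }
    if (sj != s[lr + i + 2L]) {         # i == -1 here
      if (sj < s[lr + 1L]) lr <- j
      f[j - lr + 1L] <- -1L
    } else {
      f[j - lr + 1L] <- i + 1L
    }
  }
  lr
}

# Rotate a string left by j characters (j in 0..nchar(s)-1).
rotate_string <- function(s, j) {
  n <- nchar(s)
  j <- j %% n
  if (j == 0L) return(s)
  paste0(substr(s, j + 1L, n), substr(s, 1L, j))
}

#' Compact a de Bruijn graph into unitigs
#'
#' A unitig is the string spelled by a maximal path all of whose internal
#' vertices have in-degree and out-degree exactly 1 — the unambiguous
#' contigs that every genome reconstruction must contain. Components that
#' are simple cycles of 1/1-degree vertices are emitted as circular unitigs
#' (rotation-canonicalized). Every edge belongs to exactly one unitig, and
#' the construction is linear in the number of edges.
#'
#' @param G A `DeBruijnGraph`.
#' @return An object of class `UnitigSet`: a list of `Unitig` objects, each
#'   with fields `seq` (path spelling, `n_edges + k - 1` characters),
#'   `n_edges`, `internal_vertices`, `circular` and `edge_labels`.
#' @examples
#' unitigs(build_dbg(spectrum(c("TATTA", "TAATA"), 3)))
#' @export
unitigs <- function(G) {
  if (nrow(G$edges) == 0)
    dbg_stop("graph has no edges", "dbg_param_error")
  k <- G$order
  v <- G$vertices
  nv <- length(v)
  labels <- G$edges$label
  si <- match(G$edges$source, v)
  ti <- match(G$edges$target, v)
  out_deg <- tabulate(si, nbins = nv)
  in_deg <- tabulate(ti, nbins = nv)
  through <- out_deg == 1L & in_deg == 1L
  only_out <- integer(nv)
  only_out[si[out_deg[si] == 1L]] <- which(out_deg[si] == 1L)
  m <- length(labels)
  used <- logical(m)
  res <- list()
  spell_path <- function(idx) {
    paste0(labels[idx[1]],
           if (length(idx) > 1L)
             paste(substr(labels[idx[-1]], k, k), collapse = "") else "")
  }
  # linear unitigs start on edges leaving a branching vertex
  for (e0 in which(!through[si])) {
    path <- e0
    used[e0] <- TRUE
    w <- ti[e0]
    while (through[w]) {
      e1 <- only_out[w]
      path <- c(path, e1)
      used[e1] <- TRUE
      w <- ti[e1]
    }
    res[[length(res) + 1L]] <- structure(
      list(seq = spell_path(path), n_edges = length(path),
           internal_vertices = length(path) - 1L, circular = FALSE,
           edge_labels = labels[path], k = k),
      class = "Unitig")
  }
  # leftover edges form simple cycles of 1/1 vertices
  for (e0 in which(!used)) {
    if (used[e0]) next
    path <- e0
    used[e0] <- TRUE
    w <- ti[e0]
    while (w != si[e0]) {
      e1 <- only_out[w]
      path <- c(path, e1)
      used[e1] <- TRUE
      w <- ti[e1]
    }
    rot <- least_vector_rotation(labels[path])
    res[[length(res) + 1L]] <- structure(
      list(seq = spell_path(match(rot, labels)), n_edges = length(path),
           internal_vertices = length(path), circular = TRUE,
           edge_labels = rot, k = k),
      class = "Unitig")
  }
  structure(res, class = "UnitigSet")
}

#' @export
print.Unitig <- function(x, ...) {
  cat(sprintf("Unitig%s: %s (%d edges)\n",
              if (x$circular) " (circular)" else "", x$seq, x$n_edges))
  invisible(x)
}

#' @export
print.UnitigSet <- function(x, ...) {
  cat(sprintf("UnitigSet: %d unitigs\n", length(x)))
  for (u in x) print(u)
  invisible(x)
}

#' Does a string occur in a circular reconstruction?
#'
#' Substring containment in the circular sense: the query may wrap around
#' the origin of the reconstruction. This is the right notion for checking
#' that every unitig occurs in every reconstruction, since the linearization
#' origin of a cycle is arbitrary.
#'
#' @param query A string (e.g. a unitig sequence).
#' @param rec A `Reconstruction` (or a plain circular string).
#' @return `TRUE` or `FALSE`.
#' @export
in_circular <- function(query, rec) {
  circ <- if (inherits(rec, "Reconstruction")) rec$circular_seq else rec
  if (nchar(query) > 2L * nchar(circ)) return(FALSE)
  grepl(query, paste0(circ, circ, circ), fixed = TRUE)
}

#' Write reconstructions or unitigs as FASTA
#'
#' Headers carry the record index, sequence length, circularity and k:
#' `>reconstruction_1 length=8 circular=true k=3`.
#'
#' @param x A `Reconstruction`, list of reconstructions, or `UnitigSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assembly_fasta <- function(x, path) {
  if (inherits(x, "Reconstruction")) x <- list(x)
  if (inherits(x, "UnitigSet")) {
    seqs <- vapply(x, `[[`, character(1), "seq")
    names(seqs) <- sprintf("unitig_%d length=%d circular=%s k=%d",
                           seq_along(x), nchar(seqs),
                           tolower(vapply(x, `[[`, logical(1), "circular")),
                           vapply(x, `[[`, integer(1), "k"))
  } else {
    seqs <- vapply(x, `[[`, character(1), "linearized")
    ks <- vapply(x, `[[`, integer(1), "k")
    names(seqs) <- sprintf("reconstruction_%d length=%d circular=true k=%d",
                           seq_along(x), nchar(seqs), ks)
  }
  write_fasta(seqs, path)
}
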