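#' Build an edge-centric de Bruijn graph from a k-mer spectrum
#'
#' The de Bruijn graph of order k of a k-mer set S has the (k-1)-mers of S as
#' vertices, and one edge per k-mer x, running from its (k-1)-prefix to its
#' (k-1)-suffix. Vertices are induced from the edges, so isolated vertices
#' cannot exist. Edge labels are distinct (set semantics) and adjacency lists
#' are sorted lexicographically by label, which makes every downstream
#' traversal deterministic.
#'
#' @param S A [kmer_spectrum()] (or character vector of k-mers), `k >= 2`.
#' @return An object of class `DeBruijnGraph` with fields `order`, `vertices`
#'   (sorted), `edges` (data frame `label`, `source`, `target`, sorted by
#'   label) and `adjacency` (named list vertex -> sorted outgoing edge
#'   labels).
#' @examples
#' build_dbg(spectrum(c("TATTA", "TAATA"), 3))
#' @export
build_dbg <- function(S) {
  S <- as_kmer_spectrum(S)
  if (length(S$kmers) == 0)
    dbg_stop("cannot build a graph from an empty spectrum", "dbg_param_error")
  k <- S$k
  if (k < 2L)
    dbg_stop("graph order k must be >= 2 (vertices are (k-1)-mers)",
             "dbg_param_error")
  labels <- S$kmers                       # already sorted
  src <- substr(labels, 1L, k - 1L)
  tgt <- substr(labels, 2L, k)
  vertices <- sort(unique(c(src, tgt)))
  adjacency <- rep(list(character(0)), length(vertices))
  names(adjacency) <- vertices
  by_src <- split(labels, src)            # label-sorted within each source
  adjacency[names(by_src)] <- by_src
  structure(
    list(order = k,
         vertices = vertices,
         edges = data.frame(label = labels, source = src, target = tgt,
                            stringsAsFactors = FALSE),
         adjacency = adjacency),
    class = "DeBruijnGraph"
  )
}

#' @export
print.DeBruijnGraph <- function(x, ...) {
  cat(sprintf("DeBruijnGraph (edge-centric): order k = %d, %d vertices, %d edges\n",
              x$order, length(x$vertices), nrow(x$edges)))
  invisible(x)
}

#' Build the order-(k+1) de Bruijn graph of the closure
#'
#' Convenience composition `build_dbg(closure(S))`. When `S` is the
#' k-spectrum of reads all longer than k, the vertex set of the resulting
#' graph is exactly `S` itself, which is what places Hamiltonian cycles of
#' this graph in one-to-one correspondence with Eulerian cycles of
#' `build_dbg(S)`.
#'
#' @inheritParams build_dbg
#' @return A `DeBruijnGraph` of order `k + 1`.
#' @examples
#' build_closure_graph(spectrum(c("TATTA", "TAATA"), 3))
#' @export
build_closure_graph <- function(S) {
  S <- as_kmer_spectrum(S)
  cl <- closure(S)
  if (length(cl$kmers) == 0)
    dbg_stop("closure is empty; no graph to build", "dbg_param_error")
  build_dbg(cl)
}

#' Build an overlap graph from reads
#'
#' Vertices are the distinct reads; there is an arc from x to y (x != y)
#' whenever a suffix of x of length at least `min_overlap` equals a prefix of
#' y. Only the maximal such overlap length is stored per ordered pair.
#'
#' @param reads A [read_set()] or character vector; exact duplicates are
#'   collapsed.
#' @param min_overlap Minimum overlap length, `>= 1`.
#' @return An object of class `OverlapGraph` with fields `min_overlap`,
#'   `vertices` (sorted reads) and `arcs` (data frame `from`, `to`,
#'   `overlap`).
#' @examples
#' build_overlap_graph(c("TATTA", "TAATA"), 2)
#' @export
build_overlap_graph <- function(reads, min_overlap = 1L) {
  R <- as_read_set(reads)
  min_overlap <- as.integer(min_overlap)
  if (is.na(min_overlap) || min_overlap < 1L)
    dbg_stop("min_overlap must be >= 1", "dbg_param_error")
  v <- sort(unique(R$reads))
  from <- character(0); to <- character(0); ov <- integer(0)
  for (x in v) for (y in v) {
    if (x == y) next
    o <- max_suffix_prefix_overlap(x, y, min_overlap)
    if (o > 0L) { from <- c(from, x); to <- c(to, y); ov <- c(ov, o) }
  }
  structure(
    list(min_overlap = min_overlap, vertices = v,
         arcs = data.frame(from = from, to = to, overlap = ov,
                           stringsAsFactors = FALSE)),
    class = "OverlapGraph"
  )
}

max_suffix_prefix_overlap <- function(x, y, min_o) {
  for (o in seq(min(nchar(x), nchar(y)), min_o)) {
    if (substr(x, nchar(x) - o + 1L, nchar(x)) == substr(y, 1L, o))
      return(o)
  }
  0L
}

#' @export
print.OverlapGraph <- function(x, ...) {
  cat(sprintf("OverlapGraph: %d reads, %d arcs (min overlap %d)\n",
              length(x$vertices), nrow(x$arcs), x$min_overlap))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Export

#' Export a graph as GFA1 or Graphviz DOT text
#'
#' For a de Bruijn graph the GFA1 export uses the edge-centric-as-node-centric
#' convention: each k-mer edge label becomes an S-line segment, and an L-line
#' links two segments whenever they share a (k-1)-mer vertex, with a
#' (k-1)-character overlap. For an overlap graph, segments are reads and
#' L-lines carry the stored overlap. DOT output mirrors the usual labeled
#' digraph drawing. Output is byte-stable for a given graph.
#'
#' @param G A `DeBruijnGraph` or `OverlapGraph`.
#' @param format `"gfa1"` or `"dot"`.
#' @return A single character string (the file content).
#' @export
export_graph <- function(G, format = c("gfa1", "dot")) {
  if (length(format) != 1L || !format %in% c("gfa1", "dot"))
    dbg_stop("format must be \"gfa1\" or \"dot\"", "dbg_param_error")
  UseMethod("export_graph")
}

#' @export
export_graph.DeBruijnGraph <- function(G, format = c("gfa1", "dot")) {
  format <- format[1]
  k <- G$order
  e <- G$edges
  if (format == "dot") {
    body <- sprintf("  \"%s\" -> \"%s\" [label=\"%s\"];",
                    e$source, e$target, e$label)
    return(paste(c("digraph dBG {", body, "}"), collapse = "\n"))
  }
  s_lines <- sprintf("S\t%s\t%s", e$label, e$label)
  # link x -> y when suffix_{k-1}(x) == prefix_{k-1}(y)
  by_src <- split(e$label, e$source)
  l_lines <- unlist(lapply(e$label, function(x) {
    nxt <- by_src[[substr(x, 2L, k)]]
    if (is.null(nxt)) return(character(0))
    sprintf("L\t%s\t+\t%s\t+\t%dM", x, nxt, k - 1L)
  }), use.names = FALSE)
  paste(c("H\tVN:Z:1.0", s_lines, l_lines), collapse = "\n")
}

#' @export
export_graph.OverlapGraph <- function(G, format = c("gfa1", "dot")) {
  format <- format[1]
  a <- G$arcs
  if (format == "dot") {
    body <- if (nrow(a)) sprintf("  \"%s\" -> \"%s\" [label=\"%d\"];",
                                 a$from, a$to, a$overlap) else character(0)
    return(paste(c("digraph overlap {", body, "}"), collapse = "\n"))
  }
  s_lines <- sprintf("S\t%s\t%s", G$vertices, G$vertices)
  l_lines <- if (nrow(a)) sprintf("L\t%s\t+\t%s\t+\t%dM", a$from, a$to, a$overlap)
             else character(0)
  paste(c("H\tVN:Z:1.0", s_lines, l_lines), collapse = "\n")
}

# Segment names of a GFA1 text (round-trip helper).
gfa_segments <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  s <- lines[startsWith(lines, "S\t")]
  vapply(strsplit(s, "\t", fixed = TRUE), `[[`, character(1), 2L)
}

#' Serialize a de Bruijn graph to JSON (and back)
#'
#' A plain machine-readable dump: order, vertices and the edge table.
#' `graph_from_json()` inverts it exactly.
#'
#' @param G A `DeBruijnGraph`.
#' @param text JSON string produced by `graph_json()` (or a file path).
#' @return `graph_json()`: a JSON string; `graph_from_json()`: a
#'   `DeBruijnGraph`.
#' @export
graph_json <- function(G) {
  as.character(jsonlite::toJSON(
    list(order = G$order, vertices = G$vertices,
         edges = G$edges[, c("label", "source", "target")]),
    auto_unbox = TRUE, pretty = TRUE
  ))
}

#' @rdname graph_json
#' @export
graph_from_json <- function(text) {
  if (length(text) == 1L && !grepl("{", text, fixed = TRUE) && file.exists(text))
    text <- paste(readLines(text), collapse = "\n")
  obj <- jsonlite::fromJSON(text)
  build_dbg(kmer_spectrum(obj$edges$label, k = obj$order))
}
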