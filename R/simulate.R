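# Seeded simulator of circular genomes with planted exact repeats and of
# idealized read sets (error-free, one read per rotation start), so that the
# k-spectrum of the reads provably equals the k-spectrum of the genome's
# wraparound linearization — the precondition every downstream theorem test
# relies on.

#' Define a simulation scenario
#'
#' @param genome_length Length n of the circular genome.
#' @param read_length Read length; `k < read_length <= genome_length`.
#' @param k Intended spectrum order.
#' @param seed Integer seed; fully determines genome and reads.
#' @param repeat_spec List of `c(repeat_length, copies)` pairs: each entry
#'   plants `copies` exact copies of one random `repeat_length`-mer at
#'   non-overlapping positions.
#' @param alphabet Alphabet of the genome.
#' @return An object of class `SimScenario`.
#' @examples
#' sim_scenario(30, read_length = 8, k = 4, seed = 1,
#'              repeat_spec = list(c(3, 2)))
#' @export
sim_scenario <- function(genome_length, read_length, k, seed,
                         repeat_spec = list(), alphabet = DNA_ALPHABET) {
  genome_length <- as.integer(genome_length)
  read_length <- as.integer(read_length)
  k <- as.integer(k)
  seed <- as.integer(seed)
  if (is.na(k) || k < 1L || is.na(read_length) || is.na(genome_length))
    dbg_stop("genome_length, read_length and k must be integers",
             "dbg_param_error")
  if (!(k < read_length && read_length <= genome_length))
    dbg_stop("need k < read_length <= genome_length", "dbg_param_error")
  if (length(repeat_spec) > 0) {
    mass <- sum(vapply(repeat_spec, function(r) r[1] * r[2], numeric(1)))
    if (mass >= genome_length)
      dbg_stop("planted repeats do not fit in the genome", "dbg_param_error")
  }
  structure(list(genome_length = genome_length, read_length = read_length,
                 k = k, seed = seed, repeat_spec = repeat_spec,
                 alphabet = alphabet),
            class = "SimScenario")
}

#' @export
print.SimScenario <- function(x, ...) {
  cat(sprintf("SimScenario: n = %d, read length %d, k = %d, seed %d, %d repeat spec(s)\n",
              x$genome_length, x$read_length, x$k, x$seed,
              length(x$repeat_spec)))
  invisible(x)
}

#' Simulate a random circular genome with planted exact repeats
#'
#' Draws a uniform random string over the alphabet, then overwrites, for each
#' repeat specification, `copies` non-overlapping windows with one common
#' random repeat sequence. Placement is by rejection sampling over free
#' positions (placement within the linear coordinates of the circular
#' string). Deterministic given the scenario's seed.
#'
#' @param sc A [sim_scenario()].
#' @return A single string: one period of the circular genome.
#' @export
simulate_genome <- function(sc) {
  stopifnot(inherits(sc, "SimScenario"))
  with_rng_seed(sc$seed, {
    n <- sc$genome_length
    g <- sample(sc$alphabet, n, replace = TRUE)
    rep_seqs <- lapply(sc$repeat_spec, function(spec) {
      len <- as.integer(spec[1]); copies <- as.integer(spec[2])
      if (len < 1L || copies < 1L)
        dbg_stop("repeat_spec entries must be c(length >= 1, copies >= 1)",
                 "dbg_param_error")
      list(seq = sample(sc$alphabet, len, replace = TRUE), copies = copies)
    })
    # random placement can fragment the free space at tight packings;
    # restart the whole placement a bounded number of times before refusing
    for (attempt in seq_len(100L)) {
      occupied <- logical(n)
      placements <- list()
      ok <- TRUE
      for (rs in rep_seqs) {
        len <- length(rs$seq)
        for (copy in seq_len(rs$copies)) {
          starts <- seq_len(n - len + 1L)
          feasible <- starts[vapply(starts, function(p)
            !any(occupied[p:(p + len - 1L)]), logical(1))]
          if (length(feasible) == 0) { ok <- FALSE; break }
          pos <- feasible[sample.int(length(feasible), 1L)]
          occupied[pos:(pos + len - 1L)] <- TRUE
          placements[[length(placements) + 1L]] <- list(pos = pos, seq = rs$seq)
        }
        if (!ok) break
      }
      if (ok) {
        for (p in placements)
          g[p$pos:(p$pos + length(p$seq) - 1L)] <- p$seq
        return(paste(g, collapse = ""))
      }
    }
    dbg_stop("could not place planted repeats without overlap",
             "dbg_param_error")
  })
}

#' Simulate an idealized read set by full circular tiling
#'
#' Emits one error-free read per starting position of the circular genome
#' (n reads of length `sc$read_length`). By construction the k-spectrum of
#' the reads equals the k-spectrum of the genome's wraparound linearization
#' for every k up to the read length.
#'
#' @param genome A circular genome string.
#' @param sc The [sim_scenario()] providing `read_length`.
#' @return A [read_set()] of `nchar(genome)` reads.
#' @export
simulate_reads <- function(genome, sc) {
  stopifnot(inherits(sc, "SimScenario"))
  n <- nchar(genome)
  rl <- sc$read_length
  if (rl > n)
    dbg_stop("read_length exceeds the genome length", "dbg_param_error")
  doubled <- paste0(genome, genome)
  reads <- substring(doubled, seq_len(n), seq_len(n) + rl - 1L)
  read_set(reads, alphabet = sc$alphabet)
}

#' The worked two-read example
#'
#' Returns the minimal example used throughout the documentation: reads
#' `{TATTA, TAATA}` with `k = 3`, whose order-3 de Bruijn graph has exactly
#' two Eulerian cycles spelling the two circular genomes `ATTAATAT` and
#' `ATTATAAT` (linearized with wraparound).
#'
#' @return A list with elements `reads` (a [read_set()]) and `k`.
#' @examples
#' fx <- example_fixture()
#' spectrum(fx$reads, fx$k)
#' @export
example_fixture <- function() {
  list(reads = read_set(c("TATTA", "TAATA")), k = 3L)
}

#' Write / read a scenario as a key = value text file
#'
#' @param sc A [sim_scenario()].
#' @param path File path.
#' @return `write_scenario()`: `path`, invisibly; `read_scenario()`: a
#'   `SimScenario`.
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "SimScenario"))
  rep_str <- paste(vapply(sc$repeat_spec,
                          function(r) paste0(r[1], "x", r[2]), character(1)),
                   collapse = ",")
  writeLines(c(
    sprintf("genome_length = %d", sc$genome_length),
    sprintf("read_length = %d", sc$read_length),
    sprintf("k = %d", sc$k),
    sprintf("seed = %d", sc$seed),
    sprintf("repeats = %s", rep_str),
    sprintf("alphabet = %s", paste(sc$alphabet, collapse = ""))
  ), path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="),
                        character(1)))
  get <- function(key) {
    i <- match(key, keys)
    if (is.na(i)) dbg_stop(sprintf("scenario file misses key '%s'", key),
                           "dbg_parse_error")
    vals[i]
  }
  reps <- get("repeats")
  repeat_spec <- if (nzchar(reps)) {
    lapply(strsplit(reps, ",", fixed = TRUE)[[1]], function(s) {
      p <- as.integer(strsplit(s, "x", fixed = TRUE)[[1]])
      c(p[1], p[2])
    })
  } else list()
  sim_scenario(
    genome_length = as.integer(get("genome_length")),
    read_length = as.integer(get("read_length")),
    k = as.integer(get("k")),
    seed = as.integer(get("seed")),
    repeat_spec = repeat_spec,
    alphabet = strsplit(get("alphabet"), "")[[1]]
  )
}
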