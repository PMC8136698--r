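#' @keywords internal
DNA_ALPHABET <- c("A", "C", "G", "T")

#' Construct a validated read set
#'
#' A `ReadSet` holds a collection of reads (strings over a fixed alphabet,
#' DNA by default) together with the length of its shortest read. Reads are
#' uppercased on input; duplicates are kept (deduplication happens where set
#' semantics apply, e.g. in spectra and overlap graphs).
#'
#' @param reads Character vector of reads; each must be non-empty and contain
#'   only characters from `alphabet` (after uppercasing).
#' @param alphabet Character vector of allowed single characters.
#' @return An object of class `ReadSet` with fields `reads`, `min_length`
#'   and `alphabet`.
#' @examples
#' read_set(c("TATTA", "TAATA"))
#' @export
read_set <- function(reads, alphabet = DNA_ALPHABET) {
  if (length(reads) == 0)
    dbg_stop("read set is empty", "dbg_empty_input_error")
  reads <- toupper(as.character(reads))
  if (any(is.na(reads)) || any(nchar(reads) < 1L))
    dbg_stop("every read must be a non-empty string", "dbg_param_error")
  bad <- grepl(sprintf("[^%s]", paste(alphabet, collapse = "")), reads)
  if (any(bad))
    dbg_stop(sprintf("read %d contains characters outside the alphabet {%s}",
                     which(bad)[1], paste(alphabet, collapse = ",")),
             "dbg_param_error")
  structure(
    list(reads = unname(reads), min_length = min(nchar(reads)),
         alphabet = alphabet),
    class = "ReadSet"
  )
}

as_read_set <- function(x, alphabet = DNA_ALPHABET) {
  if (inherits(x, "ReadSet")) x else read_set(x, alphabet = alphabet)
}

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("ReadSet: %d reads, min length %d, alphabet {%s}\n",
              length(x$reads), x$min_length, paste(x$alphabet, collapse = ",")))
  show <- utils::head(x$reads, 6)
  cat(paste0("  ", show, collapse = "\n"), "\n")
  if (length(x$reads) > 6) cat(sprintf("  ... (%d more)\n", length(x$reads) - 6))
  invisible(x)
}

#' Construct a k-mer spectrum object
#'
#' A `KmerSpectrum` is a set (duplicates collapsed, stored sorted) of distinct
#' strings of one common length `k`. It is the central container: spectra of
#' read sets live here, and so do closures.
#'
#' @param kmers Character vector of k-mers (may be empty).
#' @param k The common length; inferred from `kmers` when `NULL`.
#' @param alphabet Allowed characters.
#' @return An object of class `KmerSpectrum` with fields `k` and `kmers`
#'   (sorted, unique).
#' @examples
#' kmer_spectrum(c("TAT", "ATT", "TTA"))
#' @export
kmer_spectrum <- function(kmers, k = NULL, alphabet = DNA_ALPHABET) {
  kmers <- toupper(as.character(kmers))
  if (is.null(k)) {
    if (length(kmers) == 0)
      dbg_stop("k must be given for an empty spectrum", "dbg_param_error")
    k <- nchar(kmers[1])
  }
  k <- as.integer(k)
  if (is.na(k) || k < 1L)
    dbg_stop("k must be a positive integer", "dbg_param_error")
  if (length(kmers) > 0) {
    if (any(nchar(kmers) != k))
      dbg_stop(sprintf("all k-mers must have length %d", k), "dbg_param_error")
    bad <- grepl(sprintf("[^%s]", paste(alphabet, collapse = "")), kmers)
    if (any(bad))
      dbg_stop("k-mer contains characters outside the alphabet",
               "dbg_param_error")
  }
  structure(list(k = k, kmers = sort(unique(unname(kmers)))),
            class = "KmerSpectrum")
}

as_kmer_spectrum <- function(x, k = NULL) {
  if (inherits(x, "KmerSpectrum")) x else kmer_spectrum(x, k = k)
}

#' @export
print.KmerSpectrum <- function(x, ...) {
  cat(sprintf("KmerSpectrum: %d distinct %d-mers\n", length(x$kmers), x$k))
  cat("  {", paste(utils::head(x$kmers, 12), collapse = ", "),
      if (length(x$kmers) > 12) ", ..." else "", "}\n", sep = "")
  invisible(x)
}

#' Prefix and suffix of a string
#'
#' `prefix(t, i)` returns the first `i` characters of `t`; `suffix(t, i)`
#' the last `i`. Both error when `i` exceeds the string length, and both are
#' vectorised over `t`.
#'
#' @param t Character vector.
#' @param i Single non-negative integer, at most the length of each `t`.
#' @return Character vector of the same length as `t`.
#' @examples
#' prefix("TATT", 3) # "TAT"
#' suffix("TATT", 3) # "ATT"
#' @export
prefix <- function(t, i) {
  i <- check_affix_args(t, i)
  substr(t, 1L, i)
}

#' @rdname prefix
#' @export
suffix <- function(t, i) {
  i <- check_affix_args(t, i)
  n <- nchar(t)
  substr(t, n - i + 1L, n)
}

check_affix_args <- function(t, i) {
  if (length(i) != 1L || is.na(i) || i < 0)
    dbg_stop("i must be a single non-negative integer", "dbg_param_error")
  i <- as.integer(i)
  if (any(i > nchar(t)))
    dbg_stop(sprintf("i = %d exceeds string length %d", i, min(nchar(t))),
             "dbg_length_error")
  i
}

#' k-spectrum of a read set
#'
#' Returns the set of all distinct length-`k` substrings over all reads
#' (`sp^k` in the assembly literature). Duplicates are collapsed;
#' multiplicities are deliberately not tracked.
#'
#' @param reads A [read_set()] or character vector of reads.
#' @param k Window length; must satisfy `1 <= k <= min(nchar(reads))`.
#' @return A [kmer_spectrum()] of order `k`.
#' @examples
#' spectrum(c("TATTA", "TAATA"), 3)
#' @export
spectrum <- function(reads, k) {
  R <- as_read_set(reads)
  k <- as.integer(k)
  if (is.na(k) || k < 1L)
    dbg_stop("k must be a positive integer", "dbg_param_error")
  if (k > R$min_length)
    dbg_stop(sprintf("k = %d exceeds the minimum read length %d",
                     k, R$min_length), "dbg_param_error")
  kmers <- unlist(lapply(R$reads, function(r) {
    n <- nchar(r) - k + 1L
    substring(r, seq_len(n), seq_len(n) + k - 1L)
  }), use.names = FALSE)
  kmer_spectrum(unique(kmers), k = k, alphabet = R$alphabet)
}

#' Closure of a k-mer set
#'
#' The closure of a set `S` of k-mers is the set of all (k+1)-mers `y` whose
#' length-k prefix and length-k suffix both belong to `S` — every (k+1)-mer
#' constructible from `S`, whether or not it occurred in any read. It is the
#' edge set of the order-(k+1) de Bruijn graph in which the Hamiltonian
#' formulation of assembly lives.
#'
#' @param S A [kmer_spectrum()] (or character vector of equal-length k-mers).
#' @return A [kmer_spectrum()] of order `k + 1` (possibly empty).
#' @examples
#' closure(spectrum(c("TATTA", "TAATA"), 3)) # ten 4-mers
#' @export
closure <- function(S) {
  S <- as_kmer_spectrum(S)
  if (length(S$kmers) == 0)
    dbg_stop("closure requires a nonempty spectrum", "dbg_param_error")
  k <- S$k
  km <- S$kmers
  # y = x . last(z) for every ordered pair with suffix_{k-1}(x) = prefix_{k-1}(z)
  pre <- substr(km, 1L, k - 1L)
  suf <- substr(km, 2L, k)
  by_pre <- split(seq_along(km), pre)
  hits <- by_pre[suf]               # per x, indices z chaining onto it
  lens <- lengths(hits)
  z <- unlist(hits, use.names = FALSE)
  y <- paste0(rep(km, lens), substr(km[z], k, k))
  kmer_spectrum(unique(y), k = k + 1L)
}

# ---------------------------------------------------------------------------
# I/O

#' Read sequences from FASTA, FASTQ or a plain k-mer list
#'
#' FASTA/FASTQ parsing is delegated to Biostrings and is transparently
#' gzip-aware. A k-mer list is plain text with one sequence per line;
#' `#` starts a comment. Characters outside the alphabet are handled per
#' `policy`: `"split"` cuts the read at each offending character and keeps
#' fragments of length at least `min_fragment`; `"strict"` raises an error.
#'
#' @param path File path.
#' @param format One of `"auto"`, `"fasta"`, `"fastq"`, `"kmer-list"`.
#'   `"auto"` sniffs the first non-blank character (`>` FASTA, `@` FASTQ,
#'   otherwise k-mer list).
#' @param alphabet Allowed characters.
#' @param policy `"split"` (default) or `"strict"`.
#' @param min_fragment Minimum fragment length kept under the split policy;
#'   pass your intended `k`.
#' @return A [read_set()].
#' @export
read_sequences <- function(path,
                           format = c("auto", "fasta", "fastq", "kmer-list"),
                           alphabet = DNA_ALPHABET,
                           policy = c("split", "strict"),
                           min_fragment = 1L) {
  format <- match.arg(format)
  policy <- match.arg(policy)
  if (!file.exists(path))
    dbg_stop(sprintf("file not found: %s", path), "dbg_param_error")
  if (format == "auto") format <- sniff_format(path)
  seqs <- switch(format,
    "fasta" = read_xstring(path, "fasta"),
    "fastq" = read_xstring(path, "fastq"),
    "kmer-list" = read_kmer_list_file(path)
  )
  if (length(seqs) == 0)
    dbg_stop(sprintf("no sequences in %s", path), "dbg_empty_input_error")
  clean_reads(seqs, alphabet = alphabet, policy = policy,
              min_fragment = min_fragment)
}

sniff_format <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0)
      dbg_stop(sprintf("empty input file: %s", path), "dbg_empty_input_error")
    line <- trimws(line)
    if (nzchar(line)) break
  }
  first <- substr(line, 1L, 1L)
  if (first == ">") "fasta" else if (first == "@") "fastq" else "kmer-list"
}

read_xstring <- function(path, format) {
  res <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e)
      dbg_stop(sprintf("failed to parse %s as %s: %s",
                       path, format, conditionMessage(e)), "dbg_parse_error")
  )
  as.character(res)
}

read_kmer_list_file <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

clean_reads <- function(seqs, alphabet, policy, min_fragment) {
  seqs <- toupper(seqs)
  pat <- sprintf("[^%s]+", paste(alphabet, collapse = ""))
  has_bad <- grepl(pat, seqs)
  if (policy == "strict" && any(has_bad))
    dbg_stop(sprintf("record %d contains characters outside the alphabet",
                     which(has_bad)[1]), "dbg_parse_error")
  frags <- unlist(strsplit(seqs, pat), use.names = FALSE)
  frags <- frags[nchar(frags) >= max(1L, as.integer(min_fragment))]
  if (length(frags) == 0)
    dbg_stop("no usable sequence fragments after alphabet filtering",
             "dbg_empty_input_error")
  read_set(frags, alphabet = alphabet)
}

#' Write sequences as FASTA or as a plain k-mer list
#'
#' @param seqs Named or unnamed character vector, [read_set()] or
#'   [kmer_spectrum()]. Unnamed sequences get `seq1`, `seq2`, ... headers.
#' @param path Output path.
#' @param width Line-wrap width for FASTA.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  seqs <- flatten_seqs(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("seq", seq_along(seqs))
  out <- unlist(lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    c(paste0(">", names(seqs)[i]),
      substring(s, starts, pmin(starts + width - 1L, n)))
  }), use.names = FALSE)
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_kmer_list <- function(seqs, path) {
  writeLines(flatten_seqs(seqs), path)
  invisible(path)
}

flatten_seqs <- function(x) {
  if (inherits(x, "ReadSet")) x$reads
  else if (inherits(x, "KmerSpectrum")) x$kmers
  else as.character(x)
}
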