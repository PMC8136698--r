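test_that("prefix and suffix return the stated affixes and reject overlong requests", {
  expect_identical(prefix("TATT", 3), "TAT")
  expect_identical(suffix("TATT", 3), "ATT")
  expect_identical(prefix("A", 0), "")
  expect_identical(suffix("A", 0), "")
  expect_identical(prefix("ACGT", 4), "ACGT")
  expect_identical(suffix("ACGT", 4), "ACGT")
  expect_error(prefix("ACG", 4), class = "dbg_length_error")
  expect_error(suffix("ACG", 4), class = "dbg_length_error")
  expect_error(prefix("ACG", -1), class = "dbg_param_error")
})

test_that("prefix(t, i) + suffix(t, |t| - i) reassembles t", {
  set.seed(11)
  for (rep in 1:25) {
    t <- random_genome(sample(1:12, 1))
    for (i in 0:nchar(t)) {
      expect_identical(paste0(prefix(t, i), suffix(t, nchar(t) - i)), t)
    }
  }
})

test_that("spectrum matches the worked example and an independent windowing oracle", {
  S <- spectrum(c("TATTA", "TAATA"), 3)
  expect_setequal(S$kmers, c("TAT", "ATT", "TTA", "TAA", "AAT", "ATA"))
  expect_identical(spectrum("ACGT", 4)$kmers, "ACGT")
  set.seed(21)
  for (rep in 1:20) {
    reads <- vapply(seq_len(sample(1:4, 1)),
                    function(i) random_genome(sample(5:20, 1)), character(1))
    k <- sample(2:5, 1)
    expect_identical(spectrum(reads, k)$kmers, oracle_spectrum(reads, k))
  }
  expect_error(spectrum(c("TATTA"), 6), class = "dbg_param_error")
  expect_error(spectrum(c("TATTA"), 0), class = "dbg_param_error")
})

test_that("a circular genome of length n has at most n k-mers, exactly n when all distinct", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    k <- sample(2:5, 1)
    g <- random_genome(n)
    S <- spectrum(circ_lin(g, k), k)
    expect_lte(length(S$kmers), n)
    windows <- substring(paste0(g, g), 1:n, 1:n + k - 1L)
    if (!anyDuplicated(windows)) expect_identical(length(S$kmers), n)
  }
})

test_that("closure matches brute force over all candidate (k+1)-mers", {
  S <- spectrum(c("TATTA", "TAATA"), 3)
  cl <- closure(S)
  expect_identical(cl$k, 4L)
  expect_identical(cl$kmers, oracle_closure(S$kmers, 3L))
  expect_length(cl$kmers, 10)
  expect_identical(closure(kmer_spectrum("AA"))$kmers, "AAA")
  expect_length(closure(kmer_spectrum("AC"))$kmers, 0)
  set.seed(41)
  for (rep in 1:10) {
    S <- spectrum(random_genome(sample(6:15, 1)), sample(2:3, 1))
    expect_identical(closure(S)$kmers, oracle_closure(S$kmers, S$k))
  }
})

test_that("closure is monotone in its input set", {
  set.seed(51)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    big <- spectrum(random_genome(sample(10:25, 1)), k)
    keep <- sort(sample(seq_along(big$kmers),
                        max(1, length(big$kmers) - sample(1:3, 1))))
    small <- kmer_spectrum(big$kmers[keep], k)
    expect_true(all(closure(small)$kmers %in% closure(big)$kmers))
  }
})

test_that("sp^k(closure(S)) recovers S exactly for spectra of reads longer than k", {
  set.seed(61)
  for (rep in 1:200) {
    k <- sample(2:6, 1)
    reads <- vapply(seq_len(sample(1:4, 1)),
                    function(i) random_genome(k + sample(1:8, 1)), character(1))
    S <- spectrum(reads, k)
    cl <- closure(S)
    back <- if (length(cl$kmers)) spectrum(cl$kmers, k)$kmers else character(0)
    expect_identical(back, S$kmers)
    # the containment direction holds unconditionally
    expect_true(all(back %in% S$kmers))
  }
})

test_that("FASTA, FASTQ, gzip and k-mer-list inputs give the expected read sets", {
  fa <- test_path_tmp("ex.fasta")
  writeLines(c(">r1", "TATTA", ">r2", "TAATA"), fa)
  R <- read_sequences(fa)
  expect_setequal(R$reads, c("TATTA", "TAATA"))
  expect_identical(R$min_length, 5L)

  fq <- test_path_tmp("ex.fastq")
  writeLines(c("@r1", "TATTA", "+", "IIIII", "@r2", "TAATA", "+", "IIIII"), fq)
  expect_setequal(read_sequences(fq)$reads, R$reads)

  fagz <- test_path_tmp("ex.fasta.gz")
  con <- gzfile(fagz, "wt")
  writeLines(c(">r1", "tatta", ">r2", "taata"), con)   # lowercase on purpose
  close(con)
  expect_setequal(read_sequences(fagz)$reads, R$reads)

  kl <- test_path_tmp("ex.kmers")
  write_kmer_list(spectrum(R, 3), kl)
  R2 <- read_sequences(kl, format = "kmer-list")
  expect_identical(spectrum(R2, 3)$kmers, spectrum(R, 3)$kmers)

  empty <- test_path_tmp("empty.fasta")
  file.create(empty)
  expect_error(read_sequences(empty), class = "dbg_empty_input_error")
})

test_that("non-alphabet characters split reads by default and error in strict mode", {
  fa <- test_path_tmp("n.fasta")
  writeLines(c(">r1", "TATNNACGTA", ">r2", "GGGG"), fa)
  R <- read_sequences(fa, min_fragment = 3)
  expect_setequal(R$reads, c("TAT", "ACGTA", "GGGG"))
  expect_error(read_sequences(fa, policy = "strict"), class = "dbg_parse_error")
})

test_that("FASTA writer round-trips sequences", {
  p <- test_path_tmp("rt.fasta")
  seqs <- c(alpha = "ACGTACGTACGT", beta = "TTTT")
  write_fasta(seqs, p, width = 5)
  back <- read_sequences(p, format = "fasta")
  expect_setequal(back$reads, unname(seqs))
})
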