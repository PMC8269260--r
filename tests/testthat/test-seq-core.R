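test_that("read_fasta parses records, uppercases, preserves order, rejects duplicates", {
  p <- file.path(tempdir(), "two.fasta")
  writeLines(c(">seqB first record", "acgta", "cgt", ">seqA second", "TTTT"), p)
  x <- read_fasta(p)
  expect_length(x, 2L)
  expect_identical(names(x), c("seqB", "seqA"))
  expect_identical(as.character(x[["seqB"]]), "ACGTACGT")

  # CRLF tolerated
  pc <- file.path(tempdir(), "crlf.fasta")
  writeLines(c(">s1\r", "ACGT\r"), pc, sep = "\n")
  expect_identical(as.character(read_fasta(pc)[["s1"]]), "ACGT")

  pd <- file.path(tempdir(), "dup.fasta")
  writeLines(c(">x", "ACGT", ">x", "GGGG"), pd)
  expect_error(read_fasta(pd), "x")

  pe <- file.path(tempdir(), "empty.fasta")
  writeLines(character(0), pe)
  expect_error(read_fasta(pe), "empty")
})

test_that("gc_content matches direct letter counting and handles N", {
  expect_equal(gc_content("ATGC"), 50.0)
  expect_equal(gc_content("GGGG"), 100.0)
  expect_equal(gc_content("GCNN"), 100.0)  # N excluded from both sides
  expect_error(gc_content("NNNN"), "undefined")

  s <- rand_dna(10000, seed = 11, gc = 0.409)
  # independent oracle: direct letter counting via Biostrings
  f <- Biostrings::letterFrequency(Biostrings::DNAString(s), c("G", "C", "A", "T"))
  oracle <- 100 * sum(f[c("G", "C")]) / sum(f)
  expect_equal(gc_content(s), oracle)
  # within ~4 sd of binomial sampling noise around the 40.9% target
  expect_lt(abs(gc_content(s) - 40.9), 400 * sqrt(0.409 * 0.591 / 10000))
  # invariant under reverse complement
  expect_equal(gc_content(revcomp(s)), gc_content(s))
})

test_that("pairwise identity recovers designed substitution divergence", {
  a <- rand_dna(100, seed = 21)
  self <- pairwise_identity(a, a)
  expect_equal(self$percent_identity, 100.0)
  expect_equal(self$aligned_columns, 100L)

  b <- substitute_at(a, c(10, 50, 90))
  r <- pairwise_identity(a, b)
  expect_equal(r$percent_identity, 97.0)
  expect_equal(r$matched_columns, 97L)

  # symmetric up to labels
  r2 <- pairwise_identity(b, a)
  expect_equal(r2$percent_identity, r$percent_identity)

  expect_error(pairwise_identity("ACRT", a), "non-IUPAC")

  # strand canonicalization recovers identity against the reverse complement
  rc <- pairwise_identity(a, revcomp(a), canonicalize = TRUE)
  expect_equal(rc$percent_identity, 100.0)
})

test_that("pairwise_identity(a, a) is 100 over random sequences", {
  for (seed in 1:5) {
    a <- rand_dna(60 + 10 * seed, seed = seed)
    expect_equal(pairwise_identity(a, a)$percent_identity, 100.0)
  }
})

test_that("MinHash sketches are deterministic, strand-canonical, bounded", {
  s <- rand_dna(50000, seed = 31)
  k1 <- kmer_sketch(s, k = 21, s = 1000)
  k2 <- kmer_sketch(s, k = 21, s = 1000)
  expect_identical(k1$hashes, k2$hashes)
  expect_length(k1$hashes, 1000L)
  expect_false(is.unsorted(k1$hashes))

  krc <- kmer_sketch(revcomp(s), k = 21, s = 1000)
  expect_identical(k1$hashes, krc$hashes)

  expect_error(kmer_sketch("ACGT", k = 21), "shorter than k")
})

test_that("sketch distance tracks designed divergence and the exact Jaccard oracle", {
  expect_equal(sketch_distance(kmer_sketch("ACGTACGTACGTACGTACGTACGTA", k = 5, s = 10),
                               kmer_sketch("ACGTACGTACGTACGTACGTACGTA", k = 5, s = 10)),
               0)
  a <- rand_dna(20000, seed = 41)
  b <- rand_dna(20000, seed = 42)
  expect_equal(sketch_distance(kmer_sketch(a, 21, 500), kmer_sketch(b, 21, 500)), 1)
  expect_error(sketch_distance(kmer_sketch(a, 21, 100), kmer_sketch(a, 15, 100)),
               "different k")

  mut <- mutate_seq(a, 0.03, seed = 43)$seq
  d <- sketch_distance(kmer_sketch(a, 21, 1000), kmer_sketch(mut, 21, 1000))
  expect_lt(abs(d - 0.03), 0.01)
  # sketch estimate close to the distance computed from the full k-mer sets
  expect_lt(abs(d - exact_kmer_distance(a, mut, 21)), 0.01)
})

test_that("expected sketch distance is monotone in substitution rate", {
  a <- rand_dna(20000, seed = 51)
  ska <- kmer_sketch(a, 21, 500)
  mean_d <- vapply(c(0.01, 0.04, 0.08), function(p) {
    mean(vapply(1:3, function(s)
      sketch_distance(ska, kmer_sketch(mutate_seq(a, p, seed = 100 * s + p * 1000)$seq,
                                       21, 500)),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_d) > 0))
})

test_that("sketch JSON serialization round-trips", {
  sk <- kmer_sketch(rand_dna(5000, seed = 61), k = 17, s = 64, source_id = "g1")
  p <- file.path(tempdir(), "sketch.json")
  sketch_to_json(sk, p)
  back <- sketch_from_json(p)
  expect_identical(back$hashes, sk$hashes)
  expect_identical(back$k, sk$k)
  expect_identical(back$source_id, "g1")
})
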