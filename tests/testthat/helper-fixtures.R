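# Small deterministic fixtures built in code.

rand_dna <- function(n, seed, gc = 0.5) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Substitute exactly `k` fixed positions to a different letter.
substitute_at <- function(seq, positions, seed = 1) {
  set.seed(seed)
  chars <- strsplit(seq, "")[[1]]
  for (p in positions)
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

write_tmp_fasta <- function(seqs, dir = tempdir(), name = "tmp.fasta") {
  path <- file.path(dir, name)
  write_fasta(seqs, path)
  path
}

# Toy abundance table: taxa x samples percent matrix with groups.
toy_table <- function(values, groups = NULL, level = "OTU") {
  abundance_table(values, groups = groups, level = level)
}

protologue_bundles <- function() {
  read_metric_bundles(system.file("extdata", "chibac_protologues.tsv",
                                  package = "polyphasic"))
}

collection_fixture <- function() {
  read_collection_table(system.file("extdata",
                                    "chibac_collection_synthetic.tsv",
                                    package = "polyphasic"))
}

# Exact Mash-style distance from full (unsketched) canonical k-mer sets;
# independent oracle for sketch_distance.
exact_kmer_distance <- function(a, b, k) {
  ha <- polyphasic:::.cpp_kmer_hashes(a, as.integer(k), 0L)
  hb <- polyphasic:::.cpp_kmer_hashes(b, as.integer(k), 0L)
  j <- length(intersect(ha, hb)) / length(union(ha, hb))
  if (j == 0) 1 else min(1, -(1 / k) * log(2 * j / (1 + j)))
}
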