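test_that("genome generation is seeded, composition-true, and validated", {
  g1 <- gen_genome(5000, 0.5, seed = 401)
  g2 <- gen_genome(5000, 0.5, seed = 401)
  expect_identical(as.character(g1$contigs), as.character(g2$contigs))

  big <- gen_genome(100000, 0.5, seed = 402)
  ci_half <- 100 * qnorm(0.995) * sqrt(0.25 / 100000)
  expect_lt(abs(big$gc - 50), ci_half * 1.5)

  expect_error(gen_genome(500, 0.5, seed = 1), ">= 1000")
  expect_error(gen_genome(2000, 0, seed = 1), "strictly between")
  expect_error(gen_genome(2000, 1, seed = 1), "strictly between")
})

test_that("substitution mutation records its exact ground truth", {
  s <- rand_dna(2000, seed = 411)
  m0 <- mutate_seq(s, 0, seed = 412)
  expect_identical(unname(m0$seq), s)
  expect_equal(m0$truth$realized_count, 0L)

  m <- mutate_seq(s, 0.05, seed = 413)
  expect_equal(m$truth$realized_count, hamming(s, unname(m$seq)))

  big <- rand_dna(100000, seed = 414)
  mb <- mutate_seq(big, 0.05, seed = 415)
  ci_half <- qnorm(0.995) * sqrt(0.05 * 0.95 / 100000)
  expect_lt(abs(mb$truth$realized_rate - 0.05), ci_half * 1.5)

  expect_error(mutate_seq(s, 1, seed = 1), "substitution_rate")
})

test_that("proteome pairs carry their designed POCP expectation", {
  pp <- gen_proteome_pair(60, 40, seed = 421)
  expect_equal(pp$truth$expected_pocp, 60.0)
  expect_equal(gen_proteome_pair(0, 50, seed = 422)$truth$expected_pocp, 0.0)
  expect_equal(gen_proteome_pair(50, 0, seed = 423)$truth$expected_pocp, 100.0)
  expect_error(gen_proteome_pair(0, 0), "empty")
  # shared proteins really are identical; uniques differ between sides
  expect_identical(unname(as.character(pp$a)[1:60]),
                   unname(as.character(pp$b)[1:60]))
  expect_false(any(as.character(pp$a)[61:100] %in% as.character(pp$b)))
})

test_that("community tables respect spike designs and normalize per sample", {
  spikes <- list(
    spike_spec("always", presence_prob = 1, meanlog = 2),
    spike_spec("never", presence_prob = 0),
    spike_spec("diverged", presence_prob = 1, identity = 96))
  gm <- gen_member_table(c(grp = 12), spikes, n_background_taxa = 10,
                         seed = 431)
  expect_equal(unname(gm$truth$realized_prevalence$grp["synOTU_always"]), 100)
  expect_equal(unname(gm$truth$realized_prevalence$grp["synOTU_never"]), 0)
  expect_equal(unname(colSums(gm$table$values)), rep(100, 12),
               tolerance = 1e-9)

  # regeneration with the same seed is identical
  gm2 <- gen_member_table(c(grp = 12), spikes, n_background_taxa = 10,
                          seed = 431)
  expect_identical(gm$table$values, gm2$table$values)
  expect_identical(gm$rep_seqs, gm2$rep_seqs)

  # the 96%-identity representative fails the default 97% OTU rule,
  # but matches when the threshold is relaxed below its design
  hits <- match_members(gm$member_refs, gm$rep_seqs["synOTU_diverged"],
                        level = "otu")
  expect_false("synOTU_diverged" %in% hits$taxon_id)
  relaxed <- amplicon_params(otu_identity = 94)
  hits2 <- match_members(gm$member_refs, gm$rep_seqs["synOTU_diverged"],
                         level = "otu", params = relaxed)
  expect_true("synOTU_diverged" %in% hits2$taxon_id)
})

test_that("synthetic reference databases drive the expected end-to-end verdicts", {
  db <- gen_reference_db(2, species_per_genus = 2, seed = 441,
                         genome_len = 20000, with_proteomes = TRUE)
  type1 <- db$refs[[1]]  # type species of Genus01

  # a light mutant of a known species is recognized as that species
  known_iso <- list(
    id = "knowniso",
    sixteenS = unname(mutate_seq(type1$sixteenS, 0.005, seed = 442)$seq),
    genome = mutate_seq(type1$genome, 0.005, seed = 443)$seq,
    proteome = type1$proteome)
  rel <- rank_relatives(known_iso$sixteenS, db$refs, isolate_id = "knowniso")
  bundles <- lapply(rel$entries, function(r) assemble_metrics(known_iso, r))
  v <- classify(bundles)
  expect_identical(v$rank, "known_species")
  expect_identical(v$assigned_genus, "Genus01")

  # strong genome divergence within the genus: novel species
  novel_iso <- list(
    id = "noveliso",
    sixteenS = unname(mutate_seq(type1$sixteenS, 0.03, seed = 444)$seq),
    genome = mutate_seq(type1$genome, 0.09, seed = 445)$seq,
    proteome = type1$proteome)
  bundles2 <- lapply(rank_relatives(novel_iso$sixteenS, db$refs)$entries,
                     function(r) assemble_metrics(novel_iso, r))
  v2 <- classify(bundles2)
  expect_identical(v2$rank, "novel_species")
  expect_identical(v2$assigned_genus, "Genus01")

  # divergent 16S and an unrelated proteome: novel genus
  genus_iso <- list(
    id = "genusiso",
    sixteenS = unname(mutate_seq(type1$sixteenS, 0.07, seed = 446)$seq),
    genome = gen_genome(20000, 0.5, seed = 447),
    proteome = gen_proteome_pair(0, 40, seed = 448)$a)
  bundles3 <- lapply(rank_relatives(genus_iso$sixteenS, db$refs)$entries,
                     function(r) assemble_metrics(genus_iso, r))
  v3 <- classify(bundles3)
  expect_identical(v3$rank, "novel_genus")
})

test_that("reference databases round-trip through their directory format", {
  db <- gen_reference_db(2, species_per_genus = 2, seed = 451,
                         genome_len = 20000, with_proteomes = TRUE)
  dir <- file.path(tempdir(), "refdb")
  write_reference_db(db$refs, dir)
  back <- read_reference_db(dir)
  expect_length(back, 4L)
  expect_identical(vapply(back, `[[`, "", "taxon_name"),
                   vapply(db$refs, `[[`, "", "taxon_name"))
  expect_identical(back[[1]]$sixteenS, db$refs[[1]]$sixteenS)
  expect_identical(as.character(back[[1]]$genome$contigs),
                   as.character(db$refs[[1]]$genome$contigs))
  expect_true(back[[1]]$is_type_species)
  expect_false(back[[2]]$is_type_species)
})
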