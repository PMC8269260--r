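make_refs <- function() {
  base <- rand_dna(800, seed = 201)
  g <- genome_record("refg", setNames(rand_dna(5000, seed = 202), "c1"))
  list(
    reference_entry("Alpha one", "Alpha", substitute_at(base, 1:8, seed = 1),
                    genome = g, is_type_species = TRUE),
    reference_entry("Beta two", "Beta", substitute_at(base, 1:40, seed = 2),
                    genome = g),
    reference_entry("Gamma three", "Gamma", substitute_at(base, 1:80, seed = 3),
                    genome = g),
    # highest identity of all but no genome: must be excluded
    reference_entry("Nogenome best", "Nogenome", base, genome = NULL),
    # invalid name: excluded
    reference_entry("Invalid name", "Invalid", base, genome = g,
                    is_valid_name = FALSE))
}

test_that("relative ranking filters on valid name + genome and sorts by identity", {
  refs <- make_refs()
  base <- rand_dna(800, seed = 201)
  rel <- rank_relatives(base, refs, n = 50)
  expect_equal(nrow(rel$ranked), 3L)
  expect_identical(rel$ranked$taxon_name,
                   c("Alpha one", "Beta two", "Gamma three"))
  expect_false("Nogenome best" %in% rel$ranked$taxon_name)
  expect_true(all(diff(rel$ranked$percent_identity) <= 0))

  # cap applies after filtering
  rel2 <- rank_relatives(base, refs, n = 2)
  expect_equal(nrow(rel2$ranked), 2L)

  # deterministic lexicographic tie-break at identical identity
  tie <- list(
    reference_entry("Zeta sp", "Zeta", base, genome = refs[[1]]$genome),
    reference_entry("Eta sp", "Eta", base, genome = refs[[1]]$genome))
  rt <- rank_relatives(base, tie)
  expect_identical(rt$ranked$taxon_name, c("Eta sp", "Zeta sp"))

  expect_error(rank_relatives(base, refs[4:5]), "no eligible")
})

test_that("assemble_metrics fills what the available data allow", {
  refs <- make_refs()
  iso16 <- substitute_at(rand_dna(800, seed = 201), 1:4, seed = 9)
  b <- assemble_metrics(list(id = "iso", sixteenS = iso16), refs[[1]])
  expect_false(is.na(b$identity16S))
  expect_true(is.na(b$ani) && is.na(b$pocp) && is.na(b$gc_diff))

  iso <- list(id = "iso", sixteenS = iso16,
              genome = genome_record("isog", setNames(rand_dna(5000, seed = 202), "c1")))
  b2 <- assemble_metrics(iso, refs[[1]])
  expect_false(is.na(b2$ani))
  expect_false(is.na(b2$gc_diff))

  b3 <- assemble_metrics(iso, refs[[1]], dddh = 84.6)
  expect_equal(b3$dddh, 84.6)
  expect_true(b3$pocp_is_to_type_species)
})

test_that("classify reproduces the published protologue decision patterns", {
  # novel genus despite a high POCP to a non-type species
  gallibacter <- list(
    metric_bundle("iso", "Eubacterium brachy", 93.3, genus = "Eubacterium",
                  pocp = 54.8),
    metric_bundle("iso", "Eubacterium limosum", NA, genus = "Eubacterium",
                  pocp = 22.5, pocp_is_to_type_species = TRUE))
  v <- classify(gallibacter)
  expect_identical(v$rank, "novel_genus")

  # novel species within a genus anchored by its type species
  gemmiger <- list(
    metric_bundle("iso", "Gemmiger formicilis", 96.2, genus = "Gemmiger",
                  pocp = 61.2, pocp_is_to_type_species = TRUE, ani = 81.7,
                  dddh = 25.3))
  v2 <- classify(gemmiger)
  expect_identical(v2$rank, "novel_species")
  expect_identical(v2$assigned_genus, "Gemmiger")

  # everything above threshold: known species
  known <- metric_bundle("iso", "Alpha one", 99.5, genus = "Alpha", ani = 97.0,
                         pocp = 80, pocp_is_to_type_species = TRUE)
  expect_identical(classify(list(known))$rank, "known_species")

  # type-species POCP below the cutoff founds a sister genus
  gallalistipes <- list(
    metric_bundle("iso", "Alistipes indistinctus", 91.6, genus = "Alistipes",
                  pocp = 56),
    metric_bundle("iso", "Alistipes onderdonkii", 92.5, genus = "Alistipes"),
    metric_bundle("iso", "Alistipes putredinis", NA, genus = "Alistipes",
                  pocp = 48.1, pocp_is_to_type_species = TRUE))
  expect_identical(classify(gallalistipes)$rank, "novel_genus")

  expect_error(classify(list()), "length")
})

test_that("ANI near the species boundary escalates to dDDH, ambiguous when absent", {
  in_band_no_dddh <- metric_bundle("iso", "Alpha one", 99.0, genus = "Alpha",
                                   ani = 94.0, pocp = 80,
                                   pocp_is_to_type_species = TRUE)
  v <- classify(list(in_band_no_dddh))
  expect_identical(v$rank, "ambiguous")
  expect_true(any(grepl("dDDH", v$notes)))

  with_dddh <- metric_bundle("iso", "Alpha one", 99.0, genus = "Alpha",
                             ani = 94.0, dddh = 55, pocp = 80,
                             pocp_is_to_type_species = TRUE)
  expect_identical(classify(list(with_dddh))$rank, "novel_species")

  with_high_dddh <- metric_bundle("iso", "Alpha one", 99.0, genus = "Alpha",
                                  ani = 94.0, dddh = 84.6, pocp = 80,
                                  pocp_is_to_type_species = TRUE)
  expect_identical(classify(list(with_high_dddh))$rank, "known_species")

  # 16S says novel but ANI says same species: genome evidence escalates
  conflict <- metric_bundle("iso", "Alpha one", 97.5, genus = "Alpha",
                            ani = 98.0, pocp = 80,
                            pocp_is_to_type_species = TRUE)
  expect_identical(classify(list(conflict))$rank, "ambiguous")
})

test_that("lowering 16S identity never converts a novel call into a known species", {
  grid <- seq(99.5, 90, by = -0.5)
  for (ani in list(NA, 85, 99)) {
    ranks <- vapply(grid, function(id) {
      classify(list(metric_bundle("iso", "Alpha one", id, genus = "Alpha",
                                  ani = ani, pocp = 80,
                                  pocp_is_to_type_species = TRUE)))$rank
    }, character(1))
    novelty <- ranks != "known_species"
    expect_true(all(diff(novelty) >= 0))  # once not-known, stays not-known
  }
})

test_that("verdicts are deterministic with complete, non-duplicated evidence", {
  bundles <- protologue_bundles()[["Gemmiger gallinarum"]]
  v1 <- classify(bundles)
  v2 <- classify(rev(bundles))
  expect_identical(v1$rank, v2$rank)
  expect_identical(v1$evidence, v2$evidence)
  expect_identical(anyDuplicated(v1$evidence$criterion), 0L)
  expect_true(nrow(v1$evidence) >= 2)
})

test_that("protologue scaffolds serialize and round-trip", {
  bundles <- protologue_bundles()[["Gallibacter intestinalis"]]
  v <- classify(bundles)
  pr <- protologue_scaffold(v, bundles, gc = 40.9,
                            source_text = "colon content of a free-range layer chicken",
                            name_parts = c(genus = "Gallibacter",
                                           species = "intestinalis"))
  expect_equal(pr$gc, 40.9)
  expect_equal(nrow(pr$metric_table), length(bundles))
  p <- file.path(tempdir(), "protologue.json")
  protologue_to_json(pr, p)
  back <- protologue_from_json(p)
  expect_equal(back$verdict$rank, pr$verdict$rank)
  expect_equal(back$metric_table, pr$metric_table)
  expect_equal(back$gc, pr$gc)
  expect_equal(nrow(back$verdict$evidence), nrow(pr$verdict$evidence))

  known <- classify(list(metric_bundle("iso", "Alpha one", 99.5,
                                       genus = "Alpha", ani = 99)))
  expect_error(protologue_scaffold(known, bundles, gc = 50), "novel")
})

test_that("MAG matching reports only sketches below the distance cutoff", {
  g <- gen_genome(30000, 0.5, seed = 211)
  near <- mutate_seq(g, 0.02, seed = 212)$seq
  far <- mutate_seq(g, 0.10, seed = 213)$seq
  sk <- list(kmer_sketch(near, 21, 500, source_id = "MAG_near"),
             kmer_sketch(far, 21, 500, source_id = "MAG_far"),
             kmer_sketch(g, 21, 500, source_id = "MAG_self"))
  res <- mag_match(g, sk)
  expect_identical(res$mag_id[1], "MAG_self")
  expect_equal(res$distance[1], 0)
  expect_true("MAG_near" %in% res$mag_id)
  expect_false("MAG_far" %in% res$mag_id)
  # the exclusion agrees with the exact Jaccard oracle
  expect_gt(exact_kmer_distance(as.character(g$contigs[[1]]),
                                as.character(far$contigs[[1]]), 21), 0.05)
  expect_identical(nrow(mag_match(g, list())), 0L)
})
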