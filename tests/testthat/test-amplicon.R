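mk_table <- function() {
  v <- rbind(
    kept_exact = c(0.25, 0, 0),     # exactly at the inclusion filter
    dropped    = c(0.10, 0.08, 0),
    abundant   = c(40, 50, 60),
    rare_high  = c(0, 5, 0))
  colnames(v) <- c("s1", "s2", "s3")
  abundance_table(v, groups = c(s1 = "A", s2 = "A", s3 = "B"))
}

test_that("abundance filter keeps >= 0.25% taxa and is idempotent", {
  tab <- mk_table()
  f1 <- filter_low_abundance(tab)
  expect_true("kept_exact" %in% rownames(f1$values))
  expect_false("dropped" %in% rownames(f1$values))
  f2 <- filter_low_abundance(f1)
  expect_identical(f2$values, f1$values)
})

test_that("abundance tables validate inputs and round-trip through TSV", {
  v <- matrix(60, 1, 1, dimnames = list("t1", "s1"))
  expect_error(abundance_table(matrix(c(60, 50), 2, 1,
                                      dimnames = list(c("a", "b"), "s1"))),
               "more than 100")
  expect_error(abundance_table(-v), "negative")
  tab <- mk_table()
  p <- file.path(tempdir(), "tab.tsv")
  write_abundance_table(tab, p)
  back <- read_abundance_table(p)
  expect_equal(back$values, tab$values)
})

test_that("member matching applies OTU and ASV rules with best-hit assignment", {
  ref <- rand_dna(400, seed = 301)
  members <- c(memB = ref, memA = ref)  # tie: must resolve to memA
  reps <- c(
    exact = ref,
    two_pct = substitute_at(ref, seq(1, 400, length.out = 8), seed = 2),   # ~98%
    far = rand_dna(400, seed = 302),
    truncated = paste0(substr(ref, 1, 280), rand_dna(120, seed = 303)))

  otu <- match_members(members, reps, level = "otu")
  expect_true(all(c("exact", "two_pct") %in% otu$taxon_id))
  expect_false("far" %in% otu$taxon_id)
  expect_identical(otu$member_id[otu$taxon_id == "exact"], "memA")

  asv <- match_members(members, reps, level = "asv")
  expect_true("exact" %in% asv$taxon_id)
  expect_false("two_pct" %in% asv$taxon_id)   # 98% fails the >99 rule
  expect_false("truncated" %in% asv$taxon_id) # identity ok, coverage ~70%

  # ASV hits are a subset of OTU hits for the same representatives
  expect_true(all(asv$taxon_id %in% otu$taxon_id))
})

test_that("ecology profiles summarize prevalence and abundance per member", {
  v <- matrix(0, 2, 10, dimnames = list(c("t1", "t2"), paste0("s", 1:10)))
  v["t1", 1:3] <- c(5, 10, 15)
  v["t2", 4] <- 13.6
  tab <- abundance_table(v)
  hits <- data.frame(member_id = c("m1", "m2"), taxon_id = c("t1", "t2"),
                     percent_identity = 100, query_coverage = 100,
                     level = "OTU", stringsAsFactors = FALSE)
  eco <- ecology_profile(hits, tab)
  m1 <- eco[eco$member_id == "m1", ]
  expect_equal(m1$prevalence, 30.0)
  expect_equal(m1$mean_abundance_in_positives, 10.0)
  expect_equal(m1$max_abundance, 15.0)
  m2 <- eco[eco$member_id == "m2", ]
  expect_equal(m2$max_abundance, m2$mean_abundance_in_positives)
  expect_equal(m2$max_abundance, 13.6)

  # absent member: prevalence zero, undefined means
  eco0 <- ecology_profile(hits[0, ], tab, members = "ghost")
  expect_equal(eco0$prevalence, 0)
  expect_true(is.na(eco0$mean_abundance_in_positives))

  # multiple taxa of one member are summed per sample
  hits2 <- data.frame(member_id = "m", taxon_id = c("t1", "t2"),
                      percent_identity = 100, query_coverage = 100,
                      level = "OTU", stringsAsFactors = FALSE)
  eco2 <- ecology_profile(hits2, tab)
  expect_equal(eco2$prevalence, 40.0)
})

test_that("alpha diversity matches closed forms and the vegan implementation", {
  v <- matrix(c(25, 25, 25, 25,
                100, 0, 0, 0,
                50, 25, 25, 0), nrow = 4,
              dimnames = list(paste0("t", 1:4), c("uniform", "single", "skew")))
  tab <- abundance_table(v)
  d <- alpha_diversity(tab)
  expect_equal(d$richness, c(4L, 1L, 3L))
  expect_equal(d$shannon_effective[1], 4.0)
  expect_equal(d$shannon_effective[2], 1.0)
  expect_equal(d$shannon_H[3], 1.5 * log(2))
  expect_equal(d$shannon_effective[3], 2^1.5, tolerance = 1e-12)

  expect_equal(d$shannon_H,
               unname(vegan::diversity(t(v), index = "shannon")),
               tolerance = 1e-12)

  zero <- abundance_table(matrix(c(10, 0), 1, 2,
                                 dimnames = list("t", c("a", "b"))))
  expect_error(alpha_diversity(zero, "b"), "no detected taxa")
})

test_that("shannon effective equals richness only for uniform distributions", {
  v <- matrix(c(20, 20, 20, 30, 20, 10), nrow = 3,
              dimnames = list(paste0("t", 1:3), c("flat", "tilted")))
  d <- alpha_diversity(abundance_table(v))
  expect_equal(d$shannon_effective[1], d$richness[1])
  expect_lt(d$shannon_effective[2], d$richness[2])
})

test_that("venn counts partition detected taxa exactly", {
  v <- matrix(0, 10, 4, dimnames = list(paste0("t", 1:10),
                                        c("a1", "a2", "b1", "b2")))
  v[1:5, 1:2] <- 1            # A-only
  v[6:8, 3:4] <- 1            # B-only
  v[9:10, ] <- 1              # both
  tab <- abundance_table(v, groups = c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  vc <- venn_counts(tab)
  expect_equal(unname(vc$unique["A"]), 5L)
  expect_equal(unname(vc$unique["B"]), 3L)
  expect_equal(vc$shared, 2L)
  expect_equal(vc$total, 10L)
  expect_equal(sum(vc$unique) + vc$shared, vc$total)

  # identical composition: everything shared
  v2 <- matrix(1, 4, 2, dimnames = list(paste0("t", 1:4), c("x", "y")))
  vc2 <- venn_counts(abundance_table(v2, groups = c(x = "A", y = "B")))
  expect_equal(sum(vc2$unique), 0L)
  expect_equal(vc2$shared, 4L)

  # disjoint composition: nothing shared
  v3 <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("p", "q"), c("x", "y")))
  vc3 <- venn_counts(abundance_table(v3, groups = c(x = "A", y = "B")))
  expect_equal(vc3$shared, 0L)

  expect_error(venn_counts(abundance_table(v2)), "no group labels")
})

test_that("group_test wraps the standard two-group tests", {
  v <- matrix(c(0, 0, 3, 10, 11, 12), 1, 6,
              dimnames = list("t1", paste0("s", 1:6)))
  g <- setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  tab <- abundance_table(v, groups = g)
  expect_s3_class(group_test(tab, "t1"), "htest")
  expect_s3_class(group_test(tab, "t1", method = "fisher"), "htest")
})
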