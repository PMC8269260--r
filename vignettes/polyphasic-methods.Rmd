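---
title: "Polyphasic delineation of novel gut bacterial taxa: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polyphasic delineation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyphasic)
```

# The decision model

Bacterial taxonomy delineates species and genera with a battery of pairwise
metrics rather than a single statistic. `classify()` implements the
combination rule as a two-stage decision over a list of `metric_bundle`
objects (one bundle per isolate–relative pair), with every threshold
consulted recorded in an evidence table.

**Genus stage.** Genus membership is judged by POCP (percentage of conserved
proteins) against the *type species* of each candidate genus only. This
anchoring matters: an isolate can share > 50 % of its proteins with a
derived member of a genus while sharing far less with the species that
nomenclaturally anchors that genus, and it is the type-species comparison
that decides. If the largest type-species POCP is at or below 50 % for every
candidate genus, the isolate founds a new genus. When no type-species POCP
is available at all, the engine falls back to 16S rRNA identity: a best hit
at or below 94.5 % founds a new genus, otherwise the genus of the best hit
is assigned (flagged in the verdict notes, since this is weaker evidence).

**Species stage**, within the assigned genus:

1. *Known species* — best 16S identity above 98.7 % and ANI either
   unavailable or at least 95 %.
2. *Escalation to dDDH* — ANI inside the band [93, 97] %, or an ANI at or
   above 95 % contradicting a 16S identity at or below 98.7 %. dDDH at or
   below 70 % then calls a novel species, above 70 % a known species, and a
   missing dDDH yields the honest verdict `ambiguous` rather than a guess.
   dDDH is always consumed as an externally supplied value, never computed.
3. *Novel species* — otherwise (16S at or below 98.7 % with ANI below the
   band or unavailable). ANI below 93 % is decisively novel whatever the 16S
   identity says: genome-scale evidence outranks a single marker gene.

A G+C difference of at least 1 percentage point is recorded as supporting
evidence but never decides a rank. The band [93, 97] quantifies "ANI close
to the species boundary"; the exact species cutoffs (98.7, 95, 70, 50, 94.5)
are the field's standard values and are all overridable through
`delineation_thresholds()`.

Two further conventions make verdicts reproducible: relatives are ranked by
end-gap-free 16S identity with ties broken lexicographically by taxon name,
and entries without a validly published name or without a genome are
excluded *before* the 50-best-relatives cap is applied.

# Metric implementations

**16S identity.** `pairwise_identity()` performs an end-gap-free global
(overlap) alignment under match +1 / mismatch −1 / gap open −2 / gap extend
−1, reporting matches over alignment columns with terminal gap runs
excluded — the convention of the standard 16S identity servers. The exact
scoring scheme is immaterial at the divergences where the thresholds
operate, which is why a simple documented scheme is preferred over a tuned
one. Only `A`, `C`, `G`, `T`, `N` are accepted; other ambiguity codes are
rejected rather than scored so that reported identities do not depend on
how degeneracies are resolved. A `local` mode serves coverage-style checks.

**Fragment ANI.** `fragment_ani()` follows the classical fragment-based
definition: the query genome is cut into non-overlapping 1020-bp fragments
(trailing partial fragment dropped), each fragment is placed at its best
location in the subject by exact 15-mer seeding on either strand, aligned
there end-gap-free, and counted as "used" when it aligns with at least 30 %
identity over at least 70 % of its length. ANI is the mean identity of used
fragments. When no fragment passes, ANI is undefined (`NA`) and is treated
downstream as *no evidence* — never as 0, which would spuriously support
separation. The implementation is deliberately not a clone of any particular
ANI tool; its recovery property (mean error ≤ 0.5 points against
substitution-only ground truth across rates 1–8 %) is what the test suite
pins down, and every downstream use is a threshold test at 95 %.

**POCP.** A protein is conserved if some protein of the other proteome
aligns locally (BLOSUM62, gap open 11 / extend 1) with identity ≥ 40 % over
≥ 50 % of the query length. The usual expectation-value cutoff is replaced
by a raw-score threshold (default 50), because E-values depend on database
size and would make a self-contained implementation irreproducible; at the
identity/coverage cutoffs the score threshold only suppresses short spurious
hits. Counting is symmetric (C1 of T1 and C2 of T2 from one alignment pass).

**ORF translation fallback.** For genomes without a predicted proteome,
`orf_translate()` extracts stretches between stop codons (no start-codon
requirement) of at least 100 aa across all six frames, under the
bacterial/archaeal code. Overlapping calls at one locus are reduced to the
longest ORF, because every real gene otherwise reappears as a reverse-strand
"shadow" ORF and inflates protein totals. Even so, naive ORF calling on
substitution-diverged genomes loses genes to introduced in-frame stops and
biases POCP downward; the pipeline therefore leaves the fallback **off** by
default (`orf_fallback = FALSE`), treating a missing proteome as missing
evidence, and `assemble_metrics(orf_fallback = TRUE, orf_min_aa = 60)` opts
in with a shorter fragment cutoff for users who want it.

**MinHash sketches.** `kmer_sketch()` keeps the s smallest 64-bit FNV-1a
hashes (offset basis 14695981039346656037, prime 1099511628211, no extra
seed) of canonical — strand-minimum — k-mers, defaults k = 21 and s = 1000.
Hashes are stored as fixed-width hexadecimal strings, making sketches
bit-stable across platforms and trivially serializable
(`sketch_to_json()`). `sketch_distance()` estimates Jaccard similarity J
from the shared hashes in the bottom-s of the merged hash sets (the
denominator is capped at the merged-set size so identical short sequences
give J = 1) and converts it to a per-site divergence
d = −(1/k) ln(2J/(1+J)), capped at 1, with d = 1 when J = 0. MAG matching
reports sketches with d < 0.05.

# Amplicon-side tracking

Relative-abundance tables (percent, taxa × samples) are consumed as
produced by an OTU or ASV pipeline; no rarefaction is applied. The
table-inclusion filter keeps taxa reaching ≥ 0.25 % in at least one sample
and is applied before diversity and unique/shared computations, mirroring
the usual OTU workflow. "Detected" means strictly > 0 after that filter.

Representative sequences are assigned to synthetic-community members at two
levels: OTU representatives need ≥ 97 % local-alignment identity, ASVs need
> 99 % identity *and* ≥ 80 % query coverage, so ASV hits are always a subset
of OTU hits. The E-value condition of the original USEARCH-style screen is
replaced by the identity + coverage test for the same database-size reasons
as in POCP. Each taxon is assigned to at most one member (best identity,
ties to the lexicographically smaller member id), and when several taxa
match one member their abundances are summed per sample — member-level
abundance ranges are then reported over those sums.

Prevalence is the percentage of samples where a member's summed abundance
exceeds zero; mean abundance is taken over positive samples only, maxima
over all samples. Alpha diversity renormalizes each sample over its detected
taxa and reports richness, Shannon entropy H (nats) and the effective number
of species exp(H), which equals richness exactly iff the distribution is
uniform. Unique/shared partitions count a taxon into a group when it is
detected in any sample of the group; taxa in two or more groups are
"shared", and uniques + shared equals the number of detected taxa exactly.
Group-difference testing is a thin pass-through to the standard rank-sum and
exact tests.

# Collection summaries

`tally_collection()` reports counts and percentages per phylum or family
with one decimal, rounded *half up* — the rounding that matches how such
tables are conventionally printed (banker's rounding would print 76.74 % as
76.7 but 14.05 % as 14.0 instead of 14.1). `count_novel()` counts isolates
whose best 16S identity to a validly named species is at or below 98.7 %,
with the boundary value itself counting as novel. qPCR relative expression
follows the 40 − dCT convention with dCT = ct_target − ct_reference and
cycle values validated into [0, 40].

# Synthetic data: what it emulates, and what it does not

All generators run under a locally scoped RNG: identical (parameters, seed)
give byte-identical output, and ground truth sufficient to compute every
expected value is returned alongside each fixture.

- `gen_genome()` draws i.i.d. letters at a target G+C fraction.
- `mutate_seq()` substitutes each site to a different letter with fixed
  probability and records the realized count. The model is deliberately
  substitution-only — no indels — so identity, ANI and sketch-distance
  truths are exact (realized Hamming distance); indel robustness is covered
  separately by the gapped-alignment unit tests.
- `gen_proteome_pair()` builds two proteomes sharing n identical proteins
  plus per-side random uniques, giving POCP = 100 · 2n / (2(n + u)) exactly.
- `gen_member_table()` produces community tables with log-normal background
  abundances (a long-tailed model chosen to resemble real amplicon
  profiles; parameters documented, not fitted), Bernoulli × log-normal
  spiked members, per-sample renormalization to 100 %, and representative
  sequences generated at designed identities to the member references.
- `gen_reference_db()` builds a genus/species hierarchy with designed
  within- and between-genus divergences, one flagged type species per
  genus, and (optionally) designed proteomes whose proteins are
  back-translated into real ORFs in the genomes, so the stored proteome and
  an ORF-translated view of the genome agree. Leu/Ser codons are randomized
  among synonymous choices whose reverse complements read as stops, so
  coding regions do not cast long stop-free shadow ORFs.

What the generators do **not** emulate: sequencing error and read-level
artifacts, chimeras, indel divergence, rearrangements, horizontal transfer,
multi-copy 16S heterogeneity, or compositional correlation between taxa.
Passing the recovery tests therefore demonstrates that the *estimators and
decision rules* behave as designed under their stated models, not that they
are robust to every artifact of real sequencing data.

# Numerical choices and degenerate inputs

- All novelty boundaries are inclusive on the novel side (`<= 98.7`,
  `<= 94.5`, `<= 70`, `<= 50`); ANI uses strict `< 95`.
- Undefined ANI (no usable fragments) and missing POCP/dDDH propagate as
  absent evidence; `ambiguous` is a first-class verdict.
- Ties in relative ranking, member assignment and type-species selection
  break lexicographically.
- Multi-copy 16S input to the pipeline is reduced to the longest copy and
  flagged in the verdict notes.
- All-`N` sequences, empty proteomes, all-zero samples, groups without
  samples, and out-of-range cycle thresholds raise errors rather than
  returning silent zeros.
- Problem sizes in the test suite: genomes of 20–50 kb (100 kb spot
  checks), proteomes of 30–100 proteins of 100–120 aa, 16S-length references
  of 450–1200 bp, community tables up to 200 samples. These sizes keep every
  recovery property (ANI mean error ≤ 0.5, sketch distance ± 0.01, exact
  POCP fractions, prevalence within the exact binomial 99 % interval)
  statistically meaningful while the whole suite runs in about a minute.

# Known limitations

- The ANI implementation is fragment-based; tools with different fragment
  handling can differ by more than a point on real diverged genome pairs,
  which is why published ANI values are treated as context rather than as
  exact reproduction targets. The thresholded decisions are insensitive to
  this at the divergences that occur in practice.
- POCP via the ORF fallback underestimates shared gene content on diverged
  genomes (see above); supply predicted proteomes where available.
- The engine reports, but does not arbitrate, cases where external genome
  taxonomy disagrees with its own signals (notes on the verdict); final
  naming of taxa remains a human judgment.
- Nomenclatural validation, phylogenetic tree building and placement are out
  of scope.
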