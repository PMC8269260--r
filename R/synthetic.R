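## Seeded generators of synthetic fixtures with recorded ground truth.
## All generators run under a locally scoped RNG so they are byte-identical
## per (parameters, seed) and do not disturb the caller's RNG state.

.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], n, replace = TRUE),
        collapse = "")
}

#' Generate a random genome at a target G+C content
#'
#' I.i.d. letters at the target composition; deterministic per seed.
#'
#' @param length Genome length in bp (at least 1000).
#' @param gc_target Target G+C fraction in (0, 1).
#' @param seed RNG seed.
#' @param id Genome id.
#' @return A `genome_record`.
#' @export
gen_genome <- function(length, gc_target, seed,
                       id = sprintf("synthetic_genome_s%d", seed)) {
  if (length < 1000) stop("genome length must be >= 1000 bp", call. = FALSE)
  if (gc_target <= 0 || gc_target >= 1)
    stop("gc_target must lie strictly between 0 and 1", call. = FALSE)
  seqs <- .with_seed(seed, .random_dna(length, gc_target))
  genome_record(id, setNames(seqs, id))
}

#' Mutate a sequence by random substitutions
#'
#' Each site is substituted to a different letter with the given probability;
#' no indels, so the realized substitution count equals the Hamming distance
#' to the input and divergence-based truths (expected ANI, sketch distance)
#' are exact.
#'
#' @param seq DNA sequence (character, `DNAString`, or `genome_record`, whose
#'   contigs are each mutated).
#' @param substitution_rate Per-site substitution probability in \[0, 1).
#' @param seed RNG seed.
#' @return List with `seq` (same shape as the input) and `truth` (class
#'   `synthetic_truth`): generator name, parameters, `realized_count`,
#'   `realized_rate`.
#' @export
mutate_seq <- function(seq, substitution_rate, seed) {
  if (substitution_rate < 0 || substitution_rate >= 1)
    stop("substitution_rate must lie in [0, 1)", call. = FALSE)
  is_genome <- inherits(seq, "genome_record")
  seqs <- if (is_genome) as.character(seq$contigs) else .seq_chr(seq)
  letters4 <- c("A", "C", "G", "T")
  res <- .with_seed(seed, lapply(seqs, function(s) {
    chars <- strsplit(s, "")[[1L]]
    hit <- which(runif(length(chars)) < substitution_rate & chars %in% letters4)
    for (i in hit) chars[i] <- sample(setdiff(letters4, chars[i]), 1L)
    list(seq = paste(chars, collapse = ""), count = length(hit))
  }))
  out_seqs <- vapply(res, `[[`, "", "seq")
  names(out_seqs) <- names(seqs)
  count <- sum(vapply(res, `[[`, 0L, "count"))
  total <- sum(nchar(seqs))
  truth <- structure(list(generator = "mutate_seq", seed = seed,
                          substitution_rate = substitution_rate,
                          realized_count = count,
                          realized_rate = count / total),
                     class = "synthetic_truth")
  out <- if (is_genome) genome_record(paste0(seq$id, "_mut"), out_seqs)
         else out_seqs
  list(seq = out, truth = truth)
}

#' Generate a proteome pair with a designed shared fraction
#'
#' Shared proteins are identical across the two proteomes; unique proteins
#' are random. The expected POCP is
#' `100 * 2 n_shared / (2 (n_shared + n_unique_each))` by construction.
#'
#' @param n_shared Number of proteins present identically in both proteomes.
#' @param n_unique_each Number of proteome-specific random proteins on each
#'   side.
#' @param protein_len Protein length in residues.
#' @param seed RNG seed.
#' @return List with `a`, `b` (`AAStringSet`s) and `truth`
#'   (`synthetic_truth` including `expected_pocp`).
#' @export
gen_proteome_pair <- function(n_shared, n_unique_each, protein_len = 120L,
                              seed = 1L) {
  stopifnot(n_shared >= 0, n_unique_each >= 0)
  if (n_shared + n_unique_each == 0L)
    stop("empty proteomes requested", call. = FALSE)
  .with_seed(seed, {
    shared <- vapply(seq_len(n_shared), function(i) .random_protein(protein_len), "")
    ua <- vapply(seq_len(n_unique_each), function(i) .random_protein(protein_len), "")
    ub <- vapply(seq_len(n_unique_each), function(i) .random_protein(protein_len), "")
    a <- Biostrings::AAStringSet(c(shared, ua))
    b <- Biostrings::AAStringSet(c(shared, ub))
    names(a) <- sprintf("A_%03d", seq_along(a))
    names(b) <- sprintf("B_%03d", seq_along(b))
    truth <- structure(list(generator = "gen_proteome_pair", seed = seed,
                            n_shared = n_shared, n_unique_each = n_unique_each,
                            expected_pocp = 100 * 2 * n_shared /
                              (2 * (n_shared + n_unique_each))),
                       class = "synthetic_truth")
    list(a = a, b = b, truth = truth)
  })
}

#' Specification of one spiked community member
#'
#' @param member_id Member identifier.
#' @param presence_prob Per-group presence probability (scalar, or named by
#'   group).
#' @param meanlog,sdlog Log-normal abundance parameters (raw weights,
#'   renormalized per sample).
#' @param identity Designed percent identity of the member's representative
#'   sequence to its reference (100 = exact).
#' @return An object of class `spike_spec`.
#' @export
spike_spec <- function(member_id, presence_prob = 1, meanlog = 0, sdlog = 1,
                       identity = 100) {
  stopifnot(all(presence_prob >= 0 & presence_prob <= 1))
  structure(list(member_id = member_id, presence_prob = presence_prob,
                 meanlog = meanlog, sdlog = sdlog, identity = identity),
            class = "spike_spec")
}

#' Generate a synthetic community abundance table
#'
#' Background taxa follow a log-normal abundance model (long-tailed, as in
#' real amplicon profiles); spiked members are present per their Bernoulli
#' presence probability with log-normal abundance weights; every sample is
#' renormalized to 100\%. Representative sequences of spiked taxa are
#' generated at the designed identity to the member references; background
#' representatives are random sequences.
#'
#' @param n_samples_per_group Named integer vector: samples per group.
#' @param spikes List of [spike_spec()]s.
#' @param n_background_taxa Number of background taxa.
#' @param seed RNG seed.
#' @param ref_len Length of member reference and representative sequences.
#' @param background_meanlog,background_sdlog Log-normal parameters of the
#'   background weights.
#' @return List with `table` (an [abundance_table()]), `rep_seqs`,
#'   `member_refs` (named character vectors) and `truth` (`synthetic_truth`
#'   with designed presence/identity and realized per-group prevalence).
#' @export
gen_member_table <- function(n_samples_per_group, spikes,
                             n_background_taxa = 20L, seed = 1L,
                             ref_len = 450L, background_meanlog = 0,
                             background_sdlog = 1.5) {
  stopifnot(length(n_samples_per_group) >= 1L,
            !is.null(names(n_samples_per_group)))
  .with_seed(seed, {
    groups_vec <- rep(names(n_samples_per_group), n_samples_per_group)
    sample_ids <- sprintf("%s_%02d", groups_vec,
                          unlist(lapply(n_samples_per_group, seq_len)))
    groups <- setNames(groups_vec, sample_ids)
    n_samples <- length(sample_ids)

    member_refs <- setNames(
      vapply(seq_along(spikes), function(i) .random_dna(ref_len, 0.52), ""),
      vapply(spikes, `[[`, "", "member_id"))
    bg_ids <- sprintf("bgOTU_%03d", seq_len(n_background_taxa))
    spike_ids <- sprintf("synOTU_%s", names(member_refs))
    rep_seqs <- setNames(
      vapply(seq_len(n_background_taxa), function(i) .random_dna(ref_len, 0.52), ""),
      bg_ids)
    presence <- matrix(FALSE, length(spikes), n_samples,
                       dimnames = list(spike_ids, sample_ids))
    weights <- matrix(0, n_background_taxa + length(spikes), n_samples,
                      dimnames = list(c(bg_ids, spike_ids), sample_ids))
    for (j in seq_len(n_samples))
      weights[seq_len(n_background_taxa), j] <-
        rlnorm(n_background_taxa, background_meanlog, background_sdlog)
    for (i in seq_along(spikes)) {
      sp <- spikes[[i]]
      rate <- 1 - sp$identity / 100
      rep_i <- if (rate > 0) {
        chars <- strsplit(member_refs[[sp$member_id]], "")[[1L]]
        hit <- which(runif(length(chars)) < rate)
        for (h in hit) chars[h] <- sample(setdiff(c("A", "C", "G", "T"),
                                                  chars[h]), 1L)
        paste(chars, collapse = "")
      } else member_refs[[sp$member_id]]
      rep_seqs[spike_ids[i]] <- rep_i
      for (j in seq_len(n_samples)) {
        p <- if (length(sp$presence_prob) > 1L)
          sp$presence_prob[[groups[sample_ids[j]]]] else sp$presence_prob
        if (runif(1L) < p) {
          presence[i, j] <- TRUE
          weights[spike_ids[i], j] <- rlnorm(1L, sp$meanlog, sp$sdlog)
        }
      }
    }
    values <- sweep(weights, 2L, colSums(weights), "/") * 100
    realized_prev <- lapply(unique(groups_vec), function(g) {
      cols <- groups == g
      setNames(100 * rowSums(presence[, cols, drop = FALSE]) / sum(cols),
               spike_ids)
    })
    names(realized_prev) <- unique(groups_vec)
    truth <- structure(list(generator = "gen_member_table", seed = seed,
                            designed = lapply(spikes, unclass),
                            spike_taxa = setNames(spike_ids, names(member_refs)),
                            realized_prevalence = realized_prev),
                       class = "synthetic_truth")
    list(table = abundance_table(values, groups = groups, level = "OTU"),
         rep_seqs = rep_seqs, member_refs = member_refs, truth = truth)
  })
}

#' Generate a synthetic taxonomic reference database
#'
#' A hierarchy of genera and species with designed 16S and genome
#' divergences: each genus has an ancestral 16S gene and genome; species are
#' substitution-mutated copies at the within-genus rate; genera are mutated
#' at the between-genus rate from a common root. The first species of each
#' genus is flagged as its type species. Optional proteomes share a designed
#' fraction of proteins within a genus and none across genera, so POCP is
#' above 50\% within and near 0\% across.
#'
#' @param n_genera Number of genera.
#' @param species_per_genus Species per genus.
#' @param seed RNG seed.
#' @param within_16s,between_16s Within-/between-genus 16S substitution
#'   rates.
#' @param within_genome Within-genus genome substitution rate.
#' @param sixteenS_len,genome_len Sequence lengths (bp).
#' @param with_proteomes Attach designed proteomes.
#' @param proteins_per_genome,shared_within_genus,protein_len Proteome
#'   design.
#' @return List with `refs` (list of [reference_entry()]) and `truth`
#'   (`synthetic_truth` with the design parameters and per-entry ancestry).
#' @export
gen_reference_db <- function(n_genera, species_per_genus = 2L, seed = 1L,
                             within_16s = 0.02, between_16s = 0.10,
                             within_genome = 0.04, sixteenS_len = 1200L,
                             genome_len = 30000L, with_proteomes = FALSE,
                             proteins_per_genome = 40L,
                             shared_within_genus = 0.75, protein_len = 100L) {
  stopifnot(n_genera >= 1L, species_per_genus >= 1L)
  .with_seed(seed, {
    root16 <- .random_dna(sixteenS_len, 0.54)
    refs <- list()
    ancestry <- list()
    for (g in seq_len(n_genera)) {
      genus <- sprintf("Genus%02d", g)
      g16 <- .mutate_plain(root16, between_16s)
      ggenome <- .random_dna(genome_len, 0.45 + 0.02 * g)
      pool <- if (with_proteomes)
        vapply(seq_len(proteins_per_genome * 2L),
               function(i) .random_protein(protein_len), "") else NULL
      for (s in seq_len(species_per_genus)) {
        name <- sprintf("%s species%02d", genus, s)
        s16 <- .mutate_plain(g16, within_16s)
        proteome <- NULL
        if (with_proteomes) {
          n_sh <- round(shared_within_genus * proteins_per_genome)
          own <- vapply(seq_len(proteins_per_genome - n_sh),
                        function(i) .random_protein(protein_len), "")
          proteome <- Biostrings::AAStringSet(c(pool[seq_len(n_sh)], own))
          names(proteome) <- sprintf("%s_p%03d", gsub(" ", "_", name),
                                     seq_along(proteome))
        }
        ## proteome-bearing genomes encode their proteins as real ORFs so
        ## that ORF-translation fallbacks see consistent gene content
        gseq <- if (with_proteomes) {
          core <- paste0("TAA", paste(vapply(as.character(proteome),
                                             .backtranslate, ""),
                                      collapse = "TAATAA"), "TAA")
          pad <- max(0L, genome_len - nchar(core))
          paste0(core, if (pad > 0) .random_dna(pad, 0.5) else "")
        } else ggenome
        sgen <- genome_record(gsub(" ", "_", name),
                              setNames(.mutate_plain(gseq, within_genome),
                                       gsub(" ", "_", name)))
        refs[[length(refs) + 1L]] <- reference_entry(
          taxon_name = name, genus = genus, sixteenS = s16, genome = sgen,
          proteome = proteome, is_valid_name = TRUE,
          is_type_species = s == 1L)
        ancestry[[name]] <- list(genus = genus, genus_16s = g16,
                                 genome_ancestor_gc = 0.45 + 0.02 * g)
      }
    }
    truth <- structure(list(generator = "gen_reference_db", seed = seed,
                            n_genera = n_genera,
                            species_per_genus = species_per_genus,
                            within_16s = within_16s, between_16s = between_16s,
                            within_genome = within_genome,
                            ancestry = ancestry),
                       class = "synthetic_truth")
    list(refs = refs, truth = truth)
  })
}

## Back-translation with randomized synonymous codons for Leu and Ser. Their
## alternatives (TTA, CTA, TCA) read as stop codons on the reverse strand, so
## coding regions do not cast long stop-free "shadow" ORFs; uses the current
## RNG stream (deterministic inside seeded generators).
.backtranslate <- function(protein) {
  codon <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
             Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
             K = "AAA", M = "ATG", F = "TTT", P = "CCG",
             T = "ACT", W = "TGG", Y = "TAT", V = "GTT", X = "AAC")
  aa <- strsplit(protein, "")[[1L]]
  out <- character(length(aa))
  for (i in seq_along(aa)) {
    out[i] <- switch(aa[i],
                     L = sample(c("TTA", "CTA", "CTG"), 1L),
                     S = sample(c("TCA", "TCT"), 1L),
                     codon[[aa[i]]])
  }
  paste(out, collapse = "")
}

## Plain substitution mutation using the current RNG stream (for use inside
## already-seeded generators).
.mutate_plain <- function(s, rate) {
  if (rate <= 0) return(s)
  chars <- strsplit(s, "")[[1L]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  paste(chars, collapse = "")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic truth (%s, seed %d)\n", x$generator, x$seed))
  invisible(x)
}

#' Write a reference database to a directory
#'
#' One 16S FASTA and one genome FASTA per entry plus a tab-separated
#' `index.tsv` (taxon_name, genus, is_valid_name, is_type_species, paths).
#'
#' @param refs List of [reference_entry()]s.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_db <- function(refs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(refs, function(r) {
    stem <- gsub("[^A-Za-z0-9]+", "_", r$taxon_name)
    f16 <- paste0(stem, "_16S.fasta")
    write_fasta(setNames(r$sixteenS, stem), file.path(dir, f16))
    fg <- ""
    if (!is.null(r$genome)) {
      fg <- paste0(stem, "_genome.fasta")
      write_fasta(r$genome$contigs, file.path(dir, fg))
    }
    fp <- ""
    if (!is.null(r$proteome)) {
      fp <- paste0(stem, "_proteome.fasta")
      write_fasta(r$proteome, file.path(dir, fp))
    }
    data.frame(taxon_name = r$taxon_name, genus = r$genus,
               is_valid_name = r$is_valid_name,
               is_type_species = r$is_type_species, sixteenS_file = f16,
               genome_file = fg, proteome_file = fp, stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), file.path(dir, "index.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a reference database directory
#' @param dir Directory written by [write_reference_db()].
#' @return List of [reference_entry()]s.
#' @export
read_reference_db <- function(dir) {
  idx <- read.delim(file.path(dir, "index.tsv"), header = TRUE,
                    stringsAsFactors = FALSE)
  lapply(seq_len(nrow(idx)), function(i) {
    genome <- NULL
    if (!is.na(idx$genome_file[i]) && nzchar(idx$genome_file[i]))
      genome <- read_genome(file.path(dir, idx$genome_file[i]),
                            id = gsub(" ", "_", idx$taxon_name[i]))
    proteome <- NULL
    if (!is.null(idx$proteome_file) && !is.na(idx$proteome_file[i]) &&
        nzchar(idx$proteome_file[i]))
      proteome <- read_fasta(file.path(dir, idx$proteome_file[i]),
                             type = "protein")
    reference_entry(
      taxon_name = idx$taxon_name[i], genus = idx$genus[i],
      sixteenS = read_fasta(file.path(dir, idx$sixteenS_file[i]), type = "dna"),
      genome = genome, proteome = proteome,
      is_valid_name = idx$is_valid_name[i],
      is_type_species = idx$is_type_species[i])
  })
}
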