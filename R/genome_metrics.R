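#' Construct a genome record
#'
#' A draft genome as a set of contigs, with total length and G+C content
#' computed over all contigs (ambiguous bases excluded from the G+C
#' denominator).
#'
#' @param id Genome identifier.
#' @param contigs A `DNAStringSet`, or character vector of contig sequences.
#' @return An object of class `genome_record` with fields `id`, `contigs`,
#'   `total_length`, `gc`.
#' @export
genome_record <- function(id, contigs) {
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(toupper(contigs))
  stopifnot(inherits(contigs, "DNAStringSet"), length(contigs) > 0L)
  if (is.null(names(contigs)))
    names(contigs) <- paste0(id, "_contig", seq_along(contigs))
  freq <- Biostrings::alphabetFrequency(contigs)
  acgt <- sum(freq[, c("A", "C", "G", "T")])
  if (acgt == 0L) stop("genome has no unambiguous bases", call. = FALSE)
  gc <- 100 * sum(freq[, c("G", "C")]) / acgt
  structure(list(id = id, contigs = contigs,
                 total_length = sum(Biostrings::width(contigs)), gc = gc),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("genome %s: %d contig(s), %d bp, G+C %.1f%%\n",
              x$id, length(x$contigs), x$total_length, x$gc))
  invisible(x)
}

#' Read a genome from FASTA
#' @param path FASTA file of contigs.
#' @param id Genome id; defaults to the file name without extension.
#' @return A `genome_record`.
#' @export
read_genome <- function(path, id = NULL) {
  if (is.null(id)) id <- sub("\\.(fa|fasta|fna)$", "", basename(path))
  genome_record(id, read_fasta(path, type = "dna"))
}

#' Fragment-based average nucleotide identity (ANI)
#'
#' ANIb-style ANI: the query genome is chopped into non-overlapping fragments
#' (default 1020 bp; a trailing partial fragment is dropped), each fragment is
#' placed at its best location in the subject by exact k-mer seeding on either
#' strand, and aligned there end-gap-free. Fragments aligning with identity of
#' at least `min_identity` over at least `min_coverage` of their length are
#' "used"; ANI is the mean identity of used fragments. When no fragment
#' passes, ANI is undefined (`NA`) and `fragments_used` is 0 -- absence of
#' alignable sequence is "no evidence", never evidence for separation.
#'
#' @param query,subject `genome_record` objects (or objects [genome_record()]
#'   accepts as contigs).
#' @param fragment_len Fragment length in bp (default 1020).
#' @param min_identity Minimum percent identity for a fragment to be used
#'   (default 30).
#' @param min_coverage Minimum percent of the fragment length aligned
#'   (default 70).
#' @param seed_k Seed k-mer length for placement (default 15).
#' @param seed_step Seed sampling stride within a fragment (default 10).
#' @return An object of class `ani_result`: list with `query_id`,
#'   `subject_id`, `ani` (percent or `NA`), `fragments_used`,
#'   `fragments_total`.
#' @export
fragment_ani <- function(query, subject, fragment_len = 1020L,
                         min_identity = 30, min_coverage = 70,
                         seed_k = 15L, seed_step = 10L) {
  if (!inherits(query, "genome_record")) query <- genome_record("query", query)
  if (!inherits(subject, "genome_record")) subject <- genome_record("subject", subject)
  subj_chr <- as.character(subject$contigs)
  pad <- 30L
  fragments <- unlist(lapply(as.character(query$contigs), function(contig) {
    n_frag <- nchar(contig) %/% fragment_len
    if (n_frag == 0L) return(character(0))
    substring(contig, (seq_len(n_frag) - 1L) * fragment_len + 1L,
              seq_len(n_frag) * fragment_len)
  }))
  total <- length(fragments)
  idents <- numeric(0)
  if (total > 0L) {
    seeds <- .cpp_seed_fragments(fragments, subj_chr, as.integer(seed_k),
                                 as.integer(seed_step))
    for (fi in seq_len(total)) {
      if (seeds[fi, 4L] == 0L || is.na(seeds[fi, 1L])) next
      frag <- fragments[fi]
      if (seeds[fi, 3L] == 1L) frag <- revcomp(frag)
      contig <- subj_chr[seeds[fi, 1L]]
      win_start <- max(1L, seeds[fi, 2L] + 1L - pad)
      win_end <- min(nchar(contig), seeds[fi, 2L] + fragment_len + pad)
      aln <- .cpp_overlap_identity(frag, substr(contig, win_start, win_end))
      if (aln[2L] == 0L) next
      ident <- 100 * aln[1L] / aln[2L]
      cover <- 100 * aln[3L] / fragment_len
      if (ident >= min_identity && cover >= min_coverage)
        idents <- c(idents, ident)
    }
  }
  structure(list(query_id = query$id, subject_id = subject$id,
                 ani = if (length(idents)) mean(idents) else NA_real_,
                 fragments_used = length(idents), fragments_total = total),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  ani <- if (is.na(x$ani)) "undefined (no usable fragments)"
         else sprintf("%.2f%%", x$ani)
  cat(sprintf("ANI %s -> %s: %s [%d/%d fragments used]\n",
              x$query_id, x$subject_id, ani, x$fragments_used,
              x$fragments_total))
  invisible(x)
}

#' Percentage of conserved proteins (POCP)
#'
#' A protein is conserved if some protein of the other proteome aligns locally
#' (BLOSUM62, gap open 11 / extend 1) with raw score of at least `min_score`
#' (a database-size-independent surrogate for an expectation-value cutoff),
#' identity of at least `min_identity`, and an alignable region covering at
#' least `min_coverage` percent of the query protein's length. Conserved
#' proteins are counted in both directions (C1 out of T1, C2 out of T2) and
#' POCP = 100 (C1 + C2) / (T1 + T2).
#'
#' @param proteome_a,proteome_b `AAStringSet`s or named character vectors of
#'   protein sequences.
#' @param min_identity Minimum percent identity (default 40).
#' @param min_coverage Minimum percent of the query length aligned
#'   (default 50).
#' @param min_score Minimum local alignment raw score (default 50).
#' @return An object of class `pocp_result`: list with `C1`, `T1`, `C2`,
#'   `T2`, `pocp`.
#' @export
pocp <- function(proteome_a, proteome_b, min_identity = 40, min_coverage = 50,
                 min_score = 50) {
  a <- .as_aastringset(proteome_a, "proteome_a")
  b <- .as_aastringset(proteome_b, "proteome_b")
  conserved_a <- logical(length(a))
  conserved_b <- logical(length(b))
  wa <- Biostrings::width(a)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  submat <- get("BLOSUM62", envir = environment())
  for (j in seq_along(b)) {
    aln <- Biostrings::pairwiseAlignment(
      a, b[[j]], type = "local", substitutionMatrix = submat,
      gapOpening = 11, gapExtension = 1)
    ncol_aln <- nchar(aln)
    ident <- ifelse(ncol_aln > 0, 100 * Biostrings::nmatch(aln) / ncol_aln, 0)
    ok_core <- Biostrings::score(aln) >= min_score & ident >= min_identity
    cov_a <- 100 * Biostrings::width(Biostrings::pattern(aln)) / wa
    cov_b <- 100 * Biostrings::width(Biostrings::subject(aln)) /
      Biostrings::width(b)[j]
    conserved_a <- conserved_a | (ok_core & cov_a >= min_coverage)
    if (any(ok_core & cov_b >= min_coverage)) conserved_b[j] <- TRUE
  }
  C1 <- sum(conserved_a); C2 <- sum(conserved_b)
  T1 <- length(a); T2 <- length(b)
  structure(list(C1 = C1, T1 = T1, C2 = C2, T2 = T2,
                 pocp = 100 * (C1 + C2) / (T1 + T2)),
            class = "pocp_result")
}

.as_aastringset <- function(x, what) {
  if (is.character(x)) x <- Biostrings::AAStringSet(toupper(x))
  stopifnot(inherits(x, "AAStringSet"))
  if (length(x) == 0L) stop(what, " is empty", call. = FALSE)
  x
}

#' @export
print.pocp_result <- function(x, ...) {
  cat(sprintf("POCP = %.1f%% (C1/T1 = %d/%d, C2/T2 = %d/%d)\n",
              x$pocp, x$C1, x$T1, x$C2, x$T2))
  invisible(x)
}

#' Absolute difference in genomic G+C content
#'
#' A difference of at least 1 percentage point is conventionally taken as
#' supporting species-level separation.
#'
#' @param a,b `genome_record`s or G+C percentages.
#' @return Difference in percentage points.
#' @export
gc_difference <- function(a, b) {
  ga <- if (inherits(a, "genome_record")) a$gc else as.numeric(a)
  gb <- if (inherits(b, "genome_record")) b$gc else as.numeric(b)
  abs(ga - gb)
}

#' Naive six-frame ORF translation
#'
#' Extracts open reading frames (stretches between stop codons, no start
#' codon requirement) of at least `min_aa` residues on all six frames and
#' translates them with the bacterial/archaeal genetic code (table 11). By
#' default, overlapping calls at one locus (e.g. the reverse-strand "shadow"
#' of a real gene) are reduced to the longest ORF, mimicking single-gene
#' calling; set `reduce_overlaps = FALSE` for the raw six-frame set. Used as
#' a proteome stand-in for genomes lacking a predicted proteome; output order
#' is deterministic (contig, position, strand `+` then `-`).
#'
#' @param genome A `genome_record`.
#' @param min_aa Minimum ORF length in amino acids (default 100).
#' @param reduce_overlaps Drop ORFs whose genomic span overlaps a longer kept
#'   ORF by more than half of the shorter span.
#' @return An `AAStringSet` of ORF translations named
#'   `<contig>|<strand><frame>|<start>`.
#' @export
orf_translate <- function(genome, min_aa = 100L, reduce_overlaps = TRUE) {
  stopifnot(inherits(genome, "genome_record"))
  code <- Biostrings::getGeneticCode("11")
  rows <- list()
  for (ci in seq_along(genome$contigs)) {
    contig <- genome$contigs[[ci]]
    cname <- names(genome$contigs)[ci]
    L <- length(contig)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") contig else Biostrings::reverseComplement(contig)
      for (frame in 0:2) {
        n_codon <- (L - frame) %/% 3L
        if (n_codon < 1L) next
        sub <- Biostrings::subseq(s, frame + 1L, frame + 3L * n_codon)
        pep <- as.character(Biostrings::translate(sub, genetic.code = code,
                                                  if.fuzzy.codon = "solve"))
        segs <- strsplit(pep, "*", fixed = TRUE)[[1L]]
        lens <- nchar(segs)
        codon_start <- cumsum(c(0L, lens[-length(lens)] + 1L))
        for (k in which(lens >= min_aa)) {
          ## span in strand coords, then in forward-genome coords
          a <- frame + 3L * codon_start[k] + 1L
          b <- a + 3L * lens[k] - 1L
          if (strand == "-") { tmp <- a; a <- L - b + 1L; b <- L - tmp + 1L }
          rows[[length(rows) + 1L]] <- list(
            contig = cname, strand = strand, frame = frame,
            start = a, end = b, pep = segs[k])
        }
      }
    }
  }
  if (length(rows) == 0L) return(Biostrings::AAStringSet())
  df <- data.frame(contig = vapply(rows, `[[`, "", "contig"),
                   strand = vapply(rows, `[[`, "", "strand"),
                   frame = vapply(rows, `[[`, 0L, "frame"),
                   start = vapply(rows, `[[`, 0L, "start"),
                   end = vapply(rows, `[[`, 0L, "end"),
                   pep = vapply(rows, `[[`, "", "pep"),
                   stringsAsFactors = FALSE)
  if (reduce_overlaps) {
    keep <- logical(nrow(df))
    for (cname in unique(df$contig)) {
      idx <- which(df$contig == cname)
      ## longest first; ties resolved by position then strand for determinism
      ord <- idx[order(-(df$end[idx] - df$start[idx]), df$start[idx],
                       df$strand[idx])]
      kept <- integer(0)
      for (i in ord) {
        len_i <- df$end[i] - df$start[i] + 1L
        ov <- FALSE
        for (j in kept) {
          inter <- min(df$end[i], df$end[j]) - max(df$start[i], df$start[j]) + 1L
          len_j <- df$end[j] - df$start[j] + 1L
          if (inter > 0.5 * min(len_i, len_j)) { ov <- TRUE; break }
        }
        if (!ov) kept <- c(kept, i)
      }
      keep[kept] <- TRUE
    }
    df <- df[keep, , drop = FALSE]
  }
  df <- df[order(df$contig, df$start, df$strand, df$frame), , drop = FALSE]
  out <- Biostrings::AAStringSet(df$pep)
  names(out) <- sprintf("%s|%s%d|%d", df$contig, df$strand, df$frame, df$start)
  out
}
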