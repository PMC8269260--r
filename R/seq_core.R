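#' @useDynLib polyphasic, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import Biostrings
#' @importFrom stats setNames rlnorm runif na.omit
#' @importFrom utils read.delim write.table modifyList
NULL

DNA_LETTERS <- c("A", "C", "G", "T", "N")
AA_LETTERS <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")

## Coerce assorted sequence inputs to a single uppercase character string.
.seq_chr <- function(x) {
  if (inherits(x, "XStringSet")) {
    stopifnot(length(x) == 1L)
    x <- x[[1L]]
  }
  if (inherits(x, "XString")) x <- as.character(x)
  stopifnot(is.character(x), length(x) == 1L)
  toupper(x)
}

.check_dna <- function(x, what = "sequence") {
  bad <- setdiff(unique(strsplit(x, "")[[1L]]), DNA_LETTERS)
  if (length(bad) > 0L)
    stop(what, " contains non-IUPAC/unsupported letters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (nchar(x) == 0L) stop(what, " is empty", call. = FALSE)
  invisible(x)
}

#' Read a FASTA file of nucleotide or protein sequences
#'
#' Multi-line and CRLF-tolerant FASTA reader. Residues are uppercased and
#' record order is preserved. Sequence ids (the first whitespace-delimited
#' token of each header) must be unique; full headers are kept in the
#' `description` metadata column.
#'
#' @param path Path to a FASTA file.
#' @param type `"auto"` (default) guesses nucleotide vs protein from residue
#'   composition; `"dna"` or `"protein"` force the type.
#' @return A [Biostrings::DNAStringSet] or [Biostrings::AAStringSet] named by
#'   sequence id, with a `description` entry in `mcols()`.
#' @export
read_fasta <- function(path, type = c("auto", "dna", "protein")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(raw)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[`, "", 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate FASTA ids in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  seqs <- toupper(gsub("\r", "", as.character(raw)))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence record in ", path, call. = FALSE)
  if (type == "auto") {
    letters <- unique(unlist(strsplit(seqs, "")))
    type <- if (all(letters %in% DNA_LETTERS)) "dna" else "protein"
  }
  out <- if (type == "dna") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = headers)
  out
}

#' Write sequences to a FASTA file
#'
#' @param x A named character vector, `DNAStringSet` or `AAStringSet`.
#' @param path Output path.
#' @param width Line width for wrapping residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) {
    stopifnot(!is.null(names(x)))
    ids <- names(x)
    seqs <- toupper(x)
  } else {
    ids <- names(x)
    seqs <- as.character(x)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", ids[i]), con)
    s <- seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' G+C content of a nucleotide sequence
#'
#' Percentage of G and C among unambiguous bases; `N` is excluded from both
#' numerator and denominator.
#'
#' @param seq A DNA sequence (character, `DNAString`, or length-1
#'   `DNAStringSet`).
#' @return G+C content in percent.
#' @export
gc_content <- function(seq) {
  s <- .seq_chr(seq)
  .check_dna(s)
  counts <- table(factor(strsplit(s, "")[[1L]], levels = DNA_LETTERS))
  acgt <- sum(counts[c("A", "C", "G", "T")])
  if (acgt == 0L)
    stop("G+C content undefined: no unambiguous bases", call. = FALSE)
  100 * sum(counts[c("G", "C")]) / acgt
}

#' Reverse complement of a DNA string
#' @param seq DNA sequence as character.
#' @return Reverse-complemented character string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(.seq_chr(seq))))
}

#' Pairwise sequence identity
#'
#' Optimal pairwise alignment under match +1 / mismatch -1 / gap open -2 /
#' gap extend -1 and identity over aligned columns. `"global-endfree"` is an
#' end-gap-free global (overlap) alignment, the convention used when reporting
#' 16S rRNA gene identities; terminal gap runs carry no penalty and are
#' excluded from the identity denominator. `"local"` is a Smith-Waterman
#' alignment, used for coverage-style checks of amplicon variants.
#'
#' @param a,b DNA sequences (character, `DNAString`, or length-1 sets). Only
#'   `A`, `C`, `G`, `T`, `N` are accepted; other ambiguity codes are rejected
#'   so that reported identities are reproducible.
#' @param mode `"global-endfree"` or `"local"`.
#' @param canonicalize If `TRUE`, `b` is also aligned as its reverse
#'   complement and the higher-scoring orientation is reported.
#' @return An object of class `pairwise_identity`: a list with `query_id`,
#'   `subject_id`, `percent_identity`, `matched_columns`, `aligned_columns`,
#'   `query_coverage`, `method_tag`.
#' @export
pairwise_identity <- function(a, b, mode = c("global-endfree", "local"),
                              canonicalize = FALSE) {
  mode <- match.arg(mode)
  qid <- if (!is.null(names(a)) && length(names(a))) names(a)[1L] else "query"
  sid <- if (!is.null(names(b)) && length(names(b))) names(b)[1L] else "subject"
  sa <- .seq_chr(a); sb <- .seq_chr(b)
  .check_dna(sa, "query"); .check_dna(sb, "subject")
  res <- .align_identity(sa, sb, mode)
  if (canonicalize) {
    alt <- .align_identity(sa, revcomp(sb), mode)
    if (alt$score > res$score) res <- alt
  }
  structure(list(query_id = qid, subject_id = sid,
                 percent_identity = res$pid,
                 matched_columns = res$nmatch,
                 aligned_columns = res$ncol,
                 query_coverage = res$coverage,
                 method_tag = mode),
            class = "pairwise_identity")
}

.align_identity <- function(sa, sb, mode) {
  type <- if (mode == "local") "local" else "overlap"
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(sa), Biostrings::DNAString(sb), type = type,
    substitutionMatrix = submat, gapOpening = 2, gapExtension = 1)
  ncol_aln <- nchar(aln)
  nm <- Biostrings::nmatch(aln)
  list(pid = if (ncol_aln > 0) 100 * nm / ncol_aln else 0,
       nmatch = nm, ncol = ncol_aln,
       coverage = 100 * Biostrings::width(Biostrings::pattern(aln)) / nchar(sa),
       score = Biostrings::score(aln))
}

#' @export
print.pairwise_identity <- function(x, ...) {
  cat(sprintf("%s vs %s: %.2f%% identity (%d/%d columns, %.1f%% query coverage, %s)\n",
              x$query_id, x$subject_id, x$percent_identity,
              x$matched_columns, x$aligned_columns, x$query_coverage,
              x$method_tag))
  invisible(x)
}

#' MinHash k-mer sketch of a sequence
#'
#' Bottom-s MinHash sketch over canonical (strand-minimum) k-mers, hashed with
#' the 64-bit FNV-1a function (offset basis 14695981039346656037, prime
#' 1099511628211, no additional seed). Hash values are stored as fixed-width
#' hexadecimal strings so lexicographic order equals unsigned 64-bit order and
#' sketches are bit-stable across platforms. K-mers containing `N` are
#' skipped.
#'
#' @param seq DNA sequence (character, `DNAString`, length-1 set, or a
#'   `genome_record`, whose contigs are sketched jointly).
#' @param k K-mer length (default 21, the usual genome-sketch choice).
#' @param s Sketch size (default 1000).
#' @param source_id Identifier recorded in the sketch.
#' @return An object of class `kmer_sketch`: list with `k`, `s`, `hashes`
#'   (sorted), `source_id`.
#' @export
kmer_sketch <- function(seq, k = 21L, s = 1000L, source_id = NULL) {
  if (inherits(seq, "genome_record")) {
    if (is.null(source_id)) source_id <- seq$id
    seqs <- as.character(seq$contigs)
  } else {
    if (is.null(source_id))
      source_id <- if (!is.null(names(seq)) && length(names(seq))) names(seq)[1L] else "seq"
    seqs <- .seq_chr(seq)
  }
  if (all(nchar(seqs) < k))
    stop("sequence shorter than k = ", k, call. = FALSE)
  hashes <- sort(unique(unlist(lapply(seqs, .cpp_kmer_hashes, k = as.integer(k),
                                      s = as.integer(s)))))
  if (length(hashes) > s) hashes <- hashes[seq_len(s)]
  structure(list(k = as.integer(k), s = as.integer(s), hashes = hashes,
                 source_id = source_id),
            class = "kmer_sketch")
}

#' Mash-style distance between two MinHash sketches
#'
#' The Jaccard index J is estimated from the shared hashes within the bottom-s
#' of the merged hash sets, and converted to a per-site divergence estimate
#' \eqn{d = -\frac{1}{k}\ln\frac{2J}{1+J}}, capped at 1; J = 0 gives d = 1.
#'
#' @param a,b `kmer_sketch` objects with equal `k`.
#' @return Distance in \[0, 1\].
#' @export
sketch_distance <- function(a, b) {
  stopifnot(inherits(a, "kmer_sketch"), inherits(b, "kmer_sketch"))
  if (a$k != b$k)
    stop("sketches have different k (", a$k, " vs ", b$k, ")", call. = FALSE)
  s <- min(a$s, b$s)
  merged <- sort(unique(c(a$hashes, b$hashes)))
  u <- min(s, length(merged))
  bottom <- merged[seq_len(u)]
  shared <- sum(bottom %in% a$hashes & bottom %in% b$hashes)
  j <- shared / u
  if (j == 0) return(1)
  min(1, -(1 / a$k) * log(2 * j / (1 + j)))
}

#' @export
print.kmer_sketch <- function(x, ...) {
  cat(sprintf("MinHash sketch of %s: k = %d, s = %d, %d hashes\n",
              x$source_id, x$k, x$s, length(x$hashes)))
  invisible(x)
}

#' Serialize a sketch to JSON
#' @param x A `kmer_sketch`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
sketch_to_json <- function(x, path) {
  stopifnot(inherits(x, "kmer_sketch"))
  jsonlite::write_json(list(k = x$k, s = x$s, hashes = x$hashes,
                            source_id = x$source_id),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a sketch from JSON
#' @param path Path written by [sketch_to_json()].
#' @return A `kmer_sketch`.
#' @export
sketch_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(k = as.integer(j$k), s = as.integer(j$s),
                 hashes = as.character(j$hashes), source_id = j$source_id),
            class = "kmer_sketch")
}
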