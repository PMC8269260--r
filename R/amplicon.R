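#' Parameters of the amplicon profiling workflow
#'
#' Defaults follow the usual OTU/ASV conventions: OTU representative
#' sequences match a reference strain at >= 97\% identity; ASVs match at
#' > 99\% identity with >= 80\% query coverage; taxa are kept in a table only
#' when they reach >= 0.25\% relative abundance in at least one sample.
#'
#' @param otu_identity OTU-level identity threshold (percent).
#' @param asv_identity ASV-level identity threshold (percent, strict >).
#' @param asv_query_coverage ASV-level minimum query coverage (percent).
#' @param min_rel_abundance Table-inclusion filter (percent).
#' @return An object of class `amplicon_params`.
#' @export
amplicon_params <- function(otu_identity = 97.0, asv_identity = 99.0,
                            asv_query_coverage = 80.0,
                            min_rel_abundance = 0.25) {
  stopifnot(asv_identity > otu_identity)
  structure(list(otu_identity = otu_identity, asv_identity = asv_identity,
                 asv_query_coverage = asv_query_coverage,
                 min_rel_abundance = min_rel_abundance),
            class = "amplicon_params")
}

#' Construct an OTU/ASV relative-abundance table
#'
#' @param values Numeric matrix of relative abundances in percent, taxa as
#'   rows, samples as columns (dimnames required). Per-sample sums must not
#'   exceed 100 (small numerical tolerance allowed).
#' @param groups Named character vector mapping sample id to group label.
#' @param level `"OTU"` or `"ASV"`.
#' @return An object of class `abundance_table` with fields `values`,
#'   `groups`, `level`.
#' @export
abundance_table <- function(values, groups = NULL, level = c("OTU", "ASV")) {
  level <- match.arg(level)
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(values < 0)) stop("negative relative abundance", call. = FALSE)
  sums <- colSums(values)
  if (any(sums > 100 + 1e-6))
    stop("per-sample abundances sum to more than 100%: ",
         paste(colnames(values)[sums > 100 + 1e-6], collapse = ", "),
         call. = FALSE)
  if (!is.null(groups)) {
    if (!all(colnames(values) %in% names(groups)))
      stop("groups must cover every sample id", call. = FALSE)
    groups <- groups[colnames(values)]
  }
  structure(list(values = values, groups = groups, level = level),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("%s relative-abundance table: %d taxa x %d samples",
              x$level, nrow(x$values), ncol(x$values)))
  if (!is.null(x$groups))
    cat(sprintf(" (%d groups)", length(unique(x$groups))))
  cat("\n")
  invisible(x)
}

#' Read an abundance table from a tab-separated matrix
#'
#' First column is the taxon id; remaining columns are per-sample relative
#' abundances in percent. An optional two-column sample-to-group mapping file
#' (no header needed if two columns named sample/group are present a header
#' is used) assigns group labels.
#'
#' @param path Path to the taxa x samples TSV.
#' @param groups_path Optional path to a two-column TSV (sample, group).
#' @param level `"OTU"` or `"ASV"`.
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path, groups_path = NULL,
                                 level = c("OTU", "ASV")) {
  level <- match.arg(level)
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1L]]
  groups <- NULL
  if (!is.null(groups_path)) {
    g <- read.delim(groups_path, header = TRUE, stringsAsFactors = FALSE)
    groups <- setNames(as.character(g[[2L]]), g[[1L]])
  }
  abundance_table(values, groups = groups, level = level)
}

#' Write an abundance table to TSV
#' @param x An `abundance_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path) {
  stopifnot(inherits(x, "abundance_table"))
  df <- data.frame(taxon_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop low-abundance taxa
#'
#' Keeps taxa reaching at least `min_rel_abundance` percent relative
#' abundance in at least one sample (the usual table-inclusion filter).
#' Idempotent.
#'
#' @param table An [abundance_table()].
#' @param params An [amplicon_params()].
#' @return The filtered `abundance_table`.
#' @export
filter_low_abundance <- function(table, params = amplicon_params()) {
  stopifnot(inherits(table, "abundance_table"))
  keep <- apply(table$values, 1L, max) >= params$min_rel_abundance
  abundance_table(table$values[keep, , drop = FALSE], groups = table$groups,
                  level = table$level)
}

#' Match representative sequences to synthetic-community member references
#'
#' Assigns OTU/ASV representative sequences to community member reference 16S
#' sequences by local alignment. At OTU level a hit requires identity of at
#' least the OTU threshold (97\% by default); at ASV level identity strictly
#' above the ASV threshold (99\%) and query coverage of at least 80\%. Each
#' taxon is assigned to at most one member (best identity, ties broken by
#' lexicographic member id).
#'
#' @param member_refs Named character vector or `DNAStringSet` of member
#'   reference 16S sequences.
#' @param rep_seqs Named character vector or `DNAStringSet` of representative
#'   sequences; names are table taxon ids.
#' @param level `"otu"` or `"asv"`.
#' @param params An [amplicon_params()].
#' @return Data frame of class `member_hits` with columns `member_id`,
#'   `taxon_id`, `percent_identity`, `query_coverage`, `level`.
#' @export
match_members <- function(member_refs, rep_seqs, level = c("otu", "asv"),
                          params = amplicon_params()) {
  level <- match.arg(level)
  if (inherits(member_refs, "XStringSet")) member_refs <- as.character(member_refs)
  if (inherits(rep_seqs, "XStringSet")) rep_seqs <- as.character(rep_seqs)
  stopifnot(!is.null(names(member_refs)), !is.null(names(rep_seqs)))
  rows <- list()
  for (ti in names(rep_seqs)) {
    best <- NULL
    for (mi in sort(names(member_refs))) {
      pw <- pairwise_identity(rep_seqs[[ti]], member_refs[[mi]], mode = "local")
      if (is.null(best) || pw$percent_identity > best$percent_identity)
        best <- list(member_id = mi, percent_identity = pw$percent_identity,
                     query_coverage = pw$query_coverage)
    }
    pass <- if (level == "otu") {
      best$percent_identity >= params$otu_identity
    } else {
      best$percent_identity > params$asv_identity &&
        best$query_coverage >= params$asv_query_coverage
    }
    if (pass)
      rows[[length(rows) + 1L]] <- data.frame(
        member_id = best$member_id, taxon_id = ti,
        percent_identity = best$percent_identity,
        query_coverage = best$query_coverage,
        level = toupper(level), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(member_id = character(0), taxon_id = character(0),
                         percent_identity = numeric(0),
                         query_coverage = numeric(0), level = character(0),
                         stringsAsFactors = FALSE)
  class(out) <- c("member_hits", class(out))
  out
}

#' Prevalence and abundance profile of community members
#'
#' For each member, abundances of all taxa assigned to it are summed per
#' sample. A sample is positive when that sum exceeds zero. Prevalence is the
#' percentage of positive samples; mean abundance is taken over positive
#' samples only; maximum abundance is over all samples. Members without any
#' hit get prevalence 0 and `NA` means.
#'
#' @param hits A [match_members()] result (its `taxon_id`s must exist in the
#'   table), or member ids with zero hits are also allowed via `members`.
#' @param table An [abundance_table()].
#' @param members Optional character vector of member ids to profile
#'   (defaults to the members present in `hits`).
#' @return Data frame with columns `member_id`, `prevalence`,
#'   `mean_abundance_in_positives`, `max_abundance`, `n_samples`.
#' @export
ecology_profile <- function(hits, table, members = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  if (nrow(hits) > 0 && !all(hits$taxon_id %in% rownames(table$values)))
    stop("hit taxon ids missing from table", call. = FALSE)
  if (is.null(members)) members <- sort(unique(hits$member_id))
  n <- ncol(table$values)
  out <- lapply(members, function(m) {
    taxa <- hits$taxon_id[hits$member_id == m]
    if (length(taxa) == 0L)
      return(data.frame(member_id = m, prevalence = 0,
                        mean_abundance_in_positives = NA_real_,
                        max_abundance = NA_real_, n_samples = n,
                        stringsAsFactors = FALSE))
    summed <- colSums(table$values[taxa, , drop = FALSE])
    pos <- summed > 0
    data.frame(member_id = m, prevalence = 100 * sum(pos) / n,
               mean_abundance_in_positives =
                 if (any(pos)) mean(summed[pos]) else NA_real_,
               max_abundance = max(summed), n_samples = n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Alpha diversity of one sample
#'
#' Abundances are renormalized to proportions over the detected taxa of the
#' sample; richness is the count of detected taxa, Shannon entropy
#' \eqn{H = -\sum p \ln p} is in nats, and the Shannon effective count is
#' \eqn{\exp(H)}, the effective number of species.
#'
#' @param table An [abundance_table()].
#' @param sample_id Sample to summarize (default: all samples).
#' @return Data frame with columns `sample_id`, `richness`, `shannon_H`,
#'   `shannon_effective`.
#' @export
alpha_diversity <- function(table, sample_id = colnames(table$values)) {
  stopifnot(inherits(table, "abundance_table"))
  missing <- setdiff(sample_id, colnames(table$values))
  if (length(missing))
    stop("unknown sample id: ", paste(missing, collapse = ", "), call. = FALSE)
  out <- lapply(sample_id, function(s) {
    v <- table$values[, s]
    v <- v[v > 0]
    if (length(v) == 0L)
      stop("sample ", s, " has no detected taxa", call. = FALSE)
    p <- v / sum(v)
    h <- -sum(p * log(p))
    data.frame(sample_id = s, richness = length(v), shannon_H = h,
               shannon_effective = exp(h), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Unique and shared taxa between sample groups
#'
#' A taxon belongs to a group when it is detected (abundance > 0) in at least
#' one sample of that group. `unique` counts taxa found in exactly one group;
#' `shared` counts taxa found in two or more. Percentages are against the
#' total number of detected taxa. Apply [filter_low_abundance()] first to
#' reproduce the usual OTU workflow.
#'
#' @param table An [abundance_table()] with group labels.
#' @param groups Optional named character vector overriding `table$groups`.
#' @return An object of class `venn_counts`: list with `unique` (named
#'   vector), `shared`, `total`, `unique_pct`, `shared_pct`.
#' @export
venn_counts <- function(table, groups = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(groups)) groups <- table$groups
  if (is.null(groups)) stop("no group labels available", call. = FALSE)
  groups <- groups[colnames(table$values)]
  labs <- sort(unique(groups))
  if (length(labs) < 2L) stop("need at least two groups", call. = FALSE)
  sets <- lapply(labs, function(g) {
    cols <- names(groups)[groups == g]
    if (length(cols) == 0L) stop("group with no samples: ", g, call. = FALSE)
    rownames(table$values)[rowSums(table$values[, cols, drop = FALSE] > 0) > 0]
  })
  names(sets) <- labs
  detected <- unique(unlist(sets))
  membership <- vapply(detected, function(t)
    sum(vapply(sets, function(s) t %in% s, TRUE)), 0L)
  uniq <- vapply(labs, function(g)
    sum(membership[detected %in% sets[[g]]] == 1L), 0L)
  shared <- sum(membership >= 2L)
  total <- length(detected)
  structure(list(unique = uniq, shared = shared, total = total,
                 unique_pct = 100 * uniq / total,
                 shared_pct = 100 * shared / total),
            class = "venn_counts")
}

#' @export
print.venn_counts <- function(x, ...) {
  cat(sprintf("%d detected taxa: shared %d (%.1f%%)", x$total, x$shared,
              x$shared_pct))
  for (g in names(x$unique))
    cat(sprintf(", %s-only %d (%.1f%%)", g, x$unique[[g]], x$unique_pct[[g]]))
  cat("\n")
  invisible(x)
}

#' Group difference test for one taxon
#'
#' Thin pass-through to the standard rank-sum test on abundances (or Fisher's
#' exact test on presence/absence) between two groups.
#'
#' @param table An [abundance_table()] with group labels.
#' @param taxon_id Taxon to test.
#' @param method `"wilcoxon"` (abundance) or `"fisher"`
#'   (presence/absence).
#' @return The `htest` object.
#' @export
group_test <- function(table, taxon_id, method = c("wilcoxon", "fisher")) {
  method <- match.arg(method)
  stopifnot(inherits(table, "abundance_table"), !is.null(table$groups),
            taxon_id %in% rownames(table$values))
  g <- factor(table$groups)
  if (nlevels(g) != 2L) stop("need exactly two groups", call. = FALSE)
  v <- table$values[taxon_id, ]
  if (method == "wilcoxon") {
    stats::wilcox.test(v ~ g, exact = FALSE)
  } else {
    stats::fisher.test(table(v > 0, g))
  }
}
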