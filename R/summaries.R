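#' Read a culture-collection metadata table
#'
#' Tab-separated table with one row per isolate and columns `isolate_id`,
#' `species_name`, `genus`, `family`, `phylum`, `best_hit_identity` (best 16S
#' rRNA gene identity to a validly named species, percent) and
#' `is_syn_member` (logical flag for synthetic-community membership).
#'
#' @param path Path to the TSV.
#' @return A data frame of class `collection_table`.
#' @export
read_collection_table <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  required <- c("isolate_id", "species_name", "genus", "family", "phylum",
                "best_hit_identity", "is_syn_member")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("collection table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  stopifnot(all(df$best_hit_identity >= 0 & df$best_hit_identity <= 100),
            all(nzchar(df$phylum)), all(nzchar(df$family)))
  df$is_syn_member <- as.logical(df$is_syn_member)
  class(df) <- c("collection_table", class(df))
  df
}

## Round half away from zero to `digits` decimals (printed tallies use
## round-half-up, not banker's rounding).
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Tally a collection at phylum or family level
#'
#' Counts and percentages (one decimal, rounded half up) of isolates per
#' taxon at the requested level, sorted by decreasing count then name.
#'
#' @param table A [read_collection_table()] data frame.
#' @param level `"phylum"` or `"family"`.
#' @return An object of class `taxon_tally`: data frame with columns `taxon`,
#'   `count`, `percent`, plus attributes `level` and `n_total`.
#' @export
tally_collection <- function(table, level = c("phylum", "family")) {
  level <- match.arg(level)
  stopifnot(nrow(table) > 0L)
  counts <- table(table[[level]])
  out <- data.frame(taxon = names(counts), count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$percent <- round_half_up(100 * out$count / nrow(table), 1L)
  out <- out[order(-out$count, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "level") <- level
  attr(out, "n_total") <- nrow(table)
  class(out) <- c("taxon_tally", class(out))
  out
}

#' Count potentially novel isolates
#'
#' Number of isolates whose best 16S rRNA gene identity to a validly named
#' species is at or below the species-delineation threshold (98.7\% by
#' default; the boundary value itself counts as novel).
#'
#' @param table A [read_collection_table()] data frame.
#' @param threshold Identity threshold in percent.
#' @return Integer count.
#' @export
count_novel <- function(table, threshold = 98.7) {
  sum(table$best_hit_identity <= threshold)
}

#' qPCR relative expression from cycle thresholds
#'
#' Housekeeping-gene normalization: `dCT = ct_target - ct_reference` and
#' relative expression `40 - dCT` (40 being the number of amplification
#' cycles).
#'
#' @param ct_target,ct_reference Cycle-threshold values in \[0, 40\]
#'   (vectorized).
#' @param gene Optional gene label(s).
#' @return Data frame of class `qpcr_result` with columns `gene`,
#'   `ct_target`, `ct_reference`, `dCT`, `relative_expression`.
#' @export
qpcr_relative_expression <- function(ct_target, ct_reference, gene = NA) {
  if (any(ct_target < 0 | ct_target > 40 | ct_reference < 0 |
          ct_reference > 40))
    stop("cycle-threshold values must lie in [0, 40]", call. = FALSE)
  dct <- ct_target - ct_reference
  out <- data.frame(gene = gene, ct_target = ct_target,
                    ct_reference = ct_reference, dCT = dct,
                    relative_expression = 40 - dct, stringsAsFactors = FALSE)
  class(out) <- c("qpcr_result", class(out))
  out
}
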