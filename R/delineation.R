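#' Default thresholds for polyphasic taxon delineation
#'
#' The standard cutoffs used to call novel species and genera from cultured
#' isolates: 16S rRNA gene identity of 98.7\% (species) and 94.5\% (genus),
#' ANI below 95\% for separate species with an "ANI close to 95\%" band of
#' \[93, 97\] inside which dDDH (species boundary 70\%) is consulted, a G+C
#' difference of 1 percentage point as supporting (never decisive) evidence,
#' POCP of 50\% for genus membership, and a MinHash distance of 0.05 for
#' matching metagenome-assembled genomes to isolates.
#'
#' @param species16S,genus16S 16S identity cutoffs (percent).
#' @param ani_species ANI species cutoff (percent).
#' @param ani_band Two-element ANI band (percent) requiring dDDH arbitration.
#' @param dddh_species dDDH species cutoff (percent).
#' @param gc_diff_support G+C difference (percentage points) recorded as
#'   supporting evidence.
#' @param pocp_genus POCP genus cutoff (percent).
#' @param mag_match_distance Sketch distance below which a MAG is reported as
#'   matching an isolate genome.
#' @return An object of class `delineation_thresholds`.
#' @export
delineation_thresholds <- function(species16S = 98.7, genus16S = 94.5,
                                   ani_species = 95.0, ani_band = c(93, 97),
                                   dddh_species = 70.0, gc_diff_support = 1.0,
                                   pocp_genus = 50.0,
                                   mag_match_distance = 0.05) {
  stopifnot(genus16S < species16S, length(ani_band) == 2L,
            ani_band[1] <= ani_species, ani_species <= ani_band[2])
  structure(list(species16S = species16S, genus16S = genus16S,
                 ani_species = ani_species, ani_band = as.numeric(ani_band),
                 dddh_species = dddh_species,
                 gc_diff_support = gc_diff_support, pocp_genus = pocp_genus,
                 mag_match_distance = mag_match_distance),
            class = "delineation_thresholds")
}

#' Construct a reference database entry
#'
#' One candidate relative from a curated 16S reference set (e.g. an
#' all-species living tree): its 16S rRNA gene sequence plus, where
#' available, a genome and a predicted proteome.
#'
#' @param taxon_name Species name.
#' @param genus Genus the taxon belongs to.
#' @param sixteenS 16S rRNA gene sequence (character or `DNAStringSet`).
#' @param genome Optional `genome_record`.
#' @param proteome Optional `AAStringSet`.
#' @param is_valid_name Whether the name is validly published.
#' @param is_type_species Whether this is the type species of its genus.
#' @return An object of class `reference_entry`.
#' @export
reference_entry <- function(taxon_name, genus, sixteenS, genome = NULL,
                            proteome = NULL, is_valid_name = TRUE,
                            is_type_species = FALSE) {
  structure(list(taxon_name = taxon_name, genus = genus,
                 sixteenS = .seq_chr(sixteenS), genome = genome,
                 proteome = proteome, is_valid_name = isTRUE(is_valid_name),
                 is_type_species = isTRUE(is_type_species)),
            class = "reference_entry")
}

#' Rank reference relatives of an isolate by 16S identity
#'
#' Entries without a validly published name or without a genome are excluded
#' (filtering is applied before the cap of `n` best matches); the remainder
#' are ranked by end-gap-free 16S identity, ties broken lexicographically by
#' taxon name.
#'
#' @param isolate16S 16S rRNA gene sequence of the isolate.
#' @param refs List of [reference_entry()] objects.
#' @param n Maximum number of relatives kept (default 50).
#' @param isolate_id Identifier used in downstream records.
#' @return An object of class `relative_set`: list with `isolate_id`,
#'   `ranked` (data frame: taxon_name, genus, is_type_species,
#'   percent_identity) and `entries` (the matching `reference_entry` objects,
#'   in ranked order).
#' @export
rank_relatives <- function(isolate16S, refs, n = 50L, isolate_id = "isolate") {
  stopifnot(length(refs) > 0L)
  eligible <- Filter(function(r) r$is_valid_name && !is.null(r$genome), refs)
  if (length(eligible) == 0L)
    stop("no eligible reference (valid name + genome available)", call. = FALSE)
  ident <- vapply(eligible, function(r) {
    pairwise_identity(isolate16S, r$sixteenS)$percent_identity
  }, numeric(1))
  nm <- vapply(eligible, `[[`, "", "taxon_name")
  ord <- order(-ident, nm)
  keep <- ord[seq_len(min(n, length(ord)))]
  ranked <- data.frame(
    taxon_name = nm[keep],
    genus = vapply(eligible, `[[`, "", "genus")[keep],
    is_type_species = vapply(eligible, `[[`, TRUE, "is_type_species")[keep],
    percent_identity = ident[keep],
    stringsAsFactors = FALSE)
  structure(list(isolate_id = isolate_id, ranked = ranked,
                 entries = eligible[keep]),
            class = "relative_set")
}

#' @export
print.relative_set <- function(x, ...) {
  cat(sprintf("%d ranked relatives of %s (best: %s at %.2f%%)\n",
              nrow(x$ranked), x$isolate_id, x$ranked$taxon_name[1L],
              x$ranked$percent_identity[1L]))
  invisible(x)
}

#' Construct a metric bundle
#'
#' All pairwise delineation metrics between an isolate and one relative.
#' Absent metrics are `NA`; dDDH is always supplied externally, never
#' computed.
#'
#' @param isolate_id,relative_name Identifiers of the pair.
#' @param identity16S 16S rRNA gene identity (percent, required).
#' @param genus Genus of the relative.
#' @param ani,pocp,dddh,gc_diff Optional metrics (percent / percentage
#'   points).
#' @param pocp_is_to_type_species Whether the POCP value is against the type
#'   species of `genus`.
#' @return An object of class `metric_bundle`.
#' @export
metric_bundle <- function(isolate_id, relative_name, identity16S, genus = NA,
                          ani = NA, pocp = NA,
                          pocp_is_to_type_species = FALSE, dddh = NA,
                          gc_diff = NA) {
  vals <- c(identity16S = identity16S, ani = ani, pocp = pocp, dddh = dddh)
  bad <- !is.na(vals) & (vals < 0 | vals > 100)
  if (any(bad))
    stop("metric out of [0,100]: ", paste(names(vals)[bad], collapse = ", "),
         call. = FALSE)
  structure(list(isolate_id = isolate_id, relative_name = relative_name,
                 identity16S = as.numeric(identity16S),
                 genus = as.character(genus), ani = as.numeric(ani),
                 pocp = as.numeric(pocp),
                 pocp_is_to_type_species = isTRUE(pocp_is_to_type_species),
                 dddh = as.numeric(dddh), gc_diff = as.numeric(gc_diff)),
            class = "metric_bundle")
}

#' Read metric bundles from a tab-separated file
#'
#' Columns: `isolate_id`, `isolate_gc` (optional), `relative_name`, `genus`,
#' `is_type_species`, `identity16S`, `ani`, `pocp`, `dddh`, `gc_diff`; empty
#' cells are absent metrics. The packaged
#' `chibac_protologues.tsv` fixture transcribes the pairwise metric values
#' printed in the formal descriptions of the seven novel chicken-gut taxa.
#'
#' @param path Path to the TSV.
#' @return Named list (one element per isolate) of lists of
#'   [metric_bundle()]s; isolate G+C values, when present, are attached as
#'   attribute `isolate_gc`.
#' @export
read_metric_bundles <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  num <- function(x) if (is.null(x)) rep(NA_real_, nrow(df)) else as.numeric(x)
  df$identity16S <- num(df$identity16S)
  df$ani <- num(df$ani); df$pocp <- num(df$pocp)
  df$dddh <- num(df$dddh); df$gc_diff <- num(df$gc_diff)
  out <- lapply(split(df, df$isolate_id), function(d) {
    lapply(seq_len(nrow(d)), function(i)
      metric_bundle(d$isolate_id[i], d$relative_name[i],
                    identity16S = d$identity16S[i], genus = d$genus[i],
                    ani = d$ani[i], pocp = d$pocp[i],
                    pocp_is_to_type_species = isTRUE(as.logical(d$is_type_species[i])),
                    dddh = d$dddh[i], gc_diff = d$gc_diff[i]))
  })
  if ("isolate_gc" %in% names(df)) {
    gc <- vapply(split(df$isolate_gc, df$isolate_id), `[`, 0, 1L)
    attr(out, "isolate_gc") <- gc
  }
  out
}

#' Assemble the metric bundle between an isolate and one relative
#'
#' Computes 16S identity always; ANI and G+C difference when both genomes are
#' available; POCP when both proteomes are available (optionally deriving a
#' proteome by six-frame ORF translation when only genomes exist); records a
#' supplied dDDH value verbatim.
#'
#' @param isolate A list with elements `id`, `sixteenS`, and optionally
#'   `genome` (a `genome_record`) and `proteome` (an `AAStringSet`).
#' @param relative A [reference_entry()].
#' @param dddh Externally computed dDDH (percent), if any.
#' @param orf_fallback If `TRUE`, derive missing proteomes from genomes via
#'   [orf_translate()] before computing POCP.
#' @param orf_min_aa Minimum ORF length (aa) used by the fallback. Shorter
#'   than the [orf_translate()] default because diverged genomes accumulate
#'   in-frame stops that fragment long ORFs; 60-aa fragments still satisfy
#'   the POCP coverage rule.
#' @param ... Passed to [fragment_ani()].
#' @return A [metric_bundle()].
#' @export
assemble_metrics <- function(isolate, relative, dddh = NA,
                             orf_fallback = FALSE, orf_min_aa = 60L, ...) {
  stopifnot(inherits(relative, "reference_entry"), !is.null(isolate$sixteenS))
  id16 <- pairwise_identity(isolate$sixteenS, relative$sixteenS)$percent_identity
  ani <- NA_real_; gc_diff <- NA_real_; pocp_val <- NA_real_
  if (!is.null(isolate$genome) && !is.null(relative$genome)) {
    ani <- fragment_ani(isolate$genome, relative$genome, ...)$ani
    gc_diff <- gc_difference(isolate$genome, relative$genome)
  }
  pa <- isolate$proteome
  pb <- relative$proteome
  if (orf_fallback) {
    if (is.null(pa) && !is.null(isolate$genome))
      pa <- orf_translate(isolate$genome, min_aa = orf_min_aa)
    if (is.null(pb) && !is.null(relative$genome))
      pb <- orf_translate(relative$genome, min_aa = orf_min_aa)
  }
  if (!is.null(pa) && !is.null(pb) && length(pa) && length(pb))
    pocp_val <- pocp(pa, pb)$pocp
  metric_bundle(isolate$id %||% "isolate", relative$taxon_name,
                identity16S = id16, genus = relative$genus, ani = ani,
                pocp = pocp_val,
                pocp_is_to_type_species = relative$is_type_species,
                dddh = dddh, gc_diff = gc_diff)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify an isolate from its metric bundles
#'
#' The polyphasic decision logic. Genus stage: genus membership is judged by
#' POCP to type species only; if the highest type-species POCP is at or below
#' the genus cutoff for every candidate genus -- or no type-species POCP is
#' available and the best 16S identity is at or below the genus 16S cutoff --
#' the isolate founds a new genus. Otherwise it is placed in the genus whose
#' type species gives the highest POCP above the cutoff. Species stage,
#' within the assigned genus: a species is called known when the best 16S
#' identity exceeds the species cutoff and ANI (if available) is at or above
#' 95\%; ANI inside the \[93, 97\] band, or an ANI call contradicting the 16S
#' call, escalates to dDDH (novel at or below 70\%, ambiguous when dDDH is
#' missing); otherwise the isolate is a novel species. A G+C difference of at
#' least 1 point is recorded as supporting evidence only.
#'
#' @param bundles List of [metric_bundle()]s for one isolate (any order; they
#'   are re-sorted by 16S identity).
#' @param thresholds A [delineation_thresholds()].
#' @return An object of class `delineation_verdict`: list with `isolate_id`,
#'   `rank` (`known_species`, `novel_species`, `novel_genus` or `ambiguous`),
#'   `assigned_genus` (`"proposed-new"` for novel genera), `evidence` (data
#'   frame: criterion, value, threshold, pass) and `notes`.
#' @export
classify <- function(bundles, thresholds = delineation_thresholds()) {
  if (inherits(bundles, "metric_bundle")) bundles <- list(bundles)
  stopifnot(length(bundles) > 0L,
            all(vapply(bundles, inherits, TRUE, "metric_bundle")),
            inherits(thresholds, "delineation_thresholds"))
  th <- thresholds
  id16_all <- vapply(bundles, `[[`, 0, "identity16S")
  bundles <- bundles[order(-id16_all,
                           vapply(bundles, `[[`, "", "relative_name"))]
  isolate_id <- bundles[[1L]]$isolate_id
  ev <- list()
  notes <- character(0)
  add_ev <- function(criterion, value, threshold, pass) {
    if (!criterion %in% vapply(ev, `[[`, "", "criterion"))
      ev[[length(ev) + 1L]] <<- list(criterion = criterion, value = value,
                                     threshold = threshold, pass = pass)
  }

  ## ---- genus stage: POCP to type species only ----
  ts <- Filter(function(b) b$pocp_is_to_type_species && !is.na(b$pocp), bundles)
  rank <- NULL
  genus <- NA_character_
  if (length(ts) > 0L) {
    pocps <- vapply(ts, `[[`, 0, "pocp")
    best_ts <- ts[[order(-pocps, vapply(ts, `[[`, "", "relative_name"))[1L]]]
    add_ev("max_type_species_pocp_le_genus_cutoff", max(pocps), th$pocp_genus,
           max(pocps) <= th$pocp_genus)
    if (max(pocps) <= th$pocp_genus) {
      rank <- "novel_genus"
      genus <- "proposed-new"
    } else {
      genus <- best_ts$genus
      notes <- c(notes, sprintf(
        "genus %s assigned by highest type-species POCP (%.1f%% to %s)",
        genus, best_ts$pocp, best_ts$relative_name))
    }
  } else {
    best16 <- bundles[[1L]]$identity16S
    add_ev("best_16S_identity_le_genus_cutoff", best16, th$genus16S,
           best16 <= th$genus16S)
    if (best16 <= th$genus16S) {
      rank <- "novel_genus"
      genus <- "proposed-new"
      notes <- c(notes, "new genus called on 16S alone: no type-species POCP available")
    } else {
      genus <- bundles[[1L]]$genus
      notes <- c(notes,
                 sprintf("genus %s assigned by best 16S identity (no type-species POCP available)",
                         genus))
    }
  }

  ## ---- species stage within the assigned genus ----
  if (is.null(rank)) {
    in_genus <- Filter(function(b) identical(b$genus, genus), bundles)
    if (length(in_genus) == 0L) in_genus <- bundles
    best <- in_genus[[1L]]
    id16 <- best$identity16S
    ani <- best$ani
    if (is.na(ani)) {
      anis <- vapply(in_genus, `[[`, 0, "ani")
      if (any(!is.na(anis))) ani <- max(anis, na.rm = TRUE)
    }
    dddh <- best$dddh
    if (is.na(dddh)) {
      ds <- vapply(in_genus, `[[`, 0, "dddh")
      if (any(!is.na(ds))) dddh <- max(ds, na.rm = TRUE)
    }
    add_ev("best_16S_identity_le_species_cutoff", id16, th$species16S,
           id16 <= th$species16S)
    if (!is.na(ani))
      add_ev("ani_lt_species_cutoff", ani, th$ani_species, ani < th$ani_species)
    sixteen_novel <- id16 <= th$species16S
    ani_known <- !is.na(ani) && ani >= th$ani_species
    in_band <- !is.na(ani) && ani >= th$ani_band[1] && ani <= th$ani_band[2]
    ## ANI above the band while 16S says novel: genome vs 16S conflict.
    ## ANI below the band is decisively novel, whatever the 16S identity.
    contradiction <- !is.na(ani) && ani > th$ani_band[2] && sixteen_novel
    if (!sixteen_novel && (is.na(ani) || ani_known)) {
      rank <- "known_species"
    } else if (in_band || contradiction) {
      notes <- c(notes, sprintf(
        "ANI %s; escalated to dDDH",
        if (in_band) sprintf("%.1f%% is close to the species boundary", ani)
        else sprintf("call (%.1f%%) contradicts the 16S call (%.1f%%)", ani, id16)))
      if (is.na(dddh)) {
        rank <- "ambiguous"
        notes <- c(notes, "dDDH required but not supplied")
        add_ev("dddh_le_species_cutoff", NA_real_, th$dddh_species, NA)
      } else {
        add_ev("dddh_le_species_cutoff", dddh, th$dddh_species,
               dddh <= th$dddh_species)
        rank <- if (dddh <= th$dddh_species) "novel_species" else "known_species"
      }
    } else {
      rank <- "novel_species"
    }
    if (!is.na(best$gc_diff))
      add_ev("gc_difference_ge_support", best$gc_diff, th$gc_diff_support,
             best$gc_diff >= th$gc_diff_support)
  }

  evidence <- do.call(rbind, lapply(ev, function(e)
    data.frame(criterion = e$criterion, value = e$value,
               threshold = e$threshold, pass = e$pass,
               stringsAsFactors = FALSE)))
  structure(list(isolate_id = isolate_id, rank = rank,
                 assigned_genus = genus, evidence = evidence, notes = notes),
            class = "delineation_verdict")
}

#' @export
print.delineation_verdict <- function(x, ...) {
  cat(sprintf("Delineation verdict for %s: %s (genus: %s)\n", x$isolate_id,
              x$rank, x$assigned_genus))
  print(x$evidence, row.names = FALSE)
  if (length(x$notes)) cat(paste0("  note: ", x$notes, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
#' @method summary delineation_verdict
summary.delineation_verdict <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Protologue scaffold for a novel taxon
#'
#' Assembles the structured skeleton of a formal taxon description from a
#' novelty verdict: the candidate name parts, the full evidence table, the
#' genomic G+C content, the per-relative metric table and an isolation-source
#' free text.
#'
#' @param verdict A [classify()] verdict of rank `novel_species` or
#'   `novel_genus`.
#' @param bundles The metric bundles behind the verdict.
#' @param gc Genomic G+C content of the isolate (percent).
#' @param source_text Isolation source free text.
#' @param name_parts Named character vector, e.g.
#'   `c(genus = "...", species = "...")`.
#' @return An object of class `protologue`.
#' @export
protologue_scaffold <- function(verdict, bundles, gc, source_text = "",
                                name_parts = c(genus = NA, species = NA)) {
  stopifnot(inherits(verdict, "delineation_verdict"))
  if (!verdict$rank %in% c("novel_species", "novel_genus"))
    stop("protologue requires a novel_species or novel_genus verdict, got ",
         verdict$rank, call. = FALSE)
  if (inherits(bundles, "metric_bundle")) bundles <- list(bundles)
  metric_table <- do.call(rbind, lapply(bundles, function(b)
    data.frame(relative = b$relative_name, genus = b$genus,
               identity16S = b$identity16S, ani = b$ani, pocp = b$pocp,
               pocp_is_to_type_species = b$pocp_is_to_type_species,
               dddh = b$dddh, gc_diff = b$gc_diff, stringsAsFactors = FALSE)))
  structure(list(name_parts = name_parts, verdict = verdict,
                 metric_table = metric_table, gc = as.numeric(gc),
                 source_text = source_text),
            class = "protologue")
}

#' @export
print.protologue <- function(x, ...) {
  nm <- paste(na.omit(x$name_parts), collapse = " ")
  cat(sprintf("Protologue scaffold: %s (%s)\n", nm, x$verdict$rank))
  cat(sprintf("  G+C content of genomic DNA: %.1f%%\n", x$gc))
  if (nzchar(x$source_text)) cat("  Isolated from:", x$source_text, "\n")
  print(x$metric_table, row.names = FALSE)
  invisible(x)
}

#' Serialize a protologue to JSON
#' @param x A `protologue`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
protologue_to_json <- function(x, path) {
  stopifnot(inherits(x, "protologue"))
  v <- x$verdict
  jsonlite::write_json(
    list(name_parts = as.list(x$name_parts),
         verdict = list(isolate_id = v$isolate_id, rank = v$rank,
                        assigned_genus = v$assigned_genus,
                        evidence = v$evidence, notes = v$notes),
         metric_table = x$metric_table, gc = x$gc,
         source_text = x$source_text),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a protologue back from JSON
#' @param path Path written by [protologue_to_json()].
#' @return A `protologue`.
#' @export
protologue_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  verdict <- structure(list(isolate_id = j$verdict$isolate_id,
                            rank = j$verdict$rank,
                            assigned_genus = j$verdict$assigned_genus,
                            evidence = as.data.frame(j$verdict$evidence),
                            notes = as.character(j$verdict$notes)),
                       class = "delineation_verdict")
  mt <- as.data.frame(j$metric_table)
  for (col in c("identity16S", "ani", "pocp", "dddh", "gc_diff"))
    mt[[col]] <- as.numeric(mt[[col]])
  structure(list(name_parts = unlist(j$name_parts), verdict = verdict,
                 metric_table = mt, gc = as.numeric(j$gc),
                 source_text = j$source_text),
            class = "protologue")
}

#' Match an isolate genome against MAG sketches
#'
#' Sketches the genome at the k and sketch size of the supplied
#' metagenome-assembled genome (MAG) sketches and reports all MAGs whose
#' MinHash distance is below the match threshold, sorted by distance.
#'
#' @param genome A `genome_record`.
#' @param mag_sketches List of `kmer_sketch` objects sharing one `k`.
#' @param thresholds A [delineation_thresholds()].
#' @return Data frame with columns `mag_id`, `distance` (possibly empty).
#' @export
mag_match <- function(genome, mag_sketches,
                      thresholds = delineation_thresholds()) {
  empty <- data.frame(mag_id = character(0), distance = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(mag_sketches) == 0L) return(empty)
  ks <- vapply(mag_sketches, `[[`, 0L, "k")
  if (length(unique(ks)) != 1L)
    stop("MAG sketches do not share one k", call. = FALSE)
  gsk <- kmer_sketch(genome, k = ks[1L], s = mag_sketches[[1L]]$s)
  d <- vapply(mag_sketches, sketch_distance, numeric(1), a = gsk)
  ids <- vapply(mag_sketches, `[[`, "", "source_id")
  keep <- d < thresholds$mag_match_distance
  out <- data.frame(mag_id = ids[keep], distance = d[keep],
                    stringsAsFactors = FALSE)
  out[order(out$distance, out$mag_id), , drop = FALSE]
}
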