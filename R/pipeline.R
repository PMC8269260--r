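#' Build a pipeline run configuration
#'
#' Collects input paths and parameter overrides for [run_pipeline()]. Unknown
#' keys are rejected; defaults equal the standard delineation thresholds and
#' amplicon parameters.
#'
#' @param out_dir Output directory.
#' @param collection Path to a collection metadata TSV (summarize stage).
#' @param isolate_16s,isolate_genome Paths to the isolate's 16S and genome
#'   FASTA files (delineate stage).
#' @param refs_dir Reference database directory (see
#'   [write_reference_db()]).
#' @param dddh Optional TSV of externally computed dDDH values
#'   (columns `relative_name`, `dddh`).
#' @param table,reps,members,groups Paths for the profile stage: abundance
#'   table TSV, representative-sequence FASTA, member-reference FASTA,
#'   sample-to-group TSV.
#' @param level `"otu"` or `"asv"` for the profile stage.
#' @param thresholds A [delineation_thresholds()].
#' @param params An [amplicon_params()].
#' @param orf_fallback Derive missing proteomes by six-frame ORF translation
#'   before POCP (off by default: naive ORF calls on diverged genomes bias
#'   POCP downward, and an absent metric is treated as no evidence).
#' @param seed Seed recorded in the manifest and used by any stage that
#'   draws random numbers.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, collection = NULL, isolate_16s = NULL,
                       isolate_genome = NULL, refs_dir = NULL, dddh = NULL,
                       table = NULL, reps = NULL, members = NULL,
                       groups = NULL, level = "otu",
                       thresholds = delineation_thresholds(),
                       params = amplicon_params(), orf_fallback = FALSE,
                       seed = 1L) {
  structure(list(out_dir = out_dir, collection = collection,
                 isolate_16s = isolate_16s, isolate_genome = isolate_genome,
                 refs_dir = refs_dir, dddh = dddh, table = table, reps = reps,
                 members = members, groups = groups, level = level,
                 thresholds = thresholds, params = params,
                 orf_fallback = isTRUE(as.logical(orf_fallback)),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a plain-text key=value run configuration
#'
#' Lines of the form `key = value`; `#` starts a comment. Threshold and
#' parameter overrides use dotted keys (e.g. `thresholds.species16S = 98.7`,
#' `params.min_rel_abundance = 0.25`). Unknown keys are rejected.
#'
#' @param path Config file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L], call. = FALSE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  plain <- c("out_dir", "collection", "isolate_16s", "isolate_genome",
             "refs_dir", "dddh", "table", "reps", "members", "groups",
             "level", "seed", "orf_fallback")
  th <- delineation_thresholds()
  pp <- amplicon_params()
  args <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (k %in% plain) {
      args[[k]] <- switch(k, seed = as.integer(vals[i]),
                          orf_fallback = as.logical(vals[i]), vals[i])
    } else if (startsWith(k, "thresholds.")) {
      f <- sub("^thresholds\\.", "", k)
      if (!f %in% names(th)) stop("unknown config key: ", k, call. = FALSE)
      th[[f]] <- as.numeric(strsplit(vals[i], ",")[[1L]])
    } else if (startsWith(k, "params.")) {
      f <- sub("^params\\.", "", k)
      if (!f %in% names(pp)) stop("unknown config key: ", k, call. = FALSE)
      pp[[f]] <- as.numeric(vals[i])
    } else {
      stop("unknown config key: ", k, call. = FALSE)
    }
  }
  if (is.null(args$out_dir)) stop("config lacks out_dir", call. = FALSE)
  args$thresholds <- th
  args$params <- pp
  do.call(run_config, args)
}

#' Run the delineation / profiling / summary pipeline
#'
#' Executes every stage whose inputs are configured: `summarize` (collection
#' tallies and novelty count), `delineate` (rank relatives, assemble metric
#' bundles, classify, write verdict and -- for novel taxa -- a protologue
#' scaffold), and `profile` (abundance filter, member matching, ecology,
#' alpha diversity, shared/unique taxa). Writes tab-separated reports plus a
#' JSON run manifest (inputs, all parameter values, package version, seed)
#' into the output directory. All inputs are checked before any computation.
#'
#' @param config A [run_config()].
#' @return A list of stage reports, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- Filter(Negate(is.null),
                   config[c("collection", "isolate_16s", "isolate_genome",
                            "dddh", "table", "reps", "members", "groups")])
  for (nm in names(inputs))
    if (!file.exists(inputs[[nm]]))
      stop("missing input for '", nm, "': ", inputs[[nm]], call. = FALSE)
  if (!is.null(config$refs_dir) &&
      !file.exists(file.path(config$refs_dir, "index.tsv")))
    stop("missing input for 'refs_dir': ", config$refs_dir, call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list()

  if (!is.null(config$collection)) {
    ct <- read_collection_table(config$collection)
    phyla <- tally_collection(ct, "phylum")
    families <- tally_collection(ct, "family")
    novel <- count_novel(ct, config$thresholds$species16S)
    write.table(phyla, file.path(config$out_dir, "tally_phylum.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(families, file.path(config$out_dir, "tally_family.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(as.character(novel),
               file.path(config$out_dir, "novelty_count.txt"))
    report$summarize <- list(phyla = phyla, families = families,
                             novelty_count = novel)
  }

  if (!is.null(config$isolate_16s) && !is.null(config$refs_dir)) {
    refs <- read_reference_db(config$refs_dir)
    iso16 <- read_fasta(config$isolate_16s, type = "dna")
    if (length(iso16) > 1L) {
      ## multi-copy 16S: reduce to the longest copy, flagged in the report
      pick <- which.max(Biostrings::width(iso16))
      multi_note <- sprintf("multi-copy 16S input: kept longest copy %s (%d of %d)",
                            names(iso16)[pick], pick, length(iso16))
      iso16 <- iso16[pick]
    } else multi_note <- NULL
    isolate <- list(id = names(iso16)[1L], sixteenS = as.character(iso16[[1L]]))
    if (!is.null(config$isolate_genome))
      isolate$genome <- read_genome(config$isolate_genome, id = isolate$id)
    dddh_tab <- NULL
    if (!is.null(config$dddh))
      dddh_tab <- read.delim(config$dddh, stringsAsFactors = FALSE)
    rel <- rank_relatives(isolate$sixteenS, refs, isolate_id = isolate$id)
    bundles <- lapply(rel$entries, function(r) {
      d <- NA_real_
      if (!is.null(dddh_tab)) {
        hit <- match(r$taxon_name, dddh_tab$relative_name)
        if (!is.na(hit)) d <- dddh_tab$dddh[hit]
      }
      assemble_metrics(isolate, r, dddh = d,
                       orf_fallback = config$orf_fallback)
    })
    verdict <- classify(bundles, config$thresholds)
    if (!is.null(multi_note)) verdict$notes <- c(verdict$notes, multi_note)
    bt <- do.call(rbind, lapply(bundles, function(b)
      data.frame(isolate_id = b$isolate_id, relative_name = b$relative_name,
                 genus = b$genus, identity16S = b$identity16S, ani = b$ani,
                 pocp = b$pocp,
                 pocp_is_to_type_species = b$pocp_is_to_type_species,
                 dddh = b$dddh, gc_diff = b$gc_diff,
                 stringsAsFactors = FALSE)))
    write.table(bt, file.path(config$out_dir, "metric_bundles.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(isolate_id = verdict$isolate_id, rank = verdict$rank,
           assigned_genus = verdict$assigned_genus,
           evidence = verdict$evidence, notes = verdict$notes),
      file.path(config$out_dir, "verdict.json"),
      auto_unbox = TRUE, digits = NA, na = "null")
    if (verdict$rank %in% c("novel_species", "novel_genus")) {
      gc <- if (!is.null(isolate$genome)) isolate$genome$gc else NA_real_
      protologue_to_json(
        protologue_scaffold(verdict, bundles, gc = gc),
        file.path(config$out_dir, "protologue.json"))
    }
    report$delineate <- list(verdict = verdict, bundles = bundles,
                             relatives = rel$ranked)
  }

  if (!is.null(config$table) && !is.null(config$reps) &&
      !is.null(config$members)) {
    tab <- read_abundance_table(config$table, groups_path = config$groups,
                                level = toupper(config$level))
    tab <- filter_low_abundance(tab, config$params)
    reps <- read_fasta(config$reps, type = "dna")
    members <- read_fasta(config$members, type = "dna")
    reps <- reps[names(reps) %in% rownames(tab$values)]
    hits <- match_members(members, reps, level = config$level,
                          params = config$params)
    eco <- ecology_profile(hits, tab, members = sort(names(members)))
    div <- alpha_diversity(tab)
    write.table(hits, file.path(config$out_dir, "member_hits.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(eco, file.path(config$out_dir, "ecology_profiles.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(div, file.path(config$out_dir, "alpha_diversity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$profile <- list(hits = hits, ecology = eco, diversity = div)
    if (!is.null(tab$groups) && length(unique(tab$groups)) >= 2L) {
      vc <- venn_counts(tab)
      jsonlite::write_json(list(unique = as.list(vc$unique),
                                shared = vc$shared, total = vc$total),
                           file.path(config$out_dir, "venn_counts.json"),
                           auto_unbox = TRUE, digits = NA)
      report$profile$venn <- vc
    }
  }

  manifest <- list(
    package = "polyphasic",
    version = as.character(utils::packageVersion("polyphasic")),
    seed = config$seed,
    inputs = inputs,
    refs_dir = config$refs_dir,
    thresholds = unclass(config$thresholds),
    amplicon_params = unclass(config$params),
    stages = names(report))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(report)
}
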