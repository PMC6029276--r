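## Merge the three tagged sequence sources (reference database export,
## genome-assembly-predicted genes, culture-collection strains) into one
## dataset, applying the lineage-congruence filter and the genome-usability
## filter, with a full accounting log.

#' Remove records with an incongruent asserted lineage
#'
#' A record is removed iff its lineage is non-empty and contains neither the
#' expected root clade nor any name on the allowed-clade list (by default the
#' expected root plus the designated outgroup clade). Records with an empty
#' lineage are trusted and kept: collection strains typically carry no
#' database lineage and must be retained.
#'
#' @param records record data.frame with a `lineage` list column.
#' @param expected_root taxon name the ingroup lineage must contain.
#' @param allowed_clades additional clade names that are accepted.
#' @return list with `kept` (records) and `removed_ids` (character).
#' @export
filter_incongruent <- function(records, expected_root,
                               allowed_clades = character()) {
  allowed <- unique(c(expected_root, allowed_clades))
  off <- vapply(records$lineage, function(lin) {
    length(lin) > 0 && !any(lin %in% allowed)
  }, logical(1))
  list(kept = records[!off, , drop = FALSE], removed_ids = records$id[off])
}

#' Drop genome-derived records that are unusable for the target clade
#'
#' Genome-source records whose lineage is off-clade are removed (assemblies
#' whose only predicted rRNA genes are non-target contaminants). Genome
#' accessions listed in the metadata with no sequence at all (rRNA-less
#' assemblies) are logged for accounting but nothing is removed from the
#' sequence set, since they never entered it.
#'
#' @param records joined record data.frame.
#' @param genomes_without_rrna data.frame of sequence-less genome metadata
#'   rows, as returned by [join_metadata()].
#' @inheritParams filter_incongruent
#' @return list with `kept`, `removed_ids` and `genomes_without_rrna`
#'   (data.frame of id, genome_accession, reason).
#' @export
drop_unusable_genomes <- function(records, expected_root,
                                  allowed_clades = character(),
                                  genomes_without_rrna = NULL) {
  allowed <- unique(c(expected_root, allowed_clades))
  is_gen <- !is.na(records$source) & records$source == "genome"
  off <- is_gen & vapply(records$lineage, function(lin) {
    length(lin) > 0 && !any(lin %in% allowed)
  }, logical(1))
  ghosts <- if (is.null(genomes_without_rrna) || !nrow(genomes_without_rrna)) {
    data.frame(id = character(0), genome_accession = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  } else {
    data.frame(id = genomes_without_rrna$id,
               genome_accession = genomes_without_rrna$genome_accession,
               reason = "no rRNA predicted", stringsAsFactors = FALSE)
  }
  list(kept = records[!off, , drop = FALSE], removed_ids = records$id[off],
       genomes_without_rrna = ghosts)
}

#' Merge the three sequence sources with filtering and accounting
#'
#' Concatenates the reference, genome and collection record sets, assigns
#' source tags from the argument slots, joins the metadata, applies the
#' lineage-congruence filter (reference and collection records) and the
#' genome-usability filter (genome records), and returns the merged records
#' together with a `merge_report` whose accounting identity
#' `n_output = sum(inputs) - n_removed_incongruent - n_removed_unusable_genomes`
#' is checked exactly.
#'
#' @param reference,genome,collection record data.frames (globally unique ids).
#' @param metadata optional metadata data.frame; when supplied, lineages and
#'   accessions are joined from it and its source column must agree with the
#'   argument slots.
#' @inheritParams filter_incongruent
#' @return list with `records` and `report` (class `merge_report`).
#' @export
merge_sources <- function(reference, genome, collection,
                          expected_root, allowed_clades = character(),
                          metadata = NULL) {
  sets <- list(reference = reference, genome = genome, collection = collection)
  sets <- Filter(function(x) !is.null(x) && nrow(x) > 0, sets)
  ids <- unlist(lapply(sets, `[[`, "id"), use.names = FALSE)
  if (anyDuplicated(ids))
    stop("id collision across sources: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  for (s in names(sets)) sets[[s]]$source <- s
  records <- do.call(rbind, c(unname(sets), list(make.row.names = FALSE)))

  ghosts <- NULL
  if (!is.null(metadata)) {
    j <- join_metadata(records[c("id", "sequence")], metadata)
    mism <- j$records$source != records$source[match(j$records$id, records$id)]
    if (any(mism))
      stop("metadata source disagrees with the source slot for: ",
           paste(j$records$id[mism], collapse = ", "), call. = FALSE)
    records <- j$records
    ghosts <- j$genomes_without_rrna
  }

  n_input <- vapply(SOURCE_LEVELS,
                    function(s) sum(records$source == s), integer(1))

  is_gen <- records$source == "genome"
  fi <- filter_incongruent(records[!is_gen, , drop = FALSE],
                           expected_root, allowed_clades)
  dg <- drop_unusable_genomes(records[is_gen, , drop = FALSE],
                              expected_root, allowed_clades,
                              genomes_without_rrna = ghosts)
  kept <- rbind(fi$kept, dg$kept, make.row.names = FALSE)
  kept <- kept[match(intersect(records$id, kept$id), kept$id), , drop = FALSE]
  rownames(kept) <- NULL

  removed <- rbind(
    if (length(fi$removed_ids))
      data.frame(id = fi$removed_ids, reason = "incongruent lineage",
                 stringsAsFactors = FALSE),
    if (length(dg$removed_ids))
      data.frame(id = dg$removed_ids, reason = "non-target rRNA",
                 stringsAsFactors = FALSE))
  if (is.null(removed))
    removed <- data.frame(id = character(0), reason = character(0),
                          stringsAsFactors = FALSE)

  report <- structure(list(
    n_input_per_source = n_input,
    n_removed_incongruent = length(fi$removed_ids),
    n_removed_unusable_genomes = length(dg$removed_ids),
    n_genomes_without_rrna = nrow(dg$genomes_without_rrna),
    n_output = nrow(kept),
    removed_ids = removed,
    genomes_without_rrna = dg$genomes_without_rrna
  ), class = "merge_report")

  if (report$n_output != sum(report$n_input_per_source) -
      report$n_removed_incongruent - report$n_removed_unusable_genomes)
    stop("merge accounting identity violated", call. = FALSE)
  if (anyDuplicated(report$removed_ids$id))
    stop("a removed id appears with more than one reason", call. = FALSE)

  list(records = kept, report = report)
}

#' @export
print.merge_report <- function(x, ...) {
  cat("Merge report\n")
  cat("  inputs:",
      paste(sprintf("%s=%d", names(x$n_input_per_source),
                    x$n_input_per_source), collapse = ", "), "\n")
  cat(sprintf("  removed: %d incongruent lineage, %d unusable genome record(s)\n",
              x$n_removed_incongruent, x$n_removed_unusable_genomes))
  cat(sprintf("  genome accessions without rRNA: %d\n",
              x$n_genomes_without_rrna))
  cat(sprintf("  output: %d records\n", x$n_output))
  invisible(x)
}

#' Write the merge accounting report as TSV
#' @export
write_merge_report <- function(report, path) {
  hdr <- sprintf("# inputs: %s | incongruent: %d | unusable_genomes: %d | genomes_without_rrna: %d | output: %d",
                 paste(sprintf("%s=%d", names(report$n_input_per_source),
                               report$n_input_per_source), collapse = ","),
                 report$n_removed_incongruent,
                 report$n_removed_unusable_genomes,
                 report$n_genomes_without_rrna, report$n_output)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(report$removed_ids, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
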