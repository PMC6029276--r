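## Readers/writers and validated containers for every on-disk artifact the
## pipeline touches: ungapped sequence FASTA, alignment FASTA (with '-'),
## tab-separated metadata, and Newick trees.

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "M", "R", "W", "S", "Y", "K",
                 "V", "H", "D", "B", "N")
SOURCE_LEVELS <- c("reference", "genome", "collection")

#' Normalize a nucleotide sequence
#'
#' Upper-cases, converts U to T, and collapses every IUPAC ambiguity code
#' other than A/C/G/T to N (identity and entropy computations downstream need
#' a single degenerate symbol). Gap characters and non-IUPAC symbols are hard
#' errors reporting the offending position.
#'
#' @param x character vector of sequences.
#' @param ids optional identifiers used in error messages.
#' @return character vector of normalized sequences over \{A,C,G,T,N\}.
#' @export
normalize_sequence <- function(x, ids = NULL) {
  if (is.null(ids)) ids <- seq_along(x)
  x <- toupper(x)
  bad <- regexpr(sprintf("[^%s]", paste(IUPAC_CHARS, collapse = "")), x)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    ch <- substr(x[i], bad[i], bad[i])
    stop(sprintf("invalid character '%s' at position %d in sequence '%s'",
                 ch, bad[i], ids[i]), call. = FALSE)
  }
  x <- chartr("U", "T", x)
  gsub("[MRWSYKVHDB]", "N", x)
}

#' Assemble a validated set of sequence records
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param sequence character vector of nucleotide sequences (normalized).
#' @param source optional source tag per record (reference/genome/collection).
#' @param lineage optional list of character vectors (ordered taxon names).
#' @param genome_accession optional character vector (NA when absent).
#' @return a data.frame with columns id, sequence, source, lineage (list
#'   column), genome_accession.
#' @export
seq_records <- function(id, sequence, source = NA_character_,
                        lineage = NULL, genome_accession = NA_character_) {
  id <- as.character(id)
  if (any(!nzchar(id))) stop("empty record identifier", call. = FALSE)
  dup <- id[duplicated(id)]
  if (length(dup))
    stop("duplicate record identifier(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(sequence)))
    stop("empty sequence for record(s): ",
         paste(id[!nzchar(sequence)], collapse = ", "), call. = FALSE)
  sequence <- normalize_sequence(sequence, id)
  if (is.null(lineage)) lineage <- rep(list(character(0)), length(id))
  source <- rep_len(as.character(source), length(id))
  known <- is.na(source) | source %in% SOURCE_LEVELS
  if (!all(known))
    stop("unknown source value(s): ",
         paste(unique(source[!known]), collapse = ", "), call. = FALSE)
  genome_accession <- rep_len(as.character(genome_accession), length(id))
  if (any(!is.na(genome_accession) & !is.na(source) & source != "genome"))
    stop("genome_accession present implies source = genome", call. = FALSE)
  out <- data.frame(id = id, sequence = sequence, source = source,
                    genome_accession = genome_accession,
                    stringsAsFactors = FALSE)
  out$lineage <- lineage
  out
}

#' Read ungapped sequences from a FASTA file
#'
#' One record per FASTA entry, in file order; U is normalized to T and
#' ambiguity codes to N. Gap characters, duplicate identifiers and empty
#' sequences are hard errors. Metadata (source, lineage, accession) is joined
#' separately from a TSV file, not parsed from headers.
#'
#' @param path FASTA file.
#' @return record data.frame as from [seq_records()].
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  sq <- as.character(ss)
  ids <- sub("\\s.*$", "", names(ss))
  if (any(grepl("-", sq, fixed = TRUE))) {
    i <- which(grepl("-", sq, fixed = TRUE))[1]
    stop(sprintf("gap character in ungapped FASTA, record '%s'", ids[i]),
         call. = FALSE)
  }
  seq_records(ids, sq)
}

#' Write sequences to FASTA
#'
#' @param x record data.frame or a named character vector of sequences.
#' @param path output file (UTF-8, Unix line endings).
#' @param width line wrap width.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.data.frame(x)) x <- setNames(x$sequence, x$id)
  ss <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a gapped alignment from FASTA
#'
#' @param path alignment FASTA (rows may contain '-').
#' @return a validated alignment: named character vector of equal-length
#'   gapped sequences over \{A,C,G,T,N,-\}.
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  sq <- toupper(as.character(ss))
  sq <- chartr("U", "T", sq)
  sq <- gsub("[MRWSYKVHDB]", "N", sq)
  as_alignment(setNames(sq, ids))
}

#' Validate an alignment container
#'
#' All rows must have identical length, identifiers must be unique, rows must
#' contain at least one non-gap character, and the alphabet is \{A,C,G,T,N,-\}.
#'
#' @param x named character vector of gapped rows.
#' @return the validated alignment (invisibly identical to `x`).
#' @export
as_alignment <- function(x) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("alignment rows must be named", call. = FALSE)
  if (anyDuplicated(names(x)))
    stop("duplicate alignment row identifier(s): ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "),
         call. = FALSE)
  w <- nchar(x)
  if (length(unique(w)) != 1L)
    stop("alignment rows have unequal lengths", call. = FALSE)
  bad <- regexpr("[^ACGTN-]", x)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("invalid alignment character at column %d of row '%s'",
                 bad[i], names(x)[i]), call. = FALSE)
  }
  allgap <- !grepl("[ACGTN]", x)
  if (any(allgap))
    stop("all-gap alignment row(s): ",
         paste(names(x)[allgap], collapse = ", "), call. = FALSE)
  x
}

#' @export
write_alignment <- function(x, path, width = 70L) {
  write_fasta(x, path, width = width)
}

# alignment as a character matrix (rows = sequences)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln), "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

matrix_aln <- function(m) {
  as_alignment(setNames(apply(m, 1L, paste, collapse = ""), rownames(m)))
}

#' Read the per-record metadata table
#'
#' Tab-separated with header columns `id`, `source`, `lineage`
#' (semicolon-delimited ranks) and `genome_accession`. Lineage entries are
#' split on ";" with surrounding whitespace stripped; a missing accession is
#' allowed. An unknown source value is a hard error.
#'
#' @param path TSV file.
#' @return data.frame with columns id, source, lineage (list column),
#'   genome_accession.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, colClasses = "character",
                          na.strings = c("", "NA"), stringsAsFactors = FALSE)
  need <- c("id", "source", "lineage", "genome_accession")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- !md$source %in% SOURCE_LEVELS
  if (any(bad))
    stop("unknown source value(s): ",
         paste(unique(md$source[bad]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(md$id))
    stop("duplicate metadata id(s): ",
         paste(unique(md$id[duplicated(md$id)]), collapse = ", "),
         call. = FALSE)
  lin <- lapply(md$lineage, function(s) {
    if (is.na(s) || !nzchar(s)) return(character(0))
    trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  out <- md[c("id", "source", "genome_accession")]
  out$lineage <- lin
  out
}

#' Write a metadata table
#' @export
write_metadata <- function(md, path) {
  out <- data.frame(
    id = md$id, source = md$source,
    lineage = vapply(md$lineage, paste, "", collapse = ";"),
    genome_accession = ifelse(is.na(md$genome_accession), "",
                              md$genome_accession),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Join metadata onto sequence records
#'
#' The join is total on the sequence side: every record must have a metadata
#' row, and every non-genome metadata row must have a record. Genome-source
#' metadata rows without a sequence (assemblies whose rRNA genes could not be
#' predicted) are tolerated and returned separately for accounting.
#'
#' @param records record data.frame (sequences).
#' @param metadata data.frame from [read_metadata()].
#' @return list with `records` (source/lineage/accession filled in) and
#'   `genomes_without_rrna` (data.frame of id, genome_accession).
#' @export
join_metadata <- function(records, metadata) {
  m <- match(records$id, metadata$id)
  if (anyNA(m))
    stop("records without metadata row: ",
         paste(records$id[is.na(m)], collapse = ", "), call. = FALSE)
  orphan <- setdiff(metadata$id, records$id)
  oi <- match(orphan, metadata$id)
  nong <- orphan[metadata$source[oi] != "genome"]
  if (length(nong))
    stop("metadata id(s) absent from the sequence set: ",
         paste(nong, collapse = ", "), call. = FALSE)
  ghosts <- metadata[metadata$id %in% orphan, c("id", "genome_accession"),
                     drop = FALSE]
  records$source <- metadata$source[m]
  records$lineage <- metadata$lineage[m]
  records$genome_accession <- metadata$genome_accession[m]
  list(records = records, genomes_without_rrna = ghosts)
}

#' Read a Newick tree
#'
#' Standard Newick, optionally with branch lengths and internal labels.
#' Unbalanced parentheses and duplicate leaf labels are hard errors; negative
#' branch lengths are rejected.
#'
#' @param path Newick file.
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("malformed Newick in '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("malformed Newick in '", path, "'", call. = FALSE)
  validate_tree(tr)
}

#' @export
validate_tree <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a phylo tree", call. = FALSE)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "),
         call. = FALSE)
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch length", call. = FALSE)
  tr
}

#' Write a Newick tree
#'
#' Labels matching `[A-Za-z0-9_.|-]+` are written unquoted; branch lengths are
#' serialized with 10 significant digits so a parse/serialize round trip is
#' stable.
#'
#' @param tree phylo object.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}
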