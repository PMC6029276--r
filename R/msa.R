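## Align OTU representative sequences into a curated seed alignment without
## perturbing the seed's column structure (consensus threading), then trim
## columns by entropy and gap content.

#' Majority-rule consensus of an alignment
#'
#' The gap is treated as a fifth state: a column whose gap fraction exceeds
#' 0.5 gets a gap consensus; otherwise the most frequent base among A/C/G/T
#' wins (ties broken in A < C < G < T order; N is excluded from the counts,
#' and a column with gaps <= 0.5 but no A/C/G/T base at all gets N).
#'
#' @param seed alignment (named character vector of gapped rows).
#' @return a single consensus string of the seed's column count.
#' @export
consensus_profile <- function(seed) {
  m <- aln_matrix(seed)
  nr <- nrow(m)
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(m == b), numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L,
                                      dimnames = list(NULL, bases))
  gapfrac <- colSums(m == "-") / nr
  best <- bases[max.col(counts, ties.method = "first")]
  best[rowSums(counts) == 0] <- "N"
  cons <- ifelse(gapfrac > 0.5, "-", best)
  paste(cons, collapse = "")
}

#' Thread new sequences into a seed alignment
#'
#' Each new (gap-free) sequence is aligned to the seed's majority-rule
#' consensus with the same ends-free scoring used for identity computation.
#' Residues aligned to consensus bases are threaded into those bases' seed
#' columns; residues falling in insertions relative to the consensus are
#' dropped (no new columns are opened; downstream trimming would remove such
#' sparse columns anyway). The output has exactly the seed's column count and
#' the seed rows are byte-identical to the input. A sequence with fewer than
#' half of its residues placeable is rejected with a warning and listed in
#' the skip report.
#'
#' @param seed alignment (named character vector).
#' @param new_records record data.frame (id, sequence; ids disjoint from the
#'   seed's).
#' @return list with `alignment` (seed rows followed by the new rows) and
#'   `skipped` (data.frame id, placed_fraction).
#' @export
extend_alignment <- function(seed, new_records) {
  seed <- as_alignment(seed)
  if (any(new_records$id %in% names(seed)))
    stop("new record id(s) collide with seed ids: ",
         paste(intersect(new_records$id, names(seed)), collapse = ", "),
         call. = FALSE)
  if (any(grepl("-", new_records$sequence, fixed = TRUE)))
    stop("new sequences must be gap-free", call. = FALSE)
  cons <- consensus_profile(seed)
  cons_cols <- which(strsplit(cons, "")[[1]] != "-")
  cons_ungapped <- gsub("-", "", cons, fixed = TRUE)
  if (!nzchar(cons_ungapped))
    stop("seed consensus is all gaps", call. = FALSE)
  ncol_seed <- nchar(seed[[1]])

  rows <- character(0)
  skipped <- data.frame(id = character(0), placed_fraction = numeric(0),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(new_records))) {
    id <- new_records$id[i]
    sq <- new_records$sequence[i]
    al <- overlap_align_cpp(sq, cons_ungapped, TRUE)
    row <- rep("-", ncol_seed)
    placed <- 0L
    if (nzchar(al$aligned_a)) {
      aa <- strsplit(al$aligned_a, "")[[1]]
      ab <- strsplit(al$aligned_b, "")[[1]]
      jpos <- al$b_start - 1L  # consensus position before the current column
      for (t in seq_along(aa)) {
        if (ab[t] != "-") jpos <- jpos + 1L
        if (aa[t] != "-" && ab[t] != "-") {
          row[cons_cols[jpos]] <- aa[t]
          placed <- placed + 1L
        }
      }
    }
    frac <- placed / nchar(sq)
    if (frac < 0.5) {
      warning(sprintf("sequence '%s' skipped: only %.0f%% of its residues are placeable",
                      id, 100 * frac), call. = FALSE)
      skipped <- rbind(skipped,
                       data.frame(id = id, placed_fraction = frac,
                                  stringsAsFactors = FALSE))
    } else {
      rows <- c(rows, setNames(paste(row, collapse = ""), id))
    }
  }
  list(alignment = as_alignment(c(seed, rows)), skipped = skipped)
}

#' Per-column entropy and gap scores
#'
#' Entropy is plain Shannon entropy of the observed A/C/G/T frequencies,
#' normalized by log(4) so it lies in [0, 1]; N and '-' are excluded from the
#' entropy but '-' counts toward the gap fraction (gaps / rows). A column
#' with zero bases gets entropy 1. A column is kept iff
#' entropy <= entropy_cutoff and gap_fraction <= gap_cutoff.
#'
#' @param alignment alignment (named character vector).
#' @param entropy_cutoff maximum normalized entropy (default 0.5).
#' @param gap_cutoff maximum gap fraction (default 0.2).
#' @return data.frame with columns entropy, gap_fraction, kept (one row per
#'   alignment column).
#' @export
score_columns <- function(alignment, entropy_cutoff = 0.5, gap_cutoff = 0.2) {
  m <- aln_matrix(as_alignment(alignment))
  nr <- nrow(m)
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(m == b), numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L)
  tot <- rowSums(counts)
  p <- counts / ifelse(tot > 0, tot, 1)
  h <- -rowSums(ifelse(p > 0, p * log(p), 0)) / log(4)
  h[tot == 0] <- 1
  gapfrac <- colSums(m == "-") / nr
  data.frame(entropy = h, gap_fraction = gapfrac,
             kept = h <= entropy_cutoff & gapfrac <= gap_cutoff)
}

#' Trim alignment columns by entropy and gap content
#'
#' Keeps exactly the columns passing both cutoffs, in original order. Rows
#' that become all-gap are removed and reported. The missing-character
#' fraction of the trimmed alignment (gaps + N over cells) is reported as
#' well.
#'
#' @inheritParams score_columns
#' @return list with `alignment` (trimmed), `kept_columns` (0-based indices),
#'   `removed_rows` (ids), `missing_fraction`.
#' @export
trim_alignment <- function(alignment, entropy_cutoff = 0.5, gap_cutoff = 0.2) {
  alignment <- as_alignment(alignment)
  sc <- score_columns(alignment, entropy_cutoff, gap_cutoff)
  keep <- which(sc$kept)
  if (!length(keep)) stop("no conserved sites", call. = FALSE)
  m <- aln_matrix(alignment)[, keep, drop = FALSE]
  rows <- apply(m, 1L, paste, collapse = "")
  allgap <- !grepl("[ACGTN]", rows)
  removed <- names(alignment)[allgap]
  rows <- rows[!allgap]
  trimmed <- as_alignment(setNames(rows, names(alignment)[!allgap]))
  mk <- aln_matrix(trimmed)
  list(alignment = trimmed,
       kept_columns = keep - 1L,
       removed_rows = removed,
       missing_fraction = mean(mk == "-" | mk == "N"))
}
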