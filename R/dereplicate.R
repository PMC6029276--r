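## Greedy identity-threshold clustering of merged records into OTUs with
## asymmetric coverage control (cd-hit-est semantics: identity denominator is
## the shorter sequence; coverage thresholds apply separately to the longer
## and the shorter sequence), then promotion of genome-backed members to
## cluster representatives so that phylogenomic constraints can be enforced
## on the tree.

#' Identity and coverage of a pair of sequences
#'
#' Computes an ends-free global alignment (match +1, mismatch -1, a gap of
#' length L costs 2 + (L-1); leading/trailing gaps free) and reports
#' identity = identical aligned positions / length of the shorter sequence,
#' plus the aligned (non-terminal-gap) span of each sequence divided by its
#' own length. N never counts as a match. Among equally scoring alignments
#' the one with the most matches is used, so the statistic is deterministic.
#'
#' @param a,b ungapped nucleotide sequences (single strings).
#' @return list with `identity`, `cov_longer`, `cov_shorter` in [0, 1].
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  if (grepl("-", a, fixed = TRUE) || grepl("-", b, fixed = TRUE))
    stop("gapped sequence passed to pairwise_identity", call. = FALSE)
  al <- overlap_align_cpp(a, b, FALSE)
  na <- nchar(a); nb <- nchar(b)
  span_a <- max(0L, al$a_end - al$a_start + 1L)
  span_b <- max(0L, al$b_end - al$b_start + 1L)
  cov_a <- span_a / na
  cov_b <- span_b / nb
  shorter_is_b <- nb <= na
  list(identity = al$matches / min(na, nb),
       cov_longer = if (shorter_is_b) cov_a else cov_b,
       cov_shorter = if (shorter_is_b) cov_b else cov_a)
}

identity_gates_pass <- function(ir, threshold, cov_short_min, cov_long_min) {
  ir$identity >= threshold && ir$cov_shorter >= cov_short_min &&
    ir$cov_longer >= cov_long_min
}

#' Greedy identity clustering with coverage control
#'
#' Records are sorted by length (descending) then id (ascending); each record
#' joins the first existing cluster whose representative satisfies
#' identity >= threshold, shorter-sequence coverage >= cov_short_min and
#' longer-sequence coverage >= cov_long_min, otherwise it founds a new
#' cluster with itself as representative. Deterministic for fixed input. All
#' candidate representatives are checked by alignment (no k-mer prescreen),
#' so the result matches the greedy definition exactly.
#'
#' @param records record data.frame (id, sequence).
#' @param threshold identity threshold (default 0.975).
#' @param cov_short_min minimum aligned fraction of the shorter sequence
#'   (default 0.9).
#' @param cov_long_min minimum aligned fraction of the longer sequence
#'   (default 0.0).
#' @return an object of class `otu_clusters`: list of clusters, each with
#'   `representative_id` and `member_ids`, plus the parameters used.
#' @export
greedy_cluster <- function(records, threshold = 0.975,
                           cov_short_min = 0.9, cov_long_min = 0.0) {
  if (nrow(records) < 1L) stop("no records to cluster", call. = FALSE)
  ord <- order(-nchar(records$sequence), records$id, method = "radix")
  ids <- records$id[ord]
  seqs <- records$sequence[ord]
  rep_ids <- character(0)
  rep_seqs <- character(0)
  members <- list()
  # When cov_short_min <= threshold and cov_long_min = 0 the identity gate
  # alone decides membership: the shorter sequence's aligned span is at least
  # its match count, so identity >= threshold forces cov_shorter >= threshold
  # >= cov_short_min. The match-count kernel is then exact and much cheaper
  # than span tracking.
  fast <- cov_short_min <= threshold && cov_long_min == 0
  for (i in seq_along(ids)) {
    placed <- FALSE
    for (k in seq_along(rep_ids)) {
      if (fast) {
        al <- overlap_matches_cpp(rep_seqs[k], seqs[i])
        pass <- al$matches / min(nchar(rep_seqs[k]), nchar(seqs[i])) >=
          threshold
      } else {
        ir <- pairwise_identity(rep_seqs[k], seqs[i])
        pass <- identity_gates_pass(ir, threshold, cov_short_min,
                                    cov_long_min)
      }
      if (pass) {
        members[[k]] <- c(members[[k]], ids[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_ids <- c(rep_ids, ids[i])
      rep_seqs <- c(rep_seqs, seqs[i])
      members <- c(members, list(ids[i]))
    }
  }
  clusters <- Map(function(r, m) list(representative_id = r, member_ids = m,
                                      genome_backed = NA),
                  rep_ids, members)
  structure(list(clusters = unname(clusters),
                 params = list(threshold = threshold,
                               cov_short_min = cov_short_min,
                               cov_long_min = cov_long_min)),
            class = "otu_clusters")
}

validate_clusters <- function(cs, input_ids = NULL) {
  mem <- unlist(lapply(cs$clusters, `[[`, "member_ids"), use.names = FALSE)
  if (anyDuplicated(mem))
    stop("cluster membership is not a partition (duplicated member)",
         call. = FALSE)
  reps <- vapply(cs$clusters, `[[`, "", "representative_id")
  in_own <- mapply(function(cl) cl$representative_id %in% cl$member_ids,
                   cs$clusters)
  if (!all(in_own))
    stop("representative not a member of its own cluster", call. = FALSE)
  if (!is.null(input_ids) && !setequal(mem, input_ids))
    stop("cluster membership does not cover the input id set", call. = FALSE)
  invisible(cs)
}

#' Flag clusters that contain a genome-derived member
#'
#' @param clusters `otu_clusters` object.
#' @param metadata joined metadata/record data.frame with a `source` column.
#' @return the clusters with `genome_backed` set per cluster.
#' @export
set_cluster_genome_flags <- function(clusters, metadata) {
  src <- setNames(metadata$source, metadata$id)
  clusters$clusters <- lapply(clusters$clusters, function(cl) {
    cl$genome_backed <- any(src[cl$member_ids] == "genome", na.rm = TRUE)
    cl
  })
  clusters
}

#' Promote genome-derived members to cluster representatives
#'
#' In every cluster that contains at least one genome-source member but whose
#' current representative is not genome-source, the representative is
#' replaced by a genome-source member (longest first, then id ascending).
#' The partition is unchanged. This is what lets the phylogenomic backbone be
#' enforced later: backbone taxa are genome sequences, so those sequences
#' must be the OTUs that reach the tree.
#'
#' @param clusters `otu_clusters` object.
#' @param metadata joined metadata/record data.frame (id, source, sequence).
#' @return list with `clusters` (flags set, representatives promoted) and
#'   `n_replaced`.
#' @export
promote_genome_representatives <- function(clusters, metadata) {
  src <- setNames(metadata$source, metadata$id)
  len <- setNames(nchar(metadata$sequence), metadata$id)
  n_replaced <- 0L
  clusters$clusters <- lapply(clusters$clusters, function(cl) {
    gen <- cl$member_ids[src[cl$member_ids] == "genome" &
                           !is.na(src[cl$member_ids])]
    cl$genome_backed <- length(gen) > 0
    if (length(gen) && !(cl$representative_id %in% gen)) {
      ord <- order(-len[gen], gen, method = "radix")
      cl$representative_id <- gen[ord][1]
      n_replaced <<- n_replaced + 1L
    }
    cl
  })
  list(clusters = clusters, n_replaced = n_replaced)
}

#' @export
cluster_table <- function(clusters) {
  do.call(rbind, lapply(seq_along(clusters$clusters), function(k) {
    cl <- clusters$clusters[[k]]
    data.frame(cluster_id = k, representative_id = cl$representative_id,
               member_id = cl$member_ids,
               is_genome_backed = isTRUE(cl$genome_backed),
               stringsAsFactors = FALSE)
  }))
}

#' @export
write_clusters <- function(clusters, path) {
  utils::write.table(cluster_table(clusters), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
representative_ids <- function(clusters) {
  vapply(clusters$clusters, `[[`, "", "representative_id")
}

#' Map member ids to their cluster index
#' @export
cluster_membership <- function(clusters) {
  mem <- lapply(clusters$clusters, `[[`, "member_ids")
  setNames(rep(seq_along(mem), lengths(mem)), unlist(mem, use.names = FALSE))
}

#' @export
print.otu_clusters <- function(x, ...) {
  nb <- sum(vapply(x$clusters, function(cl) isTRUE(cl$genome_backed),
                   logical(1)))
  cat(sprintf("%d OTU cluster(s) over %d record(s); %d genome-backed\n",
              length(x$clusters),
              length(unlist(lapply(x$clusters, `[[`, "member_ids"))), nb))
  invisible(x)
}
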