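## Root the tree on the outgroup, collapse OTUs into named clusters, and
## compute the headline statistic: the sequenced genome fraction per cluster,
## the strict "<1% => unsequenced" classification, and cohort summaries over
## the sequenced clusters.

UNSEQUENCED_CUTOFF <- 0.01

#' Root a tree on a monophyletic outgroup
#'
#' If the outgroup forms a clan of the unrooted tree, the root is placed at
#' the midpoint of the edge subtending it; otherwise a hard error lists the
#' intruding taxa.
#'
#' @param tree phylo tree (rooted or unrooted; treated as unrooted).
#' @param outgroup_taxa non-empty proper subset of the leaves.
#' @return a rooted phylo tree whose two root children are the outgroup clan
#'   and the ingroup.
#' @export
root_on_outgroup <- function(tree, outgroup_taxa) {
  tips <- tree$tip.label
  if (!length(outgroup_taxa) || !all(outgroup_taxa %in% tips))
    stop("outgroup taxa must be a non-empty subset of the leaves",
         call. = FALSE)
  if (setequal(outgroup_taxa, tips))
    stop("outgroup cannot be the whole leaf set", call. = FALSE)
  utree <- ape::unroot(tree)
  if (is.null(utree$edge.length))
    utree$edge.length <- rep(1, nrow(utree$edge))
  B <- split_matrix(utree)
  utree <- attr(B, "tree")
  og <- tips %in% outgroup_taxa
  hit <- which(apply(B, 1L, function(side) all(side == og) ||
                       all(side == !og)))
  if (!length(hit)) {
    ing <- setdiff(tips, outgroup_taxa)[1]
    rooted <- ape::root(utree, outgroup = ing, resolve.root = TRUE)
    mrca <- ape::getMRCA(rooted, outgroup_taxa)
    under <- rooted$tip.label[phangorn::Descendants(rooted, mrca,
                                                    "tips")[[1]]]
    stop("outgroup is not monophyletic; intruding taxa: ",
         paste(setdiff(under, outgroup_taxa), collapse = ", "),
         call. = FALSE)
  }
  e <- hit[1]
  node <- utree$edge[e, 2]
  len <- utree$edge.length[e]
  # make sure the chosen child-side is the outgroup side
  side_is_og <- all(B[e, ] == og)
  if (!side_is_og && length(outgroup_taxa) == 1L)
    node <- which(tips == outgroup_taxa)
  rooted <- phytools::reroot(utree, node.number = node, position = len / 2)
  validate_tree(rooted)
}

#' Collapse OTUs into labelled clusters on a rooted tree
#'
#' For each cluster label, the OTU set is reported with a monophyly flag
#' (TRUE iff the MRCA of the set subtends no other-labelled leaf).
#' Paraphyletic labels are kept whole as single records flagged FALSE, not
#' split into monophyletic pieces: the label, not the subtree, is the unit.
#'
#' @param rooted_tree rooted phylo tree.
#' @param label_map named character vector OTU id -> cluster label, total on
#'   the ingroup OTUs.
#' @param outgroup_taxa leaves excluded from collapsing.
#' @return data.frame with columns cluster_label, otu_ids (list column),
#'   monophyletic.
#' @export
collapse_clusters <- function(rooted_tree, label_map,
                              outgroup_taxa = character()) {
  ingroup <- setdiff(rooted_tree$tip.label, outgroup_taxa)
  unlabeled <- setdiff(ingroup, names(label_map))
  if (length(unlabeled))
    stop("unlabeled ingroup OTU(s): ", paste(unlabeled, collapse = ", "),
         call. = FALSE)
  labs <- label_map[ingroup]
  out <- lapply(sort(unique(labs), method = "radix"), function(lb) {
    set <- ingroup[labs == lb]
    mono <- if (length(set) == 1L) TRUE else {
      mrca <- ape::getMRCA(rooted_tree, set)
      under <- rooted_tree$tip.label[
        phangorn::Descendants(rooted_tree, mrca, "tips")[[1]]]
      setequal(under, set)
    }
    list(cluster_label = lb, otu_ids = set, monophyletic = mono)
  })
  df <- data.frame(
    cluster_label = vapply(out, `[[`, "", "cluster_label"),
    monophyletic = vapply(out, `[[`, NA, "monophyletic"),
    stringsAsFactors = FALSE)
  df$otu_ids <- lapply(out, `[[`, "otu_ids")
  if (sum(lengths(df$otu_ids)) != length(ingroup))
    stop("cluster collapsing lost or duplicated OTUs", call. = FALSE)
  df
}

#' Sequenced genome fraction of one OTU set
#'
#' numerator = OTUs whose dereplication cluster contains a genome-derived
#' sequence; denominator = all OTUs in the set. A clade is "unsequenced" iff
#' its fraction is strictly below 1%.
#'
#' @param otu_set character vector of OTU (representative) ids.
#' @param clusters `otu_clusters` object with genome flags set.
#' @return list with n_otus, n_genome_backed_otus, fraction, status.
#' @export
sequenced_fraction <- function(otu_set, clusters) {
  if (!length(otu_set)) stop("empty OTU set", call. = FALSE)
  mem <- cluster_membership(clusters)
  miss <- setdiff(otu_set, names(mem))
  if (length(miss))
    stop("OTU(s) absent from the cluster set: ",
         paste(miss, collapse = ", "), call. = FALSE)
  gb <- vapply(clusters$clusters, function(cl) isTRUE(cl$genome_backed),
               logical(1))
  n <- length(otu_set)
  ng <- sum(gb[mem[otu_set]])
  frac <- ng / n
  list(n_otus = n, n_genome_backed_otus = ng, fraction = frac,
       status = if (frac < UNSEQUENCED_CUTOFF) "unsequenced" else "sequenced")
}

#' Summarize per-clade records into a coverage report
#'
#' Unsequenced = fraction strictly below 1%. The min/median/IQR summary is
#' computed over the sequenced clades only (a minimum of 1% is only possible
#' once zero-genome clades are excluded); quantiles use linear interpolation
#' (R type 7).
#'
#' @param clades data.frame with cluster_label, n_otus,
#'   n_genome_backed_otus, fraction, status, monophyletic.
#' @return object of class `coverage_report`.
#' @export
summarize_coverage <- function(clades) {
  if (!nrow(clades)) stop("no clades to summarize", call. = FALSE)
  stopifnot(all(clades$n_genome_backed_otus <= clades$n_otus))
  stopifnot(all(abs(clades$fraction -
                      clades$n_genome_backed_otus / clades$n_otus) < 1e-12))
  seqd <- clades$fraction[clades$status == "sequenced"]
  summ <- if (length(seqd)) {
    q <- stats::quantile(seqd, c(0.25, 0.75), type = 7, names = FALSE)
    list(min = min(seqd), median = stats::median(seqd), iqr = q[2] - q[1])
  } else list(min = NA_real_, median = NA_real_, iqr = NA_real_)
  structure(list(
    clades = clades,
    n_unsequenced = sum(clades$status == "unsequenced"),
    n_total_clusters = nrow(clades),
    summary_over_sequenced = summ
  ), class = "coverage_report")
}

#' Full coverage report from a rooted tree, clusters and a label map
#'
#' @inheritParams collapse_clusters
#' @param clusters `otu_clusters` with genome flags.
#' @return `coverage_report` object.
#' @export
coverage_report <- function(rooted_tree, clusters, label_map,
                            outgroup_taxa = character()) {
  col <- collapse_clusters(rooted_tree, label_map, outgroup_taxa)
  fr <- lapply(col$otu_ids, sequenced_fraction, clusters = clusters)
  clades <- data.frame(
    cluster_label = col$cluster_label,
    n_otus = vapply(fr, `[[`, 0L, "n_otus"),
    n_genome_backed_otus = vapply(fr, `[[`, 0L, "n_genome_backed_otus"),
    fraction = vapply(fr, `[[`, 0, "fraction"),
    status = vapply(fr, `[[`, "", "status"),
    monophyletic = col$monophyletic,
    stringsAsFactors = FALSE)
  clades$otu_ids <- col$otu_ids
  summarize_coverage(clades)
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("Coverage report: %d cluster(s), %d unsequenced (<1%%)\n",
              x$n_total_clusters, x$n_unsequenced))
  s <- x$summary_over_sequenced
  if (!is.na(s$median))
    cat(sprintf("  sequenced clusters: min = %.1f%%, median = %.1f%%, IQR = %.1f%%\n",
                100 * s$min, 100 * s$median, 100 * s$iqr))
  df <- x$clades
  df$fraction <- sprintf("%.3f", df$fraction)
  print(df[, c("cluster_label", "n_otus", "n_genome_backed_otus",
               "fraction", "status", "monophyletic")], row.names = FALSE)
  invisible(x)
}

#' Write the coverage report as TSV (with a summary footer) and JSON
#' @export
write_coverage_report <- function(report, path_tsv, path_json = NULL) {
  df <- report$clades
  df$fraction <- sprintf("%.3f", df$fraction)
  con <- file(path_tsv, "w")
  writeLines("# quantiles: linear interpolation (type 7); unsequenced: fraction < 0.01 (strict)", con)
  utils::write.table(df[, c("cluster_label", "n_otus",
                            "n_genome_backed_otus", "fraction", "status",
                            "monophyletic")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  s <- report$summary_over_sequenced
  writeLines(sprintf("# n_unsequenced=%d n_total=%d min=%.4f median=%.4f iqr=%.4f",
                     report$n_unsequenced, report$n_total_clusters,
                     s$min, s$median, s$iqr), con)
  close(con)
  if (!is.null(path_json)) {
    out <- list(clades = report$clades[, c("cluster_label", "n_otus",
                                           "n_genome_backed_otus",
                                           "fraction", "status",
                                           "monophyletic")],
                n_unsequenced = report$n_unsequenced,
                n_total_clusters = report$n_total_clusters,
                summary_over_sequenced = s)
    jsonlite::write_json(out, path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(path_tsv)
}

#' Annotated/collapsed Newick of the coverage result
#'
#' Monophyletic clusters are collapsed to a single tip labelled
#' `label|n_otus|n_genome|fraction` (mirroring the bracket annotation
#' convention of collapsed published trees); paraphyletic clusters keep their
#' tips, renamed `label.otu`.
#'
#' @param rooted_tree rooted phylo tree.
#' @param report `coverage_report`.
#' @param outgroup_taxa outgroup leaves (kept as-is).
#' @return phylo tree.
#' @export
collapse_coverage_tree <- function(rooted_tree, report,
                                   outgroup_taxa = character()) {
  tr <- rooted_tree
  clades <- report$clades
  rename <- character(0)
  for (i in seq_len(nrow(clades))) {
    ids <- clades$otu_ids[[i]]
    tag <- sprintf("%s|%d|%d|%.3f", clades$cluster_label[i],
                   clades$n_otus[i], clades$n_genome_backed_otus[i],
                   clades$fraction[i])
    if (clades$monophyletic[i]) {
      if (length(ids) > 1L) tr <- ape::drop.tip(tr, ids[-1])
      rename[ids[1]] <- tag
    } else {
      rename[ids] <- sprintf("%s.%s", clades$cluster_label[i], ids)
    }
  }
  hit <- tr$tip.label %in% names(rename)
  tr$tip.label[hit] <- unname(rename[tr$tip.label[hit]])
  tr
}
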