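## End-to-end pipeline: simulate (or load) a study, merge the sources,
## dereplicate into OTUs, promote genome representatives, extend the seed
## alignment, trim, compute distances, build the backbone-constrained tree,
## root on the outgroup and produce the coverage report, with a run manifest
## recording every stage count. Any invariant violation is a hard error.

#' Pipeline configuration
#'
#' All numeric parameters of the stages with their standard defaults
#' (identity 0.975, coverage 0.9/0.0, entropy 0.5, gaps 0.2, unsequenced
#' cutoff 0.01) plus the synthetic-study configuration. Validation happens
#' before any stage runs.
#'
#' @param study `study_config` for the synthetic generator.
#' @param identity_threshold dereplication identity threshold.
#' @param cov_short_min minimum aligned fraction of the shorter sequence.
#' @param cov_long_min minimum aligned fraction of the longer sequence.
#' @param entropy_cutoff trimming entropy cutoff.
#' @param gap_cutoff trimming gap cutoff.
#' @param seed integer seed (propagated to the study config).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(study = study_config(seed = seed),
                            identity_threshold = 0.975,
                            cov_short_min = 0.9, cov_long_min = 0.0,
                            entropy_cutoff = 0.5, gap_cutoff = 0.2,
                            seed = 1L) {
  cfg <- list(study = study,
              identity_threshold = identity_threshold,
              cov_short_min = cov_short_min, cov_long_min = cov_long_min,
              entropy_cutoff = entropy_cutoff, gap_cutoff = gap_cutoff,
              seed = as.integer(seed))
  for (p in c("identity_threshold", "cov_short_min", "cov_long_min",
              "entropy_cutoff", "gap_cutoff")) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1)
      stop(sprintf("parameter '%s' must lie in [0, 1]", p), call. = FALSE)
  }
  stopifnot(inherits(study, "study_config"))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys override [pipeline_config()] arguments; the `study` mapping
#' overrides [study_config()] arguments.
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  study_args <- y$study %||% list()
  y$study <- NULL
  if (!is.null(y$seed) && is.null(study_args$seed))
    study_args$seed <- y$seed
  do.call(pipeline_config,
          c(y, list(study = do.call(study_config, study_args))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline on a synthetic study
#'
#' Executes every stage in order and checks the hard invariants (merge
#' accounting, cluster partition, seed preservation, backbone-constraint
#' preservation, coverage partition). Reruns with the same configuration are
#' byte-identical.
#'
#' @param config `pipeline_config` (or a path to a YAML file).
#' @param bundle optionally a pre-built study bundle (from
#'   [simulate_study()]); by default one is simulated from the config.
#' @param out_dir optional directory where all artifacts are persisted.
#' @return list with the study `bundle`, `merge` (records + report),
#'   `clusters`, `n_promoted`, `alignment` (extended), `trim`, `dm`, `tree`,
#'   `rooted`, `coverage` and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), bundle = NULL,
                         out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(bundle)) bundle <- simulate_study(config$study)

  ## merge the three tagged sources
  recs <- bundle$records
  md <- bundle$metadata
  src <- setNames(md$source, md$id)[recs$id]
  split_recs <- function(s) {
    r <- recs[src == s, c("id", "sequence"), drop = FALSE]
    seq_records(r$id, r$sequence)
  }
  merged <- merge_sources(split_recs("reference"), split_recs("genome"),
                          split_recs("collection"),
                          expected_root = config$study$expected_root,
                          allowed_clades = config$study$outgroup_clade,
                          metadata = md)

  ## dereplicate into OTUs and promote genome representatives
  clusters <- greedy_cluster(merged$records,
                             threshold = config$identity_threshold,
                             cov_short_min = config$cov_short_min,
                             cov_long_min = config$cov_long_min)
  validate_clusters(clusters, merged$records$id)
  pr <- promote_genome_representatives(clusters, merged$records)
  clusters <- pr$clusters
  reps <- representative_ids(clusters)
  rep_seqs <- merged$records[match(reps, merged$records$id),
                             c("id", "sequence")]

  ## extend the seed alignment with the OTU representatives and trim
  ext <- extend_alignment(bundle$seed_alignment, rep_seqs)
  if (nrow(ext$skipped))
    stop("OTU representative(s) could not be placed in the seed alignment: ",
         paste(ext$skipped$id, collapse = ", "), call. = FALSE)
  tr <- trim_alignment(ext$alignment, config$entropy_cutoff,
                       config$gap_cutoff)

  ## distances over OTU representatives only (seed-only rows are
  ## scaffolding). Distances are computed on the full extended alignment,
  ## not the entropy-trimmed one: trimming discards fast-evolving sites,
  ## which under a homogeneous-rate distance compresses deep divergences
  ## nonlinearly and breaks tree additivity. The trimmed alignment is still
  ## produced and reported as the conserved-site quality summary.
  rep_rows <- ext$alignment[names(ext$alignment) %in% reps]
  dm <- distance_matrix(rep_rows)

  ## backbone constraint: rename species-level backbone tips to the genome
  ## record that represents them (that is why representatives were promoted)
  backbone <- bundle$backbone
  backbone$tip.label <- unname(bundle$backbone_map[backbone$tip.label])
  if (anyNA(backbone$tip.label))
    stop("backbone species without a genome record", call. = FALSE)
  avail <- intersect(backbone$tip.label, rownames(dm))
  backbone <- prune_constraint(backbone, avail)

  ## the outgroup is constrained to stay monophyletic: rooting on it
  ## presupposes that, so it is prior knowledge of the same standing as the
  ## phylogenomic backbone
  outgroup <- intersect(bundle$outgroup_ids, rownames(dm))
  tree <- constrained_build(backbone, dm, monophyletic_group = outgroup)
  chk <- check_constraint(tree, backbone)
  if (!chk$ok)
    stop("backbone constraint violated: ",
         paste(chk$violated, collapse = "; "), call. = FALSE)

  ## root on the outgroup and compute coverage
  rooted <- root_on_outgroup(tree, outgroup)
  label_map <- bundle$label_map
  cov <- coverage_report(rooted, clusters, label_map, outgroup)

  manifest <- list(
    parameters = list(
      identity_threshold = config$identity_threshold,
      cov_short_min = config$cov_short_min,
      cov_long_min = config$cov_long_min,
      entropy_cutoff = config$entropy_cutoff,
      gap_cutoff = config$gap_cutoff,
      unsequenced_cutoff = UNSEQUENCED_CUTOFF,
      seed = config$study$seed),
    n_input_per_source = as.list(merged$report$n_input_per_source),
    n_removed_incongruent = merged$report$n_removed_incongruent,
    n_removed_unusable_genomes = merged$report$n_removed_unusable_genomes,
    n_genomes_without_rrna = merged$report$n_genomes_without_rrna,
    n_merged = merged$report$n_output,
    n_otus = length(reps),
    n_promoted = pr$n_replaced,
    n_alignment_rows = length(ext$alignment),
    n_trimmed_sites = length(tr$kept_columns),
    missing_fraction = tr$missing_fraction,
    n_tree_leaves = ape::Ntip(tree),
    n_backbone_leaves = ape::Ntip(backbone),
    constraint_ok = chk$ok,
    n_clusters = cov$n_total_clusters,
    n_unsequenced = cov$n_unsequenced)

  out <- list(bundle = bundle, merge = merged, clusters = clusters,
              n_promoted = pr$n_replaced, alignment = ext$alignment,
              trim = tr, dm = dm, tree = tree, rooted = rooted,
              coverage = cov, manifest = manifest)
  if (!is.null(out_dir)) persist_pipeline(out, out_dir)
  out
}

persist_pipeline <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_study(res$bundle, file.path(dir, "study"))
  write_fasta(res$merge$records, file.path(dir, "merged.fasta"))
  write_merge_report(res$merge$report, file.path(dir, "merge_report.tsv"))
  write_clusters(res$clusters, file.path(dir, "clusters.tsv"))
  write_alignment(res$alignment, file.path(dir, "extended.afa"))
  write_alignment(res$trim$alignment, file.path(dir, "trimmed.afa"))
  utils::write.table(data.frame(kept_column = res$trim$kept_columns),
                     file.path(dir, "kept_columns.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_distance_matrix(res$dm, file.path(dir, "distances.tsv"))
  write_newick(res$tree, file.path(dir, "tree.nwk"))
  write_newick(res$rooted, file.path(dir, "rooted.nwk"))
  write_coverage_report(res$coverage, file.path(dir, "coverage.tsv"),
                        file.path(dir, "coverage.json"))
  write_newick(collapse_coverage_tree(res$rooted, res$coverage,
                                      intersect(res$bundle$outgroup_ids,
                                                res$rooted$tip.label)),
               file.path(dir, "collapsed.nwk"))
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
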