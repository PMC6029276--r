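## Generation of complete synthetic studies with known ground truth: a Yule
## species tree with an outgroup clan, K80/HKY sequence evolution along it,
## database-style records (near-duplicate replicates per species, three
## source tags, clade-structured genome availability, off-clade decoys,
## rRNA-less genome accessions), a seed alignment and a backbone constraint
## tree over genome-backed species.

#' Study configuration with shipped defaults
#'
#' The defaults define the study conditions used throughout the test suite:
#' 60 ingroup species in 12 clades, an 8-species outgroup clan, a 20-taxon
#' backbone over genome-backed species, 1-4 database replicates per species
#' at 0.3% within-species divergence, 800 bp sequences, a species tree of
#' 0.15 substitutions/site root-to-tip depth with a 0.06 terminal stem added
#' per species (which separates species pairs by at least ~0.12
#' substitutions/site, far above the 2.5% dereplication radius), an outgroup
#' joined by a 0.3 stem, and genome probabilities of 0 for 4 clades and 0.85
#' for the rest. Clades with a positive genome probability are guaranteed at
#' least one genome-backed species, so "unsequenced" ground truth is exactly
#' the zero-probability clades.
#'
#' @param n_species number of ingroup species.
#' @param replicates_per_species integer range (min, max) of database records
#'   per species.
#' @param within_species_divergence per-site substitution probability applied
#'   to each non-genome replicate.
#' @param seq_length sites per sequence.
#' @param n_clades number of clade labels the ingroup is cut into.
#' @param genome_prob_per_clade per-clade probability that a species has a
#'   sequenced genome (recycled to `n_clades`).
#' @param backbone_size taxa in the backbone constraint tree (drawn from
#'   genome-backed species only).
#' @param outgroup_size species in the outgroup clan.
#' @param seed integer seed; the whole bundle is deterministic under it.
#' @param birth_rate Yule birth rate for the raw species tree.
#' @param tree_depth root-to-tip depth (substitutions/site) the ingroup tree
#'   is rescaled to.
#' @param species_stem extra terminal branch length per ingroup species.
#' @param outgroup_depth root-to-tip depth of the outgroup clan.
#' @param outgroup_stem stem length joining the outgroup clan to the root.
#' @param kappa HKY transition/transversion rate ratio (equal base
#'   frequencies).
#' @param n_incongruent off-clade decoy records added to the reference set.
#' @param n_rnaless_genomes genome accessions listed in the metadata with no
#'   sequence.
#' @param seed_fraction fraction of species represented in the seed
#'   alignment.
#' @param expected_root ingroup clade name used in lineages.
#' @param outgroup_clade outgroup clade name used in lineages.
#' @return a validated list of class `study_config`.
#' @export
study_config <- function(n_species = 60L,
                         replicates_per_species = c(1L, 4L),
                         within_species_divergence = 0.003,
                         seq_length = 800L,
                         n_clades = 12L,
                         genome_prob_per_clade = rep(c(0, 0.85), c(4, 8)),
                         backbone_size = 20L,
                         outgroup_size = 8L,
                         seed = 1L,
                         birth_rate = 1,
                         tree_depth = 0.15,
                         species_stem = 0.06,
                         outgroup_depth = 0.05,
                         outgroup_stem = 0.3,
                         kappa = 2,
                         n_incongruent = 2L,
                         n_rnaless_genomes = 2L,
                         seed_fraction = 0.6,
                         expected_root = "Cyanobacteria",
                         outgroup_clade = "Melainabacteria") {
  cfg <- list(n_species = as.integer(n_species),
              replicates_per_species = as.integer(replicates_per_species),
              within_species_divergence = within_species_divergence,
              seq_length = as.integer(seq_length),
              n_clades = as.integer(n_clades),
              genome_prob_per_clade =
                rep_len(genome_prob_per_clade, n_clades),
              backbone_size = as.integer(backbone_size),
              outgroup_size = as.integer(outgroup_size),
              seed = as.integer(seed),
              birth_rate = birth_rate, tree_depth = tree_depth,
              species_stem = species_stem,
              outgroup_depth = outgroup_depth,
              outgroup_stem = outgroup_stem, kappa = kappa,
              n_incongruent = as.integer(n_incongruent),
              n_rnaless_genomes = as.integer(n_rnaless_genomes),
              seed_fraction = seed_fraction,
              expected_root = expected_root,
              outgroup_clade = outgroup_clade)
  stopifnot(cfg$n_species >= 3L, cfg$n_clades <= cfg$n_species,
            cfg$outgroup_size >= 1L,
            all(cfg$genome_prob_per_clade >= 0),
            all(cfg$genome_prob_per_clade <= 1),
            cfg$within_species_divergence >= 0,
            cfg$within_species_divergence < 1,
            length(cfg$replicates_per_species) == 2L,
            cfg$replicates_per_species[1] >= 1L,
            diff(cfg$replicates_per_species) >= 0L,
            cfg$seq_length >= 1L, cfg$birth_rate > 0, cfg$kappa > 0,
            cfg$seed_fraction > 0, cfg$seed_fraction <= 1)
  structure(cfg, class = "study_config")
}

#' Simulate a pure-birth (Yule) species tree
#'
#' Starts from two lineages at the root; with k lineages alive the next
#' split waits an Exp(k * birth_rate) time and a uniformly chosen lineage
#' splits, until n leaves exist; a final Exp(n * birth_rate) wait gives the
#' terminal segment, so the expected root-to-tip depth is
#' sum_{k=2..n} 1/(k * birth_rate). Deterministic under the seed.
#'
#' @param n_species number of leaves (>= 3).
#' @param birth_rate birth rate (> 0).
#' @param seed integer seed.
#' @param prefix tip label prefix.
#' @return phylo tree.
#' @export
simulate_yule_tree <- function(n_species, birth_rate = 1, seed = 1L,
                               prefix = "t") {
  stopifnot(n_species >= 3L, birth_rate > 0)
  set.seed(seed)
  # node bookkeeping: children and birth times; active lineages carry their
  # start time
  children <- list()
  start <- numeric(0)
  new_node <- function(t0) {
    start[length(start) + 1L] <<- t0
    children[[length(start)]] <<- integer(0)
    length(start)
  }
  root <- new_node(0)
  active <- c(new_node(0), new_node(0))
  children[[root]] <- active
  t <- 0
  k <- 2L
  end_len <- numeric(0)
  while (k < n_species) {
    t <- t + rexp(1, rate = k * birth_rate)
    i <- sample.int(k, 1L)
    v <- active[i]
    a <- new_node(t); b <- new_node(t)
    children[[v]] <- c(a, b)
    active <- c(active[-i], a, b)
    k <- k + 1L
  }
  t_end <- t + rexp(1, rate = k * birth_rate)
  labels <- setNames(character(0), character(0))
  tip_counter <- 0L
  to_newick <- function(v) {
    if (length(children[[v]]) == 0L) {
      tip_counter <<- tip_counter + 1L
      lab <- sprintf("%s%03d", prefix, tip_counter)
      return(sprintf("%s:%.10g", lab, t_end - start[v]))
    }
    kids <- vapply(children[[v]], to_newick, "")
    end_v <- start[children[[v]][1]]
    len <- if (v == root) 0 else end_v - start[v]
    sprintf("(%s):%.10g", paste(kids, collapse = ","), len)
  }
  nwk <- paste0(to_newick(root), ";")
  tr <- ape::read.tree(text = nwk)
  validate_tree(tr)
}

# rescale a tree so the maximum root-to-tip depth equals `depth`
scale_tree_depth <- function(tree, depth) {
  d <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * depth / d
  tree
}

# add a constant to every terminal branch
add_terminal_stem <- function(tree, stem) {
  tip_edges <- tree$edge[, 2] <= ape::Ntip(tree)
  tree$edge.length[tip_edges] <- tree$edge.length[tip_edges] + stem
  tree
}

K80_CODES <- c("A", "C", "G", "T")
TS_PARTNER <- c(3L, 4L, 1L, 2L)          # A<->G, C<->T
TV_PARTNERS <- rbind(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 3L))

# K80 transition probabilities for branch length t (substitutions/site)
k80_probs <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  c(same = 0.25 + 0.25 * e1 + 0.5 * e2,
    ts = 0.25 + 0.25 * e1 - 0.5 * e2,
    tv = 0.25 - 0.25 * e1)  # each of the two transversion targets
}

#' Evolve sequences along a tree under the HKY model
#'
#' Equal base frequencies (so effectively K80), transition/transversion rate
#' ratio `kappa`, branch lengths in substitutions/site, no indels; the root
#' sequence is uniform random and each branch applies the exact transition
#' probabilities per site.
#'
#' @param tree phylo tree with branch lengths.
#' @param seq_length sites.
#' @param kappa transition/transversion rate parameter (> 0).
#' @param seed integer seed.
#' @return named character vector of leaf sequences.
#' @export
evolve_sequences <- function(tree, seq_length, kappa = 2, seed = 1L) {
  stopifnot(kappa > 0, seq_length >= 1)
  set.seed(seed)
  tree <- stats::reorder(tree, "cladewise")
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- sample.int(4L, seq_length, replace = TRUE)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    t <- tree$edge.length[e]
    s <- seqs[[par]]
    if (t > 0) {
      pr <- k80_probs(t, kappa)
      u <- runif(seq_length)
      mut_ts <- u >= pr["same"] & u < pr["same"] + pr["ts"]
      mut_tv <- u >= pr["same"] + pr["ts"]
      if (any(mut_ts)) s[mut_ts] <- TS_PARTNER[s[mut_ts]]
      if (any(mut_tv)) {
        pick <- 1L + (runif(sum(mut_tv)) < 0.5)
        s[mut_tv] <- TV_PARTNERS[cbind(seqs[[par]][mut_tv], pick)]
      }
    }
    seqs[[ch]] <- s
  }
  out <- vapply(seq_len(ntip), function(i)
    paste(K80_CODES[seqs[[i]]], collapse = ""), "")
  setNames(out, tree$tip.label)
}

# substitute each site with probability q (uniform random different base)
mutate_sequence <- function(sq, q) {
  s <- match(strsplit(sq, "")[[1]], K80_CODES)
  hit <- which(runif(length(s)) < q & !is.na(s))
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    s[hit] <- ((s[hit] - 1L + shift) %% 4L) + 1L
  }
  out <- K80_CODES[s]
  out[is.na(s)] <- "N"
  paste(out, collapse = "")
}

# cut a tree into n monophyletic groups by repeatedly splitting the largest
# group at its root; returns species -> label ("cladeXX" in tip order)
cut_tree_clades <- function(tree, n_clades) {
  tree <- stats::reorder(tree, "cladewise")
  ntip <- ape::Ntip(tree)
  tips_under <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(tree$edge[tree$edge[, 1] == node, 2], tips_under))
  }
  groups <- lapply(tree$edge[tree$edge[, 1] == ntip + 1L, 2], tips_under)
  while (length(groups) < n_clades) {
    sizes <- lengths(groups)
    splittable <- which(sizes > 1L)
    if (!length(splittable))
      stop("cannot cut the tree into that many clades", call. = FALSE)
    g <- splittable[which.max(sizes[splittable])]
    tipset <- groups[[g]]
    node <- ape::getMRCA(tree, tree$tip.label[tipset])
    parts <- lapply(tree$edge[tree$edge[, 1] == node, 2], tips_under)
    groups <- c(groups[-g], parts)
  }
  first_tip <- vapply(groups, min, 0L)
  groups <- groups[order(first_tip)]
  lab <- character(ntip)
  for (i in seq_along(groups))
    lab[groups[[i]]] <- sprintf("clade%02d", i)
  setNames(lab, tree$tip.label)
}

#' Build database-style records from leaf sequences
#'
#' Per species, 1 to `replicates_per_species[2]` records are emitted; each
#' non-genome record is independently mutated at the within-species
#' divergence. Species are flagged genome-backed with their clade's
#' probability (a clade with positive probability is redrawn until it has at
#' least one flagged species, so planted "sequenced" clades are guaranteed);
#' a flagged species' first record is the unmutated genome-source sequence
#' with an accession. The remaining records are reference or collection
#' sources at 9:1. Outgroup species contribute one reference record each.
#' Off-clade decoy records and sequence-less genome accessions are added per
#' the configuration.
#'
#' @param leaf_sequences named character vector from [evolve_sequences()]
#'   over ingroup and outgroup species.
#' @param clade_labels named character vector species -> clade label.
#' @param outgroup_species character vector of outgroup species names.
#' @param config `study_config`.
#' @param seed integer seed.
#' @return list with `records` (id, sequence), `metadata`, `label_map`
#'   (record id -> clade label), `truth` (species flags/labels/fractions and
#'   per-species record ids).
#' @export
make_database_records <- function(leaf_sequences, clade_labels,
                                  outgroup_species, config, seed = 1L) {
  set.seed(seed)
  species <- setdiff(names(leaf_sequences), outgroup_species)
  labels <- clade_labels[species]
  clades <- sort(unique(labels), method = "radix")
  probs <- setNames(config$genome_prob_per_clade[seq_along(clades)], clades)

  flags <- setNames(logical(length(species)), species)
  for (cl in clades) {
    sp <- species[labels == cl]
    p <- probs[[cl]]
    if (p == 0) next
    repeat {
      f <- runif(length(sp)) < p
      if (any(f)) break
    }
    flags[sp] <- f
  }

  ids <- character(0); seqs <- character(0)
  src <- character(0); acc <- character(0); lin <- list()
  species_of <- character(0)
  rng <- config$replicates_per_species
  for (sp in species) {
    m <- if (rng[1] == rng[2]) rng[1] else
      sample.int(rng[2] - rng[1] + 1L, 1L) + rng[1] - 1L
    base <- leaf_sequences[[sp]]
    lineage <- c("Bacteria", config$expected_root, clade_labels[[sp]])
    for (r in seq_len(m)) {
      if (flags[[sp]] && r == 1L) {
        ids <- c(ids, sprintf("%s_g", sp))
        seqs <- c(seqs, base)
        src <- c(src, "genome")
        acc <- c(acc, sprintf("GCA_%s", sp))
      } else {
        ids <- c(ids, sprintf("%s_r%d", sp, r))
        seqs <- c(seqs, mutate_sequence(base, config$within_species_divergence))
        src <- c(src, if (runif(1) < 0.9) "reference" else "collection")
        acc <- c(acc, NA_character_)
      }
      lin <- c(lin, list(lineage))
      species_of <- c(species_of, sp)
    }
  }
  for (sp in outgroup_species) {
    ids <- c(ids, sprintf("%s_r1", sp))
    seqs <- c(seqs, leaf_sequences[[sp]])
    src <- c(src, "reference")
    acc <- c(acc, NA_character_)
    lin <- c(lin, list(c("Bacteria", config$outgroup_clade)))
    species_of <- c(species_of, sp)
  }
  for (i in seq_len(config$n_incongruent)) {
    ids <- c(ids, sprintf("decoy%02d", i))
    seqs <- c(seqs, paste(sample(K80_CODES, config$seq_length,
                                 replace = TRUE), collapse = ""))
    src <- c(src, "reference")
    acc <- c(acc, NA_character_)
    lin <- c(lin, list(c("Bacteria", "Proteobacteria")))
    species_of <- c(species_of, NA_character_)
  }

  metadata <- data.frame(id = ids, source = src, genome_accession = acc,
                         stringsAsFactors = FALSE)
  metadata$lineage <- lin
  if (config$n_rnaless_genomes > 0) {
    ghost <- data.frame(
      id = sprintf("ghost%02d_g", seq_len(config$n_rnaless_genomes)),
      source = "genome",
      genome_accession = sprintf("GCA_ghost%02d",
                                 seq_len(config$n_rnaless_genomes)),
      stringsAsFactors = FALSE)
    ghost$lineage <- rep(list(c("Bacteria", config$expected_root)),
                         nrow(ghost))
    metadata <- rbind(metadata, ghost)
  }

  ing <- !is.na(species_of) & species_of %in% species
  label_map <- setNames(unname(clade_labels[species_of[ing]]), ids[ing])
  true_fractions <- vapply(clades, function(cl)
    mean(flags[species[labels == cl]]), 0)
  list(records = data.frame(id = ids, sequence = seqs,
                            stringsAsFactors = FALSE),
       metadata = metadata,
       label_map = label_map,
       truth = list(species_of = setNames(species_of, ids),
                    genome_flags = flags,
                    clade_labels = clade_labels,
                    true_fractions = true_fractions))
}

#' Derive the seed alignment and backbone constraint tree
#'
#' The seed alignment is the true (simulated, indel-free) alignment of one
#' sequence per species for a stratified species subset, under row ids
#' `seed_<species>`. The backbone is the true ingroup tree restricted to a
#' stratified subset of genome-backed species, emulating a correct
#' phylogenomic constraint.
#'
#' @param ingroup_tree true ingroup phylo tree (species labels).
#' @param leaf_sequences named leaf sequences.
#' @param genome_flags named logical vector per species.
#' @param config `study_config`.
#' @return list with `seed` (alignment) and `backbone` (phylo over species
#'   labels).
#' @export
derive_seed_and_backbone <- function(ingroup_tree, leaf_sequences,
                                     genome_flags, config) {
  sp_order <- ingroup_tree$tip.label
  n_seed <- max(3L, ceiling(length(sp_order) * config$seed_fraction))
  pick <- sp_order[unique(round(seq(1, length(sp_order),
                                    length.out = n_seed)))]
  seed <- setNames(unname(leaf_sequences[pick]), sprintf("seed_%s", pick))

  flagged <- sp_order[genome_flags[sp_order]]
  if (length(flagged) < config$backbone_size)
    stop(sprintf("only %d genome-backed species but backbone_size = %d",
                 length(flagged), config$backbone_size), call. = FALSE)
  bb <- flagged[unique(round(seq(1, length(flagged),
                                 length.out = config$backbone_size)))]
  backbone <- ape::drop.tip(ingroup_tree, setdiff(sp_order, bb))
  list(seed = as_alignment(seed), backbone = backbone)
}

#' Simulate a complete synthetic study with known truth
#'
#' @param config `study_config`.
#' @return a bundle: `records`, `metadata`, `seed_alignment`, `backbone`
#'   (species labels), `backbone_map` (species -> genome record id),
#'   `outgroup_ids` (record ids), `label_map`, `truth` (includes the full
#'   true tree), and `config`.
#' @export
simulate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  s <- config$seed
  ig <- simulate_yule_tree(config$n_species, config$birth_rate, seed = s,
                           prefix = "sp")
  ig <- add_terminal_stem(scale_tree_depth(ig, config$tree_depth),
                          config$species_stem)
  og <- if (config$outgroup_size >= 3L) {
    t <- simulate_yule_tree(config$outgroup_size, config$birth_rate,
                            seed = s + 1L, prefix = "og")
    scale_tree_depth(t, config$outgroup_depth)
  } else if (config$outgroup_size == 2L) {
    ape::read.tree(text = sprintf("(og001:%.6f,og002:%.6f);",
                                  config$outgroup_depth,
                                  config$outgroup_depth))
  } else NULL
  ig_nwk <- sub(";$", "", ape::write.tree(ig))
  full_nwk <- if (is.null(og)) {
    sprintf("(%s:0.02,og001:%.6f);", ig_nwk, config$outgroup_stem)
  } else {
    sprintf("(%s:0.02,%s:%.6f);", ig_nwk,
            sub(";$", "", ape::write.tree(og)), config$outgroup_stem)
  }
  full_tree <- ape::read.tree(text = full_nwk)
  outgroup_species <- grep("^og", full_tree$tip.label, value = TRUE)

  leaf_seqs <- evolve_sequences(full_tree, config$seq_length, config$kappa,
                                seed = s + 2L)
  clade_labels <- cut_tree_clades(ig, config$n_clades)
  db <- make_database_records(leaf_seqs, clade_labels, outgroup_species,
                              config, seed = s + 3L)
  sb <- derive_seed_and_backbone(ig, leaf_seqs, db$truth$genome_flags,
                                 config)
  flagged <- names(db$truth$genome_flags)[db$truth$genome_flags]
  backbone_map <- setNames(sprintf("%s_g", flagged), flagged)
  og_ids <- sprintf("%s_r1", outgroup_species)

  truth <- db$truth
  truth$true_tree <- full_tree
  truth$ingroup_tree <- ig
  list(records = db$records, metadata = db$metadata,
       seed_alignment = sb$seed, backbone = sb$backbone,
       backbone_map = backbone_map, outgroup_ids = og_ids,
       label_map = db$label_map, truth = truth, config = config)
}

#' Write a study bundle to a directory as plain-text artifacts
#'
#' Emits sequence FASTA, metadata TSV, seed alignment FASTA, backbone
#' Newick, outgroup id list, label map TSV and a truth JSON.
#'
#' @param bundle from [simulate_study()].
#' @param dir output directory (created if needed).
#' @export
write_study <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$records, file.path(dir, "sequences.fasta"))
  write_metadata(bundle$metadata, file.path(dir, "metadata.tsv"))
  write_alignment(bundle$seed_alignment, file.path(dir, "seed.afa"))
  write_newick(bundle$backbone, file.path(dir, "backbone.nwk"))
  writeLines(bundle$outgroup_ids, file.path(dir, "outgroup.txt"))
  utils::write.table(
    data.frame(id = names(bundle$label_map), label = bundle$label_map),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  truth <- bundle$truth
  jsonlite::write_json(
    list(genome_flags = as.list(truth$genome_flags),
         clade_labels = as.list(truth$clade_labels),
         true_fractions = as.list(truth$true_fractions),
         species_of = as.list(truth$species_of),
         true_tree = ape::write.tree(truth$true_tree)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
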