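## Backbone-constrained tree building. The full tree over all OTUs must
## induce, on the backbone taxa, exactly the splits of the given phylogenomic
## constraint tree. Inference is distance-based minimum evolution: taxa are
## inserted greedily at the edge minimizing the balanced minimum-evolution
## (BME, Pauplin-weight) total, followed by NNI hill-climbing and leaf
## re-placement sweeps on the same criterion, rejecting any rearrangement
## whose induced backbone topology would lose a backbone split. Branch
## lengths of the final topology are fitted by unweighted least squares
## (OLS) and clamped at zero.

#' Prune a constraint tree to the available taxa
#'
#' Leaves not in `available_taxa` are removed; degree-2 internal nodes are
#' suppressed with their branch lengths summed.
#'
#' @param backbone phylo tree with >= 4 leaves.
#' @param available_taxa character set of taxa that survive.
#' @return the pruned phylo tree.
#' @export
prune_constraint <- function(backbone, available_taxa) {
  if (ape::Ntip(backbone) < 4L)
    stop("backbone must have at least 4 leaves", call. = FALSE)
  drop <- setdiff(backbone$tip.label, available_taxa)
  keepn <- ape::Ntip(backbone) - length(drop)
  if (keepn < 3L)
    stop("fewer than 3 backbone leaves survive pruning", call. = FALSE)
  if (!length(drop)) return(backbone)
  ape::drop.tip(backbone, drop)
}

# Edge-by-leaf indicator matrix: B[e, l] is TRUE iff leaf l lies on the
# child side of edge e (edges in the tree's postorder edge ordering).
# Columns follow `labels` (defaults to the tree's tips); absent labels give
# all-FALSE columns, which lets a common label universe be shared.
split_matrix <- function(tree, labels = tree$tip.label) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  E <- nrow(tree$edge)
  desc <- matrix(FALSE, ntip + nnode, length(labels))
  colnames(desc) <- labels
  tipcol <- match(tree$tip.label, labels)
  if (anyNA(tipcol)) stop("tree tips missing from the label universe",
                          call. = FALSE)
  desc[cbind(seq_len(ntip), tipcol)] <- TRUE
  B <- matrix(FALSE, E, length(labels))
  colnames(B) <- labels
  for (e in seq_len(E)) {
    ch <- tree$edge[e, 2]
    B[e, ] <- desc[ch, ]
    desc[tree$edge[e, 1], ] <- desc[tree$edge[e, 1], ] | desc[ch, ]
  }
  attr(B, "tree") <- tree
  B
}

# canonical string keys of the nontrivial bipartitions induced on `taxa`
canonical_splits <- function(B, taxa) {
  sub <- B[, taxa, drop = FALSE]
  anchor <- sort(taxa)[1]
  n <- length(taxa)
  keys <- apply(sub, 1L, function(side) {
    k <- sum(side)
    if (k < 2L || k > n - 2L) return(NA_character_)
    if (side[anchor]) side <- !side
    paste(sort(taxa[side]), collapse = "|")
  })
  unique(keys[!is.na(keys)])
}

#' Nontrivial bipartitions of a tree
#'
#' One bipartition per internal edge of the unrooted view; trivial splits
#' (singleton side) are excluded. Splits are returned as canonical string
#' keys (the side not containing the alphabetically first taxon, sorted and
#' "|"-joined).
#'
#' @param tree phylo tree.
#' @return character vector of canonical split keys.
#' @export
backbone_splits <- function(tree) {
  canonical_splits(split_matrix(ape::unroot(tree)), tree$tip.label)
}

#' Check that a tree preserves a backbone constraint
#'
#' TRUE iff every nontrivial backbone split is a split of the tree restricted
#' to the backbone taxa.
#'
#' @param tree phylo tree whose leaves are a superset of the backbone's.
#' @param backbone constraint phylo tree.
#' @return list with `ok` (logical) and `violated` (character split keys).
#' @export
check_constraint <- function(tree, backbone) {
  if (!all(backbone$tip.label %in% tree$tip.label))
    stop("backbone leaves missing from the tree: ",
         paste(setdiff(backbone$tip.label, tree$tip.label), collapse = ", "),
         call. = FALSE)
  want <- backbone_splits(backbone)
  have <- canonical_splits(split_matrix(ape::unroot(tree)),
                           backbone$tip.label)
  violated <- setdiff(want, have)
  list(ok = length(violated) == 0L, violated = violated)
}

# OLS branch lengths for a fixed topology, given a distance matrix covering
# its tips. Returns list(lengths (per postorder edge), total, tree
# (postorder, with unclamped lengths attached)).
ols_fit_tree <- function(tree, dm) {
  B <- split_matrix(tree)
  tree <- attr(B, "tree")
  labs <- tree$tip.label
  fit <- ols_fit_cpp(B * 1, dm[labs, labs])
  tree$edge.length <- as.numeric(fit$lengths)
  list(tree = tree, lengths = as.numeric(fit$lengths), total = fit$total)
}

# balanced minimum-evolution total (Pauplin weights) of a topology
bme_total <- function(tree, dm) {
  labs <- tree$tip.label
  bme_total_cpp(tree$edge, ape::Ntip(tree) + tree$Nnode,
                dm[labs, labs], ape::Ntip(tree))
}

#' Build a tree constrained by a backbone topology
#'
#' Starts from the backbone topology; inserts each non-backbone taxon, in
#' ascending id order, on the edge minimizing the balanced minimum-evolution
#' criterion (Pauplin-weighted total tree length), breaking ties by the
#' lowest edge index in the tree's postorder; then alternates NNI
#' hill-climbing with leaf re-placement sweeps on the same criterion,
#' rejecting any rearrangement whose induced backbone topology would lose a
#' backbone split. The output contains every distance matrix label as a
#' leaf, its induced backbone topology preserves every backbone split, and
#' its branch lengths are OLS estimates clamped at zero.
#'
#' @param backbone constraint phylo tree (leaves must appear in `dm`).
#' @param dm labelled symmetric distance matrix over all taxa to place.
#' @param monophyletic_group optional set of taxa (e.g. the rooting
#'   outgroup) that the output must keep together as a clan of the unrooted
#'   tree. Rooting on an outgroup presupposes its monophyly, so enforcing it
#'   during the search is the same kind of prior-knowledge constraint as the
#'   backbone itself.
#' @param max_nni_rounds cap on NNI improvement rounds.
#' @return phylo tree (unrooted) with OLS branch lengths.
#' @export
constrained_build <- function(backbone, dm, monophyletic_group = NULL,
                              max_nni_rounds = 200L) {
  labs <- rownames(dm)
  miss <- setdiff(backbone$tip.label, labs)
  if (length(miss))
    stop("distance matrix is missing backbone taxa: ",
         paste(miss, collapse = ", "), call. = FALSE)
  clan <- intersect(monophyletic_group, labs)
  if (length(intersect(clan, backbone$tip.label)))
    stop("the monophyletic group may not overlap the backbone", call. = FALSE)
  tree <- ape::unroot(backbone)
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree$node.label <- NULL

  extra <- sort(setdiff(labs, backbone$tip.label), method = "radix")
  for (k in extra) {
    tree <- insert_taxon_me(tree, k, dm, clan = clan)
  }

  ## local search: NNI hill-climbing alternating with leaf re-placement
  ## sweeps (prune one non-backbone leaf, reinsert at its ME-optimal edge),
  ## which can relocate a badly placed taxon across the whole tree in one
  ## move where NNI would need many uphill steps
  want <- backbone_splits(backbone)
  for (outer in 1:20) {
    nn <- nni_search(tree, dm, want, backbone$tip.label, max_nni_rounds,
                     clan = clan)
    sw <- replace_sweep(nn$tree, nn$total, extra, dm, clan = clan)
    tree <- sw$tree
    if (!sw$improved) break
  }

  fit <- ols_fit_tree(tree, dm)
  out <- fit$tree
  out$edge.length <- pmax(fit$lengths, 0)
  chk <- check_constraint(out, backbone)
  if (!chk$ok)
    stop("constraint violated after build (internal error): ",
         paste(chk$violated, collapse = "; "), call. = FALSE)
  if (length(clan) > 1L && !is_clan(split_matrix(out), out$tip.label, clan))
    stop("monophyletic-group constraint violated after build (internal error)",
         call. = FALSE)
  out
}

# does the taxon set form a clan (one side of some edge) of the tree?
is_clan <- function(B, tips, group) {
  og <- tips %in% group
  n_og <- sum(og)
  if (n_og <= 1L || n_og == length(tips)) return(TRUE)
  og_below <- rowSums(B[, og, drop = FALSE])
  non_below <- rowSums(B[, !og, drop = FALSE])
  any((og_below == n_og & non_below == 0) |
        (og_below == 0 & non_below == sum(!og)))
}

# which insertion edges keep `clan` (plus k, if k belongs to it) a clan?
clan_allowed_edges <- function(B, tips, k, clan) {
  og <- tips %in% clan
  if (!any(og)) return(rep(TRUE, nrow(B)))
  n_og <- sum(og)
  og_below <- rowSums(B[, og, drop = FALSE])
  non_below <- rowSums(B[, !og, drop = FALSE])
  below_in_og <- non_below == 0            # child side entirely inside clan
  comp_in_og <- non_below == sum(!og)      # complement entirely inside clan
  if (k %in% clan) {
    below_in_og | comp_in_og
  } else {
    strict_below <- below_in_og & og_below < n_og
    strict_comp <- comp_in_og & og_below > 0
    !(strict_below | strict_comp)
  }
}

# BME totals for inserting taxon k on every edge of the current tree
me_insertion_scan <- function(tree, k, dm) {
  tree <- stats::reorder(tree, "postorder")
  labs <- c(tree$tip.label, k)
  scores <- bme_insertion_scores_cpp(tree$edge,
                                     ape::Ntip(tree) + tree$Nnode,
                                     dm[labs, labs], ape::Ntip(tree))
  list(tree = tree, scores = scores)
}

# attach tip k at the midpoint of edge e (postorder index) of tree
attach_tip <- function(tree, k, e) {
  node <- tree$edge[e, 2]
  tree$edge.length <- rep(1, nrow(tree$edge))
  out <- phytools::bind.tip(tree, k, edge.length = 1, where = node,
                            position = 0.5)
  out$edge.length <- rep(1, nrow(out$edge))
  out$node.label <- NULL
  out
}

# choose and apply the ME insertion of taxon k into the current tree
insert_taxon_me <- function(tree, k, dm, clan = character()) {
  sc <- me_insertion_scan(tree, k, dm)
  scores <- sc$scores
  if (length(clan)) {
    ok <- clan_allowed_edges(split_matrix(sc$tree), sc$tree$tip.label,
                             k, clan)
    scores[!ok] <- Inf
  }
  e <- which.min(scores) # first minimum wins: lowest postorder edge index
  if (!is.finite(scores[e]))
    stop("no admissible insertion edge (internal error)", call. = FALSE)
  attach_tip(sc$tree, k, e)
}

# prune each non-backbone leaf in turn and reinsert it at its ME-optimal
# edge, accepting strict improvements of the ME total
replace_sweep <- function(tree, total, movable, dm, clan = character()) {
  improved <- FALSE
  for (k in movable) {
    pruned <- ape::drop.tip(tree, k)
    pruned$node.label <- NULL
    sc <- me_insertion_scan(pruned, k, dm)
    scores <- sc$scores
    if (length(clan)) {
      ok <- clan_allowed_edges(split_matrix(sc$tree), sc$tree$tip.label,
                               k, clan)
      scores[!ok] <- Inf
    }
    e <- which.min(scores)
    if (is.finite(scores[e]) && scores[e] < total - 1e-9) {
      tree <- attach_tip(sc$tree, k, e)
      total <- scores[e]
      improved <- TRUE
    }
  }
  list(tree = tree, total = total, improved = improved)
}

# NNI hill-climb on the BME criterion under the backbone (and optional
# clan) constraints
nni_search <- function(tree, dm, want_splits, backbone_taxa, max_rounds,
                       clan = character()) {
  cur_tree <- stats::reorder(tree, "postorder")
  cur_total <- bme_total(cur_tree, dm)
  for (round in seq_len(max_rounds)) {
    neighbors <- phangorn::nni(cur_tree)
    best <- NULL
    best_total <- cur_total - 1e-9
    for (i in seq_along(neighbors)) {
      nb <- neighbors[[i]]  # [[ decompresses multiPhylo tip labels
      tot <- bme_total(nb, dm)
      if (tot >= best_total) next
      Bn <- split_matrix(nb)
      if (length(setdiff(want_splits, canonical_splits(Bn, backbone_taxa))))
        next
      if (length(clan) > 1L && !is_clan(Bn, nb$tip.label, clan))
        next
      best_total <- tot
      best <- nb
    }
    if (is.null(best)) break
    best$edge.length <- rep(1, nrow(best$edge))
    cur_tree <- stats::reorder(best, "postorder")
    cur_total <- best_total
  }
  list(tree = cur_tree, total = cur_total)
}
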