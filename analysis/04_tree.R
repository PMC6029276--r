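#!/usr/bin/env Rscript

# Stage 4 — build the backbone-constrained OTU tree.
#
# Jukes-Cantor distances are computed over the OTU rows of the extended
# alignment (the full alignment, not the conserved-site subset: removing
# fast sites compresses deep distances nonlinearly and distorts the tree).
# The backbone constraint tree — the trusted multi-gene phylogeny over
# genome-backed taxa, with tips renamed to the genome records that represent
# their OTUs — is pruned to the available taxa, and the remaining OTUs are
# placed by balanced minimum-evolution insertion followed by constrained
# NNI and leaf re-placement. Every backbone split must survive.

suppressPackageStartupMessages(library(divcover))

ext <- read_alignment("results/extended.afa")
cl_tab <- utils::read.delim("results/clusters.tsv")
reps <- unique(cl_tab$representative_id)
dm <- distance_matrix(ext[names(ext) %in% reps])
write_distance_matrix(dm, "results/distances.tsv")

backbone <- read_newick("results/study/backbone.nwk")
truth <- jsonlite::read_json("results/study/truth.json")
# backbone tips are species; the genome record of a species is its OTU
backbone$tip.label <- paste0(backbone$tip.label, "_g")
backbone <- prune_constraint(backbone,
                             intersect(backbone$tip.label, rownames(dm)))
outgroup <- intersect(readLines("results/study/outgroup.txt"), rownames(dm))
tree <- constrained_build(backbone, dm, monophyletic_group = outgroup)
chk <- check_constraint(tree, backbone)
cat(sprintf("tree: %d leaves; backbone: %d leaves; all %d backbone splits preserved: %s\n",
            ape::Ntip(tree), ape::Ntip(backbone),
            length(backbone_splits(backbone)), chk$ok))
if (!chk$ok) stop("backbone constraint violated")
write_newick(tree, "results/tree.nwk")
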