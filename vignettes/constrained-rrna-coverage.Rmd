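---
title: "Measuring the sequenced fraction of rRNA-defined diversity with a backbone-constrained phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the sequenced fraction of rRNA-defined diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divcover)
```

## The question

Genome databases sample the tree of life very unevenly. For a clade such as
the photosynthetic Cyanobacteria (Oxyphotobacteria), thousands of SSU rRNA
(16S) sequences are known but only a few hundred genomes have been
sequenced, and those genomes cluster in a handful of well-studied lineages.
`divcover` quantifies this gap: it places all rRNA-defined operational
taxonomic units (OTUs) on one phylogeny, anchored by a trusted multi-gene
("phylogenomic") backbone over the genome-backed taxa, and reports for every
named clade the **sequenced genome fraction** — the ratio of OTUs whose
dereplication cluster contains a genome-derived sequence to all OTUs in the
clade. Clades with a fraction strictly below 1% are classified
*unsequenced*: essentially invisible to phylogenomics.

## Pipeline and model choices

### Merging three sources

Input rRNA sequences come tagged as `reference` (a curated database
export), `genome` (genes predicted from assemblies) or `collection`
(culture-collection strains), with a separate metadata table carrying
lineages and genome accessions. Two filters run before anything else:

* **Lineage congruence.** A record whose asserted lineage names neither the
  ingroup clade nor an allowed clade (by default the outgroup) is removed.
  Records with *empty* lineages are trusted and kept — collection strains
  typically carry none. The filter is a string allow-list, not a taxonomy
  graph: it reproduces the kind of manual curation it replaces without
  pulling in a taxonomy database.
* **Genome usability.** Genome-source records with an off-clade lineage are
  removed (assemblies whose only predicted rRNA is a contaminant), and
  genome accessions listed in the metadata without any sequence (rRNA-less
  assemblies, common among metagenome-derived genomes) are logged. The merge
  report keeps the exact accounting identity
  `n_output = inputs − incongruent − unusable`; logged rRNA-less accessions
  never enter the sequence set and are tallied separately.

### Dereplication (OTU clustering)

Greedy incremental clustering with cd-hit-est semantics: records sorted by
length (descending, then id), each joining the first cluster whose
representative passes **identity ≥ 0.975**, **shorter-sequence coverage ≥
0.9**, **longer-sequence coverage ≥ 0.0**. Identity is identical aligned
positions divided by the *shorter* sequence's length — the only denominator
under which the asymmetric coverage pair is meaningful. The pairwise
alignment is an ends-free global alignment (match +1, mismatch −1, a gap of
length L costs 2 + (L−1), terminal gaps free) with a deterministic
tie-break: among maximum-score alignments the one with the most matches.
There is no k-mer prescreen; every candidate representative is checked by
alignment, so the result is exactly the greedy definition. When
`cov_short_min ≤ threshold` and `cov_long_min = 0` (the defaults) the
identity gate alone is decisive — the shorter sequence's aligned span is at
least its match count — and a cheaper match-count kernel is used; the
outcome is identical.

After clustering, any cluster containing a genome-derived member but headed
by a non-genome representative has its representative replaced by a genome
member (longest, then id). This is what makes the backbone enforceable: the
backbone taxa are genome sequences, so those sequences must be the leaves
that reach the tree.

The 97.5% radius is a deliberately coarse species proxy; at ~99% one gets
closer to bacterial species resolution, but for mapping large patches of
unsequenced diversity coarse clusters suffice and the threshold is a
parameter.

### Seed-alignment extension and trimming

OTU representatives are aligned into a hand-curated seed multiple alignment
by *consensus threading*: each new sequence is aligned (same scoring as
above) to the seed's majority-rule consensus — gap treated as a fifth state,
consensus gap where gaps exceed 50% — and its residues are threaded into the
corresponding seed columns. Insertions relative to the seed are dropped
rather than opening columns: such columns would be >95% gaps and trimmed
anyway. The seed rows are byte-identical in the output and the column count
never changes; a sequence with under half of its residues placeable is
rejected into a skip report. This replaces BLASTN-anchored insertion tools
with a deterministic, dependency-free procedure that preserves the one
property the analysis relies on: the curated columns stay intact.

Columns are then scored with plain Shannon entropy over A/C/G/T frequencies
normalized by log 4 (a column with no bases scores 1) and a gap fraction;
a column is kept iff entropy ≤ 0.5 **and** gap fraction ≤ 0.2. This is a
simplification of BMGE's similarity-matrix-smoothed entropy, whose
nucleotide variant nearly reduces to it; the cutoffs transfer, the closed
forms are testable, and no window smoothing or minimum-block rule is
applied (each column is scored independently, so trimming is
order-independent and monotone in both cutoffs). The trimmed alignment's
missing-character fraction (gaps + N over cells) is reported as the
conserved-site quality summary.

### Distances and the constrained tree

The substitution model is Jukes–Cantor with pairwise deletion, capped at
5.0 substitutions/site beyond p = 0.75. This deliberately replaces the
GTR+Γ maximum-likelihood machinery of a full phylogenetics stack: the
contribution being reimplemented is the *constraint mechanism* and the
coverage statistic, not the substitution model, and JC has closed-form
values every test can check. The module boundary lets a likelihood engine
be swapped in.

Two wiring choices came out of implementation experience and differ from
the obvious design:

* **Distances are computed on the full extended alignment, not the trimmed
  one.** Entropy trimming keeps slowly evolving sites; distances estimated
  from conserved sites only are compressed nonlinearly with depth, which
  breaks tree additivity exactly where it matters (the deep outgroup stem).
  Under a rate-aware likelihood model this selection is tolerable; under
  plain JC it is not. Trimming remains a reported stage — it is the quality
  summary of the alignment — but the tree sees all columns.
* **Topology selection uses balanced minimum evolution** (BME, Pauplin
  weights, `L = Σ d_ij·2^(1−e_ij)`), the criterion that NJ and FastME
  target, with ordinary least squares used only to fit the final branch
  lengths (clamped at zero). Unweighted OLS minimum evolution — the
  simplest criterion — was measurably inconsistent under these conditions:
  on synthetic studies it genuinely preferred topologies interleaving the
  long-stem outgroup with basal ingroup taxa (e.g. totals 6.8306 broken vs
  6.8439 true on one study), which no amount of searching fixes. BME totals
  are exact for additive distances and cheap to evaluate per candidate
  topology by a breadth-first accumulation.

The constrained build starts from the backbone topology, inserts each
non-backbone taxon in ascending id order at the edge minimizing the BME
total (ties: lowest postorder edge index), and then alternates NNI
hill-climbing with *leaf re-placement sweeps* (prune one non-backbone leaf,
reinsert at its optimal edge). Re-placement can move a badly placed taxon
across the whole tree in one step, where NNI (radius one) would need a
chain of uphill moves. Every candidate rearrangement is rejected if the
induced topology on the backbone taxa would lose a backbone split — this
invariant, checked again on the final tree, is the published claim the
whole design rests on. Two further groups of taxa are special:

* Inserting a taxon absent from the backbone can never break a backbone
  split, so insertion order affects quality, not correctness.
* The **outgroup is constrained to remain one clan**. Rooting on an
  outgroup presupposes its monophyly; it is prior knowledge of the same
  standing as the backbone. Without this, the attachment point of a long
  outgroup stem among basal clades that have no backbone representation is
  decided by distance noise, and on a fraction of synthetic studies the
  criterion genuinely (if barely) preferred a split outgroup — upon which
  the rooting step correctly refuses to root. `root_on_outgroup` itself
  still hard-errors on any non-monophyletic outgroup, listing intruders.

The search is fully deterministic: identical inputs give byte-identical
Newick output.

### Rooting, collapsing, coverage

The root is placed at the midpoint of the edge subtending the outgroup clan
(the position on that edge is not identifiable from data; midpoint is the
deterministic convention). Ingroup OTUs are collapsed by a user-supplied
label map; a label whose MRCA subtends foreign leaves is *kept whole* and
flagged non-monophyletic rather than split into pieces — the label, not the
subtree, is the unit of reporting. Per label:

* `fraction = n_genome_backed_otus / n_otus`, exact;
* `status = unsequenced` iff `fraction < 0.01`, strictly — a clade at
  exactly 1% counts as sequenced;
* cohort summaries (min, median, IQR with linear-interpolation quantiles,
  R type 7) are computed over the **sequenced clades only**; a minimum of
  1% is only possible once the zero-genome clades are excluded.

## The synthetic-data generator

Every stage is testable offline because the generator produces complete
studies with known truth. What it emulates, and the shipped defaults:

* **Species tree**: pure-birth (Yule) tree, 60 ingroup species, rescaled to
  0.15 substitutions/site root-to-tip with a 0.06 stem added to every
  terminal branch. The stems enforce a minimum between-species distance of
  ~0.12 — structurally above the 2.5% dereplication radius — so that the
  spec of the study ("OTU ≈ species") holds by construction, emulating the
  fact that 16S species are well separated at 97.5%.
* **Outgroup**: an 8-species clan of its own (depth 0.05) joined at the
  ingroup root by a 0.3 stem, mirroring a sister class used for rooting.
* **Sequences**: 800 bp (a typical usable high-quality 16S core at desk
  scale), evolved under K80/HKY (κ = 2, equal frequencies, exact per-site
  transition probabilities, no indels). No indels keeps the
  consensus-threading path exact; the coverage gates are exercised by
  dedicated fixtures instead.
* **Database records**: 1–4 replicates per species, each mutated at 0.3%
  per site (intra-species 16S divergence is typically below 0.5%); sources
  reference:collection at 9:1; genome-backed species contribute one
  unmutated genome record with an accession. Two off-clade decoy records
  and two sequence-less genome accessions exercise the merge filters.
* **Genome availability** is clade-structured: 12 clades, of which 4 have
  genome probability 0 and 8 have 0.85. A clade with positive probability
  is redrawn until at least one species is flagged — the generator *plants*
  sequenced clades — so "exactly the zero-probability clades are
  unsequenced" is a structural property of the truth, not a coin flip.
* **Seed alignment**: the true (indel-free) alignment of one sequence per
  species for a stratified 60% subset; **backbone**: the true tree
  restricted to a stratified 20-species subset of the genome-backed species
  (the phylogenomic constraint is correct by construction).

What the generator does **not** emulate: rRNA secondary structure,
among-site rate variation, GC heterogeneity, indels (off by default),
chimeras, and incorrect backbones. Passing the end-to-end tests therefore
shows that the machinery is faithful to its definitions and recovers
planted truth under clean conditions; it does not certify performance on
real alignments with alignment error or model misspecification.

## Numerical choices and degenerate inputs

* Alignment scoring is pinned (+1/−1, gap open 2 including the first
  position, extension 1, free terminal gaps); the lexicographic
  (score, matches) objective removes tie ambiguity between implementations.
* Ambiguity codes collapse to N on ingest; N never matches and never enters
  entropy or distance computations.
* JC saturation (p ≥ 0.75) maps to a finite cap of 5.0 so placement remains
  well-defined for degenerate inputs; pairs with zero comparable columns
  are a hard error naming the pair.
* OLS branch lengths may come out negative; the criterion uses the fitted
  values, the reported tree clamps them at zero.
* All randomness flows from a single integer seed per study; sub-seeds are
  small fixed offsets, and reruns are byte-identical.

## Problem sizes

The shipped defaults (60 + 8 species, ~170 records, 800 bp) run end to end
in roughly ten seconds; the test suite's twenty-study sweep takes about
three minutes, and single-study unit tests use a 15-species configuration.
These sizes were chosen so the whole chain — including the 200-instance
clustering oracle comparison — stays comfortably interactive while leaving
every statistical check enough resolution to be meaningful.

## Known limitations

* The coverage statistic is only as good as the dereplication threshold and
  the label map; both are inputs, not inferences.
* JC distances underestimate deep divergence relative to GTR+Γ; the
  backbone constraint is what keeps deep structure trustworthy, which is
  precisely the method's premise.
* Paraphyletic labels are reported whole; a `--split-paraphyletic`-style
  alternative (maximal monophyletic pieces) is a natural extension.
* The greedy clustering is O(records × clusters) alignments; for database
  scale inputs a prescreen would be needed, at the cost of exactness.
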