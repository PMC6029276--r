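# Independent oracles used across the suite. These re-derive results with
# plain-R implementations that share no code with the package internals.

# Ends-free global alignment, affine gaps (first gap position costs 2, each
# further 1), objective = lexicographic (score, matches); returns the best
# score and match count. Same rules as the package's aligner but implemented
# independently as a plain matrix DP.
r_overlap_matches <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  lex_max <- function(s1, m1, s2, m2) {
    if (s1 > s2 || (s1 == s2 && m1 >= m2)) c(s1, m1) else c(s2, m2)
  }
  Ms <- matrix(NEG, n + 1, m + 1); Mm <- matrix(0, n + 1, m + 1)
  Xs <- Ms; Xm <- Mm; Ys <- Ms; Ym <- Mm
  bases <- c("A", "C", "G", "T")
  for (i in 1:n) {
    for (j in 1:m) {
      hit <- A[i] == B[j] && A[i] %in% bases
      s <- if (hit) 1 else -1
      pre <- if (i == 1 || j == 1) c(0, 0) else c(NEG, 0)
      pre <- lex_max(pre[1], pre[2], Ms[i, j], Mm[i, j])
      pre <- lex_max(pre[1], pre[2], Xs[i, j], Xm[i, j])
      pre <- lex_max(pre[1], pre[2], Ys[i, j], Ym[i, j])
      if (pre[1] > NEG / 2) {
        Ms[i + 1, j + 1] <- pre[1] + s
        Mm[i + 1, j + 1] <- pre[2] + hit
      }
      x <- lex_max(Ms[i, j + 1] - 2, Mm[i, j + 1], Xs[i, j + 1] - 1,
                   Xm[i, j + 1])
      if (x[1] > NEG / 2) { Xs[i + 1, j + 1] <- x[1]; Xm[i + 1, j + 1] <- x[2] }
      y <- lex_max(Ms[i + 1, j] - 2, Mm[i + 1, j], Ys[i + 1, j] - 1,
                   Ym[i + 1, j])
      if (y[1] > NEG / 2) { Ys[i + 1, j + 1] <- y[1]; Ym[i + 1, j + 1] <- y[2] }
    }
  }
  best <- c(0, 0) # empty alignment
  for (j in 1:(m + 1)) {
    best <- lex_max(best[1], best[2], Ms[n + 1, j], Mm[n + 1, j])
    best <- lex_max(best[1], best[2], Xs[n + 1, j], Xm[n + 1, j])
    best <- lex_max(best[1], best[2], Ys[n + 1, j], Ym[n + 1, j])
  }
  for (i in 1:(n + 1)) {
    best <- lex_max(best[1], best[2], Ms[i, m + 1], Mm[i, m + 1])
    best <- lex_max(best[1], best[2], Xs[i, m + 1], Xm[i, m + 1])
    best <- lex_max(best[1], best[2], Ys[i, m + 1], Ym[i, m + 1])
  }
  list(score = best[1], matches = best[2])
}

# Independent greedy clustering under the default gate triple
# (threshold >= cov_short_min, cov_long_min = 0), where membership is decided
# by identity alone: the shorter sequence's aligned span is at least its
# match count, so identity >= threshold forces the shorter-coverage gate, and
# identity failure rejects regardless of coverage.
oracle_greedy <- function(ids, seqs, threshold = 0.975) {
  ord <- order(-nchar(seqs), ids, method = "radix")
  ids <- ids[ord]; seqs <- seqs[ord]
  reps <- integer(0)
  assign <- integer(length(ids))
  for (i in seq_along(ids)) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      r <- reps[k]
      al <- r_overlap_matches(seqs[r], seqs[i])
      if (al$matches / min(nchar(seqs[r]), nchar(seqs[i])) >= threshold) {
        assign[i] <- k; placed <- TRUE; break
      }
    }
    if (!placed) { reps <- c(reps, i); assign[i] <- length(reps) }
  }
  split(ids, assign)
}

# OLS total tree length via an explicit pair-by-edge design matrix and
# lsfit(), independent of the package's normal-equation assembly
ols_total_lm <- function(tree, dm) {
  tree <- ape::unroot(tree)
  tips <- tree$tip.label
  n <- length(tips)
  E <- nrow(tree$edge)
  pairs <- t(combn(n, 2))
  A <- matrix(0, nrow(pairs), E)
  d <- numeric(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    np <- ape::nodepath(tree, i, j)
    for (q in seq_len(length(np) - 1)) {
      e <- which((tree$edge[, 1] == np[q] & tree$edge[, 2] == np[q + 1]) |
                   (tree$edge[, 2] == np[q] & tree$edge[, 1] == np[q + 1]))
      A[p, e] <- 1
    }
    d[p] <- dm[tips[i], tips[j]]
  }
  fit <- stats::lsfit(A, d, intercept = FALSE)
  sum(fit$coefficients)
}

# balanced minimum-evolution total via Pauplin weights, independently of the
# package's BFS accumulation: topological path lengths from ape::dist.nodes
# on a unit-branch-length copy of the tree
bme_total_oracle <- function(tree, dm) {
  tree$edge.length <- rep(1, nrow(tree$edge))
  n <- ape::Ntip(tree)
  e <- round(ape::dist.nodes(tree)[seq_len(n), seq_len(n)])
  labs <- tree$tip.label
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      tot <- tot + dm[labs[i], labs[j]] * 2^(1 - e[i, j])
    }
  }
  tot
}

# random ungapped sequence
rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# copy of a sequence with exactly k substitutions at distinct sites
mutate_k <- function(sq, k) {
  s <- strsplit(sq, "")[[1]]
  pos <- sample(length(s), k)
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  paste(s, collapse = "")
}

# a small study configuration for fast unit tests (not the shipped defaults)
small_study <- function(seed = 1L) {
  study_config(n_species = 15L, n_clades = 4L,
               genome_prob_per_clade = c(0, 0.9, 0.9, 0.9),
               backbone_size = 5L, outgroup_size = 4L,
               replicates_per_species = c(1L, 3L),
               seq_length = 400L, seed = seed)
}
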