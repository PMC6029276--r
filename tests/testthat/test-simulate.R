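test_that("Yule simulation: leaf counts, determinism, expected depth", {
  tr <- simulate_yule_tree(3, 1, seed = 61)
  expect_equal(ape::Ntip(tr), 3L)
  expect_identical(ape::write.tree(simulate_yule_tree(20, 1, seed = 62)),
                   ape::write.tree(simulate_yule_tree(20, 1, seed = 62)))
  # mean root-to-tip depth over 200 seeds vs the analytic expectation
  n <- 50L; lambda <- 1
  depths <- vapply(1:200, function(s) {
    t1 <- simulate_yule_tree(n, lambda, seed = 1000L + s)
    max(ape::node.depth.edgelength(t1))
  }, 0)
  expected <- sum(1 / (2:n)) / lambda
  expect_lt(abs(mean(depths) - expected) / expected, 0.15)
})

test_that("sequence evolution: zero branches, closed-form p, kappa bias", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  s <- evolve_sequences(tr, 500, kappa = 2, seed = 63)
  expect_identical(unname(s["a"]), unname(s["b"]))
  expect_identical(unname(s["a"]), unname(s["c"]))

  # two leaves at JC distance 0.1: observed p within 3 binomial SE of
  # p = (3/4)(1 - exp(-4d/3))
  L <- 100000L
  tr2 <- ape::read.tree(text = "(a:0.05,b:0.05);")
  # a 2-tip phylo is degenerate in ape; use a 3-tip tree with a far leaf
  tr2 <- ape::read.tree(text = "((a:0.05,b:0.05):0,c:1);")
  s2 <- evolve_sequences(tr2, L, kappa = 1, seed = 64)
  p_obs <- mean(strsplit(s2[["a"]], "")[[1]] != strsplit(s2[["b"]], "")[[1]])
  p_exp <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  se <- sqrt(p_exp * (1 - p_exp) / L)
  expect_lt(abs(p_obs - p_exp), 3 * se)

  # kappa = 4: transitions dominate transversions on a long branch
  tr3 <- ape::read.tree(text = "((a:0,b:0.4):0,c:0.01);")
  s3 <- evolve_sequences(tr3, 50000, kappa = 4, seed = 65)
  A <- strsplit(s3[["a"]], "")[[1]]; B <- strsplit(s3[["b"]], "")[[1]]
  diff <- A != B
  ts <- sum(diff & (paste0(A, B) %in% c("AG", "GA", "CT", "TC")))
  tv <- sum(diff) - ts
  expect_gt(ts / tv, 1)
})

test_that("database records carry the planted truth", {
  cfg <- small_study(seed = 13)
  tr <- simulate_yule_tree(10, 1, seed = 66, prefix = "sp")
  leaf <- evolve_sequences(tr, 200, seed = 67)
  labels <- setNames(rep(c("cladeA", "cladeB"), each = 5), names(leaf))
  cfg0 <- study_config(n_species = 10, n_clades = 2,
                       genome_prob_per_clade = c(0, 1),
                       backbone_size = 3, outgroup_size = 1,
                       within_species_divergence = 0,
                       replicates_per_species = c(2L, 2L),
                       seq_length = 200, n_incongruent = 0L,
                       n_rnaless_genomes = 0L, seed = 13)
  db <- make_database_records(leaf, labels, character(0), cfg0, seed = 68)
  # zero within-species divergence: all records of a species identical
  for (sp in names(leaf)) {
    ids <- names(db$truth$species_of)[db$truth$species_of == sp]
    expect_length(unique(db$records$sequence[db$records$id %in% ids]), 1L)
  }
  # genome probability 0 vs 1 maps straight to the planted fractions
  expect_equal(unname(db$truth$true_fractions["cladeA"]), 0)
  expect_equal(unname(db$truth$true_fractions["cladeB"]), 1)
  # independent recount from the emitted metadata
  md <- db$metadata
  gsp <- unique(db$truth$species_of[md$id[md$source == "genome"]])
  for (cl in c("cladeA", "cladeB")) {
    sp_cl <- names(labels)[labels == cl]
    expect_equal(unname(db$truth$true_fractions[cl]),
                 mean(sp_cl %in% gsp))
  }
})

test_that("seed and backbone derive from the truth", {
  bundle <- simulate_study(small_study(seed = 14))
  # the true ingroup tree induces every backbone split (split-set oracle)
  expect_true(check_constraint(bundle$truth$ingroup_tree,
                               bundle$backbone)$ok)
  # indel-free simulation: seed rows equal the raw leaf sequences (checked
  # via the unmutated genome records of flagged species)
  expect_true(all(grepl("^seed_", names(bundle$seed_alignment))))
  seed_species <- sub("^seed_", "", names(bundle$seed_alignment))
  flagged <- intersect(seed_species,
                       names(which(bundle$truth$genome_flags)))
  for (sp in flagged) {
    g <- bundle$records$sequence[bundle$records$id == paste0(sp, "_g")]
    expect_identical(unname(bundle$seed_alignment[[paste0("seed_", sp)]]), g)
  }
  # a backbone-size error fires when too few species are genome-backed
  cfg_bad <- study_config(n_species = 10, n_clades = 2,
                          genome_prob_per_clade = c(0, 0.2),
                          backbone_size = 9, outgroup_size = 2, seed = 15)
  expect_error(simulate_study(cfg_bad), "genome-backed species")
})

test_that("the study bundle is fully deterministic under its seed", {
  b1 <- simulate_study(small_study(seed = 16))
  b2 <- simulate_study(small_study(seed = 16))
  expect_identical(b1$records, b2$records)
  expect_identical(b1$metadata, b2$metadata)
  expect_identical(b1$seed_alignment, b2$seed_alignment)
  expect_identical(ape::write.tree(b1$backbone), ape::write.tree(b2$backbone))
  expect_identical(b1$truth$genome_flags, b2$truth$genome_flags)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(b1, d1); write_study(b2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})
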