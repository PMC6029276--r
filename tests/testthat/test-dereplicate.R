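test_that("pairwise identity matches direct counts on forced alignments", {
  set.seed(21)
  a <- rand_seq(100)
  expect_equal(unlist(pairwise_identity(a, a)),
               c(identity = 1, cov_longer = 1, cov_shorter = 1))
  b <- mutate_k(a, 3)
  expect_equal(pairwise_identity(a, b)$identity, 0.97)
  # exact 80-nt prefix: the shorter-coverage gate, not identity, must be the
  # thing that rejects fragments
  pre <- substr(a, 1, 80)
  ir <- pairwise_identity(a, pre)
  expect_equal(ir$identity, 1)
  expect_equal(ir$cov_shorter, 1)
  expect_equal(ir$cov_longer, 0.8)
  expect_error(pairwise_identity("", "ACGT"), "empty")
  # N never counts as a match
  expect_equal(pairwise_identity("AANNTT", "AANNTT")$identity, 4 / 6)
})

test_that("fast match kernel agrees with the span-tracking aligner", {
  set.seed(22)
  for (i in 1:50) {
    a <- rand_seq(sample(20:120, 1))
    b <- if (i %% 2) mutate_k(a, sample(0:10, 1)) else rand_seq(sample(20:120, 1))
    f <- divcover:::overlap_matches_cpp(a, b)
    s <- divcover:::overlap_align_cpp(a, b, FALSE)
    expect_identical(f$score, s$score)
    expect_identical(f$matches, s$matches)
  }
})

test_that("greedy clustering joins by identity threshold", {
  set.seed(23)
  one <- data.frame(id = "x", sequence = rand_seq(60))
  cs <- greedy_cluster(one)
  expect_length(cs$clusters, 1L)
  expect_equal(cs$clusters[[1]]$representative_id, "x")

  a <- rand_seq(1200)
  near <- data.frame(id = c("a", "b"),
                     sequence = c(a, mutate_k(a, 10)))  # identity ~0.992
  expect_length(greedy_cluster(near)$clusters, 1L)
  far <- data.frame(id = c("a", "b"),
                    sequence = c(a, mutate_k(a, 50)))   # identity ~0.958
  expect_length(greedy_cluster(far)$clusters, 2L)
})

test_that("greedy clustering equals the independent brute-force oracle", {
  set.seed(24)
  for (inst in 1:20) {
    n <- sample(2:8, 1)
    base <- rand_seq(sample(30:60, 1))
    seqs <- vapply(1:n, function(i) {
      if (runif(1) < 0.5) mutate_k(base, sample(0:3, 1)) else
        rand_seq(nchar(base))
    }, "")
    ids <- sprintf("s%02d", 1:n)
    got <- greedy_cluster(data.frame(id = ids, sequence = seqs))
    want <- oracle_greedy(ids, seqs)
    got_sets <- lapply(got$clusters, function(cl) sort(cl$member_ids))
    want_sets <- lapply(want, sort)
    expect_setequal(vapply(got_sets, paste, "", collapse = ","),
                    vapply(want_sets, paste, "", collapse = ","))
  }
})

test_that("partition and threshold guarantees hold on a synthetic bundle", {
  bundle <- simulate_study(small_study(seed = 7))
  recs <- bundle$records
  cs <- greedy_cluster(recs)
  expect_silent(validate_clusters(cs, recs$id))
  # post hoc: every member passes all three gates vs its representative
  seqs <- setNames(recs$sequence, recs$id)
  for (cl in cs$clusters) {
    for (mid in cl$member_ids) {
      ir <- pairwise_identity(seqs[[cl$representative_id]], seqs[[mid]])
      expect_true(ir$identity >= 0.975 && ir$cov_shorter >= 0.9 &&
                    ir$cov_longer >= 0)
    }
  }
})

test_that("raising the threshold never decreases the cluster count", {
  bundle <- simulate_study(small_study(seed = 8))
  recs <- bundle$records
  counts <- vapply(c(0.90, 0.95, 0.975, 0.99), function(th)
    length(greedy_cluster(recs, threshold = th)$clusters), 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("dereplication at defaults recovers the true species partition", {
  bundle <- simulate_study(small_study(seed = 9))
  cs <- greedy_cluster(bundle$records)
  mem <- cluster_membership(cs)
  sp <- bundle$truth$species_of[names(mem)]
  keep <- !is.na(sp)  # decoy records have no species
  ari <- mclust::adjustedRandIndex(mem[keep], sp[keep])
  expect_equal(ari, 1.0)
})

test_that("genome members are promoted to representatives deterministically", {
  recs <- data.frame(
    id = c("r1", "g1", "g2", "r2", "g3"),
    sequence = c(strrep("A", 50), strrep("A", 40), strrep("A", 40),
                 strrep("C", 50), strrep("C", 50)),
    source = c("reference", "genome", "genome", "reference", "genome"),
    stringsAsFactors = FALSE)
  cs <- structure(list(clusters = list(
    list(representative_id = "r1", member_ids = c("r1", "g1", "g2"),
         genome_backed = NA),
    list(representative_id = "g3", member_ids = c("g3", "r2"),
         genome_backed = NA)),
    params = list()), class = "otu_clusters")
  out <- promote_genome_representatives(cs, recs)
  expect_equal(out$n_replaced, 1L)
  # equal-length genome candidates: id ascending breaks the tie
  expect_equal(out$clusters$clusters[[1]]$representative_id, "g1")
  # genome representative already in place: no-op
  expect_equal(out$clusters$clusters[[2]]$representative_id, "g3")
  expect_true(all(vapply(out$clusters$clusters, `[[`, NA, "genome_backed")))
  # counting oracle: replacements = clusters with a genome member and a
  # non-genome representative
  src <- setNames(recs$source, recs$id)
  want <- sum(vapply(cs$clusters, function(cl)
    any(src[cl$member_ids] == "genome") &&
      src[[cl$representative_id]] != "genome", logical(1)))
  expect_equal(out$n_replaced, want)
})
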