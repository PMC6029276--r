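test_that("rooting places the root at the outgroup edge midpoint", {
  tr <- ape::read.tree(text = "((o1:1,o2:1):2,a:1,b:1);")
  rooted <- root_on_outgroup(tr, c("o1", "o2"))
  expect_true(ape::is.rooted(rooted))
  kids <- phangorn::Descendants(rooted, ape::Ntip(rooted) + 1L, "children")
  sets <- lapply(kids, function(k)
    rooted$tip.label[phangorn::Descendants(rooted, k, "tips")[[1]]])
  expect_true(any(vapply(sets, function(s) setequal(s, c("o1", "o2")),
                         logical(1))))
  # midpoint: both root-child edges carry half the original edge
  d <- ape::node.depth.edgelength(rooted)
  expect_equal(min(ape::dist.nodes(rooted)[ape::Ntip(rooted) + 1L,
                                           which(rooted$tip.label == "o1")]),
               1 + 1, tolerance = 1e-9)
})

test_that("a non-monophyletic outgroup is a hard error naming intruders", {
  tr <- ape::read.tree(text = "((o1:1,a:1):2,o2:1,b:1);")
  expect_error(root_on_outgroup(tr, c("o1", "o2")), "intruding")
  expect_error(root_on_outgroup(tr, c("o1", "a", "o2", "b")), "whole leaf")
  expect_error(root_on_outgroup(tr, "missing"), "subset")
})

test_that("a simulated outgroup clan roots cleanly", {
  bundle <- simulate_study(small_study(seed = 12))
  tr <- bundle$truth$true_tree
  og <- grep("^og", tr$tip.label, value = TRUE)
  rooted <- root_on_outgroup(tr, og)
  ing <- setdiff(rooted$tip.label, og)
  mrca <- ape::getMRCA(rooted, ing)
  under <- rooted$tip.label[phangorn::Descendants(rooted, mrca, "tips")[[1]]]
  expect_length(intersect(under, og), 0L)
})

test_that("cluster collapsing flags monophyly and conserves the partition", {
  tr <- ape::read.tree(text = "(((b1,b2),((a1,c2),(c1,a3))),o1);")
  rooted <- root_on_outgroup(ape::unroot(tr), "o1")
  lm <- c(a1 = "A", a3 = "A", b1 = "B", b2 = "B", c1 = "C", c2 = "C")
  col <- collapse_clusters(rooted, lm, outgroup_taxa = "o1")
  expect_equal(sum(lengths(col$otu_ids)), 6L)
  flags <- setNames(col$monophyletic, col$cluster_label)
  expect_true(flags[["B"]])
  # A and C interleave in one subtree: both kept whole, both flagged FALSE
  expect_false(flags[["A"]])
  expect_false(flags[["C"]])
  expect_error(collapse_clusters(rooted, lm[-1], outgroup_taxa = "o1"),
               "unlabeled")
})

make_clusters <- function(flags) {
  structure(list(clusters = lapply(names(flags), function(id)
    list(representative_id = id, member_ids = id,
         genome_backed = flags[[id]])), params = list()),
    class = "otu_clusters")
}

test_that("sequenced fraction is the exact genome-backed ratio", {
  cs <- make_clusters(setNames(c(rep(FALSE, 10), TRUE), sprintf("u%02d", 1:11)))
  r0 <- sequenced_fraction(sprintf("u%02d", 1:10), cs)
  expect_equal(r0$fraction, 0)
  expect_equal(r0$status, "unsequenced")
  r1 <- sequenced_fraction(sprintf("u%02d", 3:11), cs)  # 1 of 9
  expect_equal(r1$fraction, 1 / 9)
  expect_equal(round(r1$fraction, 3), 0.111)
  expect_equal(r1$status, "sequenced")
  r2 <- sequenced_fraction("u11", cs)
  expect_equal(r2$fraction, 1)
  expect_error(sequenced_fraction(character(0), cs), "empty")
  expect_error(sequenced_fraction("nope", cs), "absent")
})

test_that("the <1% classification boundary is strict", {
  mk <- function(frac, n = 10000L) {
    k <- round(frac * n)
    cs <- make_clusters(setNames(seq_len(n) <= k, sprintf("t%05d", 1:n)))
    sequenced_fraction(sprintf("t%05d", 1:n), cs)$status
  }
  expect_equal(mk(0.01), "sequenced")    # exactly 1% is NOT below 1%
  expect_equal(mk(0.0099), "unsequenced")
})

test_that("cohort summaries cover sequenced clades only", {
  clades <- data.frame(
    cluster_label = c("x", "y", "z"),
    n_otus = c(4L, 6L, 2L),
    n_genome_backed_otus = c(0L, 0L, 1L),
    fraction = c(0, 0, 0.5),
    status = c("unsequenced", "unsequenced", "sequenced"),
    monophyletic = TRUE, stringsAsFactors = FALSE)
  rep <- summarize_coverage(clades)
  expect_equal(rep$n_unsequenced, 2L)
  s <- rep$summary_over_sequenced
  expect_equal(c(s$min, s$median, s$iqr), c(0.5, 0.5, 0))
  # linear-interpolation quantiles over several sequenced clades
  clades2 <- data.frame(
    cluster_label = letters[1:4], n_otus = 10L,
    n_genome_backed_otus = c(1L, 2L, 3L, 6L),
    fraction = c(0.1, 0.2, 0.3, 0.6),
    status = "sequenced", monophyletic = TRUE, stringsAsFactors = FALSE)
  s2 <- summarize_coverage(clades2)$summary_over_sequenced
  expect_equal(s2$median, 0.25)
  expect_equal(s2$iqr, unname(diff(quantile(c(0.1, 0.2, 0.3, 0.6),
                                            c(0.25, 0.75), type = 7))))
})

test_that("coverage report composes collapse + fractions + summary", {
  tr <- ape::read.tree(text = "(((a1,a2),(b1,b2)),o1);")
  rooted <- root_on_outgroup(ape::unroot(tr), "o1")
  cs <- make_clusters(c(a1 = TRUE, a2 = FALSE, b1 = FALSE, b2 = FALSE))
  lm <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  rep <- coverage_report(rooted, cs, lm, outgroup_taxa = "o1")
  expect_equal(rep$n_total_clusters, 2L)
  expect_equal(rep$n_unsequenced, 1L)
  df <- rep$clades
  expect_equal(df$fraction[df$cluster_label == "A"], 0.5)
  expect_equal(sum(df$n_otus), 4L)
})
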