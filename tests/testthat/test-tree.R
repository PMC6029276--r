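test_that("constraint pruning removes leaves and is idempotent", {
  set.seed(51)
  bb <- simulate_yule_tree(10, 1, seed = 51)
  pruned <- prune_constraint(bb, bb$tip.label[1:7])
  expect_equal(ape::Ntip(pruned), 7L)
  again <- prune_constraint(pruned, pruned$tip.label)
  expect_identical(ape::write.tree(again), ape::write.tree(pruned))
  # pruning nothing keeps the topology
  noop <- prune_constraint(bb, bb$tip.label)
  expect_identical(ape::write.tree(noop), ape::write.tree(bb))
  expect_error(prune_constraint(bb, bb$tip.label[1:2]), "fewer than 3")
  # suppressed degree-2 nodes sum their branch lengths
  tr <- ape::read.tree(text = "((a:1,b:2):3,(c:4,d:5):6);")
  pr <- prune_constraint(tr, c("a", "c", "d"))
  d <- ape::cophenetic.phylo(pr)
  expect_equal(d["a", "c"], 1 + 3 + 6 + 4)
})

test_that("bipartitions: quartets, stars and edge-count identity", {
  q <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(backbone_splits(q), "c|d")
  star <- ape::read.tree(text = "(a,b,c,d);")
  expect_length(backbone_splits(star), 0L)
  for (n in c(5, 8, 12)) {
    tr <- simulate_yule_tree(n, 1, seed = n)
    expect_length(backbone_splits(tr), n - 3L)
  }
})

test_that("check_constraint detects violated splits", {
  bb <- ape::read.tree(text = "((a,b),(c,d));")
  good <- ape::read.tree(text = "(((a,e),b),(c,(d,f)));")
  expect_true(check_constraint(good, bb)$ok)
  bad <- ape::read.tree(text = "(((a,c),e),(b,(d,f)));")
  chk <- check_constraint(bad, bb)
  expect_false(chk$ok)
  expect_length(chk$violated, 1L)
  expect_error(check_constraint(ape::read.tree(text = "(a,b,x);"), bb),
               "missing")
})

test_that("with no extra taxa the backbone topology is returned refit", {
  set.seed(52)
  bb <- simulate_yule_tree(8, 1, seed = 52)
  dm <- ape::cophenetic.phylo(bb)
  out <- constrained_build(bb, dm)
  expect_equal(phangorn::RF.dist(ape::unroot(bb), out), 0)
  # OLS on additive distances reproduces the path lengths
  expect_equal(ape::cophenetic.phylo(out)[rownames(dm), colnames(dm)], dm,
               tolerance = 1e-8)
})

test_that("insertion edge equals the exhaustive criterion argmin (oracle)", {
  for (s in 53:55) {
    set.seed(s)
    bb <- ape::unroot(ape::rtree(4))
    labs <- c(bb$tip.label, "x")
    # random symmetric distances with a metric-ish structure
    base <- matrix(runif(25, 0.2, 1), 5, 5,
                   dimnames = list(labs, labs))
    dm <- (base + t(base)) / 2
    diag(dm) <- 0
    out <- constrained_build(bb, dm)
    # oracle: score every candidate attachment with an independent
    # Pauplin-weight evaluation
    bb1 <- bb
    bb1$edge.length <- rep(1, nrow(bb1$edge))
    bb1 <- stats::reorder(bb1, "postorder")
    totals <- vapply(seq_len(nrow(bb1$edge)), function(e) {
      cand <- phytools::bind.tip(bb1, "x", edge.length = 1,
                                 where = bb1$edge[e, 2], position = 0.5)
      bme_total_oracle(cand, dm)
    }, 0)
    best_e <- which.min(totals)
    want <- phytools::bind.tip(bb1, "x", edge.length = 1,
                               where = bb1$edge[best_e, 2], position = 0.5)
    expect_equal(phangorn::RF.dist(ape::unroot(want), out), 0)
  }
})

test_that("OLS branch-length fit agrees with an explicit design-matrix fit", {
  set.seed(59)
  tr <- ape::unroot(ape::rtree(7))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.3)
  dm <- ape::cophenetic.phylo(tr)
  dm <- dm + (matrix(runif(49, 0, 0.02), 7, 7) |> (\(m) (m + t(m)) / 2)())
  diag(dm) <- 0
  fit <- divcover:::ols_fit_tree(tr, dm)
  expect_equal(fit$total, ols_total_lm(tr, dm), tolerance = 1e-8)
})

test_that("additive distances on a 12-taxon tree are recovered exactly", {
  set.seed(56)
  tr <- ape::unroot(ape::rtree(12))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.3)
  dm <- ape::cophenetic.phylo(tr)
  bb <- ape::drop.tip(tr, setdiff(tr$tip.label, sort(tr$tip.label)[1:6]))
  out <- constrained_build(bb, dm)
  expect_equal(phangorn::RF.dist(out, tr), 0)
  expect_true(check_constraint(out, bb)$ok)
})

test_that("NNI hill-climbing never increases the ME total", {
  set.seed(57)
  tr <- ape::unroot(ape::rtree(10))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.3)
  dm <- ape::cophenetic.phylo(tr)
  # start from a deliberately wrong topology over the same tips
  start <- ape::unroot(ape::rtree(10))
  start$tip.label <- tr$tip.label
  before <- divcover:::bme_total(stats::reorder(start, "postorder"), dm)
  bb <- ape::keep.tip(start, start$tip.label[1:4]) # weak constraint
  res <- divcover:::nni_search(start, dm, backbone_splits(bb),
                               bb$tip.label, 100L)
  expect_lte(res$total, before + 1e-9)
  # and the search total matches the independent Pauplin evaluation
  expect_equal(res$total, bme_total_oracle(res$tree, dm), tolerance = 1e-9)
})

test_that("constrained build is deterministic", {
  set.seed(58)
  tr <- ape::unroot(ape::rtree(10))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.3)
  dm <- ape::cophenetic.phylo(tr)
  bb <- ape::drop.tip(tr, setdiff(tr$tip.label, sort(tr$tip.label)[1:5]))
  n1 <- ape::write.tree(constrained_build(bb, dm))
  n2 <- ape::write.tree(constrained_build(bb, dm))
  expect_identical(n1, n2)
})

test_that("a missing backbone taxon in the distance matrix is an error", {
  bb <- ape::read.tree(text = "((a,b),(c,d));")
  dm <- matrix(0.5, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(dm) <- 0
  expect_error(constrained_build(bb, dm), "missing backbone taxa")
})
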