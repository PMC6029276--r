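seed_aln <- function() {
  as_alignment(c(seed_a = "ACGT-ACGTACGT",
                 seed_b = "ACGT-ACGTACGT",
                 seed_c = "ACGTTACGTACGT"))
}

test_that("consensus calls majority bases and >50% gap columns", {
  cons <- consensus_profile(as_alignment(c(a = "A-G", b = "A-C", c = "ACC")))
  expect_equal(cons, "A-C")
  # tie at 50% gaps is not a consensus gap
  cons2 <- consensus_profile(as_alignment(c(a = "A-", b = "AC")))
  expect_equal(cons2, "AC")
})

test_that("threading a sequence identical to a seed row reproduces it", {
  seed <- seed_aln()
  new <- data.frame(id = "new1",
                    sequence = gsub("-", "", seed[["seed_a"]]),
                    stringsAsFactors = FALSE)
  out <- extend_alignment(seed, new)
  expect_equal(unname(out$alignment[["new1"]]), unname(seed[["seed_a"]]))
  expect_equal(nrow(out$skipped), 0L)
})

test_that("seed rows and column count are never perturbed", {
  set.seed(31)
  bundle <- simulate_study(small_study(seed = 10))
  seed <- bundle$seed_alignment
  new <- bundle$records[sample(nrow(bundle$records), 10), c("id", "sequence")]
  out <- extend_alignment(seed, new)
  expect_identical(out$alignment[names(seed)], seed)
  expect_equal(unique(nchar(out$alignment)), nchar(seed[[1]]))
})

test_that("a substituted consensus copy is placed without internal gaps", {
  set.seed(32)
  seed_rows <- replicate(6, rand_seq(200))
  seed <- as_alignment(setNames(seed_rows, sprintf("seed_%d", 1:6)))
  cons <- consensus_profile(seed)
  mutant <- mutate_k(cons, 10)  # 5% substitutions, no indels
  out <- extend_alignment(seed, data.frame(id = "m", sequence = mutant))
  placed <- out$alignment[["m"]]
  expect_false(grepl("-", placed))
  ident <- mean(strsplit(placed, "")[[1]] == strsplit(cons, "")[[1]])
  expect_gte(ident, 0.95)
})

test_that("unplaceable sequences are skipped with a report", {
  set.seed(33)
  seed <- as_alignment(setNames(replicate(4, rand_seq(120)),
                                sprintf("seed_%d", 1:4)))
  junk <- paste(rep("A", 300), collapse = "")
  expect_warning(out <- extend_alignment(seed, data.frame(id = "junk",
                                                          sequence = junk)),
                 "skipped")
  expect_equal(out$skipped$id, "junk")
  expect_false("junk" %in% names(out$alignment))
  expect_error(extend_alignment(seed, data.frame(id = "seed_1",
                                                 sequence = "ACGT")),
               "collide")
})

test_that("column entropy matches closed forms", {
  rows <- c(paste(rep("A", 4), collapse = ""))
  # column 1: all A; column via equal base counts; column at 0.7/0.1/0.1/0.1
  aln <- as_alignment(setNames(
    c("AAA", "AAC", "AAG", "AAT", "ACA", "ACC", "ACG", "ACT", "AGA", "AGC"),
    sprintf("r%02d", 1:10)))
  sc <- score_columns(aln)
  expect_equal(sc$entropy[1], 0)           # all-A column
  expect_true(sc$kept[1])
  # build explicit frequency columns
  col_eq <- as_alignment(setNames(c("A", "C", "G", "T"), sprintf("e%d", 1:4)))
  expect_equal(score_columns(col_eq)$entropy, 1)
  expect_false(score_columns(col_eq)$kept)
  col_07 <- as_alignment(setNames(c(rep("A", 7), "C", "G", "T"),
                                  sprintf("f%d", 1:10)))
  expect_equal(score_columns(col_07)$entropy, 0.6784, tolerance = 1e-4)
  expect_false(score_columns(col_07)$kept)
  # gaps count toward gap fraction, N and '-' are excluded from entropy
  col_gap <- as_alignment(setNames(c("A-", "A-", "AA", "AN"),
                                   sprintf("g%d", 1:4)))
  sc2 <- score_columns(col_gap)
  expect_equal(sc2$gap_fraction, c(0, 0.5))
  expect_equal(sc2$entropy, c(0, 0))
  expect_equal(sc2$kept, c(TRUE, FALSE))
  # a column of only gaps/N has entropy 1
  col_n <- as_alignment(setNames(c("NA", "NA", "-A"), sprintf("h%d", 1:3)))
  expect_equal(score_columns(col_n)$entropy[1], 1)
})

test_that("trimming keeps exactly the passing columns, in order", {
  aln <- as_alignment(setNames(rep("ACGTACGT", 5), sprintf("r%d", 1:5)))
  tr <- trim_alignment(aln)
  expect_equal(tr$kept_columns, 0:7)
  expect_identical(tr$alignment, aln)

  # one maximally variable column among conserved ones
  rows <- c("AAAA", "ACAA", "AGAA", "ATAA")
  aln2 <- as_alignment(setNames(rows, sprintf("r%d", 1:4)))
  tr2 <- trim_alignment(aln2)
  expect_equal(tr2$kept_columns, c(0L, 2L, 3L))
  # predicate-count oracle
  sc <- score_columns(aln2)
  expect_equal(length(tr2$kept_columns), sum(sc$kept))
  # every trimmed column exists verbatim at its reported index
  m <- do.call(rbind, strsplit(rows, ""))
  mt <- do.call(rbind, strsplit(unname(tr2$alignment), ""))
  expect_identical(mt, m[, tr2$kept_columns + 1L])
})

test_that("trimming is monotone in both cutoffs", {
  set.seed(34)
  bundle <- simulate_study(small_study(seed = 11))
  ext <- extend_alignment(bundle$seed_alignment,
                          bundle$records[1:8, c("id", "sequence")])
  grid <- expand.grid(e = c(0.3, 0.5, 0.7), g = c(0.1, 0.2, 0.5))
  kept <- lapply(seq_len(nrow(grid)), function(i)
    trim_alignment(ext$alignment, grid$e[i], grid$g[i])$kept_columns)
  for (i in seq_len(nrow(grid))) {
    for (j in seq_len(nrow(grid))) {
      if (grid$e[j] >= grid$e[i] && grid$g[j] >= grid$g[i])
        expect_true(all(kept[[i]] %in% kept[[j]]))
    }
  }
})

test_that("rows that become all-gap after trimming are removed", {
  aln <- as_alignment(setNames(c("AAAC", "AAAG", "AAAT", "AAAA", "---A"),
                               c("a", "b", "c", "e", "d")))
  tr <- trim_alignment(aln)
  expect_equal(tr$kept_columns, 0:2)
  expect_equal(tr$removed_rows, "d")
  expect_false("d" %in% names(tr$alignment))
})

test_that("gap-heavy columns are trimmed and missing fraction is reported", {
  aln <- as_alignment(setNames(c("AAACCC", "AAACCC", "---CCC"),
                               c("a", "b", "c")))
  # trim away the first three columns via the gap cutoff
  tr <- trim_alignment(aln, entropy_cutoff = 0.5, gap_cutoff = 0.2)
  expect_equal(tr$kept_columns, 3:5)
  expect_equal(tr$missing_fraction, 0)
  aln2 <- as_alignment(setNames(c("AAAC", "AAAC", "AAA-"), c("a", "b", "c")))
  tr2 <- trim_alignment(aln2, gap_cutoff = 0.5)
  expect_equal(tr2$missing_fraction, 1 / 12)
  expect_error(trim_alignment(as_alignment(
    setNames(c("A", "C", "G", "T"), c("a", "b", "c", "d")))),
    "no conserved sites")
})
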