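test_that("self-alignment scores the diagonal and contains no gaps", {
  sc <- alignment_scoring()
  s <- "MKVACDEFGH"
  res <- pairwise_align(s, s, sc)
  expect_equal(res$a_gapped, s)
  expect_equal(res$b_gapped, s)
  ch <- strsplit(s, "")[[1]]
  expect_equal(res$score, sum(diag(sc$matrix[ch, ch])))
})

test_that("MKV vs MV alignment contains exactly one gap column", {
  res <- pairwise_align("MKV", "MV")
  expect_equal(nchar(res$a_gapped), 3L)
  n_gaps <- lengths(regmatches(res$b_gapped, gregexpr("-", res$b_gapped)))
  expect_equal(sum(n_gaps), 1L)
  expect_equal(gsub("-", "", res$b_gapped), "MV")
})

test_that("empty sequences are rejected", {
  expect_error(pairwise_align("", "MKV"), "empty")
})

test_that("pairwise scores match the independent DP oracle on random pairs", {
  sc <- alignment_scoring()
  set.seed(101)
  for (k in 1:50) {
    a <- random_seq(sample(5:40, 1))
    b <- random_seq(sample(5:40, 1))
    res <- pairwise_align(a, b, sc)
    expect_equal(res$score, oracle_align_score(a, b, sc), tolerance = 1e-9)
    # reported gapped pair really scores what it claims
    expect_equal(induced_pair_score(res$a_gapped, res$b_gapped, sc), res$score,
                 tolerance = 1e-9)
  }
})

test_that("guide tree joins the closest pair first and breaks ties lexicographically", {
  d <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.9, 0.9, 0.9, 0),
              3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- build_guide_tree(distance_matrix(d))
  expect_setequal(c(tree[[1]]$left, tree[[1]]$right), c("A", "B"))

  dt <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(dt) <- 0
  tie <- build_guide_tree(distance_matrix(dt))
  expect_setequal(c(tie[[1]]$left, tie[[1]]$right), c("a", "b"))
  expect_setequal(c(tie[[2]]$left, tie[[2]]$right), c("a", "b", "c"))
  expect_error(build_guide_tree(distance_matrix(matrix(0, 1, 1, dimnames = list("x", "x")))),
               "at least 2")
})

test_that("identical sequences align gap-free; a single record is a degenerate msa", {
  recs <- protein_set(c("a", "b", "c"), rep("MKVACDEF", 3))
  m <- progressive_align(recs)
  expect_false(any(grepl("-", m$seqs, fixed = TRUE)))
  one <- progressive_align(protein_set("solo", "MKV"))
  expect_equal(one$seqs, "MKV")
})

test_that("msa rows degap to the input sequences (simulated family)", {
  fam <- simulate_family(family_sim_config(n_groups = 2, members_per_group = 4,
                                           indel_rate = 0.02, seed = 6))
  m <- progressive_align(fam$records)
  for (id in m$ids) {
    expect_identical(msa_degap(m, id),
                     fam$records$sequence[fam$records$id == id])
  }
})

test_that("coordinate maps are mutually inverse and 1-based", {
  m <- msa(c("r", "s"), c("M-KV", "MAKV"))
  expect_equal(msa_col_of(m, "r", 2), 3L)       # ungapped pos 2 (K) -> column 3
  expect_equal(msa_pos_of(m, "r", 3), 2L)
  expect_true(is.na(msa_pos_of(m, "r", 2)))     # gap column
  for (pos in 1:3) {
    expect_equal(msa_pos_of(m, "r", msa_col_of(m, "r", pos)), pos)
  }
  expect_error(msa_col_of(m, "r", 4), "out of range")
  expect_error(msa(c("x", "y"), c("AA", "AAA")), "equal length")
})

test_that("anchors co-columnate with the reference on noise-free families", {
  fam <- simulate_family(family_sim_config(n_groups = 3, members_per_group = 4,
                                           background_mutation_rate = 0,
                                           indel_rate = 0,
                                           group_divergence_rate = 0, seed = 4))
  recs <- rbind(fam$reference, fam$records)
  class(recs) <- c("protein_set", "data.frame")
  m <- progressive_align(recs)
  cols <- map_anchor_columns(m, default_anchor_config())
  for (id in rownames(fam$anchor_map)) {
    for (k in colnames(fam$anchor_map)) {
      expect_equal(msa_col_of(m, id, fam$anchor_map[id, k]), cols[[k]])
    }
  }
})

test_that("duplicating a sequence preserves the relative columns of original rows", {
  fam <- simulate_family(family_sim_config(n_groups = 2, members_per_group = 3,
                                           indel_rate = 0.02, seed = 8))
  recs <- fam$records
  m1 <- progressive_align(recs)
  dup <- recs[c(seq_len(nrow(recs)), 1L), ]
  dup$id[nrow(dup)] <- "dup_of_first"
  class(dup) <- c("protein_set", "data.frame")
  m2 <- progressive_align(dup)
  # pairwise residue correspondences among the original rows are unchanged
  pair_map <- function(m, id1, id2) {
    n1 <- nchar(msa_degap(m, id1))
    cols <- msa_col_of(m, id1, seq_len(n1))
    msa_pos_of(m, id2, cols)
  }
  for (other in recs$id[-1]) {
    expect_identical(pair_map(m1, recs$id[1], other), pair_map(m2, recs$id[1], other))
  }
})

test_that("p-distance counts identical ungapped columns", {
  m <- msa(c("a", "b"), c("AAAA", "AAAT"))
  expect_equal(unclass(p_distance(m))["a", "b"], 0.25)
  mid <- msa(c("a", "b"), c("MKV", "MKV"))
  expect_equal(unclass(p_distance(mid))["a", "b"], 0)
  disjoint <- msa(c("a", "b"), c("MK--", "--MK"))
  expect_warning(dd <- p_distance(disjoint), "no comparable")
  expect_equal(unclass(dd)["a", "b"], 1)
})

test_that("p-distance matches a hand-computed oracle on random gapped pairs", {
  set.seed(33)
  for (k in 1:20) {
    a <- random_seq(12)
    b <- random_seq(10)
    res <- pairwise_align(a, b)
    m <- msa(c("x", "y"), c(res$a_gapped, res$b_gapped))
    expect_equal(unclass(p_distance(m))["x", "y"],
                 oracle_p_distance(res$a_gapped, res$b_gapped))
  }
})

test_that("progressive rows never beat the optimal pairwise score", {
  set.seed(55)
  recs <- protein_set(sprintf("s%d", 1:6),
                      vapply(1:6, function(i) random_seq(25), character(1)))
  m <- progressive_align(recs)
  sc <- alignment_scoring()
  for (i in 1:5) for (j in (i + 1):6) {
    ind <- induced_pair_score(m$seqs[i], m$seqs[j], sc)
    opt <- oracle_align_score(recs$sequence[i], recs$sequence[j], sc)
    expect_lte(ind, opt + 1e-9)
  }
})
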