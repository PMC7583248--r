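# Noise-free five-group family aligned once and reused across this file.
sig_fixture <- local({
  fam <- simulate_family(family_sim_config(background_mutation_rate = 0,
                                           indel_rate = 0,
                                           group_divergence_rate = 0, seed = 2))
  recs <- rbind(fam$reference, fam$records)
  class(recs) <- c("protein_set", "data.frame")
  m <- progressive_align(recs)
  list(fam = fam, msa = m, cfg = default_anchor_config())
})

test_that("anchor columns equal positions in a gap-free alignment", {
  m <- sig_fixture$msa
  expect_false(any(grepl("-", m$seqs[match("REF", m$ids)], fixed = TRUE)))
  cols <- map_anchor_columns(m, sig_fixture$cfg)
  expect_equal(unname(cols), sig_fixture$cfg$anchors$position)
})

test_that("a reference gap shifts anchor columns accordingly", {
  m <- msa(c("REFX", "o"), c("M-KV", "MAKV"))
  cfg <- larasig:::new_anchor_config(
    "REFX", data.frame(position = 2L, ref_residue = "K", category = "catalytic"))
  expect_equal(unname(map_anchor_columns(m, cfg)), 3L)
  cfg2 <- larasig:::new_anchor_config(
    "missing", data.frame(position = 1L, ref_residue = "M", category = "other"))
  expect_error(map_anchor_columns(m, cfg2), "absent")
})

test_that("column profiles count residues and handle gaps", {
  m <- msa(c("a", "b", "c", "d"), c("F-", "F-", "LA", "M-"))
  p <- column_profile(m, c("a", "b", "c", "d"), 1)
  expect_equal(unname(p$freqs[c("F", "L", "M")]), c(0.5, 0.25, 0.25))
  expect_equal(sum(p$freqs), 1)
  expect_equal(p$n_effective, 4L)

  p2 <- column_profile(m, c("a", "b", "c", "d"), 2)
  expect_equal(p2$n_effective, 1L)
  expect_equal(p2$gap_fraction, 0.75)
  expect_equal(unname(p2$freqs["A"]), 1)

  p3 <- column_profile(m, c("a", "b", "d"), 2)
  expect_true(p3$empty)
  expect_equal(p3$n_effective, 0L)
})

test_that("profile frequencies sum to one on simulated columns", {
  m <- sig_fixture$msa
  ids <- grep("^g0", m$ids, value = TRUE)
  set.seed(5)
  for (col in sample(m$n_cols, 25)) {
    p <- column_profile(m, ids, col)
    if (!p$empty) expect_equal(sum(p$freqs), 1)
  }
})

test_that("information content follows the logo formula", {
  uniform <- rep(1 / 20, 20)
  names(uniform) <- larasig:::AA20
  expect_equal(information_content(uniform, 100, correction = FALSE), 0)

  single <- c(1, rep(0, 19))
  names(single) <- larasig:::AA20
  expect_equal(information_content(single, 5, correction = FALSE), log2(20))

  mixed <- c(F = 0.5, L = 0.25, M = 0.25)
  f <- setNames(rep(0, 20), larasig:::AA20)
  f[names(mixed)] <- mixed
  # direct evaluation of R = log2(20) - (H + (s-1)/(2 ln2 n)), clamped at 0
  H <- 1.5
  expect_equal(information_content(f, 4, correction = TRUE),
               max(0, log2(20) - (H + 19 / (2 * log(2) * 4))))
  expect_equal(information_content(f, 50, correction = TRUE),
               log2(20) - (H + 19 / (2 * log(2) * 50)))
  expect_error(information_content(f, 0), "n_effective")
})

test_that("information content decreases when mixing toward uniform", {
  base <- setNames(c(0.7, 0.2, 0.1, rep(0, 17)), larasig:::AA20)
  uniform <- rep(1 / 20, 20)
  bits <- vapply(seq(0, 1, by = 0.1), function(w) {
    information_content(base * (1 - w) + uniform * w, 100, correction = FALSE)
  }, numeric(1))
  expect_true(all(diff(bits) <= 1e-12))
})

test_that("category colors follow the five-color rule", {
  f <- function(res, freq) {
    x <- setNames(rep(0, 20), larasig:::AA20)
    x[res] <- freq
    x[setdiff(larasig:::AA20, res)[1]] <- 1 - freq
    x
  }
  expect_equal(assign_category_color("catalytic", f("A", 0.2), "D"), "green")
  expect_equal(assign_category_color("npn_binding", f("R", 0.99), "R"), "blue")
  expect_equal(assign_category_color("substrate", f("F", 0.95), "F", 0.7), "yellow")
  expect_equal(assign_category_color("substrate", f("K", 0.95), "F", 0.7), "red")
  expect_equal(assign_category_color("substrate", f("F", 0.4), "F", 0.7), "black")
  expect_equal(assign_category_color("other", f("I", 0.9), "I", 0.7), "yellow")
})

test_that("signature regions derive from the catalytic anchors", {
  reg <- signature_regions(default_anchor_config())
  expect_equal(reg$loop, c(175L, 176L))
  expect_equal(reg$a11, 297L)
  expect_equal(reg$a14, 358L)
})

test_that("planted groups classify to their activities; broken K298 is excluded", {
  m <- sig_fixture$msa
  cfg <- sig_fixture$cfg
  truth <- sig_fixture$fam$truth
  for (act in unique(truth)) {
    ids <- names(truth)[truth == act]
    prof <- signature_profile(m, ids, cfg)
    cl <- classify_group(prof, cfg)
    expect_true(cl$is_larah)
    expect_equal(cl$predicted_activity, act)
    expect_equal(unname(cl$match_scores[act]), 1)
  }

  # break the K298-equivalent column for the LAR group
  ids <- names(truth)[truth == "LAR"]
  col <- map_anchor_columns(m, cfg)[["298"]]
  broken <- m
  idx <- match(ids, broken$ids)
  substr(broken$seqs[idx], col, col) <- "M"
  prof_b <- signature_profile(broken, ids, cfg)
  cl_b <- classify_group(prof_b, cfg)
  expect_false(cl_b$is_larah)
  expect_equal(cl_b$predicted_activity, "unknown")
  expect_true(298L %in% cl_b$missing_required)
})

test_that("classification ignores member order and k-fold duplication", {
  m <- sig_fixture$msa
  cfg <- sig_fixture$cfg
  truth <- sig_fixture$fam$truth
  ids <- names(truth)[truth == "SAR"]
  p1 <- signature_profile(m, ids, cfg, correction = FALSE)
  p2 <- signature_profile(m, rev(ids), cfg, correction = FALSE)
  expect_equal(attr(p1, "freq_matrix"), attr(p2, "freq_matrix"))
  expect_equal(classify_group(p1, cfg)$predicted_activity,
               classify_group(p2, cfg)$predicted_activity)

  # duplicate every member 3-fold via extra msa rows
  m3 <- msa(c(m$ids, paste0(rep(ids, 2), "_dup", rep(1:2, each = length(ids)))),
            c(m$seqs, rep(m$seqs[match(ids, m$ids)], 2)))
  p3 <- signature_profile(m3, c(ids, paste0(rep(ids, 2), "_dup", rep(1:2, each = length(ids)))),
                          cfg, correction = FALSE)
  expect_equal(attr(p3, "freq_matrix"), attr(p1, "freq_matrix"))
  expect_equal(p3$information_bits, p1$information_bits)
})

test_that("GntE-style structural residues (ES/G/N) classify as GntE", {
  # build a family whose fifth group carries the crystal-structure residues
  sigs <- default_group_signatures(5)
  sigs$GntE <- c("175" = "E", "176" = "S", "297" = "G", "358" = "N")
  fam <- simulate_family(family_sim_config(group_signatures = sigs,
                                           background_mutation_rate = 0,
                                           indel_rate = 0, group_divergence_rate = 0,
                                           seed = 3))
  recs <- rbind(fam$reference, fam$records)
  class(recs) <- c("protein_set", "data.frame")
  m <- progressive_align(recs)
  ids <- names(fam$truth)[fam$truth == "GntE"]
  cl <- classify_group(signature_profile(m, ids, default_anchor_config()),
                       default_anchor_config())
  expect_equal(cl$predicted_activity, "GntE")
})

test_that("activity signature table round trips through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(lapply(builtin_activity_signatures(), identity), path,
                       auto_unbox = FALSE)
  back <- load_activity_signatures(path)
  expect_equal(lapply(back, lapply, as.character),
               lapply(builtin_activity_signatures(), lapply, as.character))
})

test_that("text logo renders one column per anchor", {
  truth <- sig_fixture$fam$truth
  ids <- names(truth)[truth == "LAR"]
  prof <- signature_profile(sig_fixture$msa, ids, sig_fixture$cfg)
  lines <- format_text_logo(prof, height = 6)
  expect_true(length(lines) >= 6)
  expect_true(any(grepl("F", lines, fixed = TRUE)))
})
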