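noise_free_cfg <- function(n_groups = 2, members = 3, seed = 1) {
  family_sim_config(n_groups = n_groups, members_per_group = members,
                    background_mutation_rate = 0, indel_rate = 0,
                    group_divergence_rate = 0, seed = seed)
}

test_that("noise-free families are identical within and differ only at substrate anchors", {
  fam <- simulate_family(noise_free_cfg())
  g1 <- fam$records$sequence[fam$truth == "LAR"]
  g2 <- fam$records$sequence[fam$truth == "SAR"]
  expect_length(unique(g1), 1L)
  expect_length(unique(g2), 1L)
  c1 <- strsplit(g1[1], "")[[1]]
  c2 <- strsplit(g2[1], "")[[1]]
  diffs <- which(c1 != c2)
  substrate <- with(default_anchor_config()$anchors, position[category == "substrate"])
  expect_true(all(diffs %in% substrate))
  expect_gt(length(diffs), 0L)
  # reference carries conserved residues and the group-1 signature
  rc <- strsplit(fam$reference$sequence, "")[[1]]
  expect_equal(rc[c(72, 108, 174, 298)], c("D", "H", "H", "K"))
  expect_equal(rc[c(175, 176, 297, 358)], c("F", "F", "V", "W"))
  expect_identical(rc, c1)
})

test_that("family generation is deterministic given the seed", {
  cfg <- family_sim_config(n_groups = 3, members_per_group = 4, seed = 42)
  a <- simulate_family(cfg)
  b <- simulate_family(cfg)
  expect_identical(a, b)
  c2 <- simulate_family(family_sim_config(n_groups = 3, members_per_group = 4, seed = 43))
  expect_false(identical(a$records$sequence, c2$records$sequence))
})

test_that("indistinguishable group signatures are rejected", {
  sigs <- default_group_signatures(2)
  sigs[[2]] <- sigs[[1]]
  expect_error(family_sim_config(n_groups = 2, group_signatures = sigs),
               "indistinguishable")
})

test_that("anchor map points at the planted residues despite indels", {
  fam <- simulate_family(family_sim_config(n_groups = 3, members_per_group = 5,
                                           indel_rate = 0.02, seed = 9))
  cfg <- default_anchor_config()
  a <- cfg$anchors
  sigs <- default_group_signatures(3)
  for (id in rownames(fam$anchor_map)) {
    ch <- strsplit(fam$records$sequence[fam$records$id == id], "")[[1]]
    g <- fam$truth[[id]]
    for (k in seq_len(nrow(a))) {
      pos <- fam$anchor_map[id, as.character(a$position[k])]
      planted <- if (a$category[k] == "substrate") {
        sigs[[g]][[as.character(a$position[k])]]
      } else a$ref_residue[k]
      expect_identical(ch[pos], planted)
    }
  }
})

test_that("within-group identity matches the i.i.d. substitution expectation", {
  r <- 0.05
  L <- 400
  n_anchor <- 20
  p_match <- (1 - r)^2 + r^2 / 19
  expected <- (n_anchor + (L - n_anchor) * p_match) / L
  obs <- vapply(1:50, function(s) {
    fam <- simulate_family(family_sim_config(
      n_groups = 1, members_per_group = 2, reference_length = L,
      background_mutation_rate = r, indel_rate = 0, group_divergence_rate = 0,
      seed = s))
    a <- strsplit(fam$records$sequence[1], "")[[1]]
    b <- strsplit(fam$records$sequence[2], "")[[1]]
    mean(a == b)
  }, numeric(1))
  se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - expected), 3 * se)
})

test_that("neighborhood simulation honors degenerate probabilities and slot count", {
  truth <- setNames(rep(c("A", "B"), each = 20), sprintf("m%02d", 1:40))
  cfg <- neighborhood_sim_config(
    group_partners = list(A = c(COGX = 1.0), B = c(COGX = 0.0)),
    background_cogs = c(COGF = 1),   # COGX weight zero: never via background
    window = 3, seed = 2)
  nb <- simulate_neighborhoods(truth, cfg)
  per_member <- split(nb$cog, nb$anchor_gene_id)
  expect_true(all(lengths(per_member) == 6L))
  a_members <- names(truth)[truth == "A"]
  b_members <- names(truth)[truth == "B"]
  expect_true(all(vapply(per_member[a_members], function(x) "COGX" %in% x, logical(1))))
  expect_false(any(vapply(per_member[b_members], function(x) "COGX" %in% x, logical(1))))
})

test_that("planted co-occurrence frequency falls in the binomial 99% interval", {
  n <- 100; p <- 0.4
  truth <- setNames(rep("A", n), sprintf("m%03d", 1:n))
  cfg <- neighborhood_sim_config(
    group_partners = list(A = c(COGP = p)),
    background_cogs = setNames(rep(1, 10), paste0("COGB", 1:10)),
    window = 3, seed = 7)
  nb <- simulate_neighborhoods(truth, cfg)
  hits <- sum(vapply(split(nb$cog, nb$anchor_gene_id),
                     function(x) "COGP" %in% x, logical(1)))
  expect_gte(hits, qbinom(0.005, n, p))
  expect_lte(hits, qbinom(0.995, n, p))
})

test_that("too many signature COGs for the window is an error; seeds reproduce", {
  truth <- c(m1 = "A")
  expect_error(neighborhood_sim_config(
    group_partners = list(A = setNames(rep(0.5, 7), paste0("C", 1:7))),
    background_cogs = c(B = 1), window = 3), "flank slots")
  cfg <- neighborhood_sim_config(group_partners = list(A = c(C1 = 0.5)),
                                 background_cogs = c(B = 1), window = 2, seed = 5)
  expect_identical(simulate_neighborhoods(truth, cfg),
                   simulate_neighborhoods(truth, cfg))
})

test_that("kinetics simulator satisfies the model identities at zero noise", {
  km <- 0.38; kcat <- 66; E <- 0.1
  d <- simulate_kinetics(kinetics_sim_config(true_km = km, true_kcat = kcat,
                                             enzyme_conc = E, substrate_grid = km,
                                             noise_cv = 0, replicates = 1, seed = 1))
  expect_equal(d$v, kcat * E / 2)   # half-saturation identity

  # competitive inhibition at I = ki doubles the apparent K_M: at small S the
  # rate halves relative to the uninhibited value
  S0 <- km * 1e-4
  base <- simulate_kinetics(kinetics_sim_config(true_km = km, true_kcat = kcat,
                                                enzyme_conc = E, substrate_grid = S0,
                                                noise_cv = 0, replicates = 1, seed = 1))
  inh <- simulate_kinetics(kinetics_sim_config(true_km = km, true_kcat = kcat,
                                               enzyme_conc = E, substrate_grid = S0,
                                               inhibitor_grid = km, true_ki = km,
                                               noise_cv = 0, replicates = 1, seed = 1))
  expect_equal(inh$v / base$v, 0.5, tolerance = 1e-3)
})

test_that("simulated rate noise has the configured coefficient of variation", {
  cv <- 0.05
  cvs <- vapply(1:200, function(s) {
    d <- simulate_kinetics(kinetics_sim_config(true_km = 1, true_kcat = 10,
                                               enzyme_conc = 1, substrate_grid = 1,
                                               noise_cv = cv, replicates = 10, seed = s))
    sd(d$v) / mean(d$v)
  }, numeric(1))
  se <- sd(cvs) / sqrt(length(cvs))
  expect_lt(abs(mean(cvs) - cv), 3 * se + 0.002)  # small-sample sd bias allowance
})
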