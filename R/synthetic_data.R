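# Synthetic ground-truth generators: protein families with planted group
# signatures, neighborhood tables with planted COG co-occurrence
# probabilities, and noisy initial-rate kinetics from known parameters.
# All generators are pure functions of (config, seed).

#' Default planted group signatures
#'
#' Substrate-anchor residues (positions 175, 176, 297, 358 of the default
#' anchor configuration) for up to five planted activities, chosen to match
#' the built-in activity-signature table: LAR (FF/V/W), SAR (LM/V/W), MAR
#' (QK/Q/K), HGR (NQ/T/Y), GntE (ES/G/N).
#'
#' @param n_groups number of groups (1..5; more require explicit signatures).
#' @return Named list: activity -> named residue vector keyed by position.
#' @export
default_group_signatures <- function(n_groups = 5L) {
  sigs <- list(
    LAR  = c("175" = "F", "176" = "F", "297" = "V", "358" = "W"),
    SAR  = c("175" = "L", "176" = "M", "297" = "V", "358" = "W"),
    MAR  = c("175" = "Q", "176" = "K", "297" = "Q", "358" = "K"),
    HGR  = c("175" = "N", "176" = "Q", "297" = "T", "358" = "Y"),
    GntE = c("175" = "E", "176" = "S", "297" = "G", "358" = "N"))
  if (n_groups > length(sigs)) {
    stop("default signatures cover at most 5 groups; supply group_signatures explicitly",
         call. = FALSE)
  }
  sigs[seq_len(n_groups)]
}

#' Family simulation configuration
#'
#' The stated world of the family generator: groups share conserved
#' catalytic/NPN-binding/other anchor residues, differ at substrate anchors
#' by their planted signature, and diverge by a two-level substitution
#' process — a group ancestor drawn from the reference at
#' `group_divergence_rate`, then members drawn from the ancestor at
#' `background_mutation_rate` — plus geometric indels (mean length 2) that
#' never touch anchors.
#'
#' @param n_groups,members_per_group family shape (default 5 x 10).
#' @param reference_length residues (default 400, enough for the LarA-style
#'   anchor numbering up to 362).
#' @param anchors an `anchor_config` ([default_anchor_config()]).
#' @param group_signatures named list activity -> position-named residues at
#'   substrate anchors; groups must differ at >= 1 anchor.
#' @param conserved_map position-named residues at non-substrate anchors
#'   shared by every group (default: the anchor config's reference residues).
#' @param background_mutation_rate per-site substitution probability within a
#'   group (default 0.05, about 90% within-group identity).
#' @param indel_rate per-site insertion/deletion start probability (default 0.01).
#' @param group_divergence_rate per-site substitution probability between the
#'   reference and each group ancestor (default 0.30).
#' @param seed integer seed.
#' @return A list of class `family_sim_config`.
#' @export
family_sim_config <- function(n_groups = 5L, members_per_group = 10L,
                              reference_length = 400L,
                              anchors = default_anchor_config(),
                              group_signatures = default_group_signatures(n_groups),
                              conserved_map = NULL,
                              background_mutation_rate = 0.05,
                              indel_rate = 0.01,
                              group_divergence_rate = 0.30,
                              seed = 1L) {
  assert_prob(background_mutation_rate, "background_mutation_rate")
  assert_prob(indel_rate, "indel_rate")
  assert_prob(group_divergence_rate, "group_divergence_rate")
  a <- anchors$anchors
  if (reference_length < max(a$position)) {
    stop("reference_length shorter than the largest anchor position", call. = FALSE)
  }
  if (length(group_signatures) != n_groups) {
    stop("need one signature per group", call. = FALSE)
  }
  substrate_pos <- as.character(a$position[a$category == "substrate"])
  for (g in seq_along(group_signatures)) {
    if (!all(substrate_pos %in% names(group_signatures[[g]]))) {
      stop("each group signature must cover all substrate anchors", call. = FALSE)
    }
  }
  # groups must be distinguishable at >= 1 anchor
  sig_strings <- vapply(group_signatures,
                        function(s) paste(s[substrate_pos], collapse = ""), character(1))
  if (anyDuplicated(sig_strings)) {
    stop("two groups share an identical signature at all anchors (indistinguishable)",
         call. = FALSE)
  }
  if (is.null(conserved_map)) {
    keep <- a$category != "substrate"
    conserved_map <- setNames(a$ref_residue[keep], as.character(a$position[keep]))
  }
  need <- as.character(a$position[a$category %in% c("catalytic", "npn_binding")])
  if (!all(need %in% names(conserved_map))) {
    stop("conserved_map must cover all catalytic and npn_binding anchors", call. = FALSE)
  }
  structure(list(n_groups = as.integer(n_groups),
                 members_per_group = as.integer(members_per_group),
                 reference_length = as.integer(reference_length),
                 anchors = anchors, group_signatures = group_signatures,
                 conserved_map = conserved_map,
                 background_mutation_rate = background_mutation_rate,
                 indel_rate = indel_rate,
                 group_divergence_rate = group_divergence_rate,
                 seed = as.integer(seed)),
            class = "family_sim_config")
}

# substitute each eligible site with probability `rate`, uniformly over the
# 19 alternative residues
substitute_sites <- function(chars, eligible, rate) {
  if (rate <= 0) return(chars)
  hit <- eligible[runif(length(eligible)) < rate]
  for (i in hit) {
    alt <- AA20[AA20 != chars[i]]
    chars[i] <- alt[sample.int(19L, 1L)]
  }
  chars
}

# apply indels to a mutated copy of the reference; anchors are never deleted
# and insertions never separate the mapping. Returns the sequence and the
# member coordinate of every reference position (NA when deleted).
apply_indels <- function(chars, anchor_pos, indel_rate) {
  L <- length(chars)
  is_anchor <- rep(FALSE, L)
  is_anchor[anchor_pos] <- TRUE
  out <- character(0)
  ref_of <- integer(0)
  i <- 1L
  while (i <= L) {
    if (!is_anchor[i] && indel_rate > 0) {
      u <- runif(1)
      if (u < indel_rate / 2) {           # deletion run, geometric mean 2
        len <- rgeom(1, 0.5) + 1L
        while (len > 0L && i <= L && !is_anchor[i]) { i <- i + 1L; len <- len - 1L }
        next
      } else if (u < indel_rate) {        # insertion run after this site
        ins <- AA20[sample.int(20L, rgeom(1, 0.5) + 1L, replace = TRUE)]
        out <- c(out, chars[i], ins)
        ref_of <- c(ref_of, i, rep(NA_integer_, length(ins)))
        i <- i + 1L
        next
      }
    }
    out <- c(out, chars[i])
    ref_of <- c(ref_of, i)
    i <- i + 1L
  }
  member_pos <- match(seq_len(L), ref_of)
  list(seq = chars_to_seq(out), member_pos = member_pos)
}

#' Simulate a protein family with planted group signatures
#'
#' @param config a [family_sim_config()].
#' @return List: `records` (a [protein_set()] with `group_label` set to the
#'   planted activity), `truth` (named member -> group label vector),
#'   `reference` (single-row [protein_set()], conserved residues at
#'   non-substrate anchors and the group-1 signature at substrate anchors),
#'   `anchor_map` (members x anchors matrix of member coordinates of each
#'   anchor), `ancestors` (group ancestor sequences).
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "family_sim_config"))
  a <- config$anchors$anchors
  anchor_pos <- a$position
  with_seed(config$seed, {
    L <- config$reference_length
    ref_chars <- AA20[sample.int(20L, L, replace = TRUE)]
    ref_chars[as.integer(names(config$conserved_map))] <- config$conserved_map
    sig1 <- config$group_signatures[[1L]]
    ref_chars[as.integer(names(sig1))] <- sig1

    groups <- names(config$group_signatures)
    if (is.null(groups)) groups <- as.character(seq_along(config$group_signatures))
    non_anchor <- setdiff(seq_len(L), anchor_pos)

    ids <- character(0); seqs <- character(0); labels <- character(0)
    anc_seqs <- character(length(groups))
    amap <- list()
    for (g in seq_along(groups)) {
      anc <- ref_chars
      sig <- config$group_signatures[[g]]
      anc[as.integer(names(sig))] <- sig
      anc <- substitute_sites(anc, non_anchor, config$group_divergence_rate)
      anc_seqs[g] <- chars_to_seq(anc)
      for (mb in seq_len(config$members_per_group)) {
        mem <- substitute_sites(anc, non_anchor, config$background_mutation_rate)
        res <- apply_indels(mem, anchor_pos, config$indel_rate)
        id <- sprintf("g%02d_m%03d", g, mb)
        ids <- c(ids, id); seqs <- c(seqs, res$seq); labels <- c(labels, groups[g])
        amap[[id]] <- res$member_pos[anchor_pos]
      }
    }
    anchor_map <- do.call(rbind, amap)
    colnames(anchor_map) <- as.character(anchor_pos)
    list(records = protein_set(ids, seqs, species = "synthetic family member",
                               group_label = labels),
         truth = setNames(labels, ids),
         reference = protein_set(config$anchors$reference_id, chars_to_seq(ref_chars),
                                 species = "synthetic reference"),
         anchor_map = anchor_map,
         ancestors = setNames(anc_seqs, groups))
  })
}

#' Neighborhood simulation configuration
#'
#' @param group_partners named list: group label -> named probability vector
#'   (COG -> inclusion probability in each member's flank).
#' @param background_cogs named numeric vector of sampling weights for filler
#'   COGs.
#' @param window flank half-width (default 3: three genes on each side).
#' @param seed integer seed.
#' @return A list of class `neighborhood_sim_config`.
#' @export
neighborhood_sim_config <- function(group_partners, background_cogs,
                                    window = 3L, seed = 1L) {
  if (window < 1) stop("`window` must be >= 1", call. = FALSE)
  for (g in names(group_partners)) assert_prob(group_partners[[g]], paste0("p[", g, "]"))
  if (any(background_cogs < 0)) stop("background weights must be >= 0", call. = FALSE)
  over <- vapply(group_partners, length, integer(1)) > 2L * window
  if (any(over)) {
    stop(sprintf("group(s) %s have more signature COGs than 2*window flank slots",
                 paste(names(group_partners)[over], collapse = ", ")), call. = FALSE)
  }
  structure(list(group_partners = group_partners,
                 background_cogs = background_cogs,
                 window = as.integer(window), seed = as.integer(seed)),
            class = "neighborhood_sim_config")
}

#' Simulate gene neighborhoods with planted COG co-occurrence
#'
#' Each member gets exactly `2 * window` flanking genes: every signature COG
#' of its group is included independently with its planted probability and
#' the remaining slots are filled from the background pool; offsets are a
#' random assignment of `-window..-1, 1..window`.
#'
#' @param truth named member -> group label vector ([simulate_family()] truth).
#' @param config a [neighborhood_sim_config()].
#' @return A `neighborhood_set` (genome per member: `"genome_<member>"`).
#' @export
simulate_neighborhoods <- function(truth, config) {
  stopifnot(inherits(config, "neighborhood_sim_config"))
  w <- config$window
  offsets <- c(seq.int(-w, -1L), seq.int(1L, w))
  bg <- config$background_cogs
  with_seed(config$seed, {
    members <- sort(names(truth))
    rows <- vector("list", length(members))
    for (k in seq_along(members)) {
      m <- members[k]
      p <- config$group_partners[[truth[[m]]]]
      present <- if (length(p)) names(p)[runif(length(p)) < p] else character(0)
      n_fill <- 2L * w - length(present)
      fill <- if (n_fill > 0L) {
        sample(names(bg), n_fill, replace = TRUE, prob = bg)
      } else character(0)
      cogs <- c(present, fill)
      rows[[k]] <- data.frame(genome_id = paste0("genome_", m),
                              anchor_gene_id = m,
                              offset = sample(offsets, 2L * w),
                              cog = cogs, stringsAsFactors = FALSE)
    }
    neighborhood_set(do.call(rbind, rows))
  })
}

#' Kinetics simulation configuration
#'
#' @param true_km Michaelis constant (mM).
#' @param true_kcat turnover number (per second).
#' @param enzyme_conc enzyme concentration (uM).
#' @param substrate_grid substrate concentrations (mM); default 8 points
#'   geometric from `true_km / 5` to `5 * true_km`, spanning the constant.
#' @param inhibitor_grid optional inhibitor concentrations (mM); requires
#'   `true_ki`.
#' @param true_ki competitive inhibition constant (mM).
#' @param noise_cv relative standard deviation of the rate (default 0.05).
#' @param replicates measurements per grid point (default 3).
#' @param seed integer seed.
#' @return A list of class `kinetics_sim_config`.
#' @export
kinetics_sim_config <- function(true_km, true_kcat, enzyme_conc = 0.1,
                                substrate_grid = NULL, inhibitor_grid = NULL,
                                true_ki = NULL, noise_cv = 0.05,
                                replicates = 3L, seed = 1L) {
  if (true_km <= 0 || true_kcat <= 0 || enzyme_conc <= 0) {
    stop("km, kcat and enzyme concentration must be > 0", call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (is.null(substrate_grid)) {
    substrate_grid <- true_km * 5^seq(-1, 1, length.out = 8L)
  }
  if (any(substrate_grid <= 0)) stop("substrate concentrations must be > 0", call. = FALSE)
  if (!is.null(inhibitor_grid)) {
    if (is.null(true_ki) || true_ki <= 0) {
      stop("inhibitor grid requires a positive true_ki", call. = FALSE)
    }
    if (any(inhibitor_grid < 0)) stop("inhibitor concentrations must be >= 0", call. = FALSE)
  }
  structure(list(true_km = true_km, true_kcat = true_kcat,
                 enzyme_conc = enzyme_conc, substrate_grid = substrate_grid,
                 inhibitor_grid = inhibitor_grid, true_ki = true_ki,
                 noise_cv = noise_cv, replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "kinetics_sim_config")
}

#' Simulate initial-rate kinetics
#'
#' Rates follow the (competitively inhibited) Michaelis-Menten model
#' `v = kcat * E * S / (km * (1 + I / ki) + S)` with multiplicative Gaussian
#' noise of coefficient of variation `noise_cv`.
#'
#' @param config a [kinetics_sim_config()].
#' @return A [kinetics_dataset()].
#' @export
simulate_kinetics <- function(config) {
  stopifnot(inherits(config, "kinetics_sim_config"))
  I_grid <- if (is.null(config$inhibitor_grid)) NA_real_ else config$inhibitor_grid
  grid <- expand.grid(replicate = seq_len(config$replicates),
                      I = I_grid, S = config$substrate_grid,
                      KEEP.OUT.ATTRS = FALSE)
  inhib_term <- ifelse(is.na(grid$I), 1, 1 + grid$I / (config$true_ki %||% Inf))
  v_true <- config$true_kcat * config$enzyme_conc * grid$S /
    (config$true_km * inhib_term + grid$S)
  v <- with_seed(config$seed,
                 v_true * (1 + rnorm(length(v_true), 0, config$noise_cv)))
  kinetics_dataset(S = grid$S, v = v, I = grid$I, replicate = grid$replicate,
                   enzyme_conc = config$enzyme_conc)
}
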