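# Structure-anchored signature profiles: map reference anchor residues
# through the alignment, compute per-group residue frequencies and
# information content, color anchors by the five-category rule, and classify
# groups by conserved-motif activity signatures.

#' Map anchor positions to alignment columns
#'
#' Each anchor is a 1-based position on the ungapped reference; its alignment
#' column is shared by all rows, which is what makes per-group logos
#' comparable across the family.
#'
#' @param m an [msa()] containing the reference row.
#' @param config an `anchor_config` (see [default_anchor_config()]).
#' @return Integer vector of 1-based columns, named by anchor position.
#' @export
map_anchor_columns <- function(m, config) {
  if (!config$reference_id %in% m$ids) {
    stop(sprintf("reference '%s' absent from alignment", config$reference_id),
         call. = FALSE)
  }
  cols <- msa_col_of(m, config$reference_id, config$anchors$position)
  if (anyDuplicated(cols)) stop("anchor columns are not distinct", call. = FALSE)
  setNames(as.integer(cols), as.character(config$anchors$position))
}

#' Residue profile of one alignment column for a set of members
#'
#' Frequencies are over the non-gap residues of the selected rows; rows
#' gapped at the column are excluded from the frequencies (never treated as
#' a 21st symbol) and tracked in `gap_fraction`.
#'
#' @param m an [msa()].
#' @param member_ids rows to profile.
#' @param column 1-based alignment column.
#' @return List: `freqs` (named over the 20 residues, summing to 1),
#'   `gap_fraction`, `n_effective`. When every row is gapped, `n_effective`
#'   is 0, `freqs` is `NA` and the profile is flagged `empty = TRUE`.
#' @export
column_profile <- function(m, member_ids, column) {
  if (!length(member_ids)) stop("empty member set", call. = FALSE)
  idx <- match(member_ids, m$ids)
  if (anyNA(idx)) {
    stop(sprintf("member(s) absent from msa: %s",
                 paste(member_ids[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  res <- substring(m$seqs[idx], column, column)
  gaps <- res == "-"
  n_eff <- sum(!gaps)
  if (n_eff == 0L) {
    return(list(freqs = setNames(rep(NA_real_, 20L), AA20), gap_fraction = 1,
                n_effective = 0L, empty = TRUE))
  }
  counts <- table(factor(res[!gaps], levels = AA20))
  freqs <- setNames(as.numeric(counts) / n_eff, AA20)
  list(freqs = freqs, gap_fraction = sum(gaps) / length(gaps),
       n_effective = as.integer(n_eff), empty = FALSE)
}

#' Sequence-logo information content of a column profile
#'
#' The standard logo statistic over a 20-letter alphabet:
#' `R = log2(20) - (H + e_n)` with Shannon entropy `H = -sum f log2 f` and
#' small-sample correction `e_n = (s - 1) / (2 ln 2 n)`, `s = 20`, clamped
#' at zero.
#'
#' @param freqs residue frequency vector (sums to 1).
#' @param n_effective number of sequences contributing a residue.
#' @param correction apply the small-sample correction (default TRUE).
#' @return Bits in `[0, log2(20)]`.
#' @export
information_content <- function(freqs, n_effective, correction = TRUE) {
  if (n_effective < 1) stop("n_effective must be >= 1 (empty profiles carry no information)",
                            call. = FALSE)
  f <- freqs[freqs > 0]
  if (abs(sum(freqs) - 1) > 1e-6) stop("frequencies must sum to 1", call. = FALSE)
  H <- -sum(f * log2(f))
  e_n <- if (correction) (20 - 1) / (2 * log(2) * n_effective) else 0
  max(0, log2(20) - (H + e_n))
}

#' Five-category anchor coloring
#'
#' Reproduces the logo color rule: catalytic anchors are green and
#' NPN-binding anchors blue regardless of conservation (a separate
#' conservation flag is carried by the profile); for the remaining anchors,
#' a conserved column (dominant residue frequency >= threshold) is yellow
#' when the dominant residue equals the reference residue and red when it
#' differs, and a non-conserved column is black.
#'
#' @param category anchor category.
#' @param freqs column frequency vector.
#' @param ref_residue reference residue at the anchor.
#' @param conservation_threshold dominant-frequency cutoff (default 0.7).
#' @return One of `"green"`, `"blue"`, `"yellow"`, `"red"`, `"black"`.
#' @export
assign_category_color <- function(category, freqs, ref_residue,
                                  conservation_threshold = 0.7) {
  if (category == "catalytic") return("green")
  if (category == "npn_binding") return("blue")
  dom <- dominant_residue(freqs)
  if (freqs[dom] >= conservation_threshold) {
    if (dom == ref_residue) "yellow" else "red"
  } else "black"
}

# Maximal-frequency residue; ties broken to the alphabetically smallest.
dominant_residue <- function(freqs) {
  names(freqs)[which.max(freqs)]  # names are alphabetical, which.max takes first
}

#' Signature profile of one group across all anchors
#'
#' @param m an [msa()].
#' @param member_ids group members (reference excluded by the caller).
#' @param config anchor configuration.
#' @param conservation_threshold dominant-frequency cutoff.
#' @param correction small-sample correction for information content.
#' @return A data frame of class `signature_profile`: one row per anchor with
#'   `position`, `ref_residue`, `category`, `dominant`, `dominant_freq`,
#'   `gap_fraction`, `n_effective`, `information_bits`, `conserved`, `color`;
#'   attribute `freq_matrix` (anchors x 20) for plotting/logos.
#' @export
signature_profile <- function(m, member_ids, config, conservation_threshold = 0.7,
                              correction = TRUE) {
  cols <- map_anchor_columns(m, config)
  a <- config$anchors
  fm <- matrix(NA_real_, nrow = nrow(a), ncol = 20L,
               dimnames = list(as.character(a$position), AA20))
  rows <- vector("list", nrow(a))
  for (k in seq_len(nrow(a))) {
    prof <- column_profile(m, member_ids, cols[[k]])
    if (prof$empty) {
      rows[[k]] <- data.frame(position = a$position[k], ref_residue = a$ref_residue[k],
                              category = a$category[k], dominant = NA_character_,
                              dominant_freq = NA_real_, gap_fraction = 1,
                              n_effective = 0L, information_bits = NA_real_,
                              conserved = FALSE, color = "black",
                              stringsAsFactors = FALSE)
      next
    }
    fm[k, ] <- prof$freqs
    dom <- dominant_residue(prof$freqs)
    rows[[k]] <- data.frame(
      position = a$position[k], ref_residue = a$ref_residue[k],
      category = a$category[k], dominant = dom,
      dominant_freq = unname(prof$freqs[dom]),
      gap_fraction = prof$gap_fraction, n_effective = prof$n_effective,
      information_bits = information_content(prof$freqs, prof$n_effective, correction),
      conserved = unname(prof$freqs[dom]) >= conservation_threshold,
      color = assign_category_color(a$category[k], prof$freqs, a$ref_residue[k],
                                    conservation_threshold),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "freq_matrix") <- fm
  class(out) <- c("signature_profile", "data.frame")
  out
}

#' Substrate-recognition regions derived from the anchor configuration
#'
#' The three regions come from structural comparison of family members:
#' `loop` = the two residues just after the second catalytic histidine
#' (F175/F176 in LarA), `a11` = the residue preceding the catalytic lysine
#' (V297), `a14` = the remaining substrate-category anchor, the helix-14
#' residue pointing at the substrate side chain (W358).
#'
#' @param config an `anchor_config`.
#' @return Named list of integer position vectors: `loop`, `a11`, `a14`.
#' @export
signature_regions <- function(config) {
  a <- config$anchors
  his <- a$position[a$category == "catalytic" & a$ref_residue == "H"]
  lys <- a$position[a$category == "catalytic" & a$ref_residue == "K"]
  if (length(his) < 1L || length(lys) != 1L) {
    stop("anchor config must contain catalytic His and exactly one catalytic Lys",
         call. = FALSE)
  }
  h2 <- max(his)
  loop <- c(h2 + 1L, h2 + 2L)
  a11 <- lys - 1L
  substrate <- a$position[a$category == "substrate"]
  if (!all(c(loop, a11) %in% a$position)) {
    stop("loop/a11 positions are not anchors in this configuration", call. = FALSE)
  }
  a14 <- setdiff(substrate, c(loop, a11))
  if (length(a14) != 1L) {
    stop("could not identify a unique a14 anchor (substrate-category anchors minus loop/a11)",
         call. = FALSE)
  }
  list(loop = loop, a11 = a11, a14 = a14)
}

#' Built-in activity-signature table
#'
#' Allowed residue strings per substrate-recognition region for the five
#' activities with characterized or strongly suspected members: lactate
#' racemase (LAR: loop FF, a11 V, a14 W), short-chain aliphatic
#' alpha-hydroxyacid racemase (SAR: loop LM or FM), malate racemase (MAR:
#' loop QK or HK — Gln/His followed by Lys replacing the LAR phenylalanines),
#' alpha-hydroxyglutarate racemase (HGR: loop NQ with a11 T, the NQT motif)
#' and gluconate 2-epimerase-like (GntE: loop EV/ES, a11 W or G, a14 A/V/N).
#' An unconstrained region is absent from the entry.
#'
#' @return Named list of class `activity_signatures`; each element maps
#'   region name -> character vector of allowed residue strings.
#' @export
builtin_activity_signatures <- function() {
  structure(list(
    LAR  = list(loop = "FF", a11 = "V", a14 = "W"),
    SAR  = list(loop = c("LM", "FM")),
    MAR  = list(loop = c("QK", "HK")),
    HGR  = list(loop = "NQ", a11 = "T"),
    GntE = list(loop = c("EV", "ES"), a11 = c("W", "G"), a14 = c("A", "V", "N"))
  ), class = "activity_signatures")
}

#' Load an activity-signature table from JSON
#' @param path JSON file: activity -> region -> allowed residue strings.
#' @return An `activity_signatures` list.
#' @export
load_activity_signatures <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sigs <- lapply(raw, function(e) lapply(e, as.character))
  if (any(!lengths(sigs))) stop("each activity must constrain at least one region",
                                call. = FALSE)
  structure(sigs, class = "activity_signatures")
}

#' Classify one group from its signature profile
#'
#' A group is accepted as a LarA homolog (`is_larah`) only when every
#' catalytic and every NPN-binding anchor is conserved with the reference
#' residue as dominant; otherwise the group is excluded (as were the groups
#' whose catalytic/NPN residues were not conserved) and its activity is
#' `"unknown"`. For accepted groups, each activity's `match_score` is the
#' fraction of its constrained regions whose anchors are all conserved and
#' whose dominant-residue string is among the allowed set; the predicted
#' activity is the unique activity with score 1, otherwise `"unknown"` with
#' ranked candidates.
#'
#' @param profile a [signature_profile()] for the group.
#' @param config anchor configuration.
#' @param signatures an `activity_signatures` table.
#' @param conservation_threshold dominant-frequency cutoff (default 0.7).
#' @return A list of class `group_classification`: `is_larah`,
#'   `missing_required`, `predicted_activity`, `match_scores`, `candidates`.
#' @export
classify_group <- function(profile, config, signatures = builtin_activity_signatures(),
                           conservation_threshold = 0.7) {
  a <- config$anchors
  if (!all(a$position %in% profile$position)) {
    stop("profile does not cover all anchors", call. = FALSE)
  }
  prow <- function(pos) profile[match(pos, profile$position), , drop = FALSE]
  required <- a$position[a$category %in% c("catalytic", "npn_binding")]
  req <- prow(required)
  ok <- !is.na(req$dominant) & req$conserved & req$dominant == req$ref_residue
  missing_required <- required[!ok]
  is_larah <- all(ok)

  regions <- signature_regions(config)
  region_string <- function(pos) {
    r <- prow(pos)
    if (anyNA(r$dominant) || !all(r$conserved)) return(NA_character_)
    paste(r$dominant, collapse = "")
  }
  observed <- vapply(regions, region_string, character(1))

  scores <- vapply(signatures, function(sig) {
    hit <- vapply(names(sig), function(rn) {
      obs <- observed[[rn]]
      !is.na(obs) && obs %in% sig[[rn]]
    }, logical(1))
    mean(hit)
  }, numeric(1))

  predicted <- "unknown"
  if (is_larah) {
    perfect <- names(scores)[scores >= 1 - 1e-12]
    if (length(perfect) == 1L) predicted <- perfect
  }
  structure(list(is_larah = is_larah,
                 missing_required = as.integer(missing_required),
                 predicted_activity = predicted,
                 match_scores = scores,
                 candidates = names(sort(scores, decreasing = TRUE))),
            class = "group_classification")
}

#' Plain-text signature logo
#'
#' Stacked-letter rendering of a group's anchor profile for terminal
#' display: one column per anchor, letters sorted by contribution to the
#' column's information content.
#'
#' @param profile a [signature_profile()].
#' @param height character rows (default 8), representing `log2(20)` bits.
#' @return Character vector of lines.
#' @export
format_text_logo <- function(profile, height = 8L) {
  fm <- attr(profile, "freq_matrix")
  total_bits <- profile$information_bits
  n_anchor <- nrow(profile)
  grid <- matrix(" ", nrow = height, ncol = n_anchor)
  max_bits <- log2(20)
  for (k in seq_len(n_anchor)) {
    if (is.na(total_bits[k])) next
    f <- fm[k, ]
    f <- sort(f[f > 0], decreasing = TRUE)
    letter_rows <- round(height * total_bits[k] * f / max_bits)
    col <- unlist(mapply(function(l, r) rep(l, r), names(letter_rows), letter_rows,
                         SIMPLIFY = FALSE))
    if (length(col)) {
      col <- utils::head(col, height)
      grid[seq(height, by = -1L, length.out = length(col)), k] <- col
    }
  }
  lines <- apply(grid, 1L, paste, collapse = " ")
  footer <- paste(formatC(substr(as.character(profile$position), 1, 3), width = 1),
                  collapse = " ")
  c(lines, paste(rep("-", 2L * n_anchor - 1L), collapse = ""),
    paste(substr(profile$ref_residue, 1, 1), collapse = " "))
}

#' Write per-group signature report (TSV) and classification (JSON)
#' @param profiles named list of [signature_profile()]s (one per group).
#' @param path output TSV.
#' @export
write_signature_report <- function(profiles, path) {
  rows <- lapply(names(profiles), function(g) {
    df <- as.data.frame(profiles[[g]])
    cbind(group = g, df)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature_report
#' @param classifications named list of [classify_group()] results.
#' @export
write_classification_json <- function(classifications, path) {
  payload <- lapply(classifications, function(cl) {
    list(is_larah = cl$is_larah,
         missing_required = cl$missing_required,
         predicted_activity = cl$predicted_activity,
         match_scores = as.list(cl$match_scores))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
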