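# Multiple sequence alignment: affine-gap pairwise/profile alignment,
# guide trees, progressive alignment, and coordinate maps.

#' Alignment scoring scheme
#'
#' Substitution matrix plus affine gap penalties. A gap of length k costs
#' `gap_open + k * gap_extend`. Defaults follow common practice for protein
#' alignment (BLOSUM62, open 10, extend 0.5).
#'
#' @param matrix 20x20 substitution matrix with amino-acid dimnames
#'   (default: BLOSUM62 from Biostrings, restricted to the 20 standard
#'   residues).
#' @param gap_open,gap_extend non-negative penalties.
#' @return A list of class `alignment_scoring`.
#' @export
alignment_scoring <- function(matrix = NULL, gap_open = 10, gap_extend = 0.5) {
  if (is.null(matrix)) matrix <- blosum62()
  stopifnot(gap_open >= 0, gap_extend >= 0)
  if (!all(AA20 %in% rownames(matrix)) || !all(AA20 %in% colnames(matrix))) {
    stop("substitution matrix must cover the 20 standard amino acids", call. = FALSE)
  }
  structure(list(matrix = matrix[AA20, AA20], gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "alignment_scoring")
}

blosum62_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(blosum62_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum62_cache$m <- e$BLOSUM62[AA20, AA20]
  }
  blosum62_cache$m
}

# Residue profile of a set of gapped rows: 20 x n_cols matrix of per-column
# residue frequencies normalized by total row weight, so columns with gaps
# carry proportionally less weight. Row weights default to 1; duplicate
# sequences are down-weighted by progressive_align (1/multiplicity) so that
# redundant input does not distort profile frequencies.
profile_of <- function(gapped_rows, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(gapped_rows))
  mats <- lapply(gapped_rows, seq_to_chars)
  chars <- do.call(rbind, mats)
  n_cols <- ncol(chars)
  prof <- matrix(0, nrow = 20L, ncol = n_cols, dimnames = list(AA20, NULL))
  for (a in AA20) prof[a, ] <- colSums((chars == a) * weights)
  prof / sum(weights)
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch-Gotoh alignment with affine gaps and deterministic
#' tie-breaking (diagonal preferred over a gap in `a`, preferred over a gap
#' in `b`, on traceback).
#'
#' @param a,b ungapped amino-acid sequences.
#' @param scoring an [alignment_scoring()].
#' @return list with `a_gapped`, `b_gapped`, `score`.
#' @export
pairwise_align <- function(a, b, scoring = alignment_scoring()) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence", call. = FALSE)
  ca <- seq_to_chars(toupper(a))
  cb <- seq_to_chars(toupper(b))
  if (!all(ca %in% AA20) || !all(cb %in% AA20)) {
    stop("sequences must use the 20-letter amino-acid alphabet", call. = FALSE)
  }
  S <- scoring$matrix[ca, cb, drop = FALSE]
  res <- gotoh_align(S, scoring$gap_open, scoring$gap_extend)
  ga <- gb <- character(length(res$path))
  i <- j <- 0L
  for (k in seq_along(res$path)) {
    mv <- res$path[k]
    if (mv == 1L) { i <- i + 1L; j <- j + 1L; ga[k] <- ca[i]; gb[k] <- cb[j] }
    else if (mv == 2L) { j <- j + 1L; ga[k] <- "-"; gb[k] <- cb[j] }
    else { i <- i + 1L; ga[k] <- ca[i]; gb[k] <- "-" }
  }
  list(a_gapped = chars_to_seq(ga), b_gapped = chars_to_seq(gb), score = res$score)
}

#' Construct a distance matrix object
#'
#' @param d symmetric numeric matrix with values in `[0, 1]`, zero diagonal,
#'   and id dimnames.
#' @return `d` with class `dist_matrix`.
#' @export
distance_matrix <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d))) stop("distance matrix needs id dimnames", call. = FALSE)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero", call. = FALSE)
  if (any(d < 0 | d > 1)) stop("distances must lie in [0, 1]", call. = FALSE)
  colnames(d) <- rownames(d)
  class(d) <- c("dist_matrix", class(d))
  d
}

# Deterministic agglomerative clustering. Returns the merge schedule:
# a list of steps, each with the two member-id sets joined and the linkage
# height. Ties in the minimum linkage distance are broken by the
# lexicographically smallest (representative_i, representative_j) pair,
# where a cluster's representative is its lexicographically smallest member.
agglomerate <- function(d, linkage = c("average", "single", "complete", "wpgma")) {
  linkage <- match.arg(linkage)
  ids <- rownames(d)
  n <- length(ids)
  clusters <- as.list(ids)
  reps <- ids
  sizes <- rep(1L, n)
  D <- unclass(d)
  active <- rep(TRUE, n)
  steps <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    mn <- min(sub)
    cand <- which(sub <= mn + 1e-12, arr.ind = TRUE)
    # tie-break: smallest representative pair, lexicographic
    ri <- reps[idx[cand[, 1]]]
    rj <- reps[idx[cand[, 2]]]
    lo <- pmin(ri, rj); hi <- pmax(ri, rj)
    ord <- order(lo, hi)
    pick <- cand[ord[1L], ]
    i <- idx[pick[1L]]; j <- idx[pick[2L]]
    steps[[s]] <- list(left = clusters[[i]], right = clusters[[j]], height = D[i, j])
    # Lance-Williams update into slot i
    others <- setdiff(idx, c(i, j))
    if (length(others)) {
      new_d <- switch(linkage,
        average  = (sizes[i] * D[i, others] + sizes[j] * D[j, others]) /
                   (sizes[i] + sizes[j]),
        single   = pmin(D[i, others], D[j, others]),
        complete = pmax(D[i, others], D[j, others]),
        wpgma    = (D[i, others] + D[j, others]) / 2)
      D[i, others] <- new_d
      D[others, i] <- new_d
    }
    clusters[[i]] <- sort(c(clusters[[i]], clusters[[j]]))
    reps[i] <- min(reps[i], reps[j])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
  }
  steps
}

#' Build a guide tree from a distance matrix
#'
#' Weighted average-linkage (WPGMA) agglomerative joining with deterministic
#' lexicographic tie-breaking; used to order progressive profile merges.
#' The weighted update makes the tree — and hence the progressive alignment
#' — invariant to duplicated sequences: a duplicate joins its twin at
#' distance zero and the merged pair behaves exactly like the original.
#'
#' @param dm a [distance_matrix()].
#' @return A list of class `guide_tree`: merge steps (`left`, `right`,
#'   `height`) from first to last join.
#' @export
build_guide_tree <- function(dm) {
  if (nrow(dm) < 2L) stop("guide tree needs at least 2 sequences", call. = FALSE)
  structure(agglomerate(unclass(dm), "wpgma"), class = "guide_tree")
}

# 3-mer distance used only to seed the guide tree for progressive alignment:
# 1 - shared k-mer count / smaller k-mer count (Clustal-style quick distance).
kmer_distance_matrix <- function(records, k = 3L) {
  n <- nrow(records)
  tabs <- lapply(records$sequence, function(s) {
    L <- nchar(s)
    if (L < k) return(table(character(0)))
    table(substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L))
  })
  d <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      ti <- tabs[[i]]; tj <- tabs[[j]]
      common <- intersect(names(ti), names(tj))
      shared <- sum(pmin(ti[common], tj[common]))
      denom <- min(sum(ti), sum(tj))
      val <- if (denom == 0) 1 else 1 - shared / denom
      d[i, j] <- d[j, i] <- val
    }
  }
  distance_matrix(d)
}

#' Construct an Msa object
#'
#' @param ids record ids (unique).
#' @param seqs gapped sequences (equal length, `-` for gaps).
#' @return A list of class `msa` with `ids`, `seqs`, `n_cols`.
#' @export
msa <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs))
  if (anyDuplicated(ids)) stop("duplicate ids in msa", call. = FALSE)
  n_cols <- unique(nchar(seqs))
  if (length(n_cols) != 1L) stop("all msa rows must have equal length", call. = FALSE)
  structure(list(ids = as.character(ids), seqs = as.character(seqs),
                 n_cols = as.integer(n_cols)),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns\n", length(x$ids), x$n_cols))
  invisible(x)
}

msa_row <- function(m, id) {
  i <- match(id, m$ids)
  if (is.na(i)) stop(sprintf("id '%s' not in msa", id), call. = FALSE)
  m$seqs[i]
}

#' Coordinate maps between alignment columns and ungapped positions
#'
#' `msa_col_of` maps a 1-based ungapped residue position of a row to its
#' 1-based alignment column; `msa_pos_of` is the inverse (NA at gap columns).
#'
#' @param m an [msa()].
#' @param id row id.
#' @param pos ungapped position(s).
#' @return Integer vector of columns / positions.
#' @export
msa_col_of <- function(m, id, pos) {
  ch <- seq_to_chars(msa_row(m, id))
  cols <- which(ch != "-")
  if (any(pos < 1L | pos > length(cols))) {
    stop("ungapped position out of range", call. = FALSE)
  }
  cols[pos]
}

#' @rdname msa_col_of
#' @param col alignment column(s).
#' @export
msa_pos_of <- function(m, id, col) {
  ch <- seq_to_chars(msa_row(m, id))
  if (any(col < 1L | col > length(ch))) stop("column out of range", call. = FALSE)
  pos_map <- cumsum(ch != "-")
  out <- pos_map[col]
  out[ch[col] == "-"] <- NA_integer_
  as.integer(out)
}

#' Degap an msa row back to its input sequence
#' @param m an [msa()].
#' @param id row id.
#' @return Ungapped sequence string.
#' @export
msa_degap <- function(m, id) gsub("-", "", msa_row(m, id), fixed = TRUE)

#' Progressive multiple sequence alignment
#'
#' Profile-profile progressive alignment along an average-linkage guide tree
#' built from a quick 3-mer distance. Column pairs are scored by the
#' expectation of the substitution matrix under the two column profiles
#' (gap symbols contribute zero), with affine gap penalties.
#'
#' @param records a [protein_set()] (>= 1 record).
#' @param scoring an [alignment_scoring()].
#' @return An [msa()]; rows degap exactly to the input sequences.
#' @export
progressive_align <- function(records, scoring = alignment_scoring()) {
  n <- nrow(records)
  if (n == 0L) stop("no records to align", call. = FALSE)
  if (n == 1L) return(msa(records$id, records$sequence))
  tree <- build_guide_tree(kmer_distance_matrix(records))
  # duplicate sequences share one sequence's worth of profile weight, so
  # adding a copy of a record never changes the alignment of the others
  mult <- table(records$sequence)
  weight <- as.numeric(1 / mult[records$sequence])
  blocks <- lapply(seq_len(n), function(i) {
    list(ids = records$id[i], rows = records$sequence[i], w = weight[i])
  })
  names(blocks) <- records$id
  key_of <- function(ids) min(ids)
  for (step in tree) {
    a <- blocks[[key_of(step$left)]]
    b <- blocks[[key_of(step$right)]]
    merged <- align_profiles(a, b, scoring)
    blocks[[key_of(c(step$left, step$right))]] <- merged
  }
  final <- blocks[[key_of(records$id)]]
  ord <- match(records$id, final$ids)
  msa(final$ids[ord], final$rows[ord])
}

# Merge two aligned blocks by profile-profile Gotoh alignment. Gap costs
# are scaled per column by its non-gap fraction so that new gaps
# preferentially co-locate with existing ones (position-specific gap
# penalties in the ClustalW tradition).
align_profiles <- function(a, b, scoring) {
  pa <- profile_of(a$rows, a$w)
  pb <- profile_of(b$rows, b$w)
  occ_a <- colSums(pa)
  occ_b <- colSums(pb)
  S <- t(pa) %*% scoring$matrix %*% pb
  # residue-vs-gap pairs inside a diagonal move are charged like a short
  # gap, so residues cannot thread through sparsely occupied columns free
  gp <- scoring$gap_open / 2 + scoring$gap_extend
  S <- S - gp * (outer(occ_a, 1 - occ_b) + outer(1 - occ_a, occ_b))
  res <- gotoh_align(S, scoring$gap_open, scoring$gap_extend,
                     wa_ = occ_a, wb_ = occ_b)
  path <- res$path
  gap_a <- path == 2L  # insert gap column into block a
  gap_b <- path == 3L
  expand <- function(rows, gap_here, take) {
    vapply(rows, function(r) {
      ch <- seq_to_chars(r)
      out <- character(length(path))
      out[gap_here] <- "-"
      out[!gap_here] <- ch
      chars_to_seq(out)
    }, character(1), USE.NAMES = FALSE)
  }
  list(ids = c(a$ids, b$ids),
       rows = c(expand(a$rows, gap_a), expand(b$rows, gap_b)),
       w = c(a$w, b$w))
}

#' p-distance matrix from an alignment
#'
#' `d(i, j)` is 1 minus the fraction of identical residues over columns where
#' neither row is gapped. Pairs with no comparable columns get distance 1
#' with a warning.
#'
#' @param m an [msa()].
#' @return A [distance_matrix()].
#' @export
p_distance <- function(m) {
  n <- length(m$ids)
  chars <- do.call(rbind, lapply(m$seqs, seq_to_chars))
  is_res <- chars != "-"
  d <- matrix(0, n, n, dimnames = list(m$ids, m$ids))
  warned <- FALSE
  for (i in seq_len(n)) {
    for (j in seq_len(max(0L, i - 1L))) {
      comp <- is_res[i, ] & is_res[j, ]
      nc <- sum(comp)
      if (nc == 0L) {
        d[i, j] <- d[j, i] <- 1
        warned <- TRUE
      } else {
        ident <- sum(chars[i, comp] == chars[j, comp])
        d[i, j] <- d[j, i] <- 1 - ident / nc
      }
    }
  }
  if (warned) warning("pair(s) with no comparable (both-ungapped) columns set to distance 1")
  distance_matrix(d)
}

#' Read / write aligned FASTA
#'
#' External alignments are first-class: any aligner's FASTA output can be
#' ingested and used in place of [progressive_align()].
#'
#' @param path aligned FASTA file.
#' @return An [msa()].
#' @export
read_msa <- function(path) {
  aa <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  msa(ids, toupper(as.character(aa)))
}

#' @rdname read_msa
#' @param m an [msa()].
#' @export
write_msa <- function(m, path) {
  x <- Biostrings::BStringSet(m$seqs)
  names(x) <- m$ids
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Write a distance matrix as TSV
#' @param dm a [distance_matrix()].
#' @param path output file.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(id = rownames(dm), unclass(dm), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
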