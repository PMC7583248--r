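# Independent oracles and tiny fixture builders shared across the suite.
# The alignment oracle is a plain-R Gotoh implementation kept deliberately
# separate from the package's C++ path.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_seq <- function(len) paste(sample(AA, len, replace = TRUE), collapse = "")

# Quadratic-space affine-gap global alignment score (no traceback).
# Cost convention matches the package: a gap of length k costs
# gap_open + k * gap_extend, terminal gaps included.
oracle_align_score <- function(a, b, scoring = alignment_scoring()) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  M <- matrix(-Inf, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)  # gap in b (a advances)
  Y <- matrix(-Inf, n + 1, m + 1)  # gap in a
  go <- scoring$gap_open; ge <- scoring$gap_extend
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(go + ge * (i - 1))
  for (j in 2:(m + 1)) Y[1, j] <- -(go + ge * (j - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- scoring$matrix[ca[i - 1], cb[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge, Y[i - 1, j] - go - ge)
      Y[i, j] <- max(M[i, j - 1] - go - ge, Y[i, j - 1] - ge, X[i, j - 1] - go - ge)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Score an already-aligned pair of gapped rows under the standard scheme
# (both-gap columns dropped; each gap run costs open + len * extend).
induced_pair_score <- function(ga, gb, scoring = alignment_scoring()) {
  a <- strsplit(ga, "")[[1]]
  b <- strsplit(gb, "")[[1]]
  keep <- !(a == "-" & b == "-")
  a <- a[keep]; b <- b[keep]
  score <- 0
  run_a <- 0L; run_b <- 0L
  close_run <- function(len) if (len > 0) scoring$gap_open + len * scoring$gap_extend else 0
  for (k in seq_along(a)) {
    if (a[k] == "-") {
      run_a <- run_a + 1L
      score <- score - close_run(run_b); run_b <- 0L
    } else if (b[k] == "-") {
      run_b <- run_b + 1L
      score <- score - close_run(run_a); run_a <- 0L
    } else {
      score <- score - close_run(run_a) - close_run(run_b)
      run_a <- 0L; run_b <- 0L
      score <- score + scoring$matrix[a[k], b[k]]
    }
  }
  score - close_run(run_a) - close_run(run_b)
}

# hand-counted p-distance on a gapped pair
oracle_p_distance <- function(ga, gb) {
  a <- strsplit(ga, "")[[1]]
  b <- strsplit(gb, "")[[1]]
  comp <- a != "-" & b != "-"
  if (!sum(comp)) return(1)
  1 - sum(a[comp] == b[comp]) / sum(comp)
}

write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

write_tmp_tsv <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# small two-block distance matrix: within `w`, between `b`
block_dm <- function(ids1, ids2, w = 0.05, b = 0.8) {
  ids <- c(ids1, ids2)
  d <- matrix(b, length(ids), length(ids), dimnames = list(ids, ids))
  d[ids1, ids1] <- w
  d[ids2, ids2] <- w
  diag(d) <- 0
  distance_matrix(d)
}
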