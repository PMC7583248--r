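# Shared constants and small internal helpers.

# The 20 standard amino acids, alphabetical. All sequence containers in the
# package are restricted to this alphabet (no gaps, no ambiguity codes).
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Run code under a temporary RNG seed
#'
#' Evaluates `code` with the global RNG seeded at `seed` and restores the
#' previous RNG state afterwards, so generators are pure functions of their
#' configuration and never perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# FNV-1a 32-bit hash of a character string, returned as 8 hex digits.
# Used only to stamp run manifests with a config fingerprint.
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(lo8, b %% 256)  # xor touches only the low byte
    # multiply by the FNV prime modulo 2^32 in 16-bit halves to stay exact
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

seq_to_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

chars_to_seq <- function(ch) paste(ch, collapse = "")

#' Adjusted Rand index between two partitions
#'
#' Agreement between a computed grouping and a reference partition; 1 for
#' identical partitions, about 0 for independent ones.
#'
#' @param a,b label vectors over the same elements (names, if present, are used
#'   to align them).
#' @return numeric scalar.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y"))
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) {
      stop("partitions cover different element sets", call. = FALSE)
    }
    b <- b[names(a)]
  }
  if (length(a) != length(b)) stop("partitions have different lengths", call. = FALSE)
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
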