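# Gene-neighborhood (genomic context) association analysis: for each
# phylogenetic group, the fraction of members whose flanking genes contain a
# given COG, and the >30%-association filter used to flag putative
# functional partners.

#' Per-group COG association table
#'
#' For every (group, COG) pair: the number of members whose neighborhood
#' contains the COG at least once (presence/absence semantics — a COG seen
#' at two offsets still counts once) and the fraction of the group size.
#' Members without a neighborhood record still count in the group size.
#'
#' @param grouping a [family_grouping()]; member ids must match
#'   `anchor_gene_id` in the neighborhood table.
#' @param neighborhoods a `neighborhood_set` from [read_neighborhoods()] or
#'   [simulate_neighborhoods()].
#' @param window flank window half-width re-applied defensively (default 3).
#' @param exclude COGs omitted from the output (default the core NPN
#'   biosynthesis genes larB, larC, larE, whose presence is expected and
#'   uninformative).
#' @return A data frame of class `association_table` with columns `group`,
#'   `cog`, `count`, `group_size`, `fraction`; attribute `group_sizes`.
#' @export
associate <- function(grouping, neighborhoods, window = 3L,
                      exclude = c("larB", "larC", "larE")) {
  if (window <= 0) stop("`window` must be positive", call. = FALSE)
  nb <- as.data.frame(neighborhoods)
  nb <- nb[abs(nb$offset) <= window, , drop = FALSE]
  labels <- grouping_labels(grouping)
  missing_nb <- setdiff(names(labels), unique(nb$anchor_gene_id))
  if (length(missing_nb)) {
    message(sprintf("%d member(s) have no neighborhood record (still counted in group sizes)",
                    length(missing_nb)))
  }
  nb <- nb[nb$anchor_gene_id %in% names(labels), , drop = FALSE]
  # presence per (member, cog)
  pres <- unique(nb[, c("anchor_gene_id", "cog")])
  pres$group <- labels[pres$anchor_gene_id]
  sizes <- vapply(grouping$groups, length, integer(1))
  rows <- list()
  for (g in names(grouping$groups)) {
    sub <- pres[pres$group == g & !(pres$cog %in% exclude), , drop = FALSE]
    if (!nrow(sub)) next
    counts <- table(sub$cog)
    rows[[g]] <- data.frame(group = g, cog = names(counts),
                            count = as.integer(counts),
                            group_size = sizes[[g]],
                            fraction = as.integer(counts) / sizes[[g]],
                            stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(group = character(), cog = character(), count = integer(),
               group_size = integer(), fraction = numeric())
  }
  out <- out[order(out$group, -out$fraction, out$cog), ]
  rownames(out) <- NULL
  attr(out, "group_sizes") <- sizes
  class(out) <- c("association_table", "data.frame")
  out
}

#' Putative functional partners per group
#'
#' Retains, per group, the COGs whose association fraction is strictly
#' greater than `threshold` (default 0.30, the "more than 30% association"
#' rule), sorted by decreasing fraction. Groups with no qualifying COG are
#' reported with an empty data frame so "no candidate partner" is explicit.
#'
#' @param table an [associate()] result.
#' @param threshold strict lower bound on the fraction.
#' @return Named list (one element per group) of data frames
#'   (`cog`, `fraction`, `count`).
#' @export
top_associations <- function(table, threshold = 0.30) {
  assert_prob(threshold, "threshold")
  sizes <- attr(table, "group_sizes")
  out <- lapply(names(sizes), function(g) {
    sub <- table[table$group == g & table$fraction > threshold, , drop = FALSE]
    sub <- sub[order(-sub$fraction, sub$cog), c("cog", "fraction", "count")]
    rownames(sub) <- NULL
    sub
  })
  names(out) <- names(sizes)
  out
}

#' Write an association table (TSV) and top-partner report (JSON)
#' @param table an [associate()] result.
#' @param path output TSV path.
#' @export
write_associations <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_associations
#' @param partners a [top_associations()] result.
#' @export
write_partners_json <- function(partners, path) {
  payload <- lapply(partners, function(df) {
    if (!nrow(df)) return(list(candidates = list(), note = "no candidate partner"))
    list(candidates = df)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
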