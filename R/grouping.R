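# Partitioning family members into phylogenetic groups from a distance
# matrix, mirroring the clustering of LarA homologs into groups.

#' Family grouping object
#'
#' A partition of member ids into named groups. Produced by
#' [cluster_family()]; group labels are dense integers (as strings) numbered
#' by decreasing group size, ties broken by smallest member id. After
#' [split_group()] labels such as `"7a"`, `"7b"` may appear.
#'
#' @param groups named list: group label -> character vector of member ids.
#' @param method_params list recording linkage and cutoff.
#' @return A list of class `family_grouping`.
#' @export
family_grouping <- function(groups, method_params = list()) {
  if (!length(groups) || any(!lengths(groups))) {
    stop("all groups must be non-empty", call. = FALSE)
  }
  members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(members)) stop("groups must be disjoint", call. = FALSE)
  groups <- lapply(groups, sort)
  structure(list(groups = groups, method_params = method_params),
            class = "family_grouping")
}

#' @export
print.family_grouping <- function(x, ...) {
  cat(sprintf("family_grouping: %d members in %d groups\n",
              length(unlist(x$groups)), length(x$groups)))
  invisible(x)
}

#' Flat member -> group label vector from a grouping
#' @param grouping a [family_grouping()].
#' @return Named character vector.
#' @export
grouping_labels <- function(grouping) {
  labs <- rep(names(grouping$groups), lengths(grouping$groups))
  setNames(labs, unlist(grouping$groups, use.names = FALSE))
}

# Number groups: by decreasing size, ties by smallest member id.
number_groups <- function(member_sets) {
  smallest <- vapply(member_sets, min, character(1))
  ord <- order(-lengths(member_sets), smallest)
  out <- member_sets[ord]
  names(out) <- as.character(seq_along(out))
  out
}

#' Cluster family members into phylogenetic groups
#'
#' Agglomerative clustering of the distance matrix, merging while the
#' linkage distance is at most `cutoff`. Deterministic under lexicographic
#' tie-breaking; singleton groups are permitted.
#'
#' @param dm a [distance_matrix()].
#' @param cutoff distance cutoff in `[0, 1]`.
#' @param linkage one of `"average"`, `"single"`, `"complete"`.
#' @return A [family_grouping()].
#' @export
cluster_family <- function(dm, cutoff = 0.3, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  if (!is.numeric(cutoff) || cutoff < 0 || cutoff > 1) {
    stop("`cutoff` must lie in [0, 1]", call. = FALSE)
  }
  ids <- rownames(dm)
  if (length(ids) == 1L) {
    return(family_grouping(setNames(list(ids), "1"),
                           list(linkage = linkage, cutoff = cutoff)))
  }
  steps <- agglomerate(unclass(dm), linkage)
  sets <- as.list(ids)
  key_of <- function(members) min(members)
  names(sets) <- ids
  for (step in steps) {
    if (step$height > cutoff) break
    merged <- sort(c(step$left, step$right))
    sets[[key_of(step$left)]] <- NULL
    sets[[key_of(step$right)]] <- NULL
    sets[[key_of(merged)]] <- merged
  }
  family_grouping(number_groups(unname(sets)),
                  list(linkage = linkage, cutoff = cutoff))
}

#' Split one group at a tighter cutoff
#'
#' Re-clusters only the named group (as done for group 7 -> 7a/7b when its
#' signature logos were divergent); other groups are untouched. Subgroups
#' are labelled `"<id>a"`, `"<id>b"`, ... in decreasing size order.
#'
#' @param grouping a [family_grouping()].
#' @param group_id label of the group to split.
#' @param dm the [distance_matrix()] covering at least that group's members.
#' @param cutoff2 tighter cutoff; if `>=` the original cutoff the grouping is
#'   returned unchanged with a warning.
#' @return A [family_grouping()].
#' @export
split_group <- function(grouping, group_id, dm, cutoff2) {
  group_id <- as.character(group_id)
  if (!group_id %in% names(grouping$groups)) {
    stop(sprintf("unknown group id '%s'", group_id), call. = FALSE)
  }
  orig_cut <- grouping$method_params$cutoff
  if (!is.null(orig_cut) && cutoff2 >= orig_cut) {
    warning("cutoff2 >= original cutoff; no split performed")
    return(grouping)
  }
  members <- grouping$groups[[group_id]]
  if (length(members) == 1L) {
    warning("group has a single member; no split performed")
    return(grouping)
  }
  sub <- distance_matrix(unclass(dm)[members, members, drop = FALSE])
  subg <- cluster_family(sub, cutoff2, grouping$method_params$linkage %||% "average")
  if (length(subg$groups) == 1L) {
    warning("group did not separate at cutoff2; no split performed")
    return(grouping)
  }
  groups <- grouping$groups
  groups[[group_id]] <- NULL
  sub_sets <- number_groups(unname(subg$groups))
  names(sub_sets) <- paste0(group_id, letters[seq_along(sub_sets)])
  groups <- c(groups, sub_sets)
  family_grouping(groups, modifyList(grouping$method_params,
                                     list(split = list(group = group_id,
                                                       cutoff2 = cutoff2))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
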