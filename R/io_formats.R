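# External representations: FASTA, neighborhood TSV, anchor config JSON,
# kinetics CSV, grouping TSV, and report writers.

#' Construct a protein record collection
#'
#' A `protein_set` is a data frame with columns `id`, `species`, `sequence`
#' and optional `group_label`. Sequences are uppercase strings over the 20
#' standard amino acids; ids are unique.
#'
#' @param id character vector of unique ids.
#' @param sequence character vector of amino-acid sequences.
#' @param species free-text description (default empty).
#' @param group_label optional group assignment.
#' @return A data frame of class `protein_set`.
#' @export
protein_set <- function(id, sequence, species = "", group_label = NA_character_) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop(sprintf("duplicate record id(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  if (any(!nzchar(sequence))) stop("empty sequence not allowed", call. = FALSE)
  bad <- gsub(sprintf("[%s]", paste(AA20, collapse = "")), "", sequence)
  if (any(nzchar(bad))) {
    i <- which(nzchar(bad))[1]
    stop(sprintf("record '%s' contains illegal character(s) '%s' (alphabet is %s)",
                 id[i], substr(bad[i], 1, 1), paste(AA20, collapse = "")),
         call. = FALSE)
  }
  out <- data.frame(id = id, species = rep_len(as.character(species), length(id)),
                    sequence = sequence,
                    group_label = rep_len(as.character(group_label), length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Read protein sequences from FASTA
#'
#' The header token before the first whitespace becomes the record id; the
#' remainder is kept verbatim as `species` metadata. Sequences are uppercased
#' and validated against the 20-letter amino-acid alphabet.
#'
#' @param path FASTA file.
#' @return A [protein_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  aa <- Biostrings::readBStringSet(path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  protein_set(id = ids, sequence = as.character(aa), species = desc)
}

#' Write protein sequences to FASTA
#'
#' @param records a [protein_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  headers <- ifelse(nzchar(records$species),
                    paste(records$id, records$species), records$id)
  x <- Biostrings::BStringSet(records$sequence)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read a gene-neighborhood table
#'
#' Expects a TSV with columns `genome_id`, `anchor_gene_id`, `offset`, `cog`
#' (additional columns such as `strand` are carried along but unused). Rows
#' are grouped into one record per (genome, anchor gene); offsets outside
#' `[-window, window]` are dropped with a warning.
#'
#' @param path TSV file.
#' @param window flank window half-width (genes on each side; default 3).
#' @return A data frame of class `neighborhood_set` with columns
#'   `genome_id`, `anchor_gene_id`, `offset`, `cog`.
#' @export
read_neighborhoods <- function(path, window = 3L) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (window < 1) stop("`window` must be >= 1", call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(first)) {
    return(neighborhood_set(data.frame(genome_id = character(), anchor_gene_id = character(),
                                       offset = integer(), cog = character())))
  }
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("genome_id", "anchor_gene_id", "offset", "cog")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(sprintf("neighborhood TSV missing column(s): %s",
                                 paste(miss, collapse = ", ")), call. = FALSE)
  off_num <- suppressWarnings(as.numeric(df$offset))
  if (any(is.na(off_num)) || any(off_num != round(off_num))) {
    stop("non-integer offset in neighborhood table", call. = FALSE)
  }
  df$offset <- as.integer(off_num)
  if (any(df$offset == 0L)) {
    stop("offset 0 found: anchor cannot be its own neighbor", call. = FALSE)
  }
  out <- abs(df$offset) > window
  if (any(out)) {
    warning(sprintf("%d flank row(s) outside +/-%d window dropped", sum(out), window))
    df <- df[!out, , drop = FALSE]
  }
  neighborhood_set(df[, need])
}

neighborhood_set <- function(df) {
  key <- paste(df$genome_id, df$anchor_gene_id, df$offset)
  if (anyDuplicated(key)) {
    stop("duplicate offset within a neighborhood record", call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("neighborhood_set", "data.frame")
  df
}

#' Write a gene-neighborhood table
#' @param nb a `neighborhood_set`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_neighborhoods <- function(nb, path) {
  write.table(as.data.frame(nb), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default LarA anchor-residue configuration
#'
#' The 20 reference positions used to anchor signature logos across the
#' family, numbered on the ungapped LarA-like reference: the catalytic tetrad
#' (D72, H108, H174, K298), the NPN-cofactor binding triad (R75, K184, H200),
#' the three substrate-recognition regions (loop F175/F176, alpha-11 V297,
#' alpha-14 W358) and further conserved positions.
#'
#' @param reference_id id of the reference record (default `"REF"`).
#' @return An `anchor_config` object: list with `reference_id` and a data
#'   frame `anchors` (`position`, `ref_residue`, `category`).
#' @export
default_anchor_config <- function(reference_id = "REF") {
  anchors <- data.frame(
    position = c(72L, 75L, 108L, 174L, 175L, 176L, 184L, 200L, 220L, 294L,
                 295L, 297L, 298L, 353L, 355L, 356L, 358L, 359L, 360L, 362L),
    ref_residue = c("D", "R", "H", "H", "F", "F", "K", "H", "I", "Y",
                    "Q", "V", "K", "T", "P", "D", "W", "T", "A", "I"),
    category = c("catalytic", "npn_binding", "catalytic", "catalytic",
                 "substrate", "substrate", "npn_binding", "npn_binding",
                 "other", "other", "other", "substrate", "catalytic",
                 "other", "other", "other", "substrate", "other", "other",
                 "other"),
    stringsAsFactors = FALSE)
  new_anchor_config(reference_id, anchors)
}

new_anchor_config <- function(reference_id, anchors) {
  stopifnot(is.data.frame(anchors),
            all(c("position", "ref_residue", "category") %in% names(anchors)))
  anchors$position <- as.integer(anchors$position)
  if (is.unsorted(anchors$position, strictly = TRUE)) {
    stop("anchor positions must be strictly increasing", call. = FALSE)
  }
  bad <- !anchors$category %in% c("catalytic", "npn_binding", "substrate", "other")
  if (any(bad)) {
    stop(sprintf("unknown anchor category: %s",
                 paste(unique(anchors$category[bad]), collapse = ", ")), call. = FALSE)
  }
  structure(list(reference_id = reference_id, anchors = anchors),
            class = "anchor_config")
}

#' Load and validate an anchor configuration
#'
#' Reads a JSON anchor config (`reference_id`, `anchors` with 1-based
#' `position`, `ref_residue`, `category`) and validates every declared
#' residue against the reference sequence; all mismatches are reported in a
#' single error.
#'
#' @param path JSON file.
#' @param reference a single-row [protein_set()] (or a row of one) holding
#'   the reference sequence.
#' @return A validated `anchor_config`.
#' @export
load_anchor_config <- function(path, reference) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- new_anchor_config(raw$reference_id, as.data.frame(raw$anchors))
  validate_anchor_config(cfg, reference)
}

#' @rdname load_anchor_config
#' @param config an `anchor_config` to validate in memory.
#' @export
validate_anchor_config <- function(config, reference) {
  refseq <- reference$sequence[match(config$reference_id, reference$id)]
  if (is.na(refseq)) {
    stop(sprintf("reference id '%s' not found among records", config$reference_id),
         call. = FALSE)
  }
  a <- config$anchors
  if (any(a$position > nchar(refseq))) {
    stop(sprintf("anchor position(s) beyond reference length %d: %s", nchar(refseq),
                 paste(a$position[a$position > nchar(refseq)], collapse = ", ")),
         call. = FALSE)
  }
  actual <- substring(refseq, a$position, a$position)
  bad <- actual != a$ref_residue
  if (any(bad)) {
    msgs <- sprintf("position %d declared %s but reference has %s",
                    a$position[bad], a$ref_residue[bad], actual[bad])
    stop(paste(c("anchor/reference mismatch:", msgs), collapse = "\n  "), call. = FALSE)
  }
  config
}

#' Write an anchor configuration to JSON
#' @param config an `anchor_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_anchor_config <- function(config, path) {
  jsonlite::write_json(list(reference_id = config$reference_id,
                            anchors = config$anchors),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a kinetics dataset from CSV
#'
#' Format: an optional comment line `# enzyme_conc=<uM>` followed by a CSV
#' with columns `S` (substrate, mM), `I` (inhibitor, mM; empty or absent
#' column when none), `v` (initial rate) and `replicate`.
#'
#' @param path CSV file.
#' @param enzyme_conc enzyme concentration in uM; overrides the header line.
#' @return A `kinetics_dataset`: data frame (`S`, `I`, `v`, `replicate`) with
#'   attribute `enzyme_conc`.
#' @export
read_kinetics <- function(path, enzyme_conc = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  econc <- enzyme_conc
  hdr <- grep("^#", lines, value = TRUE)
  if (is.null(econc) && length(hdr)) {
    m <- regmatches(hdr, regexpr("enzyme_conc\\s*=\\s*[0-9.eE+-]+", hdr))
    m <- unlist(m)
    if (length(m)) econc <- as.numeric(sub(".*=\\s*", "", m[1]))
  }
  if (is.null(econc)) stop("enzyme concentration not given (header or argument)", call. = FALSE)
  df <- utils::read.csv(text = lines[!grepl("^#", lines)], stringsAsFactors = FALSE)
  if (!"I" %in% names(df)) df$I <- NA_real_
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  kinetics_dataset(df$S, df$v, I = df$I, replicate = df$replicate, enzyme_conc = econc)
}

#' @rdname read_kinetics
#' @param data a `kinetics_dataset`.
#' @export
write_kinetics <- function(data, path) {
  writeLines(sprintf("# enzyme_conc=%.10g", attr(data, "enzyme_conc")), path)
  suppressWarnings(write.table(as.data.frame(data), path, sep = ",", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Construct a kinetics dataset
#'
#' @param S substrate concentrations (mM), positive.
#' @param v initial rates (concentration per second).
#' @param I inhibitor concentrations (mM) or `NA` when absent.
#' @param replicate replicate ids.
#' @param enzyme_conc enzyme concentration (uM).
#' @param substrate,inhibitor optional names.
#' @return A data frame of class `kinetics_dataset`.
#' @export
kinetics_dataset <- function(S, v, I = NA_real_, replicate = 1L, enzyme_conc,
                             substrate = NA_character_, inhibitor = NA_character_) {
  if (any(S <= 0)) stop("substrate concentrations must be > 0", call. = FALSE)
  if (enzyme_conc <= 0) stop("enzyme concentration must be > 0", call. = FALSE)
  df <- data.frame(S = as.numeric(S), I = as.numeric(rep_len(I, length(S))),
                   v = as.numeric(v),
                   replicate = rep_len(replicate, length(S)))
  attr(df, "enzyme_conc") <- as.numeric(enzyme_conc)
  attr(df, "substrate") <- substrate
  attr(df, "inhibitor") <- inhibitor
  class(df) <- c("kinetics_dataset", "data.frame")
  df
}

#' Read / write a grouping table (member_id, group_id TSV)
#' @param path TSV file.
#' @return A named character vector: member id -> group label.
#' @export
read_grouping <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("member_id", "group_id") %in% names(df))) {
    stop("grouping TSV needs columns member_id, group_id", call. = FALSE)
  }
  setNames(df$group_id, df$member_id)
}

#' @rdname read_grouping
#' @param grouping a [family_grouping()] or named member->group vector.
#' @export
write_grouping <- function(grouping, path) {
  v <- if (inherits(grouping, "family_grouping")) grouping_labels(grouping) else grouping
  df <- data.frame(member_id = names(v), group_id = unname(v), stringsAsFactors = FALSE)
  df <- df[order(df$member_id), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
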