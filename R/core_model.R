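# Domain containers and file I/O for the DE-motif secretion pipeline.
#
# Coordinate convention: motif start positions are 0-based half-open
# internally; every emitted table uses 1-based inclusive coordinates.

VALID_LABELS <- c("secretory", "non_secretory", "unknown")
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a single protein record
#'
#' A protein record bundles an amino-acid sequence with an optional
#' per-residue three-state secondary-structure string (`H` helix, `E` sheet,
#' `C` coil/loop/disordered), a secretion label and a free-text group tag.
#' When working from DSSP-style 8-state assignments, map H/G/I to `H`,
#' E/B to `E` and everything else to `C` before constructing the record.
#'
#' @param id unique identifier.
#' @param sequence amino-acid string over the 20-letter alphabet plus `X`.
#' @param ss optional secondary-structure string over `{H,E,C}`, same length
#'   as `sequence`; `NA` when no structure is available (order-dependent
#'   features are then undefined for this protein).
#' @param label one of `"secretory"`, `"non_secretory"`, `"unknown"`.
#' @param group free string tag used for sub-group analyses.
#' @return an object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, ss = NA_character_,
                           label = "unknown", group = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(sequence)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequence))
    stop("record '", id, "': sequence contains characters outside the ",
         "amino-acid alphabet (20 residues plus X)")
  if (!is.na(ss) && nzchar(ss)) {
    ss <- toupper(ss)
    if (nchar(ss) != nchar(sequence))
      stop("record '", id, "': secondary-structure length (", nchar(ss),
           ") does not match sequence length (", nchar(sequence), ")")
    if (grepl("[^HEC]", ss))
      stop("record '", id, "': secondary-structure string contains states ",
           "outside {H,E,C}")
  } else {
    ss <- NA_character_
  }
  if (!label %in% VALID_LABELS)
    stop("record '", id, "': label '", label, "' not in {",
         paste(VALID_LABELS, collapse = ", "), "}")
  structure(list(id = id, sequence = sequence, ss = ss,
                 label = label, group = group),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s  (%d aa, label=%s, group=%s, ss=%s)\n",
              x$id, nchar(x$sequence), x$label,
              if (nzchar(x$group)) x$group else "-",
              if (is.na(x$ss)) "absent" else "present"))
  invisible(x)
}

new_dataset <- function(records, provenance = "",
                        n_excluded_no_de = 0L, excluded_ids = character(0)) {
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate protein id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(records) <- ids
  structure(list(records = records, provenance = provenance,
                 n_excluded_no_de = n_excluded_no_de,
                 excluded_ids = excluded_ids),
            class = "de_dataset")
}

#' @export
print.de_dataset <- function(x, ...) {
  labs <- dataset_labels(x)
  cat(sprintf("<de_dataset> %d proteins (%d secretory, %d non-secretory, %d unknown)\n",
              length(x$records), sum(labs == "secretory"),
              sum(labs == "non_secretory"), sum(labs == "unknown")))
  if (x$n_excluded_no_de > 0)
    cat(sprintf("  %d record(s) excluded for lacking a DE motif\n",
                x$n_excluded_no_de))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.de_dataset <- function(x) length(x$records)

dataset_labels <- function(dataset)
  vapply(dataset$records, `[[`, character(1), "label")

dataset_groups <- function(dataset)
  vapply(dataset$records, `[[`, character(1), "group")

dataset_ids <- function(dataset) names(dataset$records)

#' Read a labelled protein dataset
#'
#' Combines a tab-separated annotation table (columns `id`, `label`,
#' `group`), a FASTA file of sequences and an optional companion file of
#' per-residue secondary-structure strings (FASTA layout, states `{H,E,C}`,
#' ids matching the table). Records whose sequence contains no `DE`
#' dipeptide are excluded from the analysis set; the exclusion count is
#' reported via `message()` and stored on the returned object.
#'
#' @param table_path TSV file with header `id  label  group`.
#' @param fasta_path FASTA file; every table id must be present.
#' @param ss_path optional FASTA-layout file mapping id to an `{H,E,C}`
#'   string of the same length as the sequence.
#' @param provenance free-text source note stored on the dataset.
#' @return a `de_dataset`.
#' @export
read_dataset <- function(table_path, fasta_path, ss_path = NULL,
                         provenance = "") {
  tab <- utils::read.delim(table_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("id", "label", "group")
  if (!all(need %in% names(tab)))
    stop("dataset table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$id))
    stop("duplicate protein id(s) in table: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  seqs <- read_fasta_named(fasta_path)
  ss <- if (!is.null(ss_path)) read_fasta_named(ss_path) else NULL

  records <- list()
  excluded <- character(0)
  for (i in seq_len(nrow(tab))) {
    id <- tab$id[i]
    if (!id %in% names(seqs))
      stop("id '", id, "' in table but absent from FASTA file")
    rec <- protein_record(id, seqs[[id]],
                          ss = if (!is.null(ss) && id %in% names(ss))
                            ss[[id]] else NA_character_,
                          label = tab$label[i], group = tab$group[i])
    if (!grepl("DE", rec$sequence, fixed = TRUE)) {
      excluded <- c(excluded, id)
      next
    }
    records[[id]] <- rec
  }
  if (length(excluded) > 0)
    message(length(excluded), " record(s) without a DE motif excluded: ",
            paste(excluded, collapse = ", "))
  if (length(records) == 0)
    stop("no DE-containing records in dataset")
  new_dataset(records, provenance = provenance,
              n_excluded_no_de = length(excluded), excluded_ids = excluded)
}

# FASTA reader returning a plain named character vector (uppercased).
read_fasta_named <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(out)))
    stop("duplicate FASTA id(s) in ", path)
  out
}

#' Read a multiple sequence alignment
#'
#' Supports aligned FASTA (`format = "afa"`) and Stockholm
#' (`format = "stockholm"`). Residues are uppercased and `.` gap characters
#' are normalized to `-`.
#'
#' @param path alignment file.
#' @param format `"afa"` or `"stockholm"`.
#' @return an object of class `de_msa` with fields `ids`, `rows`
#'   (named character vector of aligned sequences) and `ncols`.
#' @export
read_msa <- function(path, format = c("afa", "stockholm")) {
  format <- match.arg(format)
  rows <- switch(format,
    afa = read_fasta_named(path),
    stockholm = read_stockholm_rows(path))
  new_msa(names(rows), unname(rows))
}

read_stockholm_rows <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^# STOCKHOLM", lines[1]))
    stop("not a Stockholm file (missing '# STOCKHOLM' header): ", path)
  acc <- list()
  order <- character(0)
  for (ln in lines[-1]) {
    if (grepl("^\\s*$", ln) || startsWith(ln, "#") || startsWith(ln, "//"))
      next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2)
      stop("malformed Stockholm sequence line: ", ln)
    id <- parts[1]
    if (!id %in% order) order <- c(order, id)
    acc[[id]] <- paste0(if (is.null(acc[[id]])) "" else acc[[id]], parts[2])
  }
  if (length(acc) == 0) stop("Stockholm file contains no sequences: ", path)
  toupper(unlist(acc[order]))
}

new_msa <- function(ids, rows) {
  stopifnot(length(ids) == length(rows))
  if (anyDuplicated(ids))
    stop("duplicate MSA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rows <- toupper(rows)
  rows <- gsub(".", "-", rows, fixed = TRUE)
  widths <- nchar(rows)
  ncols <- widths[1]
  if (any(widths != ncols))
    stop("ragged alignment: sequence '", ids[which(widths != ncols)[1]],
         "' has width ", widths[which(widths != ncols)[1]],
         ", expected ", ncols)
  names(rows) <- ids
  structure(list(ids = ids, rows = rows, ncols = ncols), class = "de_msa")
}

#' @export
print.de_msa <- function(x, ...) {
  cat(sprintf("<de_msa> %d sequences x %d columns\n",
              length(x$ids), x$ncols))
  invisible(x)
}

msa_matrix <- function(msa) {
  m <- matrix(unlist(strsplit(msa$rows, "")), nrow = length(msa$ids),
              ncol = msa$ncols, byrow = TRUE)
  rownames(m) <- msa$ids
  m
}

#' Write a DE-motif context table
#'
#' Emits a TSV with columns `id`, `start_1based`, `H`, `C`, `order_class`,
#' `flank_left`, `flank_right`, sorted deterministically by id (C locale)
#' then position. Motif starts are converted from the internal 0-based
#' convention to 1-based inclusive coordinates.
#'
#' @param motifs a context data frame as produced by [annotate_dataset()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_motif_table <- function(motifs, path) {
  out <- data.frame(
    id = motifs$protein_id,
    start_1based = motifs$start + 1L,
    H = motifs$H,
    C = motifs$C,
    order_class = ifelse(is.na(motifs$order_class), "NA", motifs$order_class),
    flank_left = motifs$flank_left,
    flank_right = motifs$flank_right,
    stringsAsFactors = FALSE)
  out <- out[order(out$id, out$start_1based, method = "radix"), ,
             drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a motif context table written by [write_motif_table()]
#' @param path TSV file.
#' @return data frame with internal 0-based `start` positions.
#' @export
read_motif_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(id = "character",
                                          flank_left = "character",
                                          flank_right = "character"))
  data.frame(protein_id = tab$id,
             start = tab$start_1based - 1L,
             H = tab$H, C = tab$C,
             order_class = ifelse(tab$order_class == "NA",
                                  NA_character_, tab$order_class),
             flank_left = ifelse(is.na(tab$flank_left), "", tab$flank_left),
             flank_right = ifelse(is.na(tab$flank_right), "", tab$flank_right),
             stringsAsFactors = FALSE)
}
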