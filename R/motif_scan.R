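# Short-linear-motif scanners: diacidic DE, phosphorylatable diacidic
# insertions, and LC3-interacting regions (LIR). All hits use 0-based
# start positions and half-open intervals [start, start + length).

#' Residues with propensity for phosphorylation used as the "X" of the
#' diacidic insertion motifs: O-phosphorylatable S, T, Y and
#' N-phosphorylatable H, R, K.
#' @export
PHOSPHO_X <- c("S", "T", "Y", "H", "R", "K")

# Pattern table for the six 3-residue phospho-context kinds: regex and the
# offset of the X residue within the match.
PHOSPHO_PATTERNS <- list(
  XDE = list(regex = "[STYHRK]DE", x_offset = 0L),
  DXE = list(regex = "D[STYHRK]E", x_offset = 1L),
  DEX = list(regex = "DE[STYHRK]", x_offset = 2L),
  XED = list(regex = "[STYHRK]ED", x_offset = 0L),
  EXD = list(regex = "E[STYHRK]D", x_offset = 1L),
  EDX = list(regex = "ED[STYHRK]", x_offset = 2L))

# Core LIR: aromatic-x-x-aliphatic tetrapeptide. Extended (xLIR) pattern:
# the published 6-residue consensus; its positions 3-6 are a core match.
LIR_CORE_REGEX <- "[WFY]..[LIV]"
LIR_XLIR_REGEX <- "[ADEFGLPRSK][DEGMSTV][WFY][DEILQTV][ADEFHIKLMPSTV][ILV]"

# All overlapping match starts (0-based) of a regex in a single sequence.
overlapping_starts <- function(sequence, regex) {
  m <- gregexpr(paste0("(?=", regex, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

motif_hit_frame <- function(protein_id, start, length, kind, x_residue) {
  data.frame(protein_id = protein_id, start = start, length = length,
             kind = kind, x_residue = x_residue, stringsAsFactors = FALSE)
}

empty_hits <- function() {
  motif_hit_frame(character(0), integer(0), integer(0),
                  character(0), character(0))
}

#' Locate all DE dipeptides in a sequence
#'
#' Every index `i` (0-based) with `sequence[i] == "D"` and
#' `sequence[i+1] == "E"`, in ascending order; overlapping occurrences
#' (e.g. in `"DEDE"`) are all reported.
#'
#' @param sequence uppercase amino-acid string.
#' @param protein_id id recorded on the hits.
#' @return data frame of motif hits with columns `protein_id`, `start`
#'   (0-based), `length`, `kind`, `x_residue`.
#' @export
find_de_motifs <- function(sequence, protein_id = NA_character_) {
  starts <- overlapping_starts(sequence, "DE")
  if (length(starts) == 0) return(empty_hits())
  motif_hit_frame(protein_id, starts, 2L, "DE", "")
}

#' Locate phosphorylatable diacidic insertion motifs
#'
#' Scans for the six 3-residue patterns XDE, DXE, DEX, XED, EXD, EDX with
#' X restricted to the six phosphorylatable residues S, T, Y, H, R, K.
#' A position may yield several kinds; each (position, kind) pair is a
#' separate hit.
#'
#' @inheritParams find_de_motifs
#' @param kinds subset of the six kinds to scan for.
#' @return data frame of motif hits; `x_residue` holds the matched X.
#' @export
find_phospho_context_motifs <- function(sequence, protein_id = NA_character_,
                                        kinds = names(PHOSPHO_PATTERNS)) {
  kinds <- match.arg(kinds, names(PHOSPHO_PATTERNS), several.ok = TRUE)
  out <- lapply(kinds, function(kind) {
    pat <- PHOSPHO_PATTERNS[[kind]]
    starts <- overlapping_starts(sequence, pat$regex)
    if (length(starts) == 0) return(empty_hits())
    xs <- substring(sequence, starts + pat$x_offset + 1L,
                    starts + pat$x_offset + 1L)
    motif_hit_frame(protein_id, starts, 3L, kind, xs)
  })
  out <- do.call(rbind, out)
  out[order(out$start, out$kind, method = "radix"), , drop = FALSE]
}

#' Locate LC3-interacting region (LIR) motifs
#'
#' `mode = "core"` scans for the aromatic-x-x-aliphatic tetrapeptide
#' `[WFY]..[LIV]`; `mode = "xlir"` scans for the published extended
#' 6-residue consensus
#' `[ADEFGLPRSK][DEGMSTV][WFY][DEILQTV][ADEFHIKLMPSTV][ILV]`.
#' Position-specific scoring of candidate LIRs is out of scope; the scanner
#' is a motif-presence oracle only.
#'
#' @inheritParams find_de_motifs
#' @param mode `"core"` or `"xlir"`.
#' @return data frame of motif hits (kind `LIR_core` or `LIR_xlir`).
#' @export
find_lir_motifs <- function(sequence, mode = c("core", "xlir"),
                            protein_id = NA_character_) {
  mode <- match.arg(mode)
  regex <- if (mode == "core") LIR_CORE_REGEX else LIR_XLIR_REGEX
  len <- if (mode == "core") 4L else 6L
  starts <- overlapping_starts(sequence, regex)
  if (length(starts) == 0) return(empty_hits())
  motif_hit_frame(protein_id, starts, len,
                  if (mode == "core") "LIR_core" else "LIR_xlir", "")
}

#' Are a DE hit and a LIR hit contiguous in the primary sequence?
#'
#' TRUE iff the two half-open intervals overlap or directly abut with at
#' most `gap` intervening residues (default 0: "joined in the primary
#' sequence" read literally).
#'
#' @param de_hit,lir_hit single-row motif hit data frames from the same
#'   protein.
#' @param gap maximum number of residues allowed between the motifs.
#' @return logical scalar.
#' @export
de_lir_contiguous <- function(de_hit, lir_hit, gap = 0L) {
  stopifnot(nrow(de_hit) == 1L, nrow(lir_hit) == 1L)
  if (!is.na(de_hit$protein_id) && !is.na(lir_hit$protein_id) &&
      de_hit$protein_id != lir_hit$protein_id)
    stop("hits come from different proteins: '", de_hit$protein_id,
         "' vs '", lir_hit$protein_id, "'")
  de_end <- de_hit$start + de_hit$length
  lir_end <- lir_hit$start + lir_hit$length
  de_hit$start <= lir_end + gap && lir_hit$start <= de_end + gap
}

#' Per-group DE-LIR contiguity summary
#'
#' For each (group, label) stratum, counts proteins whose every DE-LIR pair
#' is discontiguous, proteins with at least one contiguous pair, and
#' proteins carrying no LIR motif at all.
#'
#' @param dataset a `de_dataset`.
#' @param mode LIR scan mode, `"core"` or `"xlir"`.
#' @param gap contiguity gap threshold (see [de_lir_contiguous()]).
#' @return data frame with columns `group`, `label`, `contiguous`,
#'   `discontiguous`, `no_lir`.
#' @export
lir_contiguity_summary <- function(dataset, mode = c("core", "xlir"),
                                   gap = 0L) {
  mode <- match.arg(mode)
  per <- lapply(dataset$records, function(rec) {
    lir <- find_lir_motifs(rec$sequence, mode, rec$id)
    bin <- if (nrow(lir) == 0) {
      "no_lir"
    } else {
      de <- find_de_motifs(rec$sequence, rec$id)
      de_end <- de$start + de$length
      lir_end <- lir$start + lir$length
      hit <- any(outer(de$start, lir_end + gap, `<=`) &
                 outer(de_end + gap, lir$start, `>=`))
      if (hit) "contiguous" else "discontiguous"
    }
    data.frame(group = rec$group, label = rec$label, bin = bin,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, c(per, make.row.names = FALSE))
  if (is.null(per) || nrow(per) == 0)
    return(data.frame(group = character(0), label = character(0),
                      contiguous = integer(0), discontiguous = integer(0),
                      no_lir = integer(0)))
  strata <- unique(per[, c("group", "label")])
  strata <- strata[order(strata$group, strata$label, method = "radix"), ,
                   drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    sub <- per[per$group == strata$group[i] & per$label == strata$label[i], ]
    data.frame(group = strata$group[i], label = strata$label[i],
               contiguous = sum(sub$bin == "contiguous"),
               discontiguous = sum(sub$bin == "discontiguous"),
               no_lir = sum(sub$bin == "no_lir"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
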