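# Physicochemical context of each DE motif: flanking hydrophobicity (H),
# flanking charge (C) and three-state structural order class (O/D/B).

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values (Kyte & Doolittle), dimensionless; the
#' unknown residue `X` is imputed as 0 (neutral).
#' @export
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2,
  X =  0.0)

# Formal side-chain charge at physiological pH: D/E -1, K/R +1, everything
# else (including H by default, and X) 0. Histidine is switchable to +1.
residue_charges <- function(his_charge = 0) {
  ch <- stats::setNames(rep(0, 21), names(KYTE_DOOLITTLE))
  ch[c("D", "E")] <- -1
  ch[c("K", "R")] <- 1
  ch["H"] <- his_charge
  ch
}

# Fast per-character lookup tables indexed by UTF-8 code.
lookup_by_code <- function(named_values) {
  out <- rep(NA_real_, 128L)
  out[utf8ToInt(paste(names(named_values), collapse = ""))] <- named_values
  out
}
KD_BY_CODE <- lookup_by_code(KYTE_DOOLITTLE)

check_de_at <- function(sequence, start) {
  if (start < 0 || start + 2 > nchar(sequence) ||
      substring(sequence, start + 1, start + 2) != "DE")
    stop("position ", start, " (0-based) is not a DE motif in the sequence")
}

window_sum <- function(sequence, start, half_width, values_by_code) {
  n <- nchar(sequence)
  codes <- utf8ToInt(sequence)
  li <- (start - half_width + 1L):start          # 1-based indices left of D
  li <- li[li >= 1L]
  ri <- (start + 3L):(start + 2L + half_width)   # 1-based indices right of E
  ri <- ri[ri <= n]
  vals <- values_by_code[codes[c(li, ri)]]
  list(value = sum(vals), n_left = length(li), n_right = length(ri))
}

#' Flanking hydrophobicity of a DE motif
#'
#' Sum of Kyte-Doolittle hydropathy over up to `half_width` residues
#' immediately left of the D and right of the E (default 3 per side). The
#' D and E themselves are excluded; windows truncate at the termini.
#'
#' @param sequence uppercase amino-acid string.
#' @param start 0-based position of the D of a DE motif.
#' @param half_width flank size per side (>= 1).
#' @return numeric H value.
#' @export
window_hydrophobicity <- function(sequence, start, half_width = 3L) {
  stopifnot(half_width >= 1L)
  check_de_at(sequence, start)
  window_sum(sequence, start, half_width, KD_BY_CODE)$value
}

#' Flanking charge of a DE motif
#'
#' Sum of formal residue charges (D,E = -1; K,R = +1; others 0) over the
#' same flanking window as [window_hydrophobicity()].
#'
#' @inheritParams window_hydrophobicity
#' @param his_charge charge assigned to histidine (default 0; set 1 to
#'   treat H as protonated).
#' @return numeric C value (elementary charges).
#' @export
window_charge <- function(sequence, start, half_width = 3L, his_charge = 0) {
  stopifnot(half_width >= 1L)
  check_de_at(sequence, start)
  window_sum(sequence, start, half_width,
             lookup_by_code(residue_charges(his_charge)))$value
}

#' Structural order class of a DE motif
#'
#' `O` (ordered) when both motif residues lie in helix or sheet states
#' (`H`/`E`), `D` (disordered) when both lie in coil/loop (`C`), and `B`
#' (border) when the two residues straddle the boundary.
#'
#' @param ss_string three-state structure string over `{H,E,C}`.
#' @param start 0-based position of the D.
#' @return `"O"`, `"D"` or `"B"`.
#' @export
order_class <- function(ss_string, start) {
  if (is.null(ss_string) || length(ss_string) != 1L || is.na(ss_string))
    stop("order class undefined: no secondary-structure string")
  if (start < 0 || start + 2 > nchar(ss_string))
    stop("start ", start, " out of range for structure string")
  s <- substring(ss_string, start + 1L, start + 2L)
  st <- strsplit(s, "")[[1]]
  ordered <- st %in% c("H", "E")
  if (all(ordered)) "O" else if (!any(ordered)) "D" else "B"
}

CH_BY_CODE_DEFAULT <- lookup_by_code(residue_charges(0))

# Vectorised context computation for one record; starts are 0-based D
# positions. Uses integer-code lookups so whole-dataset annotation stays
# cheap for thousands of proteins. Returns a plain list of vectors; the
# caller assembles the data frame once per dataset.
contexts_for_record <- function(rec, starts, half_width = 3L,
                                ch_by_code = CH_BY_CODE_DEFAULT) {
  n <- nchar(rec$sequence)
  codes <- utf8ToInt(rec$sequence)
  kd <- KD_BY_CODE[codes]
  ch <- ch_by_code[codes]
  csum_kd <- c(0, cumsum(kd))
  csum_ch <- c(0, cumsum(ch))
  # left window covers 1-based [start-hw+1, start]; right [start+3, start+2+hw]
  l_lo <- pmax(starts - half_width, 0L)   # prefix index just before window
  l_hi <- starts
  r_lo <- starts + 2L
  r_hi <- pmin(starts + 2L + half_width, n)
  H <- (csum_kd[l_hi + 1L] - csum_kd[l_lo + 1L]) +
       (csum_kd[r_hi + 1L] - csum_kd[r_lo + 1L])
  C <- (csum_ch[l_hi + 1L] - csum_ch[l_lo + 1L]) +
       (csum_ch[r_hi + 1L] - csum_ch[r_lo + 1L])
  if (!is.na(rec$ss)) {
    s1 <- substring(rec$ss, starts + 1L, starts + 1L)
    s2 <- substring(rec$ss, starts + 2L, starts + 2L)
    o1 <- s1 %in% c("H", "E")
    o2 <- s2 %in% c("H", "E")
    oc <- ifelse(o1 & o2, "O", ifelse(!o1 & !o2, "D", "B"))
  } else {
    oc <- rep(NA_character_, length(starts))
  }
  k <- length(starts)
  list(
    protein_id = rep(rec$id, k),
    start = as.integer(starts),
    H = round(H, 10), C = C,
    order_class = oc,
    n_flank_left = as.integer(l_hi - l_lo),
    n_flank_right = as.integer(r_hi - r_lo),
    flank_left = substring(rec$sequence, l_lo + 1L, l_hi),
    flank_right = substring(rec$sequence, r_lo + 1L, r_hi),
    label = rep(rec$label, k), group = rep(rec$group, k))
}

#' Annotate every DE motif of every protein with its context
#'
#' Produces one context record per DE occurrence: flanking hydrophobicity
#' `H`, flanking charge `C`, order class (`NA` when the protein has no
#' structure string), flank truncation counts and the flank sequences.
#' Rows are ordered by dataset record order, then motif position.
#'
#' @param dataset a `de_dataset`.
#' @param half_width flank size per side (default 3).
#' @param his_charge histidine charge (default 0).
#' @return data frame of DE motif contexts (includes `label` and `group`
#'   columns for downstream model building).
#' @export
annotate_dataset <- function(dataset, half_width = 3L, his_charge = 0) {
  ch_by_code <- if (his_charge == 0) CH_BY_CODE_DEFAULT
                else lookup_by_code(residue_charges(his_charge))
  parts <- lapply(dataset$records, function(rec) {
    starts <- overlapping_starts(rec$sequence, "DE")
    if (length(starts) == 0) return(NULL)
    contexts_for_record(rec, starts, half_width, ch_by_code)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0) stop("dataset contains no DE motifs")
  fields <- names(parts[[1]])
  out <- lapply(fields, function(f)
    unlist(lapply(parts, `[[`, f), use.names = FALSE))
  names(out) <- fields
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
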