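# Simplified statistical-coupling-analysis pipeline on consensus-binarized
# alignments: per-sequence gap filtering, majority consensus, binarization,
# pairwise coupling matrix, and per-position partner ranking.

#' Filter MSA sequences by gap fraction
#'
#' Keeps sequences whose gap fraction is at most `max_gap` (boundary
#' inclusive); sequence order is preserved.
#'
#' @param msa a `de_msa`.
#' @param max_gap maximum allowed per-sequence gap fraction (default 0.2).
#' @return filtered `de_msa`.
#' @export
filter_by_gap <- function(msa, max_gap = 0.2) {
  gapfrac <- vapply(msa$rows, function(r)
    lengths(regmatches(r, gregexpr("-", r, fixed = TRUE))) / msa$ncols,
    numeric(1))
  keep <- gapfrac <= max_gap
  if (!any(keep))
    stop("no sequences survive the gap filter (max_gap = ", max_gap,
         "); consider raising the threshold")
  new_msa(msa$ids[keep], unname(msa$rows[keep]))
}

#' Majority consensus sequence of an MSA
#'
#' Per column, the most frequent non-gap residue; ties are broken
#' alphabetically; an all-gap column yields `X`.
#'
#' @param msa a `de_msa`.
#' @return consensus string of length `ncols` (no gap characters).
#' @export
build_consensus <- function(msa) {
  stopifnot(length(msa$ids) >= 1L)
  m <- msa_matrix(msa)
  cons <- apply(m, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0) return("X")
    counts <- table(col)
    # which.max on a table keeps the first (alphabetical) maximum
    names(counts)[which.max(counts)]
  })
  paste(cons, collapse = "")
}

#' Binarize an MSA against a consensus
#'
#' Entry (s, i) is 1 iff sequence s carries the consensus residue at
#' column i; gaps count as 0. Column frequencies `f_i` are the fraction of
#' 1s per column.
#'
#' @param msa a `de_msa`.
#' @param consensus consensus string (defaults to [build_consensus()]).
#' @return list of class `de_binmsa`: `matrix` (n_seq x n_col, 0/1),
#'   `consensus`, `f` (column frequencies), `kept_ids`.
#' @export
binarize <- function(msa, consensus = build_consensus(msa)) {
  if (nchar(consensus) != msa$ncols)
    stop("consensus length (", nchar(consensus),
         ") does not match alignment width (", msa$ncols, ")")
  m <- msa_matrix(msa)
  cons <- strsplit(consensus, "")[[1]]
  bin <- m == matrix(cons, nrow = nrow(m), ncol = msa$ncols, byrow = TRUE)
  storage.mode(bin) <- "double"
  structure(list(matrix = bin, consensus = consensus,
                 f = colMeans(bin), kept_ids = msa$ids),
            class = "de_binmsa")
}

#' Pairwise co-evolution coupling matrix
#'
#' Plain mode: `C[i,j] = |f_ij - f_i f_j|`, the absolute deviation of the
#' joint consensus-match frequency from independence. `sca_weighted`
#' multiplies by positional weights
#' `phi_i = |ln(f_i (1 - qbar) / (qbar (1 - f_i)))|` (0 for constant
#' columns), echoing the frequency reweighting of classic statistical
#' coupling analysis. The diagonal is zero by convention and couplings of
#' constant columns are zero.
#'
#' @param bmsa a `de_binmsa` from [binarize()].
#' @param mode `"plain"` (default) or `"sca_weighted"`.
#' @param qbar background match frequency for the weighted mode.
#' @return list of class `de_coupling`: `C` (symmetric matrix), `mode`,
#'   `qbar`, `f`.
#' @export
coupling_matrix <- function(bmsa, mode = c("plain", "sca_weighted"),
                            qbar = 0.05) {
  mode <- match.arg(mode)
  M <- bmsa$matrix
  n <- nrow(M)
  if (n < 2L) stop("coupling requires at least 2 sequences")
  f <- colMeans(M)
  Fij <- crossprod(M) / n
  C <- abs(Fij - outer(f, f))
  if (mode == "sca_weighted") {
    phi <- abs(log(f * (1 - qbar) / (qbar * (1 - f))))
    phi[f <= 0 | f >= 1 | !is.finite(phi)] <- 0
    C <- C * outer(phi, phi)
  }
  const <- f <= 0 | f >= 1
  C[const, ] <- 0
  C[, const] <- 0
  diag(C) <- 0
  structure(list(C = C, mode = mode, qbar = qbar, f = f),
            class = "de_coupling")
}

#' Top coupling partners of one alignment column
#'
#' Ranks the other columns by coupling score with `position` and reports a
#' z-score of each partner against the mean and SD of that position's
#' off-diagonal couplings. Partners with `z >= z_threshold` (default 2)
#' are flagged as having a co-evolutionary relation.
#'
#' @param coupling a `de_coupling`.
#' @param position column index (1-based, as for any R matrix).
#' @param k number of partners to return (truncated to the number of
#'   available columns).
#' @param z_threshold relation flag threshold.
#' @return data frame `partner`, `score`, `z`, `relation`, ranked by
#'   decreasing score.
#' @export
top_partners <- function(coupling, position, k = 5L, z_threshold = 2) {
  C <- coupling$C
  ncol_ <- ncol(C)
  if (position < 1 || position > ncol_)
    stop("position ", position, " out of range 1..", ncol_)
  scores <- C[position, -position]
  partners <- seq_len(ncol_)[-position]
  mu <- mean(scores)
  sdv <- stats::sd(scores)
  z <- if (sdv > 0) (scores - mu) / sdv else rep(0, length(scores))
  ord <- order(-scores, partners, method = "radix")
  k <- min(k, length(partners))
  idx <- ord[seq_len(k)]
  data.frame(partner = partners[idx], score = scores[idx], z = z[idx],
             relation = z[idx] >= z_threshold)
}

#' Map residue positions of one MSA row to alignment columns
#'
#' Converts 0-based residue indices of the ungapped sequence of
#' `sequence_id` into 0-based alignment column indices, skipping gaps.
#' Each requested position is checked to carry `D` with `E` at the next
#' residue (a DE motif) unless `check_de = FALSE`.
#'
#' @param sequence_id row id in the MSA.
#' @param msa a `de_msa`.
#' @param de_positions 0-based residue indices of the D of each DE motif.
#' @param check_de verify the mapped residues are D followed by E.
#' @return data frame `de_position`, `d_col`, `e_col` (0-based columns).
#' @export
map_de_to_columns <- function(sequence_id, msa, de_positions,
                              check_de = TRUE) {
  if (!sequence_id %in% msa$ids)
    stop("sequence '", sequence_id, "' not present in MSA")
  row <- strsplit(msa$rows[[sequence_id]], "")[[1]]
  resid_cols <- which(row != "-")          # 1-based columns of residues
  n_res <- length(resid_cols)
  out <- lapply(de_positions, function(p) {
    if (p < 0 || p + 1 >= n_res)
      stop("residue position ", p, " (0-based) out of range; sequence '",
           sequence_id, "' has ", n_res, " residues")
    d_col <- resid_cols[p + 1L]
    e_col <- resid_cols[p + 2L]
    if (check_de && (row[d_col] != "D" || row[e_col] != "E"))
      stop("residues at position ", p, " of '", sequence_id,
           "' are ", row[d_col], row[e_col], ", not DE")
    data.frame(de_position = p, d_col = d_col - 1L, e_col = e_col - 1L)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}
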