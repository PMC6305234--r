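# Seeded generators for labelled protein datasets and MSAs with known
# ground truth, so that every pipeline stage has a download-free test
# surface. All randomness is drawn under a locally scoped seed: the
# caller's RNG state is saved and restored.

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Configuration for the synthetic protein dataset generator
#'
#' Defaults describe a plausible analysis-scale world: proteins of
#' 120-300 residues with 1-4 planted DE motifs, uniform background
#' residue usage, secondary structure as alternating runs of H/E/C with
#' geometric lengths (mean 6 for ordered runs, 5 for coil) so ordered,
#' disordered and border motifs all occur, and a logistic secretion model
#' on the (H, C, order) features of the "signal" DE selected by one
#' hypothesis case. The default planted case (id 6: ordered preference,
#' border regrouped to disordered, minimum charge, maximum
#' hydrophobicity) mirrors the headline hypothesis that an ordered,
#' low-charge, high-hydrophobicity DE context favours secretion; the
#' default coefficients give moderate, recoverable effects and the
#' intercept roughly balances the two classes.
#'
#' @param n_proteins number of proteins.
#' @param length_range min/max sequence length.
#' @param de_count integer vector of allowed planted-DE counts per
#'   protein (sampled uniformly).
#' @param beta planted coefficients `(intercept, H, C, order)`.
#' @param signal_case case id (1-16) whose selection rule designates the
#'   generative signal DE.
#' @param residue_freqs background residue probabilities over the 20
#'   amino acids (default uniform).
#' @param mean_run_ordered,mean_run_coil mean secondary-structure run
#'   lengths for H/E and C runs.
#' @param group group tag assigned to all records.
#' @param seed integer seed; fully determines the output.
#' @return a list of class `protein_gen_config`.
#' @export
protein_gen_config <- function(n_proteins = 100L,
                               length_range = c(120L, 300L),
                               de_count = 1:4,
                               beta = c(intercept = -2.5, H = 0.25,
                                        C = -0.75, order = 1.5),
                               signal_case = 6L,
                               residue_freqs = NULL,
                               mean_run_ordered = 6,
                               mean_run_coil = 5,
                               group = "simulated",
                               seed = 1L) {
  stopifnot(n_proteins >= 1, length(length_range) == 2,
            length_range[1] <= length_range[2],
            all(de_count >= 1), length(beta) == 4)
  if (length_range[1] < max(de_count) * 10 + 10)
    stop("infeasible config: minimum length ", length_range[1],
         " too short for up to ", max(de_count),
         " well-separated DE motifs with flanking windows")
  if (is.null(residue_freqs))
    residue_freqs <- stats::setNames(rep(1 / 20, 20), AA20)
  stopifnot(length(residue_freqs) == 20, abs(sum(residue_freqs) - 1) < 1e-6)
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 de_count = as.integer(de_count),
                 beta = stats::setNames(as.numeric(beta),
                                        c("intercept", "H", "C", "order")),
                 signal_case = as.integer(signal_case),
                 residue_freqs = residue_freqs,
                 mean_run_ordered = mean_run_ordered,
                 mean_run_coil = mean_run_coil,
                 group = group, seed = as.integer(seed)),
            class = "protein_gen_config")
}

# Alternating-state secondary structure: geometric run lengths, next state
# drawn uniformly from the other two, so all of O, D, B motif classes occur.
gen_ss_string <- function(len, mean_ordered, mean_coil) {
  # draw more runs than can possibly be needed, then truncate
  ss_states <- c("H", "E", "C")
  n_runs <- max(8L, ceiling(2 * len / min(mean_ordered, mean_coil)))
  repeat {
    # Markov walk on 1..3 that never repeats a state
    steps <- sample.int(2L, n_runs - 1L, replace = TRUE)
    st <- integer(n_runs)
    st[1] <- sample.int(3L, 1L)
    for (r in 2:n_runs) st[r] <- ((st[r - 1L] - 1L + steps[r - 1L]) %% 3L) + 1L
    runs <- 1L + stats::rgeom(n_runs, 1 / ifelse(st == 3L, mean_coil,
                                                 mean_ordered))
    if (sum(runs) >= len) break
    n_runs <- n_runs * 2L
  }
  states <- rep.int(ss_states[st], runs)
  paste(states[seq_len(len)], collapse = "")
}

# Non-overlapping planted DE start positions with minimum spacing 8.
plant_positions <- function(len, k) {
  cand <- 4:(len - 6)     # 0-based D positions, flanks mostly interior
  for (try in 1:100) {
    pos <- sort(sample(cand, k))
    if (k == 1L || min(diff(pos)) >= 8L) return(pos)
  }
  # fall back to an evenly spaced grid
  sort(sample(seq(4L, len - 6L, by = 8L), k))
}

#' Generate a labelled protein dataset from a planted logistic model
#'
#' Each protein gets a random background sequence, an alternating-run
#' secondary-structure string and 1-4 planted DE motifs. The secretion
#' label is Bernoulli with success probability
#' `logit^-1(b0 + bH * H + bC * C + bO * O)` computed on the features of
#' the signal DE, i.e. the motif selected by the configured hypothesis
#' case (accidental background DE motifs participate in selection, as
#' they would in real data). The ground truth (signal motif, features,
#' probability, planted coefficients) is attached as `$truth`.
#'
#' @param config a [protein_gen_config()].
#' @return a `de_dataset` with an extra `truth` element (data frame) and
#'   attributes `beta` and `signal_case` on the truth table.
#' @export
gen_protein_dataset <- function(config = protein_gen_config()) {
  stopifnot(inherits(config, "protein_gen_config"))
  with_local_seed(config$seed, {
    n <- config$n_proteins
    lens <- sample(config$length_range[1]:config$length_range[2], n,
                   replace = TRUE)
    ids <- sprintf("SYN%04d", seq_len(n))
    records <- vector("list", n)
    for (i in seq_len(n)) {
      len <- lens[i]
      aa <- sample(AA20, len, replace = TRUE, prob = config$residue_freqs)
      k <- if (length(config$de_count) == 1L) config$de_count
           else sample(config$de_count, 1L)
      pos <- plant_positions(len, k)
      aa[pos + 1L] <- "D"
      aa[pos + 2L] <- "E"
      records[[i]] <- protein_record(
        ids[i], paste(aa, collapse = ""),
        ss = gen_ss_string(len, config$mean_run_ordered,
                           config$mean_run_coil),
        label = "unknown", group = config$group)
    }
    dataset <- new_dataset(records,
                           provenance = sprintf("gen_protein_dataset(seed=%d)",
                                                config$seed))
    contexts <- annotate_dataset(dataset)
    sel <- select_by_case(contexts, config$signal_case)
    b <- config$beta
    eta <- b["intercept"] + b["H"] * sel$H + b["C"] * sel$C +
      b["order"] * sel$order_indicator
    prob <- stats::plogis(eta)
    lab <- ifelse(stats::rbinom(n, 1L, prob) == 1L,
                  "secretory", "non_secretory")
    for (i in seq_len(n)) dataset$records[[i]]$label <- lab[i]
    truth <- data.frame(protein_id = sel$protein_id,
                        signal_start = sel$start,
                        H = sel$H, C = sel$C,
                        order_indicator = sel$order_indicator,
                        prob = as.numeric(prob),
                        label = lab,
                        stringsAsFactors = FALSE)
    attr(truth, "beta") <- b
    attr(truth, "signal_case") <- config$signal_case
    attr(truth, "seed") <- config$seed
    dataset$truth <- truth
    dataset
  })
}

#' Configuration for the synthetic MSA generator
#'
#' @param n_seq,n_col alignment dimensions.
#' @param match_prob probability that a residue matches the column
#'   consensus (scalar or per-column vector).
#' @param planted_pairs list of 2-element integer vectors (1-based,
#'   pairwise disjoint columns) whose consensus-match indicators are
#'   correlated.
#' @param rho correlation of the planted pairs (0..1).
#' @param gap_rate i.i.d. gap probability per cell.
#' @param seed integer seed.
#' @return a list of class `msa_gen_config`.
#' @export
msa_gen_config <- function(n_seq = 500L, n_col = 100L, match_prob = 0.7,
                           planted_pairs = list(c(10L, 45L), c(30L, 70L)),
                           rho = 0.9, gap_rate = 0.05, seed = 1L) {
  stopifnot(n_seq >= 2, n_col >= 2)
  if (rho < 0 || rho > 1)
    stop("infeasible correlation rho = ", rho, "; must lie in [0, 1]")
  cols <- unlist(planted_pairs)
  if (anyDuplicated(cols))
    stop("planted pairs must be pairwise disjoint")
  if (length(cols) && (min(cols) < 1 || max(cols) > n_col))
    stop("planted pair columns out of range 1..", n_col)
  structure(list(n_seq = as.integer(n_seq), n_col = as.integer(n_col),
                 match_prob = match_prob, planted_pairs = planted_pairs,
                 rho = rho, gap_rate = gap_rate, seed = as.integer(seed)),
            class = "msa_gen_config")
}

#' Generate a synthetic MSA with planted covarying column pairs
#'
#' Each column has a random consensus residue matched with probability
#' `match_prob`; mismatches are uniform over the other 19 residues. For
#' every planted pair, the two columns' match indicators share a latent
#' Bernoulli variable with probability `rho` (giving correlation `rho`);
#' gaps are injected i.i.d. afterwards. The truth (consensus, planted
#' pairs, rho) is attached as attribute `truth` on the returned MSA.
#'
#' @param config an [msa_gen_config()].
#' @return a `de_msa` with attribute `truth`.
#' @export
gen_msa <- function(config = msa_gen_config()) {
  stopifnot(inherits(config, "msa_gen_config"))
  with_local_seed(config$seed, {
    n <- config$n_seq
    m <- config$n_col
    p <- rep(config$match_prob, length.out = m)
    cons <- sample(AA20, m, replace = TRUE)
    match <- matrix(stats::rbinom(n * m, 1L, rep(p, each = n)), n, m)
    for (pair in config$planted_pairs) {
      i <- pair[1]; j <- pair[2]
      # shared-latent construction: corr(match_i, match_j) = rho
      share <- stats::rbinom(n, 1L, config$rho) == 1L
      match[share, j] <- match[share, i]
      match[!share, j] <- stats::rbinom(sum(!share), 1L, p[i])
    }
    chars <- matrix("", n, m)
    consmat <- matrix(cons, n, m, byrow = TRUE)
    chars[match == 1L] <- consmat[match == 1L]
    n_mis <- sum(match == 0L)
    if (n_mis > 0) {
      # mismatch residues uniform over the 19 non-consensus letters
      mis_idx <- which(match == 0L)
      draw <- sample(AA20, n_mis, replace = TRUE)
      clash <- draw == consmat[mis_idx]
      while (any(clash)) {
        draw[clash] <- sample(AA20, sum(clash), replace = TRUE)
        clash <- draw == consmat[mis_idx]
      }
      chars[mis_idx] <- draw
    }
    gaps <- matrix(stats::runif(n * m) < config$gap_rate, n, m)
    chars[gaps] <- "-"
    rows <- apply(chars, 1, paste, collapse = "")
    msa <- new_msa(sprintf("seq%04d", seq_len(n)), rows)
    attr(msa, "truth") <- list(
      consensus = paste(cons, collapse = ""),
      planted_pairs = config$planted_pairs,
      rho = config$rho, match_prob = config$match_prob,
      gap_rate = config$gap_rate, seed = config$seed)
    msa
  })
}

#' Ground-truth table of a generated object
#'
#' For a generated dataset: per-protein signal-DE position, features and
#' planted coefficients. For a generated MSA: the planted pair list with
#' correlation. Errors for objects not produced by the generators.
#'
#' @param x a `de_dataset` from [gen_protein_dataset()] or a `de_msa`
#'   from [gen_msa()].
#' @param path optional TSV output path.
#' @return data frame of ground truth (invisibly when `path` is given).
#' @export
truth_report <- function(x, path = NULL) {
  if (inherits(x, "de_dataset")) {
    if (is.null(x$truth))
      stop("object carries no ground-truth record (not generated by ",
           "gen_protein_dataset)")
    out <- x$truth
    b <- attr(x$truth, "beta")
    out$beta_intercept <- b["intercept"]
    out$beta_H <- b["H"]; out$beta_C <- b["C"]; out$beta_order <- b["order"]
    out$signal_case <- attr(x$truth, "signal_case")
  } else if (inherits(x, "de_msa")) {
    tr <- attr(x, "truth")
    if (is.null(tr))
      stop("object carries no ground-truth record (not generated by gen_msa)")
    out <- do.call(rbind, lapply(tr$planted_pairs, function(pr)
      data.frame(col_i = pr[1], col_j = pr[2], rho = tr$rho)))
  } else {
    stop("truth_report expects a generated de_dataset or de_msa")
  }
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
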