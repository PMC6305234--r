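# End-to-end orchestration: scan -> features -> 16 hypothesis cases ->
# logistic regressions -> a-posteriori case ranking -> contingency / LIR
# reports. Outputs are deterministic functions of the inputs.

#' Run the full DE-context analysis
#'
#' Annotates every DE motif, builds the 16 per-case design matrices, fits
#' the 16 logistic regressions, ranks the converged non-separated fits by
#' model LRT p-value (ties resolved to the lowest case id and flagged),
#' and attaches extreme-feature summaries, the phospho-context
#' contingency analysis and the DE-LIR contiguity summary. When the
#' dataset carries more than one group tag, per-group regressions are run
#' as well.
#'
#' @param dataset a `de_dataset` with at least two label classes.
#' @param half_width flanking window size per side (default 3).
#' @param his_charge histidine charge (default 0).
#' @param lir_mode LIR scan mode, `"core"` or `"xlir"`.
#' @param lir_gap DE-LIR contiguity gap threshold (default 0).
#' @return an object of class `de_run_report`: `case_results` (one row
#'   per case), `best_case`, `best_case_tie`, `fits` (list of `de_logit`),
#'   `extremes`, `phospho`, `lir`, `by_group`, `provenance`.
#' @export
run_full_analysis <- function(dataset, half_width = 3L, his_charge = 0,
                              lir_mode = c("core", "xlir"), lir_gap = 0L) {
  lir_mode <- match.arg(lir_mode)
  labs <- dataset_labels(dataset)
  if (length(unique(labs[labs != "unknown"])) < 2L)
    stop("run_full_analysis requires both secretory and non-secretory ",
         "proteins")
  contexts <- annotate_dataset(dataset, half_width, his_charge)
  no_ss <- unique(contexts$protein_id[is.na(contexts$order_class)])
  if (length(no_ss) > 0) {
    message(length(no_ss), " protein(s) without structure strings ",
            "excluded from hypothesis regressions")
    contexts_hyp <- contexts[!contexts$protein_id %in% no_ss, , drop = FALSE]
  } else {
    contexts_hyp <- contexts
  }

  ranking <- rank_cases(contexts_hyp)
  case_results <- ranking$case_results
  fits <- ranking$fits
  best_case <- ranking$best_case
  best_tie <- ranking$best_case_tie

  groups <- dataset_groups(dataset)
  by_group <- NULL
  if (length(unique(groups)) > 1L) {
    by_group <- lapply(sort(unique(groups)), function(g) {
      sub <- contexts_hyp[contexts_hyp$group == g, , drop = FALSE]
      tryCatch(rank_cases(sub)$case_results, error = function(e) NULL)
    })
    names(by_group) <- sort(unique(groups))
  }

  report <- structure(list(
    case_results = case_results,
    best_case = best_case,
    best_case_tie = best_tie,
    fits = fits,
    extremes = compare_groups_extremes(dataset, contexts = contexts),
    phospho = phospho_contingency(dataset),
    lir = lir_contiguity_summary(dataset, mode = lir_mode, gap = lir_gap),
    by_group = by_group,
    provenance = list(
      n_proteins = length(dataset$records),
      n_excluded_no_de = dataset$n_excluded_no_de,
      n_no_structure = length(no_ss),
      half_width = half_width, his_charge = his_charge,
      lir_mode = lir_mode, lir_gap = lir_gap,
      dataset_provenance = dataset$provenance)),
    class = "de_run_report")
  report
}

#' Fit and rank the 16 hypothesis cases
#'
#' Builds the per-case design matrix, fits the logistic model for every
#' case and ranks converged, non-separated fits by model LRT p-value.
#' Ties are resolved to the lowest case id and flagged (datasets where
#' every protein has a single DE make all 16 cases numerically
#' identical).
#'
#' @param contexts annotated context table (see [annotate_dataset()])
#'   with defined order classes and labels.
#' @return list with `case_results` (16-row data frame), `fits` (list of
#'   `de_logit` or `NULL`), `best_case` (`NA` if no case is rankable) and
#'   `best_case_tie`.
#' @export
rank_cases <- function(contexts) {
  cases <- enumerate_cases()
  fits <- vector("list", nrow(cases))
  rows <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    design <- build_design_matrix(contexts, cases[i, ])
    fit <- tryCatch(
      suppressWarnings(fit_logistic(design, case_id = cases$case_id[i])),
      error = function(e) NULL)
    fits[[i]] <- fit
    rows[[i]] <- data.frame(
      case_id = cases$case_id[i],
      order_pref = cases$order_pref[i],
      border_regroup = cases$border_regroup[i],
      charge_extreme = cases$charge_extreme[i],
      hydro_extreme = cases$hydro_extreme[i],
      n = if (is.null(fit)) NA_integer_ else fit$n,
      n_fallback = sum(design$fallback),
      beta_H = fit_coef(fit, "H"), beta_C = fit_coef(fit, "C"),
      beta_order = fit_coef(fit, "order_indicator"),
      wald_p_H = fit_wald(fit, "H"), wald_p_C = fit_wald(fit, "C"),
      wald_p_order = fit_wald(fit, "order_indicator"),
      deviance = if (is.null(fit)) NA_real_
                 else 2 * (fit$loglik - fit$loglik_null),
      lrt_p = if (is.null(fit)) NA_real_ else fit$lrt_p,
      lrt_p_bonferroni = if (is.null(fit)) NA_real_
                         else min(1, fit$lrt_p * nrow(cases)),
      converged = if (is.null(fit)) FALSE else fit$converged,
      separation = if (is.null(fit)) NA else fit$separation_detected,
      stringsAsFactors = FALSE)
  }
  case_results <- do.call(rbind, c(rows, make.row.names = FALSE))

  rankable <- case_results$converged & !case_results$separation &
    !is.na(case_results$lrt_p)
  if (any(rankable)) {
    # all cases share df, so smallest LRT p == largest deviance; compare
    # deviances (relative tolerance) because tiny p-values underflow any
    # absolute comparison
    dev <- case_results$deviance
    dmax <- max(dev[rankable])
    winners <- case_results$case_id[rankable &
                                    dev >= dmax - 1e-9 * max(1, abs(dmax))]
    best_case <- min(winners)
    best_tie <- length(winners) > 1L
  } else {
    best_case <- NA_integer_
    best_tie <- FALSE
  }
  list(case_results = case_results, fits = fits,
       best_case = best_case, best_case_tie = best_tie)
}

fit_coef <- function(fit, name) {
  if (is.null(fit) || !name %in% names(fit$coefficients)) NA_real_
  else unname(fit$coefficients[name])
}
fit_wald <- function(fit, name) {
  if (is.null(fit) || !name %in% names(fit$wald_p)) NA_real_
  else unname(fit$wald_p[name])
}

#' @export
print.de_run_report <- function(x, ...) {
  cat("== DE-context analysis report ==\n")
  cat(sprintf("proteins: %d (%d excluded without DE, %d without structure)\n",
              x$provenance$n_proteins, x$provenance$n_excluded_no_de,
              x$provenance$n_no_structure))
  cat("\nPer-case logistic regressions (ranked by model LRT p):\n")
  tab <- x$case_results[order(x$case_results$lrt_p),
                        c("case_id", "order_pref", "border_regroup",
                          "charge_extreme", "hydro_extreme", "lrt_p",
                          "converged", "separation")]
  print(utils::head(tab, 5), row.names = FALSE, digits = 4)
  if (is.na(x$best_case)) {
    cat("\nno rankable case (all fits non-converged or separated)\n")
  } else {
    cat(sprintf("\nbest case: %d%s\n", x$best_case,
                if (x$best_case_tie) " (tie, lowest id reported)" else ""))
  }
  cat(sprintf("\nphospho-context motif contingency (all six kinds): OR=%.3g, Fisher p=%.3g\n",
              x$phospho$overall$odds_ratio,
              x$phospho$overall$fisher_p_two_sided))
  cat("\nDE-LIR contiguity summary:\n")
  print(x$lir, row.names = FALSE)
  invisible(x)
}

#' Extreme-feature summary by label, per group
#'
#' Per-protein extreme features (min/max flanking charge and
#' hydrophobicity over all DE motifs) summarised by secretion label:
#' median and quartiles for each feature within each group tag (plus an
#' `"all"` pseudo-group), with a two-sided Wilcoxon rank-sum p-value as a
#' descriptive aid. When one label class is empty in a group the
#' comparison is skipped (p = NA).
#'
#' @param dataset a `de_dataset`.
#' @param contexts optional pre-computed context table.
#' @param half_width flank size used if contexts must be computed.
#' @return data frame with one row per (group, feature, label) and the
#'   rank-sum p attached to each (group, feature).
#' @export
compare_groups_extremes <- function(dataset, contexts = NULL,
                                    half_width = 3L) {
  if (is.null(contexts)) contexts <- annotate_dataset(dataset, half_width)
  ex <- extreme_features_all(contexts)
  ex <- ex[ex$label %in% c("secretory", "non_secretory"), , drop = FALSE]
  features <- c("min_charge", "max_charge", "min_hydro", "max_hydro")
  groups <- c("all", sort(unique(ex$group)))
  out <- list()
  for (g in groups) {
    sub <- if (g == "all") ex else ex[ex$group == g, , drop = FALSE]
    for (feat in features) {
      for (lab in c("secretory", "non_secretory")) {
        v <- sub[[feat]][sub$label == lab]
        q <- if (length(v) > 0) stats::quantile(v, c(0.25, 0.5, 0.75),
                                                names = FALSE)
             else rep(NA_real_, 3)
        out[[length(out) + 1L]] <- data.frame(
          group = g, feature = feat, label = lab, n = length(v),
          q1 = q[1], median = q[2], q3 = q[3], stringsAsFactors = FALSE)
      }
      a <- sub[[feat]][sub$label == "secretory"]
      b <- sub[[feat]][sub$label == "non_secretory"]
      p <- if (length(a) > 0 && length(b) > 0)
        suppressWarnings(stats::wilcox.test(a, b)$p.value) else NA_real_
      idx <- length(out) - 1:0
      out[[idx[1]]]$ranksum_p <- p
      out[[idx[2]]]$ranksum_p <- p
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Write a run report to disk
#'
#' Emits `per_case_results.tsv`, `extremes.tsv`, `lir_contiguity.tsv`,
#' `contingency.json` and `report.json` under `dir`.
#'
#' @param report a `de_run_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$case_results,
                     file.path(dir, "per_case_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$extremes, file.path(dir, "extremes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$lir, file.path(dir, "lir_contiguity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cont <- list(
    overall = contingency_as_list(report$phospho$overall),
    by_group = lapply(report$phospho$by_group, contingency_as_list))
  jsonlite::write_json(cont, file.path(dir, "contingency.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(list(best_case = report$best_case,
                            best_case_tie = report$best_case_tie,
                            provenance = report$provenance),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

contingency_as_list <- function(x) {
  if (is.null(x)) return(NULL)
  list(table = as.vector(t(x$table)), odds_ratio = x$odds_ratio,
       or_ci_95 = x$or_ci_95, fisher_p_two_sided = x$fisher_p_two_sided,
       correction_applied = x$correction_applied)
}
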