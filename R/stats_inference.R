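# Inference layer: binary logistic regression fitted by hand-written IRLS
# (the model is the analysis core, so it is implemented, not delegated),
# likelihood-ratio and Wald p-values, odds ratios with Haldane-Anscombe
# correction, and Fisher's exact test by hypergeometric enumeration.

# Numerically stable log(1 + exp(x)).
log1pexp <- function(x) ifelse(x > 35, x, log1p(exp(pmin(x, 35))))

logistic_loglik <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1pexp(eta))
}

#' Fit a binary logistic regression by IRLS
#'
#' Maximum-likelihood fit of `P(label = 1) = logit^-1(X beta)` by
#' iteratively reweighted least squares. Convergence is declared when the
#' largest coefficient update falls below `tol` (default 1e-8) within
#' `max_iter` iterations. Per-coefficient Wald z tests use the normal
#' approximation; the model-level p-value is a likelihood-ratio test
#' against the intercept-only model. Complete separation is detected
#' heuristically (perfect classification with extreme linear predictors)
#' and flagged rather than silently diverging.
#'
#' @param design_rows data frame containing a 0/1 (or logical) `label`
#'   column and the predictor columns.
#' @param predictors character vector of predictor column names; defaults
#'   to whichever of `H`, `C`, `order_indicator` are present. An empty
#'   vector fits the intercept-only model.
#' @param case_id optional hypothesis case id carried into the result.
#' @param max_iter,tol IRLS controls.
#' @param ridge optional L2 penalty (default 0, i.e. plain MLE); a small
#'   ridge can rescue separated fits at the cost of biased p-values.
#' @return an object of class `de_logit`: coefficients, standard errors,
#'   Wald z and p, odds ratios with 95 percent CIs, log-likelihoods,
#'   `lrt_p`, `converged` and `separation_detected` flags.
#' @export
fit_logistic <- function(design_rows,
                         predictors = intersect(c("H", "C", "order_indicator"),
                                                names(design_rows)),
                         case_id = NA_integer_,
                         max_iter = 100L, tol = 1e-8, ridge = 0) {
  y <- as.numeric(design_rows$label)
  stopifnot(all(y %in% c(0, 1)))
  n <- length(y)
  if (length(unique(y)) < 2L)
    stop("logistic fit requires both label classes to be present")
  X <- cbind(`(Intercept)` = 1,
             as.matrix(design_rows[, predictors, drop = FALSE]))
  storage.mode(X) <- "double"
  p <- ncol(X)
  if (n <= p)
    stop("need more observations (", n, ") than parameters (", p, ")")

  beta <- rep(0, p)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    A <- XtW %*% X + diag(ridge, p)
    beta_new <- tryCatch(drop(solve(A, XtW %*% z)),
                         error = function(e)
                           drop(solve(A + diag(1e-8, p), XtW %*% z)))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)

  # Separation heuristic: every observation classified correctly and some
  # linear predictors already extreme -> the MLE is at infinity.
  separation <- all((mu > 0.5) == (y == 1)) && max(abs(eta)) > 15
  if (separation)
    warning("complete or quasi-complete separation detected; ",
            "coefficients and p-values are unreliable")

  w <- pmax(mu * (1 - mu), 1e-10)
  A <- t(X * w) %*% X + diag(ridge, p)
  cov_beta <- tryCatch(solve(A), error = function(e)
    solve(A + diag(1e-8, p)))
  se <- sqrt(pmax(diag(cov_beta), 0))
  zstat <- beta / se
  wald_p <- 2 * stats::pnorm(-abs(zstat))

  ll <- logistic_loglik(beta, X, y)
  pbar <- mean(y)
  ll0 <- n * (pbar * log(pbar) + (1 - pbar) * log(1 - pbar))
  df <- p - 1L
  lrt_p <- if (df >= 1L) lrt_pvalue(ll, ll0, df) else NA_real_

  structure(list(
    case_id = case_id, n = n,
    coefficients = stats::setNames(beta, colnames(X)),
    standard_errors = stats::setNames(se, colnames(X)),
    wald_z = stats::setNames(zstat, colnames(X)),
    wald_p = stats::setNames(wald_p, colnames(X)),
    odds_ratios = stats::setNames(exp(beta), colnames(X)),
    or_ci_low = stats::setNames(exp(beta - 1.96 * se), colnames(X)),
    or_ci_high = stats::setNames(exp(beta + 1.96 * se), colnames(X)),
    loglik = ll, loglik_null = ll0, df = df, lrt_p = lrt_p,
    n_iter = iter, converged = converged,
    separation_detected = separation), class = "de_logit")
}

#' @export
print.de_logit <- function(x, ...) {
  cat(sprintf("<de_logit> n=%d  loglik=%.4f  LRT p=%s  %s%s\n",
              x$n, x$loglik,
              if (is.na(x$lrt_p)) "NA" else format.pval(x$lrt_p, digits = 4),
              if (x$converged) "converged" else "NOT converged",
              if (x$separation_detected) "  [SEPARATION]" else ""))
  tab <- data.frame(coef = x$coefficients, se = x$standard_errors,
                    z = x$wald_z, p = x$wald_p, OR = x$odds_ratios)
  print(round(tab, 4))
  invisible(x)
}

#' Likelihood-ratio test p-value
#'
#' Survival function of the chi-square distribution with `df` degrees of
#' freedom evaluated at the deviance `2 * (loglik - loglik_null)`.
#'
#' @param loglik fitted model log-likelihood.
#' @param loglik_null nested null model log-likelihood.
#' @param df degrees of freedom (>= 1).
#' @return p-value in (0, 1].
#' @export
lrt_pvalue <- function(loglik, loglik_null, df) {
  stopifnot(df >= 1)
  dev <- 2 * (loglik - loglik_null)
  if (dev < -1e-8)
    stop("negative deviance: alternative log-likelihood below the null")
  stats::pchisq(max(dev, 0), df = df, lower.tail = FALSE)
}

as_2x2 <- function(table) {
  cells <- as.numeric(table)
  if (length(cells) != 4L || any(cells < 0) || any(cells != round(cells)))
    stop("expected a 2x2 table of non-negative integer counts")
  # c(a, b, c, d): rows = motif present/absent, cols = secretory/non
  cells
}

#' Odds ratio of a 2x2 contingency table
#'
#' `OR = (a * d) / (b * c)` for cell order `(a, b, c, d)` = (row 1 col 1,
#' row 1 col 2, row 2 col 1, row 2 col 2). When any cell is zero, 0.5 is
#' added to every cell (Haldane-Anscombe) and the correction is flagged.
#' The 95 percent CI is the Wald interval on the log odds ratio.
#'
#' @param table 2x2 matrix (row-major `c(a, b, c, d)` also accepted).
#' @return list of class `de_contingency`: `table`, `odds_ratio`,
#'   `or_ci_95`, `fisher_p_two_sided`, `correction_applied`.
#' @export
odds_ratio <- function(table) {
  cells <- as_2x2(table)
  if (all(cells == 0)) stop("all-zero contingency table")
  correction <- any(cells == 0)
  adj <- if (correction) cells + 0.5 else cells
  or <- (adj[1] * adj[4]) / (adj[2] * adj[3])
  se_log <- sqrt(sum(1 / adj))
  ci <- exp(log(or) + c(-1.96, 1.96) * se_log)
  structure(list(table = matrix(cells, 2, 2, byrow = TRUE,
                                dimnames = list(c("present", "absent"),
                                                c("secretory", "non_secretory"))),
                 odds_ratio = or, or_ci_95 = ci,
                 fisher_p_two_sided = fisher_exact_two_sided(cells),
                 correction_applied = correction),
            class = "de_contingency")
}

#' @export
print.de_contingency <- function(x, ...) {
  print(x$table)
  cat(sprintf("OR = %.4g  [%.4g, %.4g]%s   Fisher p = %.4g\n",
              x$odds_ratio, x$or_ci_95[1], x$or_ci_95[2],
              if (x$correction_applied) " (Haldane-Anscombe corrected)" else "",
              x$fisher_p_two_sided))
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Sums the hypergeometric probabilities, under fixed margins, of every
#' table at least as extreme as the observed one (probability no greater
#' than the observed table's, with relative tolerance 1e-7 for ties).
#'
#' @param table 2x2 matrix or row-major `c(a, b, c, d)`.
#' @return two-sided p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(table) {
  cells <- as_2x2(table)
  a <- cells[1]; b <- cells[2]; c_ <- cells[3]; d <- cells[4]
  m <- a + b          # row-1 total
  n2 <- c_ + d        # row-2 total
  k <- a + c_         # col-1 total
  if (m + n2 == 0) stop("empty contingency table")
  lo <- max(0, k - n2)
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Contingency analysis of phosphorylatable diacidic motifs vs secretion
#'
#' Splits labelled proteins into those carrying at least one
#' phospho-context motif of the requested kinds and those carrying none,
#' crosses that with the secretion label, and reports the 2x2 table with
#' odds ratio and Fisher's exact p — overall and per group tag.
#'
#' @param dataset a `de_dataset`.
#' @param kinds subset of `XDE, DXE, DEX, XED, EXD, EDX` (default: all six).
#' @return list with elements `overall` (a `de_contingency`) and
#'   `by_group` (named list of `de_contingency`, one per group with both
#'   motif statuses and both labels represented; degenerate groups are
#'   reported with `NULL`).
#' @export
phospho_contingency <- function(dataset, kinds = names(PHOSPHO_PATTERNS)) {
  if (length(dataset$records) == 0) stop("empty dataset")
  labs <- dataset_labels(dataset)
  keep <- labs %in% c("secretory", "non_secretory")
  recs <- dataset$records[keep]
  if (length(recs) == 0) stop("no labelled proteins in dataset")
  present <- vapply(recs, function(rec)
    nrow(find_phospho_context_motifs(rec$sequence, rec$id, kinds)) > 0,
    logical(1))
  secr <- vapply(recs, `[[`, character(1), "label") == "secretory"
  grp <- vapply(recs, `[[`, character(1), "group")

  tab_of <- function(pr, sc) c(sum(pr & sc), sum(pr & !sc),
                               sum(!pr & sc), sum(!pr & !sc))
  overall <- odds_ratio(tab_of(present, secr))
  by_group <- lapply(sort(unique(grp)), function(g) {
    idx <- grp == g
    cells <- tab_of(present[idx], secr[idx])
    if (all(cells == 0)) NULL else odds_ratio(cells)
  })
  names(by_group) <- sort(unique(grp))
  list(overall = overall, by_group = by_group,
       kinds = kinds, n = length(recs))
}
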