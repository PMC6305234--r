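test_that("IRLS recovers closed-form fits", {
  # intercept-only on balanced labels: logit(0.5) = 0
  d0 <- data.frame(label = rep(c(1, 0), each = 5))
  f0 <- fit_logistic(d0, predictors = character(0))
  expect_equal(unname(f0$coefficients), 0, tolerance = 1e-8)
  expect_true(f0$converged)

  # saturated single-binary-predictor model: slope = log OR = ln 9
  d1 <- data.frame(
    label = c(rep(1, 6), rep(0, 2), rep(1, 2), rep(0, 6)),
    x = c(rep(1, 8), rep(0, 8)))
  f1 <- fit_logistic(d1, predictors = "x")
  expect_equal(unname(f1$coefficients["x"]), log(9), tolerance = 1e-6)
  expect_equal(unname(f1$coefficients["(Intercept)"]), log(2 / 6),
               tolerance = 1e-6)
  expect_equal(unname(f1$odds_ratios["x"]), 9, tolerance = 1e-5)
  expect_false(f1$separation_detected)
  expect_gte(f1$loglik, f1$loglik_null)
})

test_that("degenerate inputs are caught", {
  expect_error(fit_logistic(data.frame(label = rep(1, 10))),
               "both label classes")
  # perfectly ordered labels along a continuous predictor -> separation
  d <- data.frame(label = rep(c(0, 1), each = 10), x = c(1:10, 21:30))
  expect_warning(f <- fit_logistic(d, predictors = "x"), "separation")
  expect_true(f$separation_detected)
})

test_that("IRLS matches direct likelihood maximization on random data", {
  set.seed(21)
  for (rep in 1:6) {
    n <- sample(20:50, 1)
    X <- cbind(1, stats::rnorm(n), stats::rbinom(n, 1, 0.5))
    beta <- c(0.3, -0.8, 0.6)
    y <- stats::rbinom(n, 1, stats::plogis(drop(X %*% beta)))
    if (length(unique(y)) < 2) next
    d <- data.frame(label = y, x1 = X[, 2], x2 = X[, 3])
    fit <- suppressWarnings(fit_logistic(d, predictors = c("x1", "x2")))
    if (fit$separation_detected) next
    oracle <- oracle_logit_fit(X, y)
    expect_lt(max(abs(unname(fit$coefficients) - oracle)), 1e-4)
  }
})

test_that("rescaling a predictor rescales its coefficient only", {
  set.seed(22)
  n <- 80
  x <- stats::rnorm(n)
  y <- stats::rbinom(n, 1, stats::plogis(0.5 * x))
  f1 <- fit_logistic(data.frame(label = y, x = x), predictors = "x")
  f2 <- fit_logistic(data.frame(label = y, x = 10 * x), predictors = "x")
  expect_equal(unname(f2$coefficients["x"]),
               unname(f1$coefficients["x"]) / 10, tolerance = 1e-8)
  expect_equal(unname(f2$wald_z["x"]), unname(f1$wald_z["x"]),
               tolerance = 1e-6)
  expect_equal(f2$lrt_p, f1$lrt_p, tolerance = 1e-8)
})

test_that("lrt_pvalue is the chi-square survival function of the deviance", {
  expect_equal(lrt_pvalue(-10, -10, 1), 1.0)
  expect_equal(lrt_pvalue(-10 + 3.841 / 2, -10, 1), 0.05, tolerance = 1e-3)
  expect_equal(lrt_pvalue(-10 + 6.635 / 2, -10, 1), 0.01, tolerance = 1e-3)
  expect_error(lrt_pvalue(-11, -10, 1), "negative deviance")
})

test_that("odds ratios follow (ad)/(bc) with Haldane-Anscombe correction", {
  r <- odds_ratio(c(10, 5, 2, 8))
  expect_equal(r$odds_ratio, 8.0)
  expect_false(r$correction_applied)
  expect_equal(odds_ratio(c(5, 5, 5, 5))$odds_ratio, 1.0)

  rc <- odds_ratio(c(3, 0, 2, 4))
  expect_true(rc$correction_applied)
  expect_equal(rc$odds_ratio, (3.5 * 4.5) / (0.5 * 2.5))  # 12.6
  expect_true(rc$odds_ratio > 0)
  expect_lt(rc$or_ci_95[1], rc$odds_ratio)
  expect_gt(rc$or_ci_95[2], rc$odds_ratio)

  expect_error(odds_ratio(c(0, 0, 0, 0)), "all-zero")
  expect_error(odds_ratio(c(1, 2, 3)), "2x2")
})

test_that("Fisher exact test equals hypergeometric enumeration", {
  expect_equal(fisher_exact_two_sided(c(3, 1, 1, 3)), 34 / 70)
  expect_equal(fisher_exact_two_sided(c(0, 4, 4, 0)), 2 / 70)
  expect_equal(fisher_exact_two_sided(c(2, 2, 2, 2)), 1.0)
  set.seed(23)
  for (rep in 1:100) {
    cells <- as.integer(stats::rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
    if (sum(cells) == 0) next
    expect_equal(fisher_exact_two_sided(cells),
                 oracle_fisher(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12, label = paste(cells, collapse = ","))
  }
})

test_that("phospho contingency splits proteins by motif presence", {
  with_motif <- "AAADEAAADSEAAA"     # has DE and a DXE (X = S)
  without <- "AAADEAAAA"             # DE only, neutral flanks
  tab <- data.frame(
    id = paste0("P", 1:8),
    label = rep(c("secretory", "non_secretory"), each = 4),
    group = "g")
  seqs <- stats::setNames(
    c(rep(with_motif, 3), without, with_motif, rep(without, 3)),
    tab$id)
  files <- write_dataset_files(tab, seqs)
  d <- read_dataset(files$table, files$fasta)
  res <- phospho_contingency(d)
  expect_equal(as.vector(t(res$overall$table)), c(3, 1, 1, 3))
  expect_equal(res$overall$fisher_p_two_sided, 34 / 70, tolerance = 1e-9)

  # restricting the kind set changes the table
  res_dxe <- phospho_contingency(d, kinds = "DXE")
  expect_equal(as.vector(t(res_dxe$overall$table)), c(3, 1, 1, 3))
  res_xde <- phospho_contingency(d, kinds = "XDE")
  expect_equal(sum(res_xde$overall$table[1, ]), 0)  # nobody has XDE
  expect_true(res_xde$overall$correction_applied)
})
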