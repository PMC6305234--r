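# Independent brute-force oracles. These deliberately avoid the package's
# regex / IRLS / dhyper code paths: scanners check substrings by set
# membership, Fisher enumerates with choose(), the logistic oracle is a
# direct quasi-Newton maximisation of the log-likelihood, and selection
# is literal nested filtering.

ORACLE_PATTERN_SETS <- list(
  DE = list("D", "E"),
  XDE = list(c("S", "T", "Y", "H", "R", "K"), "D", "E"),
  DXE = list("D", c("S", "T", "Y", "H", "R", "K"), "E"),
  DEX = list("D", "E", c("S", "T", "Y", "H", "R", "K")),
  XED = list(c("S", "T", "Y", "H", "R", "K"), "E", "D"),
  EXD = list("E", c("S", "T", "Y", "H", "R", "K"), "D"),
  EDX = list("E", "D", c("S", "T", "Y", "H", "R", "K")),
  LIR_core = list(c("W", "F", "Y"), NULL, NULL, c("L", "I", "V")),
  LIR_xlir = list(
    c("A", "D", "E", "F", "G", "L", "P", "R", "S", "K"),
    c("D", "E", "G", "M", "S", "T", "V"),
    c("W", "F", "Y"),
    c("D", "E", "I", "L", "Q", "T", "V"),
    c("A", "D", "E", "F", "H", "I", "K", "L", "M", "P", "S", "T", "V"),
    c("I", "L", "V")))

# 0-based starts of all pattern matches, by checking every substring.
oracle_scan <- function(sequence, kind) {
  sets <- ORACLE_PATTERN_SETS[[kind]]
  len <- length(sets)
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  hits <- integer(0)
  if (n < len) return(hits)
  for (i in seq_len(n - len + 1L)) {
    ok <- TRUE
    for (j in seq_len(len)) {
      allowed <- sets[[j]]
      if (!is.null(allowed) && !chars[i + j - 1L] %in% allowed) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, i - 1L)
  }
  hits
}

# Two-sided Fisher p by full hypergeometric enumeration with choose().
oracle_fisher <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  prob <- vapply(lo:hi, function(k)
    choose(r1, k) * choose(r2, c1 - k) / choose(n, c1), numeric(1))
  p_obs <- choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# Direct maximum-likelihood logistic fit (BFGS with analytic gradient).
oracle_logit_fit <- function(X, y) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    sum(ifelse(eta > 35, eta, log1p(exp(pmin(eta, 35))))) - sum(y * eta)
  }
  gr <- function(b) {
    mu <- stats::plogis(drop(X %*% b))
    drop(t(X) %*% (mu - y))
  }
  stats::optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))$par
}

# Literal nested-filter representative-DE selection; returns the row index.
oracle_select_idx <- function(ctx, case) {
  oc <- ctx$order_class
  oc[oc == "B"] <- case$border_regroup
  cand <- which(oc == case$order_pref)
  if (length(cand) == 0) cand <- seq_len(nrow(ctx))
  cvals <- ctx$C[cand]
  best_c <- if (case$charge_extreme == "min") min(cvals) else max(cvals)
  cand <- cand[cvals == best_c]
  hvals <- ctx$H[cand]
  best_h <- if (case$hydro_extreme == "min") min(hvals) else max(hvals)
  cand <- cand[hvals == best_h]
  cand[which.min(ctx$start[cand])]
}

random_aa_seq <- function(len, alphabet = c("A", "C", "D", "E", "F", "G",
                                            "H", "I", "K", "L", "M", "N",
                                            "P", "Q", "R", "S", "T", "V",
                                            "W", "Y")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Toy context table with controllable order classes / features.
make_contexts <- function(protein_id, starts, H, C, order_class,
                          label = "secretory", group = "g") {
  data.frame(protein_id = protein_id, start = starts, H = H, C = C,
             order_class = order_class,
             n_flank_left = 3L, n_flank_right = 3L,
             flank_left = "AAA", flank_right = "AAA",
             label = label, group = group, stringsAsFactors = FALSE)
}
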