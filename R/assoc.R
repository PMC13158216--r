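#' Spearman rank correlation with exact small-sample p-value
#'
#' Ties receive average ranks; rho is the Pearson correlation of the ranks.
#' For `3 < n <= exact_n_max` the two-sided p-value is computed by full
#' enumeration of the permutation distribution of rho (ties handled by
#' enumerating distinct arrangements); for larger n the usual t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom is used.
#'
#' @param x,y Paired numeric vectors; incomplete pairs are dropped.
#' @param exact_n_max Largest n for which the exact permutation p is used.
#' @return Data frame `rho, p, n, method`; `rho` is `NA` (flagged via
#'   `method = "undefined"`) when either vector has zero rank variance or
#'   fewer than 3 complete pairs remain.
#' @export
spearman_test <- function(x, y, exact_n_max = 10) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  undef <- data.frame(rho = NA_real_, p = NA_real_, n = n,
                      method = "undefined", stringsAsFactors = FALSE)
  if (n < 3) return(undef)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(undef)
  rho <- cor(rx, ry)
  if (n <= exact_n_max) {
    # |rho| >= |rho_obs| expressed as tail bounds on S = sum(rx * ry_perm)
    mx <- mean(rx); my <- mean(ry)
    denom <- (n - 1) * sd(rx) * sd(ry)
    s_obs <- sum(rx * ry)
    dev <- abs(s_obs - n * mx * my)
    hi <- n * mx * my + dev - 1e-9 * denom
    lo <- n * mx * my - dev + 1e-9 * denom
    ct <- perm_crossprod_tail_count(rx, ry, lo, hi)
    p <- ct[1] / ct[2]
    method <- "exact_permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * pt(-abs(tstat), df = n - 2))
    method <- "t_approximation"
  }
  data.frame(rho = rho, p = p, n = n, method = method,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the input
#' order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   propagated; the effective family size is the number of non-missing
#'   values).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_nddprs("p-values must lie in [0, 1]",
                class = "nddprs_validation_error")
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(out)
  o <- order(p[ok])
  q <- p[ok][o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out[ok[o]] <- pmin(q, 1)
  out
}

#' Welch's two-sample t-test from raw data or summary statistics
#'
#' Computes `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with the
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value. Supply
#' either two raw vectors (`x`, `y`) or the six summary statistics.
#'
#' @param x,y Raw group vectors (optional).
#' @param n1,mean1,sd1,n2,mean2,sd2 Group summaries (used when `x` is
#'   missing).
#' @return Data frame `t, df, p, flag`; when both variances are zero, `p` is
#'   1 for equal means and 0 otherwise, flagged `"degenerate"`.
#' @export
welch_t <- function(x = NULL, y = NULL, n1 = NULL, mean1 = NULL, sd1 = NULL,
                    n2 = NULL, mean2 = NULL, sd2 = NULL) {
  if (!is.null(x)) {
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    n1 <- length(x); mean1 <- mean(x); sd1 <- sd(x)
    n2 <- length(y); mean2 <- mean(y); sd2 <- sd(y)
  }
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  if (v1 + v2 == 0) {
    equal <- isTRUE(all.equal(mean1, mean2))
    return(data.frame(t = if (equal) 0 else Inf * sign(mean1 - mean2),
                      df = NA_real_, p = if (equal) 1 else 0,
                      flag = "degenerate", stringsAsFactors = FALSE))
  }
  tstat <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  data.frame(t = tstat, df = df, p = 2 * pt(-abs(tstat), df),
             flag = NA_character_, stringsAsFactors = FALSE)
}

#' Freeman-Halton exact test for r x c contingency tables
#'
#' Enumerates every table with the observed margins and sums the
#' multivariate hypergeometric probabilities of tables whose probability
#' does not exceed that of the observed table (probability ordering, with a
#' 1e-12 tolerance for ties). Specializes to Fisher's exact test for 2 x 2
#' tables. Rows and columns with zero margins are dropped first; if fewer
#' than two rows or columns remain the distribution is degenerate and p = 1.
#'
#' @param tab Matrix of non-negative integer counts.
#' @param max_tables Enumeration cap; exceeding it raises an error advising
#'   a Monte-Carlo approach.
#' @return Two-sided exact p-value.
#' @export
exact_rxc <- function(tab, max_tables = 1e7) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop_nddprs("contingency table must hold non-negative integers",
                class = "nddprs_validation_error")
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(1)
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)

  log_const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(N + 1)
  log_p_table <- function(m) log_const - sum(lgamma(m + 1))
  lp_obs <- log_p_table(tab)

  n_r <- length(rs); n_c <- length(cs)
  total <- 0
  n_enum <- 0L
  # depth-first fill, row-major; last column and last row are forced
  cell_fill <- function(m, i, j, col_rem, row_rem) {
    if (n_enum > max_tables)
      stop_nddprs("table enumeration exceeded cap (", format(max_tables),
                  "); use a Monte-Carlo approximation",
                  class = "nddprs_enumeration_cap")
    if (i == n_r) {                       # last row forced by column margins
      m[i, ] <- col_rem
      n_enum <<- n_enum + 1L
      lp <- log_p_table(m)
      if (lp <= lp_obs + 1e-12) total <<- total + exp(lp)
      return(invisible())
    }
    if (j == n_c) {                       # last cell of row forced
      v <- row_rem
      if (v < 0 || v > col_rem[j]) return(invisible())
      m[i, j] <- v
      col_rem[j] <- col_rem[j] - v
      cell_fill(m, i + 1L, 1L, col_rem, rs[i + 1L])
      return(invisible())
    }
    for (v in 0:min(row_rem, col_rem[j])) {
      m[i, j] <- v
      cr <- col_rem; cr[j] <- cr[j] - v
      cell_fill(m, i, j + 1L, cr, row_rem - v)
    }
  }
  m0 <- matrix(0L, n_r, n_c)
  cell_fill(m0, 1L, 1L, cs, rs[1])
  min(1, total)
}

#' Median split of polygenic scores into high and low groups
#'
#' Scores strictly above the median are labelled `"high"`, all others
#' (including the median itself and ties at it) `"low"`; with odd n the
#' median patient therefore falls in the low group.
#'
#' @param scores Named numeric vector of per-patient scores.
#' @return Factor of labels `low`/`high`, named like `scores`.
#' @export
median_split <- function(scores) {
  stopifnot(length(scores) >= 2)
  med <- median(scores, na.rm = TRUE)
  lab <- ifelse(scores > med, "high", "low")
  if (all(lab == "low", na.rm = TRUE))
    warning("all scores identical or below median; every patient in 'low'")
  factor(lab, levels = c("low", "high"))
}

#' Correlation battery between polygenic scores and clinical measures
#'
#' Computes Spearman correlations of every PRS column against every symptom
#' (DIBS subscale) and responsiveness (ARS subscale) column, with
#' Benjamini-Hochberg adjustment either within each PRS family (default;
#' one family = the 6 tests of one PRS) or globally across all tests.
#'
#' @param prs Data frame with `patient_id` plus one numeric column per PRS.
#' @param ars_table Output of [build_ars_table()] (uses `ars_pos, ars_neg,
#'   ars_gen`).
#' @param dibs Data frame with `patient_id` plus DIBS subscale severity
#'   columns `dibs_pos, dibs_neg, dibs_gen`.
#' @param family `"per_prs"` or `"global"` BH family.
#' @param exact_n_max Passed to [spearman_test()].
#' @return Data frame `prs, variable, rho, p, p_adj, n, method, family`.
#' @export
run_association_battery <- function(prs, ars_table, dibs,
                                    family = c("per_prs", "global"),
                                    exact_n_max = 10) {
  family <- match.arg(family)
  if (!all(ars_table$patient_id %in% prs$patient_id) ||
      !all(dibs$patient_id %in% prs$patient_id))
    stop_nddprs("patient ids of the clinical tables do not match the PRS ",
                "table", class = "nddprs_join_error")
  prs_cols <- setdiff(names(prs), "patient_id")
  dibs_cols <- intersect(c("dibs_pos", "dibs_neg", "dibs_gen"), names(dibs))
  ars_cols <- intersect(c("ars_pos", "ars_neg", "ars_gen"),
                        names(ars_table))
  merged <- merge(merge(prs, dibs, by = "patient_id"),
                  ars_table[, c("patient_id", ars_cols)], by = "patient_id")
  rows <- list()
  for (pc in prs_cols) for (vc in c(dibs_cols, ars_cols)) {
    st <- spearman_test(merged[[pc]], merged[[vc]],
                        exact_n_max = exact_n_max)
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(prs = pc, variable = vc, stringsAsFactors = FALSE),
            st)
  }
  out <- do.call(rbind, rows)
  out$family <- if (family == "per_prs") out$prs else "global"
  out$p_adj <- NA_real_
  for (f in unique(out$family)) {
    idx <- out$family == f
    out$p_adj[idx] <- bh_adjust(out$p[idx])
  }
  out[, c("prs", "variable", "rho", "p", "p_adj", "n", "method", "family")]
}

#' Demographic comparison table between two patient subgroups
#'
#' Mirrors the usual cohort-description table: categorical variables are
#' compared with the Freeman-Halton exact test, continuous variables with
#' Welch's t-test; means and SDs per group are reported.
#'
#' @param clinical Clinical data frame (one row per patient).
#' @param groups Factor of subgroup labels aligned with `clinical` rows.
#' @param continuous,categorical Column names to compare.
#' @return Data frame `variable, test, group1, group2, p` where `group1/2`
#'   hold `mean +/- sd` (continuous) or level counts (categorical).
#' @export
demographics_table <- function(clinical, groups,
                               continuous = c("age", "doi", "cpeq_3mo"),
                               categorical = "sex") {
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2, length(groups) == nrow(clinical))
  lv <- levels(groups)
  rows <- list()
  for (v in intersect(categorical, names(clinical))) {
    tab <- table(clinical[[v]], groups)
    fmt <- apply(tab, 2, function(cnt)
      paste(paste0(rownames(tab), "=", cnt), collapse = ", "))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, test = "freeman_halton",
      group1 = fmt[1], group2 = fmt[2],
      p = exact_rxc(t(tab)), stringsAsFactors = FALSE)
  }
  for (v in intersect(continuous, names(clinical))) {
    x <- clinical[[v]][groups == lv[1]]
    y <- clinical[[v]][groups == lv[2]]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) next
    wt <- welch_t(x, y)
    fmt <- function(z) sprintf("%.2f +/- %.2f", mean(z), sd(z))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, test = "welch_t", group1 = fmt(x), group2 = fmt(y),
      p = wt$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
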