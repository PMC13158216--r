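#' Harmonize discovery summary statistics to a target genotype panel
#'
#' Drops variants with imputation INFO below `info_min`, matches the
#' remainder to the target panel by chromosome and position, and aligns the
#' effect size to the allele counted by the target dosage (`a2`): a direct
#' match keeps `BETA`, swapped allele order flips its sign, and a
#' complement-strand match (non-ambiguous variants only) is resolved by
#' complementing before the same rule. Variants that remain unmatched, or
#' whose allele pair is strand-ambiguous so a complement match cannot be
#' oriented, are dropped.
#'
#' @param stats Summary-statistic data frame with columns
#'   `SNP, CHR, BP, A1, A2, BETA, P, INFO` (A1 = effect allele).
#' @param g Target [geno_matrix()].
#' @param info_min Minimum INFO score retained.
#' @return Data frame with columns `id` (target variant id), `chrom`, `pos`,
#'   `beta` (per copy of the target `a2` allele), `p`, `info`, `match`;
#'   attribute `"report"` counts variants per harmonization category.
#' @export
harmonize_sumstats <- function(stats, g, info_min = 0.8) {
  need <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "P", "INFO")
  if (!all(need %in% names(stats)))
    stop_nddprs("summary statistics must have columns ",
                paste(need, collapse = ", "), class = "nddprs_parse_error")
  n_in <- nrow(stats)
  stats <- stats[!is.na(stats$INFO) & stats$INFO >= info_min, , drop = FALSE]
  n_info <- n_in - nrow(stats)

  v <- g$variants
  key_t <- paste(v$chrom, v$pos, sep = ":")
  key_s <- paste(stats$CHR, stats$BP, sep = ":")
  m <- match(key_s, key_t)
  matched <- !is.na(m)
  stats <- stats[matched, , drop = FALSE]
  tv <- v[m[matched], , drop = FALSE]
  n_unmatched_pos <- sum(!matched)

  a1 <- stats$A1; a2 <- stats$A2
  direct  <- a1 == tv$a2 & a2 == tv$a1    # effect allele is the counted one
  swapped <- a1 == tv$a1 & a2 == tv$a2    # effect allele is the other one
  amb_s <- paste0(a1, a2) %in% c("AT", "TA", "CG", "GC")
  c1 <- unname(.complement[a1]); c2 <- unname(.complement[a2])
  comp    <- !direct & !swapped & !amb_s & c1 == tv$a2 & c2 == tv$a1
  comp_sw <- !direct & !swapped & !amb_s & c1 == tv$a1 & c2 == tv$a2
  keep <- direct | swapped | comp | comp_sw
  sign <- ifelse(swapped | comp_sw, -1, 1)
  match_type <- rep("dropped", nrow(stats))
  match_type[direct] <- "direct"; match_type[swapped] <- "swapped"
  match_type[comp] <- "complement"; match_type[comp_sw] <- "complement_swapped"

  out <- data.frame(id = tv$id[keep], chrom = tv$chrom[keep],
                    pos = tv$pos[keep],
                    beta = stats$BETA[keep] * sign[keep],
                    p = stats$P[keep], info = stats$INFO[keep],
                    match = match_type[keep], stringsAsFactors = FALSE)
  if (nrow(out) == 0)
    stop_nddprs("no summary-statistic variants overlap the target panel",
                class = "nddprs_empty_overlap")
  attr(out, "report") <- c(input = n_in, info_removed = n_info,
                           no_position_match = n_unmatched_pos,
                           direct = sum(direct), swapped = sum(swapped),
                           complement = sum(comp),
                           complement_swapped = sum(comp_sw),
                           allele_mismatch = sum(!keep))
  out
}

#' Greedy LD clumping of summary statistics
#'
#' Repeatedly takes the not-yet-clumped variant with the smallest GWAS
#' p-value as an index variant and removes every variant on the same
#' chromosome within `window_bp` (center-to-center, boundary inclusive)
#' whose squared Pearson correlation of dosages with the index exceeds
#' `r2_thresh`. Ties on p are broken by chromosome then position. LD is
#' computed from the target-sample dosages (pairwise-complete).
#'
#' @param harmonized Output of [harmonize_sumstats()].
#' @param g Target [geno_matrix()] providing dosages for LD.
#' @param r2_thresh Squared-correlation threshold; removal is strict `>`.
#' @param window_bp Window half-width in base pairs.
#' @return Character vector of retained (index) variant ids, ordered by
#'   ascending p.
#' @export
clump_variants <- function(harmonized, g, r2_thresh = 0.1,
                           window_bp = 200000) {
  h <- harmonized[order(harmonized$p, harmonized$chrom, harmonized$pos), ,
                  drop = FALSE]
  dos <- g$dosage[, h$id, drop = FALSE]
  k <- nrow(h)
  alive <- rep(TRUE, k)
  retained <- character(0)
  for (i in seq_len(k)) {
    if (!alive[i]) next
    retained <- c(retained, h$id[i])
    cand <- which(alive & h$chrom == h$chrom[i] &
                    abs(h$pos - h$pos[i]) <= window_bp)
    cand <- setdiff(cand, i)
    if (length(cand)) {
      r <- suppressWarnings(
        cor(dos[, i], dos[, cand, drop = FALSE],
            use = "pairwise.complete.obs"))
      kill <- cand[!is.na(r) & r^2 > r2_thresh]
      alive[kill] <- FALSE
    }
    alive[i] <- FALSE
  }
  retained
}

#' Polygenic score at one p-value threshold
#'
#' Over the clumped variants with GWAS `p <= threshold`, computes for each
#' sample the weighted allele-dosage sum and the per-allele average
#' `sum(beta * dosage) / (2 * m_i)`, where `m_i` is the number of scored
#' variants with an observed (non-missing) dosage for that sample; missing
#' dosages enter the numerator mean-imputed.
#'
#' @param harmonized Output of [harmonize_sumstats()].
#' @param g Target [geno_matrix()].
#' @param clumped_ids Ids retained by [clump_variants()].
#' @param threshold GWAS p-value threshold.
#' @return Data frame with `sample, score, raw_score, n_nonmissing`;
#'   attributes `"n_variants"` (variants scored) and `"defined"` (`FALSE`
#'   when no variant passes the threshold, in which case scores are `NA`).
#' @export
prs_score <- function(harmonized, g, clumped_ids, threshold) {
  sel <- harmonized[harmonized$id %in% clumped_ids &
                      harmonized$p <= threshold, , drop = FALSE]
  samples <- g$samples$id
  if (nrow(sel) == 0) {
    out <- data.frame(sample = samples, score = NA_real_,
                      raw_score = NA_real_, n_nonmissing = 0L)
    attr(out, "n_variants") <- 0L
    attr(out, "defined") <- FALSE
    return(out)
  }
  dos <- g$dosage[, sel$id, drop = FALSE]
  m_i <- rowSums(!is.na(dos))
  imp <- impute_dosage_mean(dos)
  raw <- as.numeric(imp %*% sel$beta)
  score <- ifelse(m_i > 0, raw / (2 * m_i), NA_real_)
  out <- data.frame(sample = samples, score = score, raw_score = raw,
                    n_nonmissing = m_i, stringsAsFactors = FALSE)
  attr(out, "n_variants") <- nrow(sel)
  attr(out, "defined") <- TRUE
  out
}

#' Nagelkerke pseudo-R2 of a score for a binary outcome
#'
#' Fits intercept-only and intercept-plus-score logistic models by maximum
#' likelihood and returns `[1 - (L0/L1)^(2/n)] / [1 - L0^(2/n)]`.
#'
#' @param score Numeric predictor.
#' @param y Binary outcome (0/1 or logical).
#' @return List with `r2`, `converged` (FALSE under separation or
#'   non-convergence) and the fitted slope.
#' @export
nagelkerke_r2 <- function(score, y) {
  y <- as.integer(y)
  ok <- is.finite(score) & !is.na(y)
  score <- score[ok]; y <- y[ok]
  n <- length(y)
  fit1 <- suppressWarnings(glm(y ~ score, family = binomial(),
                               control = list(maxit = 100, epsilon = 1e-8)))
  fit0 <- glm(y ~ 1, family = binomial())
  ll1 <- as.numeric(logLik(fit1)); ll0 <- as.numeric(logLik(fit0))
  cox_snell <- 1 - exp(2 * (ll0 - ll1) / n)
  max_r2 <- 1 - exp(2 * ll0 / n)
  fitted1 <- fitted(fit1)
  separated <- all(fitted1 < 1e-8 | fitted1 > 1 - 1e-8)
  list(r2 = cox_snell / max_r2,
       converged = fit1$converged && !separated,
       slope = unname(coef(fit1)[2]))
}

#' Select the best PRS p-value threshold by variance explained
#'
#' @param scores Data frame or matrix of per-sample scores, one column per
#'   threshold (column names are the thresholds), or the `scores` element of
#'   [prs_pipeline()].
#' @param diagnosis Binary case/control labels (1/"SCZ" = case), one per row.
#' @return Data frame `threshold, r2_nagelkerke, converged` with attribute
#'   `"best_threshold"` (argmax over converged fits; ties take the smaller
#'   threshold).
#' @export
select_threshold <- function(scores, diagnosis) {
  y <- if (is.numeric(diagnosis)) as.integer(diagnosis != 0)
       else as.integer(diagnosis %in% c("SCZ", "case", "1", "CASE"))
  if (sum(y == 1) < 2 || sum(y == 0) < 2)
    stop_nddprs("threshold selection needs >= 2 cases and >= 2 controls",
                class = "nddprs_invalid_config")
  thr <- as.numeric(colnames(scores))
  res <- lapply(seq_along(thr), function(j) {
    s <- scores[, j]
    if (all(is.na(s)) || sd(s, na.rm = TRUE) == 0)
      return(data.frame(threshold = thr[j], r2_nagelkerke = NA_real_,
                        converged = FALSE))
    nk <- nagelkerke_r2(s, y)
    data.frame(threshold = thr[j], r2_nagelkerke = nk$r2,
               converged = nk$converged)
  })
  res <- do.call(rbind, res)
  usable <- res$converged & !is.na(res$r2_nagelkerke)
  best <- if (any(usable)) {
    cand <- res[usable, , drop = FALSE]
    cand$threshold[order(-cand$r2_nagelkerke, cand$threshold)][1]
  } else NA_real_
  attr(res, "best_threshold") <- best
  res
}

#' Clumping-and-thresholding PRS pipeline
#'
#' Harmonizes summary statistics to the QC'd target panel, clumps, scores
#' every sample at each threshold and selects the threshold with the highest
#' Nagelkerke R2 for case/control status.
#'
#' @param stats Raw summary statistics (see [harmonize_sumstats()]).
#' @param g QC'd [geno_matrix()].
#' @param diagnosis Per-sample case/control labels aligned with
#'   `g$samples$id`; defaults to `g$samples$diagnosis`.
#' @param thresholds GWAS p-value thresholds.
#' @param info_min,r2_thresh,window_bp Passed to the harmonization and
#'   clumping steps.
#' @return List with `scores` (samples x thresholds matrix), `n_variants`
#'   (per threshold), `selection` (from [select_threshold()]),
#'   `best_threshold`, `best_score` (per-sample score at the best
#'   threshold), `clumped_ids` and `harmonized`.
#' @export
prs_pipeline <- function(stats, g, diagnosis = g$samples$diagnosis,
                         thresholds = c(0.01, 0.03, 0.05, 1.00),
                         info_min = 0.8, r2_thresh = 0.1,
                         window_bp = 200000) {
  h <- harmonize_sumstats(stats, g, info_min = info_min)
  clumped <- clump_variants(h, g, r2_thresh = r2_thresh,
                            window_bp = window_bp)
  thresholds <- sort(thresholds)
  score_list <- lapply(thresholds, function(t)
    prs_score(h, g, clumped, t))
  scores <- do.call(cbind, lapply(score_list, `[[`, "score"))
  dimnames(scores) <- list(g$samples$id, format(thresholds, trim = TRUE))
  n_var <- vapply(score_list, attr, integer(1), which = "n_variants")
  names(n_var) <- colnames(scores)
  sel <- if (!is.null(diagnosis)) select_threshold(scores, diagnosis)
         else NULL
  best <- if (!is.null(sel)) attr(sel, "best_threshold") else NA_real_
  best_score <- if (!is.na(best))
    scores[, match(best, thresholds)] else NULL
  list(scores = scores, n_variants = n_var, selection = sel,
       best_threshold = best, best_score = best_score,
       clumped_ids = clumped, harmonized = h)
}
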