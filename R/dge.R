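#' Filter a count matrix to informative autosomal genes
#'
#' Removes genes annotated off the autosomes (sex-chromosome bias guard),
#' then genes whose counts-per-million reach `cpm_min` in fewer than
#' `min(table(groups))` samples (i.e. CPM below the cutoff in more than
#' `n - min group size` samples).
#'
#' @param counts Genes x samples integer matrix.
#' @param gene_chrom Chromosome per gene (character, aligned with rows).
#' @param groups Per-sample group labels (sets the expression-filter
#'   sample floor).
#' @param cpm_min CPM cutoff.
#' @return List `counts`, `gene_chrom` (filtered) and `report` (removal
#'   counts).
#' @export
dge_filter_genes <- function(counts, gene_chrom, groups, cpm_min = 1) {
  stopifnot(nrow(counts) == length(gene_chrom))
  auto <- gene_chrom %in% .nddprs_autosomes
  counts <- counts[auto, , drop = FALSE]
  gene_chrom <- gene_chrom[auto]
  lib <- colSums(counts)
  if (any(lib == 0))
    stop_nddprs("sample(s) with zero total counts",
                class = "nddprs_validation_error")
  cpm <- t(t(counts) / lib) * 1e6
  floor_n <- min(table(groups))
  expressed <- rowSums(cpm >= cpm_min) >= floor_n
  out <- counts[expressed, , drop = FALSE]
  if (nrow(out) == 0)
    stop_nddprs("no genes pass the expression filter",
                class = "nddprs_validation_error")
  list(counts = out, gene_chrom = gene_chrom[expressed],
       report = c(non_autosomal = sum(!auto),
                  low_expression = sum(!expressed),
                  retained = nrow(out)))
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values against a reference sample (the one whose
#' upper-quartile count fraction is closest to the mean upper quartile).
#' For each sample, genes with zero counts in either member of the pair are
#' dropped, the most extreme 30% of log ratios (M) and 5% of average log
#' abundances (A) are trimmed, and the remaining M values are combined with
#' inverse-asymptotic-variance weights. Factors are scaled to have
#' geometric mean 1; effective library sizes are `colSums(counts) * factor`.
#'
#' @param counts Genes x samples matrix.
#' @return Named numeric vector of normalization factors.
#' @export
tmm_factors <- function(counts) {
  lib <- colSums(counts)
  if (any(lib == 0))
    stop_nddprs("sample(s) with zero total counts",
                class = "nddprs_validation_error")
  uq <- apply(counts, 2, function(x) quantile(x, 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(k) {
    if (k == ref) return(1)
    tmm_pair(counts[, k], counts[, ref], lib[k], lib[ref])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m = 0.3, trim_a = 0.05) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (length(obs) == 0) return(1)
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- 1 / ((n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref))
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep2)) return(1)
  2^(sum(w[keep2] * m[keep2]) / sum(w[keep2]))
}

#' Fit a negative-binomial log-link GLM for one gene
#'
#' Iteratively reweighted least squares for mean
#' `mu_i = exp(x_i' beta + offset_i)` and variance `mu + phi * mu^2`;
#' `phi = 0` gives the Poisson model.
#'
#' @param y Counts for one gene.
#' @param design Full-rank model matrix.
#' @param offset Per-sample log effective library size.
#' @param phi Dispersion.
#' @param max_iter,tol IRLS controls.
#' @param beta_start Optional starting coefficients (warm start).
#' @return List `beta`, `mu`, `loglik`, `converged`, `iter`.
#' @export
nb_glm_fit <- function(y, design, offset, phi, max_iter = 100, tol = 1e-8,
                       beta_start = NULL) {
  n <- length(y)
  beta <- if (!is.null(beta_start)) beta_start else
    qr.solve(design, log(pmax(y, 0.5)) - offset)
  dev_old <- Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(design %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    wx <- design * w
    beta_new <- tryCatch(
      solve(crossprod(design, wx), crossprod(wx, z)),
      error = function(e) NULL)
    if (is.null(beta_new)) break
    delta <- max(abs(beta_new - beta))
    beta <- drop(beta_new)
    if (delta < tol * (1 + max(abs(beta)))) { converged <- TRUE; break }
  }
  eta <- pmin(pmax(drop(design %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  list(beta = beta, mu = mu, loglik = nb_loglik(y, mu, phi),
       converged = converged, iter = iter)
}

#' Negative-binomial log-likelihood
#' @param y Counts.
#' @param mu Fitted means.
#' @param phi Dispersion (0 = Poisson).
#' @return Total log-likelihood.
#' @export
nb_loglik <- function(y, mu, phi) {
  if (phi <= 0) return(sum(stats::dpois(y, mu, log = TRUE)))
  sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

# Cox-Reid adjusted profile log-likelihood of phi for one gene
apl_gene <- function(y, design, offset, phi, beta_start = NULL) {
  fit <- nb_glm_fit(y, design, offset, phi, beta_start = beta_start)
  w <- fit$mu / (1 + phi * fit$mu)
  xtwx <- crossprod(design, design * w)
  ld <- determinant(xtwx, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  structure(fit$loglik - 0.5 * as.numeric(ld$modulus), beta = fit$beta)
}

# peak of the parabola through three points around a grid argmax (log-x)
quad_peak <- function(lx, ly) {
  j <- which.max(ly)
  if (j == 1 || j == length(ly) || !all(is.finite(ly[(j - 1):(j + 1)])))
    return(lx[j])
  x <- lx[(j - 1):(j + 1)]; y <- ly[(j - 1):(j + 1)]
  d21 <- y[2] - y[1]; d23 <- y[2] - y[3]
  denom <- d21 + d23
  if (denom <= 0) return(lx[j])
  # equispaced grid: vertex offset in units of spacing
  off <- 0.5 * (d21 - d23) / denom
  x[2] + off * (x[3] - x[2])
}

#' Estimate negative-binomial dispersions (common + shrunk gene-wise)
#'
#' Maximizes the Cox-Reid adjusted profile likelihood (APL) on a log-spaced
#' dispersion grid. The common dispersion maximizes the APL summed over
#' genes; gene-wise dispersions maximize each gene's APL plus
#' `prior_df / residual_df` times the across-gene average APL, shrinking
#' them toward the common trend with a weight equivalent to `prior_df`
#' residual degrees of freedom.
#'
#' @param counts Filtered genes x samples matrix.
#' @param design Model matrix.
#' @param offset Log effective library sizes.
#' @param prior_df Shrinkage prior degrees of freedom.
#' @param grid Dispersion grid (log-spaced by default).
#' @return List `common`, `genewise` (per-gene), `grid`, `apl` (genes x
#'   grid matrix).
#' @export
estimate_dispersions <- function(counts, design, offset, prior_df = 10,
                                 grid = exp(seq(log(1e-4), log(5),
                                                length.out = 19))) {
  g <- nrow(counts)
  resid_df <- ncol(counts) - ncol(design)
  if (resid_df < 2)
    stop_nddprs("need at least 2 residual degrees of freedom",
                class = "nddprs_validation_error")
  if (all(counts == 0))
    stop_nddprs("no positive counts", class = "nddprs_validation_error")
  apl <- matrix(-Inf, g, length(grid))
  for (i in seq_len(g)) {
    y <- counts[i, ]
    bs <- NULL
    for (j in seq_along(grid)) {
      a <- apl_gene(y, design, offset, grid[j], beta_start = bs)
      bs <- attr(a, "beta")
      apl[i, j] <- as.numeric(a)
    }
  }
  lgrid <- log(grid)
  common <- exp(quad_peak(lgrid, colSums(apl)))
  prior_n <- prior_df / resid_df
  score <- apl + prior_n * matrix(colMeans(apl), g, length(grid),
                                  byrow = TRUE)
  genewise <- vapply(seq_len(g), function(i)
    exp(quad_peak(lgrid, score[i, ])), numeric(1))
  list(common = common, genewise = genewise, grid = grid, apl = apl)
}

#' Likelihood-ratio test for the group effect of one gene
#'
#' @param fit_full,fit_reduced Fits from [nb_glm_fit()] under nested designs
#'   sharing the same dispersion.
#' @return Data frame `lrt, p, flag`; a reduced fit beating the full fit by
#'   more than 1e-8 flags the gene `"nonmonotone_likelihood"`.
#' @export
lrt_test <- function(fit_full, fit_reduced) {
  stat <- 2 * (fit_full$loglik - fit_reduced$loglik)
  if (stat < -1e-8)
    return(data.frame(lrt = NA_real_, p = NA_real_,
                      flag = "nonmonotone_likelihood",
                      stringsAsFactors = FALSE))
  stat <- max(stat, 0)
  data.frame(lrt = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
             flag = NA_character_, stringsAsFactors = FALSE)
}

#' Differential expression between PRS subgroups (NB GLM with LRT)
#'
#' Filters to informative autosomal genes, computes TMM effective library
#' sizes, estimates dispersions (common + shrunk gene-wise, Cox-Reid
#' adjusted), fits per-gene negative-binomial GLMs with group, sex and
#' age-decade covariates, and tests the group coefficient by a chi-square
#' likelihood-ratio test. The first level of `group` (the low-PRS subgroup)
#' is the reference, so positive log2 fold changes mean higher expression in
#' the high-PRS subgroup. Genes with nominal `p < deg_alpha` are flagged as
#' differentially expressed; BH-adjusted p-values (FDR) are reported
#' alongside.
#'
#' @param counts Genes x samples integer matrix.
#' @param gene_chrom Chromosome per gene.
#' @param group Two-level factor (reference = low).
#' @param sex Optional per-sample factor covariate.
#' @param age Optional per-sample numeric age, categorized into decades
#'   (`floor(age/10)`) as unordered factor covariates.
#' @param cpm_min,prior_df,deg_alpha Tuning parameters.
#' @return Data frame (sorted by p): `gene, logFC, logCPM, dispersion, lrt,
#'   p, fdr, deg, flag`; attribute `"filter_report"` carries the gene-filter
#'   counts.
#' @export
run_dge <- function(counts, gene_chrom, group, sex = NULL, age = NULL,
                    cpm_min = 1, prior_df = 10, deg_alpha = 0.05) {
  group <- factor(group)
  if (nlevels(group) != 2 || min(table(group)) < 2)
    stop_nddprs("need two groups with >= 2 samples each",
                class = "nddprs_validation_error")
  flt <- dge_filter_genes(counts, gene_chrom, group, cpm_min = cpm_min)
  counts <- flt$counts

  covars <- data.frame(group = group)
  if (!is.null(sex)) covars$sex <- droplevels(factor(sex))
  if (!is.null(age))
    covars$age_decade <- droplevels(factor(floor(age / 10)))
  # drop covariates that are constant or aliased with the rest
  design <- model.matrix(~., covars)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    keep <- qrd$pivot[seq_len(qrd$rank)]
    warning("design not full rank; dropping aliased column(s): ",
            paste(colnames(design)[-keep], collapse = ", "))
    design <- design[, keep, drop = FALSE]
  }
  design_red <- design[, !grepl("^group", colnames(design)), drop = FALSE]

  f <- tmm_factors(counts)
  offset <- log(colSums(counts) * f)
  disp <- estimate_dispersions(counts, design, offset, prior_df = prior_df)

  g <- nrow(counts)
  res <- vector("list", g)
  grp_col <- grep("^group", colnames(design))
  cpm_mean <- rowMeans(t(t(counts) / exp(offset)) * 1e6)
  for (i in seq_len(g)) {
    y <- counts[i, ]
    phi <- disp$genewise[i]
    full <- nb_glm_fit(y, design, offset, phi)
    red <- nb_glm_fit(y, design_red, offset, phi)
    lt <- lrt_test(full, red)
    if (!full$converged || !red$converged)
      lt$flag <- "nonconverged"
    res[[i]] <- data.frame(
      gene = rownames(counts)[i],
      logFC = full$beta[grp_col] / log(2),
      logCPM = log2(cpm_mean[i] + 0.5),
      dispersion = phi, lrt = lt$lrt, p = lt$p, flag = lt$flag,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  usable <- is.na(out$flag) | out$flag != "nonmonotone_likelihood"
  out$fdr <- NA_real_
  out$fdr[usable] <- bh_adjust(out$p[usable])
  out$deg <- !is.na(out$p) & out$p < deg_alpha
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  attr(out, "filter_report") <- flt$report
  attr(out, "dispersion_common") <- disp$common
  out
}

#' Plot-ready volcano table
#'
#' @param deg_table Output of [run_dge()].
#' @return Data frame `gene, logFC, neg_log10_p, deg`.
#' @export
volcano_table <- function(deg_table) {
  if (nrow(deg_table) == 0)
    return(data.frame(gene = character(0), logFC = numeric(0),
                      neg_log10_p = numeric(0), deg = logical(0)))
  data.frame(gene = deg_table$gene, logFC = deg_table$logFC,
             neg_log10_p = -log10(deg_table$p), deg = deg_table$deg,
             stringsAsFactors = FALSE)
}
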