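#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the observed allele counts. All
#' heterozygote counts compatible with the minor-allele count (same parity)
#' are assigned their conditional probabilities by the standard recurrence;
#' the p-value is the sum of probabilities no greater than that of the
#' observed heterozygote count (with a small tolerance for floating-point
#' ties).
#'
#' @param n_hom_minor,n_het,n_hom_major Genotype counts (minor homozygote,
#'   heterozygote, major homozygote).
#' @return Exact two-sided p-value in `(0, 1]`; degenerate inputs return 1.
#' @export
hwe_exact_p <- function(n_hom_minor, n_het, n_hom_major) {
  stopifnot(n_hom_minor >= 0, n_het >= 0, n_hom_major >= 0)
  n <- n_hom_minor + n_het + n_hom_major
  if (n < 1) return(1)
  n_minor <- 2L * n_hom_minor + n_het
  n_major <- 2L * n_hom_major + n_het
  if (n_minor > n_major) {          # orient to the rarer allele
    tmp <- n_minor; n_minor <- n_major; n_major <- tmp
  }
  if (n_minor == 0L) return(1)

  # heterozygote counts share the parity of the minor allele count
  hets <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  probs <- numeric(length(hets))
  mid_i <- which.min(abs(hets - n_minor * n_major / (2 * n)))
  probs[mid_i] <- 1
  # upward recurrence: P(h+2)/P(h) = 4 a(h) b(h) / ((h+2)(h+1))
  if (mid_i < length(hets)) for (i in mid_i:(length(hets) - 1L)) {
    h <- hets[i]
    a <- (n_minor - h) / 2           # minor homozygotes at h
    b <- (2 * n - n_minor - h) / 2   # major homozygotes at h
    probs[i + 1L] <- probs[i] * 4 * a * b / ((h + 2) * (h + 1))
  }
  # downward recurrence: P(h-2)/P(h) = h (h-1) / (4 (a+1)(b+1))
  if (mid_i > 1L) for (i in mid_i:2L) {
    h <- hets[i]
    a <- (n_minor - h) / 2
    b <- (2 * n - n_minor - h) / 2
    probs[i - 1L] <- probs[i] * h * (h - 1) / (4 * (a + 1) * (b + 1))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  if (is.na(p_obs)) return(1)       # inconsistent counts: degenerate
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

qc_report_row <- function(step, removed, retained) {
  data.frame(step = step, removed = removed, retained = retained,
             stringsAsFactors = FALSE)
}

#' Variant-level quality control
#'
#' Applies, in order: (1) autosomal location, (2) call rate strictly above
#' `call_rate`, (3) removal of duplicated sites (same chromosome, position
#' and allele set; first occurrence kept), (4) removal of strand-ambiguous
#' (A/T, C/G) variants, (5) minor allele frequency at least `maf_min`, and
#' (6) exact Hardy-Weinberg p-value at least `hwe_p`. All statistics are
#' computed on observed (non-missing) dosages; HWE uses hard genotype calls
#' (rounded dosages) in controls only by default.
#'
#' @param g A [geno_matrix()].
#' @param call_rate Retain variants with call rate `> call_rate`.
#' @param maf_min Retain variants with MAF `>= maf_min`.
#' @param hwe_p Retain variants with exact HWE p `>= hwe_p`.
#' @param hwe_samples `"controls"` (default; falls back to all samples when
#'   no diagnosis column is present) or `"all"`.
#' @return List with `geno` (filtered matrix) and `report` (per-step removal
#'   counts).
#' @export
filter_variants <- function(g, call_rate = 0.90, maf_min = 0.01,
                            hwe_p = 1e-5,
                            hwe_samples = c("controls", "all")) {
  stopifnot(inherits(g, "geno_matrix"))
  hwe_samples <- match.arg(hwe_samples)
  if (ncol(g$dosage) == 0)
    stop_nddprs("no variants to filter", class = "nddprs_empty_panel")
  report <- NULL
  keep_step <- function(keep, step) {
    report <<- rbind(report, qc_report_row(step, sum(!keep), sum(keep)))
    subset_geno(g, variants = which(keep))
  }

  g <- keep_step(g$variants$chrom %in% .nddprs_autosomes, "non_autosomal")
  cr <- colMeans(!is.na(g$dosage))
  g <- keep_step(cr > call_rate, "low_call_rate")
  key <- paste(g$variants$chrom, g$variants$pos,
               pmin(g$variants$a1, g$variants$a2),
               pmax(g$variants$a1, g$variants$a2), sep = ":")
  g <- keep_step(!duplicated(key), "duplicated")
  amb <- paste0(g$variants$a1, g$variants$a2) %in% c("AT", "TA", "CG", "GC")
  g <- keep_step(!amb, "ambiguous")
  freq <- colMeans(g$dosage, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  g <- keep_step(!is.na(maf) & maf >= maf_min, "low_maf")

  hwe_idx <- seq_len(nrow(g$dosage))
  if (hwe_samples == "controls" && !is.null(g$samples$diagnosis) &&
      any(g$samples$diagnosis == "CON"))
    hwe_idx <- which(g$samples$diagnosis == "CON")
  hp <- vapply(seq_len(ncol(g$dosage)), function(j) {
    d <- round(g$dosage[hwe_idx, j])
    d <- d[!is.na(d)]
    freq <- mean(d) / 2
    if (!length(d)) return(1)
    if (is.nan(freq)) return(1)
    minor_is_a2 <- freq <= 0.5
    n2 <- sum(d == 2); n1 <- sum(d == 1); n0 <- sum(d == 0)
    if (minor_is_a2) hwe_exact_p(n2, n1, n0) else hwe_exact_p(n0, n1, n2)
  }, numeric(1))
  g <- keep_step(hp >= hwe_p, "hwe")

  if (ncol(g$dosage) == 0)
    stop_nddprs("variant QC removed every variant",
                class = "nddprs_empty_panel")
  list(geno = g, report = report)
}

#' Sample-level quality control
#'
#' Removes samples with genotyping rate strictly below `sample_rate`, then
#' computes pairwise relatedness as the off-diagonal of a MAF-standardized
#' genomic relationship matrix and, for any pair exceeding `rel_thresh`,
#' drops the member with the lower call rate (ties broken by sample id).
#'
#' @param g A variant-QC'd [geno_matrix()].
#' @param sample_rate Retain samples with call rate `>= sample_rate`
#'   (exclusion is strict `<`).
#' @param rel_thresh Relatedness threshold above which one member of a pair
#'   is removed.
#' @return List with `geno`, `report`, and `relatedness` (the GRM).
#' @export
filter_samples <- function(g, sample_rate = 0.99, rel_thresh = 0.2) {
  stopifnot(inherits(g, "geno_matrix"))
  report <- NULL
  cr <- rowMeans(!is.na(g$dosage))
  keep <- cr >= sample_rate
  report <- rbind(report, qc_report_row("low_genotyping_rate",
                                        sum(!keep), sum(keep)))
  g <- subset_geno(g, samples = which(keep))
  cr <- cr[keep]
  if (nrow(g$dosage) < 2)
    stop_nddprs("fewer than 2 samples remain after call-rate filtering",
                class = "nddprs_insufficient_cohort")

  grm <- grm_matrix(g$dosage)
  alive <- rep(TRUE, nrow(grm))
  repeat {
    off <- grm
    off[!alive, ] <- -Inf; off[, !alive] <- -Inf
    diag(off) <- -Inf
    mx <- max(off)
    if (mx <= rel_thresh) break
    ij <- which(off == mx, arr.ind = TRUE)[1, ]
    # drop the lower-call-rate member; tie -> lexicographically later id
    ids <- g$samples$id[ij]
    pick <- if (cr[ij[1]] < cr[ij[2]]) ij[1]
            else if (cr[ij[2]] < cr[ij[1]]) ij[2]
            else ij[if (ids[1] > ids[2]) 1L else 2L]
    alive[pick] <- FALSE
  }
  report <- rbind(report, qc_report_row("relatedness",
                                        sum(!alive), sum(alive)))
  g <- subset_geno(g, samples = which(alive))
  if (nrow(g$dosage) < 2)
    stop_nddprs("fewer than 2 samples remain after relatedness filtering",
                class = "nddprs_insufficient_cohort")
  list(geno = g, report = report, relatedness = grm)
}

#' Genomic relationship matrix from dosages
#'
#' Standardizes each variant by its observed allele frequency
#' (`(d - 2p)/sqrt(2p(1-p))`, missing set to 0 after centering) and returns
#' `X Xt / m` over the `m` polymorphic variants.
#'
#' @param dosage Samples x variants dosage matrix.
#' @return Samples x samples relationship matrix.
#' @export
grm_matrix <- function(dosage) {
  p <- colMeans(dosage, na.rm = TRUE) / 2
  ok <- !is.na(p) & p > 0 & p < 1
  d <- dosage[, ok, drop = FALSE]
  p <- p[ok]
  X <- sweep(d, 2, 2 * p, "-")
  X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  X[is.na(X)] <- 0
  tcrossprod(X) / ncol(X)
}

#' Full genotype QC (variants then samples)
#'
#' @inheritParams filter_variants
#' @inheritParams filter_samples
#' @return List with `geno`, `report` (variant and sample steps stacked) and
#'   `relatedness`.
#' @export
run_geno_qc <- function(g, call_rate = 0.90, maf_min = 0.01, hwe_p = 1e-5,
                        hwe_samples = c("controls", "all"),
                        sample_rate = 0.99, rel_thresh = 0.2) {
  vq <- filter_variants(g, call_rate = call_rate, maf_min = maf_min,
                        hwe_p = hwe_p, hwe_samples = hwe_samples)
  sq <- filter_samples(vq$geno, sample_rate = sample_rate,
                       rel_thresh = rel_thresh)
  list(geno = sq$geno,
       report = rbind(cbind(level = "variant", vq$report),
                      cbind(level = "sample", sq$report)),
       relatedness = sq$relatedness)
}
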