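#' Configuration for the synthetic cohort generator
#'
#' Bundles every tunable of the simulated study: a small postmortem
#' schizophrenia case/control cohort genotyped on a block-LD variant panel,
#' an external (much larger) discovery GWAS providing summary statistics,
#' antemortem symptom-scale records with antipsychotic dosing for a subset of
#' the cases, and a bulk RNA-seq count matrix for the clinically documented
#' patients.
#'
#' Defaults mirror the target study design: 24 cases and 48 controls
#' genotyped, 19 cases with complete clinical (DIBS + CP-eq) records, a
#' moderately polygenic liability (50 causal variants, liability-scale
#' heritability 0.3), a discovery GWAS of 50,000 individuals, a target rank
#' correlation of -0.5 between polygenic burden and responsiveness of
#' positive symptoms, and a 2,000-gene expression panel with 200 genes
#' carrying group effects.
#'
#' @param n_cases,n_controls Cohort sizes for the genotyped sample.
#' @param n_clinical Number of cases with complete clinical records
#'   (DIBS subscale timelines and CP-eq dose); remaining cases get missing
#'   clinical fields.
#' @param n_variants Total variants on the panel.
#' @param n_blocks Number of contiguous LD blocks the panel is split into.
#' @param within_block_r Latent (liability-scale) correlation of variants
#'   within a block, in `[0, 1)`.
#' @param ld_model `"equicorrelated"` or `"ar1"` latent correlation within a
#'   block.
#' @param maf_range Range the per-variant minor allele frequency is drawn
#'   from, in `(0, 0.5]`.
#' @param n_causal Number of causal variants behind the liability.
#' @param heritability_liability Liability-scale heritability in `[0, 1)`.
#' @param discovery_n Sample size of the discovery GWAS that generated the
#'   summary statistics.
#' @param prs_ars_rho Target Spearman correlation between the true polygenic
#'   score and the antipsychotic responsiveness score of positive symptoms,
#'   in `(-1, 1)`.
#' @param n_genes,n_de_genes Expression panel size and number of genes with
#'   planted group effects.
#' @param lfc_sd Standard deviation of planted log2 fold changes.
#' @param dispersion_shape Scale of the gene-wise negative-binomial
#'   dispersion prior; dispersions are drawn as
#'   `dispersion_shape * 10 / rchisq(10)`.
#' @param libsize_log_sd Standard deviation of log library sizes.
#' @param missing_rate Approximate overall fraction of genotype entries set
#'   missing. Missingness is concentrated, as in array cohorts: a fraction
#'   `bad_sample_rate` of samples carries heavy missingness (entry rate
#'   0.2, so they fail the 0.99 sample call-rate filter) while ordinary
#'   samples have a low entry rate of `0.2 * missing_rate`.
#' @param bad_sample_rate Expected fraction of heavily missing samples.
#' @param ambiguous_rate Fraction of variants given strand-ambiguous (A/T or
#'   C/G) allele pairs.
#' @param nonauto_rate Fraction of variants placed on chromosome X.
#' @param nonauto_gene_rate Fraction of genes annotated to chromosome X.
#' @param info_shape Shape `a` of the Beta(a, 1) distribution INFO scores are
#'   drawn from (mass near 1).
#' @param swap_rate Fraction of summary-statistic rows reported with
#'   effect/other alleles in the opposite order to the target panel.
#' @param strand_flip_rate Fraction of summary-statistic rows reported on the
#'   opposite strand (alleles complemented).
#' @param seed Integer seed; every generator is a pure function of
#'   `(config, seed)`.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cases = 24L, n_controls = 48L, n_clinical = 19L,
                       n_variants = 5000L, n_blocks = 250L,
                       within_block_r = 0.5,
                       ld_model = c("equicorrelated", "ar1"),
                       maf_range = c(0.05, 0.5),
                       n_causal = 50L, heritability_liability = 0.3,
                       discovery_n = 50000L, prs_ars_rho = -0.5,
                       n_genes = 2000L, n_de_genes = 200L, lfc_sd = 1,
                       dispersion_shape = 0.1, libsize_log_sd = 0.3,
                       missing_rate = 0.01, bad_sample_rate = 0.03,
                       ambiguous_rate = 0.02,
                       nonauto_rate = 0.02, nonauto_gene_rate = 0.05,
                       info_shape = 12, swap_rate = 0.3,
                       strand_flip_rate = 0.05, seed = 1L) {
  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_clinical = as.integer(n_clinical),
    n_variants = as.integer(n_variants), n_blocks = as.integer(n_blocks),
    within_block_r = within_block_r, ld_model = match.arg(ld_model),
    maf_range = maf_range, n_causal = as.integer(n_causal),
    heritability_liability = heritability_liability,
    discovery_n = as.integer(discovery_n), prs_ars_rho = prs_ars_rho,
    n_genes = as.integer(n_genes), n_de_genes = as.integer(n_de_genes),
    lfc_sd = lfc_sd, dispersion_shape = dispersion_shape,
    libsize_log_sd = libsize_log_sd, missing_rate = missing_rate,
    bad_sample_rate = bad_sample_rate,
    ambiguous_rate = ambiguous_rate, nonauto_rate = nonauto_rate,
    nonauto_gene_rate = nonauto_gene_rate, info_shape = info_shape,
    swap_rate = swap_rate, strand_flip_rate = strand_flip_rate,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pos <- c("n_cases", "n_controls", "n_variants", "n_blocks", "n_genes",
           "discovery_n")
  for (f in pos)
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 1L)
      stop_nddprs("sim_config: '", f, "' must be a positive count",
                  class = "nddprs_invalid_config")
  if (cfg$discovery_n < 2L)
    stop_nddprs("sim_config: 'discovery_n' must be at least 2",
                class = "nddprs_invalid_config")
  if (cfg$n_causal < 0L || cfg$n_causal > cfg$n_variants)
    stop_nddprs("sim_config: need 0 <= n_causal <= n_variants",
                class = "nddprs_invalid_config")
  if (cfg$n_de_genes < 0L || cfg$n_de_genes > cfg$n_genes)
    stop_nddprs("sim_config: need 0 <= n_de_genes <= n_genes",
                class = "nddprs_invalid_config")
  if (cfg$within_block_r < 0 || cfg$within_block_r >= 1)
    stop_nddprs("sim_config: 'within_block_r' must lie in [0, 1)",
                class = "nddprs_invalid_config")
  if (abs(cfg$prs_ars_rho) >= 1)
    stop_nddprs("sim_config: |prs_ars_rho| must be < 1",
                class = "nddprs_invalid_config")
  if (cfg$heritability_liability < 0 || cfg$heritability_liability >= 1)
    stop_nddprs("sim_config: 'heritability_liability' must lie in [0, 1)",
                class = "nddprs_invalid_config")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop_nddprs("sim_config: 'maf_range' must lie in (0, 0.5]",
                class = "nddprs_invalid_config")
  if (cfg$n_clinical > cfg$n_cases)
    stop_nddprs("sim_config: n_clinical cannot exceed n_cases",
                class = "nddprs_invalid_config")
  invisible(cfg)
}

# Sub-stream offsets: each stage reseeds at seed + offset so stages are
# independently reproducible regardless of what ran before them.
.sim_offsets <- c(genotypes = 0L, sumstats = 11L, clinical = 23L,
                  counts = 37L, genesets = 53L)

.sim_seed <- function(cfg, stage, extra = 0L) {
  set.seed(cfg$seed + .sim_offsets[[stage]] + as.integer(extra))
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

#' Simulate a diploid genotype matrix with block-wise LD
#'
#' Variants are partitioned into `n_blocks` contiguous blocks. Within a
#' block, haplotypes are drawn from a latent Gaussian with equicorrelated or
#' AR(1) correlation `within_block_r` and thresholded at the per-variant
#' minor allele frequency; the two haplotypes of an individual are
#' independent, so single-variant genotypes are in Hardy-Weinberg
#' equilibrium by construction. Blocks are independent and separated by at
#' least 1 Mb, so LD-based clumping never reaches across blocks. A fraction
#' of entries is set missing, a fraction of variants gets strand-ambiguous
#' allele pairs, and per-variant imputation INFO scores are drawn from a
#' Beta(`info_shape`, 1).
#'
#' @param cfg A [sim_config()].
#' @return A `geno_matrix`: list with `dosage` (samples x variants, values
#'   0/1/2 or `NA`), `variants` (id, chrom, pos, a1, a2, info, maf_target)
#'   and `samples` (id) data frames. Dosage counts the `a2` allele.
#' @export
simulate_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  .sim_seed(cfg, "genotypes")
  n <- cfg$n_cases + cfg$n_controls
  m <- cfg$n_variants
  block_of <- sort(rep_len(seq_len(cfg$n_blocks), m))
  maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  thr <- qnorm(maf)

  dosage <- matrix(0L, n, m)
  r <- cfg$within_block_r
  for (b in seq_len(cfg$n_blocks)) {
    idx <- which(block_of == b)
    mb <- length(idx)
    for (hap in 1:2) {
      if (cfg$ld_model == "equicorrelated") {
        shared <- rnorm(n)
        z <- sqrt(r) * matrix(shared, n, mb) +
          sqrt(1 - r) * matrix(rnorm(n * mb), n, mb)
      } else {
        z <- matrix(rnorm(n * mb), n, mb)
        if (mb > 1) for (j in 2:mb)
          z[, j] <- r * z[, j - 1] + sqrt(1 - r^2) * z[, j]
      }
      alleles <- sweep(z, 2, thr[idx], "<")
      dosage[, idx] <- dosage[, idx] + alleles
    }
  }
  storage.mode(dosage) <- "double"

  # genomic coordinates: one block per 1 Mb slot, cycling over autosomes
  chrom <- character(m); pos <- integer(m)
  for (b in seq_len(cfg$n_blocks)) {
    idx <- which(block_of == b)
    chrom[idx] <- .nddprs_autosomes[((b - 1L) %% 22L) + 1L]
    slot <- (b - 1L) %/% 22L
    pos[idx] <- 1000000L * slot + 10000L + 2000L * seq_along(idx)
  }
  if (cfg$nonauto_rate > 0) {
    nx <- round(cfg$nonauto_rate * m)
    if (nx > 0) chrom[sample.int(m, nx)] <- "X"
  }

  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  pick <- pairs[sample.int(nrow(pairs), m, replace = TRUE), , drop = FALSE]
  amb <- rbind(c("A", "T"), c("C", "G"))
  n_amb <- round(cfg$ambiguous_rate * m)
  if (n_amb > 0) {
    which_amb <- sample.int(m, n_amb)
    pick[which_amb, ] <- amb[sample.int(2, n_amb, replace = TRUE), ,
                             drop = FALSE]
  }
  flip <- runif(m) < 0.5   # randomize which of the pair is a1
  a1 <- ifelse(flip, pick[, 2], pick[, 1])
  a2 <- ifelse(flip, pick[, 1], pick[, 2])

  info <- rbeta(m, cfg$info_shape, 1)
  if (cfg$missing_rate > 0) {
    # heavily missing ("failed") samples fall well below the 0.99 sample
    # call-rate cut; the rest stay well above it
    bad <- runif(n) < cfg$bad_sample_rate
    rate_s <- ifelse(bad, 0.2, 0.2 * cfg$missing_rate)
    miss <- matrix(runif(n * m), n, m) < rate_s
    dosage[miss] <- NA_real_
  }

  ids <- sprintf("snp%05d", seq_len(m))
  samples <- sprintf("S%03d", seq_len(n))
  dimnames(dosage) <- list(samples, ids)
  geno_matrix(
    dosage = dosage,
    variants = data.frame(id = ids, chrom = chrom, pos = pos, a1 = a1,
                          a2 = a2, info = info, maf_target = maf,
                          stringsAsFactors = FALSE),
    samples = data.frame(id = samples, stringsAsFactors = FALSE))
}

#' Simulate discovery-GWAS summary statistics for a genotype panel
#'
#' `n_causal` variants receive true standardized effects with total variance
#' `heritability_liability`; per-allele effects are scaled by
#' `1/sqrt(2 p (1-p))`. Observed effects add sampling noise with the
#' standard error of a quantitative-trait GWAS of `discovery_n` individuals,
#' and p-values come from the Wald statistic. A fraction of rows is reported
#' with swapped allele order and a fraction on the opposite strand, to
#' exercise harmonization. The per-sample true polygenic score (standardized
#' genotypes times true standardized effects) is attached as attribute
#' `"true_score"`, and the truth table as attribute `"truth"`.
#'
#' @param cfg A [sim_config()].
#' @param geno A `geno_matrix` from [simulate_genotypes()] on the same panel.
#' @param stream Integer sub-stream index; use different values to draw
#'   independent discovery GWAS (e.g. two disorders) for one cohort.
#' @return A data frame with columns `SNP, CHR, BP, A1, A2, BETA, P, INFO`
#'   (A1 = effect allele).
#' @export
simulate_summary_stats <- function(cfg, geno, stream = 0L) {
  validate_sim_config(cfg)
  stopifnot(inherits(geno, "geno_matrix"))
  if (cfg$discovery_n < 2L)
    stop_nddprs("summary stats need discovery_n >= 2",
                class = "nddprs_invalid_config")
  .sim_seed(cfg, "sumstats", extra = 7L * as.integer(stream))
  v <- geno$variants
  m <- nrow(v)
  p_all <- v$maf_target

  beta_std <- numeric(m)
  causal <- integer(0)
  if (cfg$n_causal > 0) {
    causal <- sample.int(m, cfg$n_causal)
    beta_std[causal] <- rnorm(cfg$n_causal,
                              sd = sqrt(cfg$heritability_liability /
                                          cfg$n_causal))
  }
  scale_j <- sqrt(2 * p_all * (1 - p_all))
  beta_true <- beta_std / scale_j
  se <- 1 / (scale_j * sqrt(cfg$discovery_n))
  beta_obs <- beta_true + rnorm(m) * se
  pval <- pmax(2 * pnorm(-abs(beta_obs / se)), 1e-300)

  # reported allele order / strand
  a1 <- v$a2; a2 <- v$a1; beta_rep <- beta_obs
  swap <- runif(m) < cfg$swap_rate
  a1[swap] <- v$a1[swap]; a2[swap] <- v$a2[swap]
  beta_rep[swap] <- -beta_obs[swap]
  flip <- runif(m) < cfg$strand_flip_rate
  a1[flip] <- .complement[a1[flip]]
  a2[flip] <- .complement[a2[flip]]

  ss <- data.frame(SNP = v$id, CHR = v$chrom, BP = v$pos, A1 = a1, A2 = a2,
                   BETA = beta_rep, P = pval, INFO = v$info,
                   stringsAsFactors = FALSE)
  X <- impute_dosage_mean(geno$dosage)
  Xs <- scale(X, center = 2 * p_all, scale = scale_j)
  true_score <- as.numeric(Xs %*% beta_std)
  names(true_score) <- geno$samples$id
  attr(ss, "true_score") <- true_score
  attr(ss, "truth") <- data.frame(id = v$id, causal = seq_len(m) %in% causal,
                                  beta_true = beta_true,
                                  stringsAsFactors = FALSE)
  ss
}

#' Simulate clinical records with a copula-controlled responsiveness score
#'
#' Case/control status is assigned by a liability threshold: liability is
#' the standardized true polygenic score (weight `sqrt(h2)`) plus
#' independent Gaussian noise, and the `n_cases` individuals with the
#' largest liability are the cases. For the `n_clinical` cases with complete
#' records, a latent responsiveness variable is drawn from a Gaussian copula
#' with target Spearman correlation `prs_ars_rho` against the true score
#' (Pearson parameter `2 sin(pi * rho / 6)`). Integer DIBS subscale scores
#' at the most severe point are drawn, 3-months-before-death scores are
#' back-solved from drawn improvement fractions, and the CP-eq dose is
#' obtained by pairing log-normally drawn doses with realized improvement
#' fractions so that the resulting ARS of positive symptoms carries exactly
#' the latent responsiveness ranks. Negative and general-psychopathology
#' subscales use independent latents (no PRS link).
#'
#' @param cfg A [sim_config()].
#' @param true_score Per-sample true polygenic score (one per genotyped
#'   sample; see [simulate_summary_stats()]).
#' @param completeness Optional per-sample genotype completeness (call
#'   rate). When given, the `n_clinical` documented cases are the cases
#'   with the most complete genotype data, emulating a study in which the
#'   clinically documented subset is the QC-passing analysis cohort; when
#'   `NULL`, the first `n_clinical` cases are documented.
#' @return A clinical data frame (one row per sample) with columns
#'   `patient_id, diagnosis, sex, age, doi, cpeq_3mo,
#'   dibs_{pos,neg,gen}_max, dibs_{pos,neg,gen}_3mo`. Controls and cases
#'   without clinical documentation have `NA` in the DIBS/CP-eq fields.
#' @export
simulate_clinical <- function(cfg, true_score, completeness = NULL) {
  validate_sim_config(cfg)
  if (abs(cfg$prs_ars_rho) >= 1)
    stop_nddprs("|prs_ars_rho| must be < 1", class = "nddprs_invalid_config")
  n <- length(true_score)
  if (n != cfg$n_cases + cfg$n_controls)
    stop_nddprs("true_score must have one entry per simulated sample",
                class = "nddprs_invalid_config")
  .sim_seed(cfg, "clinical")
  h2 <- cfg$heritability_liability
  ts_sd <- sd(true_score)
  ts_std <- if (is.na(ts_sd) || ts_sd == 0) rep(0, n) else
    (true_score - mean(true_score)) / ts_sd
  liability <- sqrt(h2) * ts_std + sqrt(1 - h2) * rnorm(n)
  case <- rank(-liability, ties.method = "first") <= cfg$n_cases

  ids <- names(true_score) %||% sprintf("S%03d", seq_len(n))
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.6, 0.4))
  age <- round(pmin(pmax(rnorm(n, 67, 10), 40), 95))
  onset <- round(pmin(pmax(rnorm(n, 25, 5), 15), 45))
  doi <- ifelse(case, pmax(age - onset, 1), NA_real_)

  cl <- data.frame(patient_id = ids,
                   diagnosis = ifelse(case, "SCZ", "CON"),
                   sex = sex, age = age, doi = doi,
                   cpeq_3mo = NA_real_,
                   dibs_pos_max = NA_real_, dibs_pos_3mo = NA_real_,
                   dibs_neg_max = NA_real_, dibs_neg_3mo = NA_real_,
                   dibs_gen_max = NA_real_, dibs_gen_3mo = NA_real_,
                   stringsAsFactors = FALSE)

  case_idx <- which(case)
  k <- min(cfg$n_clinical, length(case_idx))
  if (k == 0) return(cl)
  if (!is.null(completeness)) {
    stopifnot(length(completeness) == n)
    case_idx <- case_idx[order(-completeness[case_idx])]
  }
  doc <- sort(case_idx[seq_len(k)])

  # latent responsiveness via Gaussian copula against the true score
  r_pearson <- 2 * sin(pi * cfg$prs_ars_rho / 6)
  z1 <- qnorm((rank(true_score[doc], ties.method = "first") - 0.5) / k)
  latent <- r_pearson * z1 + sqrt(1 - r_pearson^2) * rnorm(k)

  draw_subscale <- function(lambda, shift) {
    s_max <- rpois(k, lambda) + shift
    c_target <- runif(k, 0.1, 0.9)
    s_pre <- pmin(pmax(round(s_max * (1 - c_target)), 0), s_max - 1L)
    list(s_max = s_max, s_pre = s_pre,
         c_real = (s_max - s_pre) / s_max)    # realized improvement, > 0
  }
  pos <- draw_subscale(8, 2L)
  neg <- draw_subscale(3, 1L)
  gen <- draw_subscale(3, 1L)

  # pair log-normal doses with realized improvements, then re-assign the
  # resulting ARS values by the latent ranks (dose absorbs the tie-break)
  dose <- rlnorm(k, meanlog = log(450), sdlog = 0.8)
  ars_pool <- sort(pos$c_real / dose)
  ars_assigned <- ars_pool[rank(latent, ties.method = "first")]
  dose_final <- pos$c_real / ars_assigned

  cl$cpeq_3mo[doc] <- dose_final
  cl$dibs_pos_max[doc] <- pos$s_max; cl$dibs_pos_3mo[doc] <- pos$s_pre
  cl$dibs_neg_max[doc] <- neg$s_max; cl$dibs_neg_3mo[doc] <- neg$s_pre
  cl$dibs_gen_max[doc] <- gen$s_max; cl$dibs_gen_3mo[doc] <- gen$s_pre
  cl
}

#' Simulate a negative-binomial RNA-seq count matrix with planted effects
#'
#' Gene-wise dispersions follow a scaled inverse-chi-square prior
#' (`dispersion_shape * 10 / rchisq(10)`), library sizes are log-normal, and
#' `n_de_genes` genes carry log2 fold changes drawn from
#' `Normal(0, lfc_sd)` between the two groups. A fraction of genes is
#' annotated to chromosome X to exercise the autosome filter.
#'
#' @param cfg A [sim_config()].
#' @param group_labels Per-sample binary labels (factor/character/0-1);
#'   the second level is the "high" group receiving the planted effects.
#' @return A list with `counts` (genes x samples integer matrix), `genes`
#'   (id, chrom), and `truth` (id, is_de, lfc2, dispersion).
#' @export
simulate_counts <- function(cfg, group_labels) {
  validate_sim_config(cfg)
  grp <- as.integer(factor(group_labels)) - 1L
  if (length(unique(grp)) != 2L || min(table(grp)) < 2L)
    stop_nddprs("simulate_counts needs two groups with >= 2 samples each",
                class = "nddprs_invalid_config")
  .sim_seed(cfg, "counts")
  g <- cfg$n_genes; n <- length(grp)
  q <- rlnorm(g, meanlog = log(20), sdlog = 1.2)   # relative abundance
  q <- q / sum(q)
  lib <- 1e6 * rlnorm(n, 0, cfg$libsize_log_sd)
  phi <- cfg$dispersion_shape * 10 / rchisq(g, df = 10)
  lfc2 <- numeric(g)
  de <- integer(0)
  if (cfg$n_de_genes > 0) {
    de <- sample.int(g, cfg$n_de_genes)
    lfc2[de] <- rnorm(cfg$n_de_genes, sd = cfg$lfc_sd)
  }
  mu <- outer(q, lib)                     # genes x samples
  mu <- mu * 2^(outer(lfc2, grp))
  counts <- matrix(rnbinom(g * n, mu = mu, size = 1 / phi), g, n)
  gene_ids <- sprintf("gene%05d", seq_len(g))
  samp_ids <- names(group_labels) %||% sprintf("P%03d", seq_len(n))
  dimnames(counts) <- list(gene_ids, samp_ids)
  chrom <- sample(.nddprs_autosomes, g, replace = TRUE)
  nx <- round(cfg$nonauto_gene_rate * g)
  if (nx > 0) chrom[sample.int(g, nx)] <- "X"
  list(counts = counts,
       genes = data.frame(id = gene_ids, chrom = chrom,
                          stringsAsFactors = FALSE),
       truth = data.frame(id = gene_ids, is_de = seq_len(g) %in% de,
                          lfc2 = lfc2, dispersion = phi,
                          stringsAsFactors = FALSE))
}

#' Simulate gene-set collections for enrichment testing
#'
#' Draws random gene sets from a universe, optionally enriching a fraction
#' of sets in a designated (e.g. truly differentially expressed) gene list.
#'
#' @param cfg A [sim_config()].
#' @param universe Character vector of gene ids.
#' @param de_genes Genes to over-represent in the first `n_enriched` sets.
#' @param n_sets Number of sets.
#' @param set_size Size of each set.
#' @param n_enriched Number of sets biased toward `de_genes`.
#' @return Named list of character vectors (a GMT-style collection).
#' @export
simulate_gene_sets <- function(cfg, universe, de_genes = character(0),
                               n_sets = 20L, set_size = 50L,
                               n_enriched = 3L) {
  .sim_seed(cfg, "genesets")
  set_size <- min(set_size, length(universe))
  sets <- vector("list", n_sets)
  names(sets) <- sprintf("PATHWAY_%02d", seq_len(n_sets))
  de_genes <- intersect(de_genes, universe)
  for (i in seq_len(n_sets)) {
    if (i <= n_enriched && length(de_genes) > 0) {
      n_de <- min(ceiling(set_size / 2), length(de_genes))
      sets[[i]] <- unique(c(sample(de_genes, n_de),
                            sample(universe, set_size - n_de)))
    } else {
      sets[[i]] <- sample(universe, set_size)
    }
  }
  sets
}
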