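#' Default pipeline configuration
#'
#' All QC and statistical parameters of the analysis with their standard
#' values: variant call rate > 0.90, sample genotyping rate >= 0.99,
#' MAF >= 0.01, HWE exact p >= 1e-5, INFO >= 0.8, clumping r2 0.1 within a
#' 200 kb window, PRS p-value thresholds {0.01, 0.03, 0.05, 1.00},
#' relatedness cut 0.2, and nominal DEG alpha 0.05.
#'
#' @param seed Integer seed driving the synthetic cohort.
#' @param ... Overrides for any configuration entry (including a nested
#'   `sim` list passed to [sim_config()]).
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    call_rate = 0.90, sample_rate = 0.99, maf_min = 0.01, hwe_p = 1e-5,
    hwe_samples = "controls",
    rel_thresh = 0.2, info_min = 0.8, r2_thresh = 0.1, window_bp = 200000,
    thresholds = c(0.01, 0.03, 0.05, 1.00),
    bh_family = "per_prs", exact_n_max = 10,
    cpm_min = 1, prior_df = 10, deg_alpha = 0.05, top_pathways = 10,
    sim = list(),
    geno_path = NULL, sumstats_paths = NULL, clinical_path = NULL,
    counts_path = NULL, gene_annot_path = NULL, gmt_path = NULL)
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg))
      stop_nddprs("unknown configuration entry '", nm, "'",
                  class = "nddprs_validation_error")
    cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Any entry of [default_run_config()] may be set; unset entries keep their
#' defaults.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_nddprs("configuration file not found: ", path,
                class = "nddprs_validation_error")
  y <- yaml::read_yaml(path)
  do.call(default_run_config, y)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages of the study workflow on a synthetic cohort
#' generated from `config$seed` (external inputs can be supplied through
#' the path entries of the configuration): genotype simulation and QC,
#' harmonization/clumping/thresholding PRS for two discovery GWAS
#' ("ADHD"-like, tied to the responsiveness copula, and an independent
#' "ASD"-like one), ARS construction, the Spearman/BH association battery
#' with a Table-1-style demographic comparison of the median-split
#' subgroups, negative-binomial differential expression between the
#' subgroups, and over-representation analysis of the DEG list.
#'
#' @param config A `run_config` from [default_run_config()] or
#'   [read_run_config()].
#' @param out_dir Optional output directory; when given, stage outputs are
#'   written as TSV and the manifest as JSON.
#' @return List with elements `geno_qc`, `prs` (one entry per score),
#'   `ars`, `associations`, `demographics`, `split`, `deg`, `enrichment`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  for (pth in c("geno_path", "clinical_path", "counts_path",
                "gene_annot_path", "gmt_path"))
    if (!is.null(config[[pth]]) && !file.exists(config[[pth]]))
      stop_nddprs("configured ", pth, " does not exist: ", config[[pth]],
                  class = "nddprs_validation_error")
  for (pth in config$sumstats_paths)
    if (!file.exists(pth))
      stop_nddprs("configured summary-statistics file does not exist: ",
                  pth, class = "nddprs_validation_error")
  sim_args <- config$sim
  sim_args$seed <- sim_args$seed %||% config$seed
  scfg <- do.call(sim_config, sim_args)

  # --- inputs: synthetic unless external paths are configured
  if (is.null(config$geno_path)) {
    geno <- simulate_genotypes(scfg)
    ss_adhd <- simulate_summary_stats(scfg, geno, stream = 0L)
    ss_asd <- simulate_summary_stats(scfg, geno, stream = 1L)
    clinical <- simulate_clinical(scfg, attr(ss_adhd, "true_score"),
                                  completeness =
                                    rowMeans(!is.na(geno$dosage)))
  } else {
    geno <- read_genotypes(config$geno_path)
    ss_adhd <- read.delim(config$sumstats_paths[[1]],
                          stringsAsFactors = FALSE)
    ss_asd <- if (length(config$sumstats_paths) > 1)
      read.delim(config$sumstats_paths[[2]], stringsAsFactors = FALSE)
      else NULL
    clinical <- read.delim(config$clinical_path, stringsAsFactors = FALSE)
  }
  mi <- match(geno$samples$id, clinical$patient_id)
  geno$samples$diagnosis <- clinical$diagnosis[mi]
  geno$samples$sex <- clinical$sex[mi]
  geno$samples$age <- clinical$age[mi]

  # --- genotype QC
  qc <- run_geno_qc(geno, call_rate = config$call_rate,
                    maf_min = config$maf_min, hwe_p = config$hwe_p,
                    hwe_samples = config$hwe_samples,
                    sample_rate = config$sample_rate,
                    rel_thresh = config$rel_thresh)

  # --- PRS (clumping + thresholding, threshold by Nagelkerke R2)
  prs_of <- function(ss) prs_pipeline(
    ss, qc$geno, thresholds = config$thresholds,
    info_min = config$info_min, r2_thresh = config$r2_thresh,
    window_bp = config$window_bp)
  prs <- list(adhd_prs = prs_of(ss_adhd))
  if (!is.null(ss_asd)) prs$asd_prs <- prs_of(ss_asd)

  # --- clinical: ARS for the documented patients
  ars_tab <- build_ars_table(clinical)
  evaluable <- ars_tab$patient_id[!is.na(ars_tab$ars_pos)]
  patients <- intersect(qc$geno$samples$id, evaluable)

  prs_df <- data.frame(patient_id = qc$geno$samples$id,
                       stringsAsFactors = FALSE)
  for (nm in names(prs)) prs_df[[nm]] <- unname(prs[[nm]]$best_score)
  prs_pat <- prs_df[prs_df$patient_id %in% patients, , drop = FALSE]

  dibs <- data.frame(patient_id = clinical$patient_id,
                     dibs_pos = clinical$dibs_pos_max,
                     dibs_neg = clinical$dibs_neg_max,
                     dibs_gen = clinical$dibs_gen_max,
                     stringsAsFactors = FALSE)
  assoc <- run_association_battery(
    prs_pat, ars_tab[ars_tab$patient_id %in% patients, , drop = FALSE],
    dibs[dibs$patient_id %in% patients, , drop = FALSE],
    family = config$bh_family, exact_n_max = config$exact_n_max)

  # --- median split on the lead PRS + demographic table
  lead <- setNames(prs_pat[["adhd_prs"]], prs_pat$patient_id)
  split <- median_split(lead)
  clin_pat <- clinical[match(names(split), clinical$patient_id), ,
                       drop = FALSE]
  demog <- demographics_table(clin_pat, split)

  # --- expression: counts for the split patients, NB-GLM DGE
  if (is.null(config$counts_path)) {
    sim_counts <- simulate_counts(scfg, split)
    counts <- sim_counts$counts
    gene_chrom <- sim_counts$genes$chrom
  } else {
    counts <- as.matrix(read.delim(config$counts_path, row.names = 1,
                                   check.names = FALSE))
    annot <- read.delim(config$gene_annot_path, stringsAsFactors = FALSE)
    gene_chrom <- annot$chrom[match(rownames(counts), annot$id)]
  }
  deg <- run_dge(counts, gene_chrom, split,
                 sex = clin_pat$sex, age = clin_pat$age,
                 cpm_min = config$cpm_min, prior_df = config$prior_df,
                 deg_alpha = config$deg_alpha)

  # --- enrichment of the nominal DEG list
  universe <- deg$gene
  deg_set <- deg$gene[deg$deg]
  sets <- if (is.null(config$gmt_path)) {
    truth_de <- if (is.null(config$counts_path))
      sim_counts$truth$id[sim_counts$truth$is_de] else character(0)
    simulate_gene_sets(scfg, universe, de_genes = truth_de)
  } else read_gmt(config$gmt_path)
  enrichment <- if (length(deg_set) > 0) {
    r <- run_ora(deg_set, sets, universe)
    rank_pathways(r, n = config$top_pathways)
  } else NULL

  manifest <- list(
    seed = config$seed,
    parameters = config[c("call_rate", "sample_rate", "maf_min", "hwe_p",
                          "info_min", "r2_thresh", "window_bp",
                          "thresholds", "rel_thresh", "deg_alpha")],
    stages = list(
      genotypes_in = ncol(geno$dosage),
      variants_after_qc = ncol(qc$geno$dosage),
      samples_after_qc = nrow(qc$geno$dosage),
      prs_best_threshold = lapply(prs, `[[`, "best_threshold"),
      patients_with_ars = length(patients),
      split = as.list(table(split)),
      genes_tested = nrow(deg),
      degs_nominal = sum(deg$deg),
      degs_fdr = sum(deg$fdr < 0.05, na.rm = TRUE),
      pathways_tested = if (is.null(enrichment)) 0L else length(sets)))

  out <- list(geno_qc = qc, prs = prs, ars = ars_tab,
              associations = assoc, demographics = demog, split = split,
              deg = deg, enrichment = enrichment, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(res$geno_qc$report, file.path(out_dir, "qc_report.tsv"))
  for (nm in names(res$prs)) {
    write_tsv(as.data.frame(res$prs[[nm]]$scores),
              file.path(out_dir, paste0(nm, "_scores.tsv")))
    write_tsv(res$prs[[nm]]$selection,
              file.path(out_dir, paste0(nm, "_thresholds.tsv")))
  }
  write_tsv(res$ars, file.path(out_dir, "ars.tsv"))
  write_tsv(res$associations, file.path(out_dir, "correlations.tsv"))
  write_tsv(res$demographics, file.path(out_dir, "demographics.tsv"))
  write_tsv(res$deg, file.path(out_dir, "deg.tsv"))
  if (!is.null(res$enrichment))
    write_tsv(res$enrichment, file.path(out_dir, "enrichment.tsv"))
  jsonlite::write_json(res$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
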