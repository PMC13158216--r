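#' Construct a genotype matrix object
#'
#' The central genotype container: a samples x variants dosage matrix (each
#' entry in `[0, 2]` or `NA`, counting copies of the `a2` allele) plus
#' per-variant and per-sample metadata.
#'
#' @param dosage Numeric samples x variants matrix with dimnames.
#' @param variants Data frame with columns `id, chrom, pos, a1, a2` and
#'   optionally `info`; one row per dosage column.
#' @param samples Data frame with column `id` (and optionally `diagnosis`,
#'   `sex`, `age`); one row per dosage row.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, variants, samples) {
  stopifnot(is.matrix(dosage), nrow(variants) == ncol(dosage),
            nrow(samples) == nrow(dosage))
  need <- c("id", "chrom", "pos", "a1", "a2")
  if (!all(need %in% names(variants)))
    stop_nddprs("variants must have columns ", paste(need, collapse = ", "),
                class = "nddprs_parse_error")
  if (any(variants$pos <= 0))
    stop_nddprs("variant positions must be positive (1-based)",
                class = "nddprs_parse_error")
  rng <- range(dosage, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop_nddprs("dosages must lie in [0, 2]", class = "nddprs_parse_error")
  if (is.null(variants$info)) variants$info <- NA_real_
  rownames(variants) <- NULL; rownames(samples) <- NULL
  structure(list(dosage = dosage, variants = variants, samples = samples),
            class = "geno_matrix")
}

#' @export
#' @method print geno_matrix
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "variants\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing dosages: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

subset_geno <- function(g, samples = NULL, variants = NULL) {
  if (!is.null(variants)) {
    g$dosage <- g$dosage[, variants, drop = FALSE]
    g$variants <- g$variants[variants, , drop = FALSE]
    rownames(g$variants) <- NULL
  }
  if (!is.null(samples)) {
    g$dosage <- g$dosage[samples, , drop = FALSE]
    g$samples <- g$samples[samples, , drop = FALSE]
    rownames(g$samples) <- NULL
  }
  g
}

#' Mean-impute missing dosages per variant
#'
#' Used only at scoring time; QC statistics are always computed on observed
#' dosages.
#'
#' @param dosage Samples x variants dosage matrix.
#' @return The matrix with each `NA` replaced by its variant's observed mean
#'   (0 if a variant is entirely missing).
#' @export
impute_dosage_mean <- function(dosage) {
  mu <- colMeans(dosage, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(dosage), arr.ind = TRUE)
  if (nrow(idx)) dosage[idx] <- mu[idx[, 2]]
  dosage
}

#' Read genotypes from VCF or a dosage TSV
#'
#' For VCF, the `DS` FORMAT field is preferred when present; otherwise `GT`
#' is converted to an alternate-allele count. Half-calls and missing
#' genotypes map to `NA`. For the dosage TSV format the first six columns
#' are `id, chrom, pos, a1, a2, info` followed by one column per sample.
#'
#' @param path File path.
#' @param format `"vcf"` or `"dosage"`; guessed from the extension when
#'   omitted.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  if (format == "vcf") read_genotypes_vcf(path) else
    read_genotypes_dosage(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  variants <- data.frame(id = fix[, "ID"], chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         a1 = fix[, "REF"], a2 = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  info_str <- vcfR::extract.info(v, element = "INFO")
  variants$info <- suppressWarnings(as.numeric(info_str))
  fmt <- unique(v@gt[, "FORMAT"])
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS")
    dosage <- t(matrix(suppressWarnings(as.numeric(ds)), nrow = nrow(ds),
                       dimnames = dimnames(ds)))
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    dosage <- t(gt_to_dosage(gt))
  }
  if (anyNA(variants$pos))
    stop_nddprs("VCF has unparseable POS fields",
                class = "nddprs_parse_error")
  miss_id <- is.na(variants$id) | variants$id == "."
  variants$id[miss_id] <- paste0(variants$chrom[miss_id], ":",
                                 variants$pos[miss_id])
  colnames(dosage) <- variants$id
  geno_matrix(dosage, variants,
              data.frame(id = rownames(dosage), stringsAsFactors = FALSE))
}

# GT strings ("0/1", "1|1", "./.", "0/.") -> alt-allele count or NA
gt_to_dosage <- function(gt) {
  conv <- function(s) {
    al <- strsplit(s, "[/|]")
    vapply(al, function(a) {
      if (length(a) == 0 || any(a == "." | a == "" | is.na(a)))
        return(NA_real_)
      sum(as.numeric(a) > 0)
    }, numeric(1))
  }
  out <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  gt[is.na(gt)] <- "."
  u <- unique(as.vector(gt))
  map <- setNames(conv(u), u)
  out[] <- map[as.vector(gt)]
  out
}

read_genotypes_dosage <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "chrom", "pos", "a1", "a2", "info")
  if (!all(need %in% names(d)))
    stop_nddprs("dosage TSV must start with columns ",
                paste(need, collapse = ", "), class = "nddprs_parse_error")
  samp <- setdiff(names(d), need)
  if (length(samp) == 0)
    stop_nddprs("dosage TSV has no sample columns",
                class = "nddprs_parse_error")
  dosage <- t(as.matrix(d[, samp, drop = FALSE]))
  colnames(dosage) <- d$id
  geno_matrix(dosage,
              data.frame(id = d$id, chrom = as.character(d$chrom),
                         pos = as.integer(d$pos), a1 = d$a1, a2 = d$a2,
                         info = as.numeric(d$info),
                         stringsAsFactors = FALSE),
              data.frame(id = samp, stringsAsFactors = FALSE))
}

#' Write genotypes to a plain-text VCF (GT + DS)
#'
#' Integer dosages are emitted as hard genotype calls plus a DS field;
#' non-integer dosages get a missing GT with the dosage carried in DS.
#'
#' @param g A [geno_matrix()].
#' @param path Output path (`.vcf`, uncompressed).
#' @export
write_genotypes_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation quality\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of ALT allele\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", g$samples$id),
                     collapse = "\t")), con)
  gt_of <- function(d) {
    out <- rep("./.:.", length(d))
    ok <- !is.na(d)
    hard <- ok & abs(d - round(d)) < 1e-9
    out[hard] <- paste0(c("0/0", "0/1", "1/1")[round(d[hard]) + 1L], ":",
                        format(d[hard], trim = TRUE))
    soft <- ok & !hard
    out[soft] <- paste0("./.:", format(round(d[soft], 4), trim = TRUE))
    out
  }
  v <- g$variants
  for (j in seq_len(ncol(g$dosage))) {
    info <- if (is.na(v$info[j])) "." else
      paste0("INFO=", format(round(v$info[j], 4), trim = TRUE))
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], v$a1[j], v$a2[j],
                       ".", "PASS", info, "GT:DS",
                       gt_of(g$dosage[, j])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write genotypes to a dosage TSV
#'
#' @param g A [geno_matrix()].
#' @param path Output path.
#' @export
write_genotypes_tsv <- function(g, path) {
  d <- cbind(g$variants[, c("id", "chrom", "pos", "a1", "a2", "info")],
             as.data.frame(t(g$dosage)))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a data frame as TSV
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
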