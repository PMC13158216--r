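#' Read a GMT gene-set file
#'
#' Tab-separated: set name, description, then member gene ids.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3)
  if (length(bad))
    stop_nddprs("GMT line ", bad[1], " has fewer than 3 fields",
                class = "nddprs_parse_error")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  sets
}

#' Write a gene-set collection to GMT
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation test for one gene set
#'
#' Upper-tail probability of observing at least the realized overlap when
#' drawing `|deg_set|` genes without replacement from a universe containing
#' `|gene_set|` set members. The enrichment ratio is the observed overlap
#' fraction over its expectation.
#'
#' @param deg_set Character vector of significant genes (intersected with
#'   the universe).
#' @param gene_set Character vector of set members (intersected with the
#'   universe).
#' @param universe Background gene ids (the analyzed genes).
#' @return Data frame `overlap, set_size, deg_size, universe_size, ratio,
#'   p`.
#' @export
ora_test <- function(deg_set, gene_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0)
    stop_nddprs("empty universe", class = "nddprs_validation_error")
  deg_set <- intersect(deg_set, universe)
  gene_set <- intersect(gene_set, universe)
  k <- length(intersect(deg_set, gene_set))
  n_u <- length(universe); n_s <- length(gene_set); n_d <- length(deg_set)
  p <- phyper(k - 1, n_s, n_u - n_s, n_d, lower.tail = FALSE)
  expected <- n_d * n_s / n_u
  data.frame(overlap = k, set_size = n_s, deg_size = n_d,
             universe_size = n_u,
             ratio = if (expected > 0) k / expected else NA_real_,
             p = p)
}

#' Over-representation analysis across a gene-set collection
#'
#' @param deg_set Significant genes.
#' @param sets Named list of gene sets (e.g. from [read_gmt()]); sets empty
#'   after intersection with the universe are skipped.
#' @param universe Background gene ids.
#' @return Data frame with one row per tested set, BH-adjusted p-values.
#' @export
run_ora <- function(deg_set, sets, universe) {
  keep <- vapply(sets, function(s) length(intersect(s, universe)) > 0,
                 logical(1))
  sets <- sets[keep]
  if (length(sets) == 0)
    stop_nddprs("no gene set overlaps the universe",
                class = "nddprs_validation_error")
  res <- do.call(rbind, lapply(names(sets), function(nm)
    cbind(data.frame(set = nm, stringsAsFactors = FALSE),
          ora_test(deg_set, sets[[nm]], universe))))
  res$p_adj <- bh_adjust(res$p)
  res
}

#' Rank enriched pathways
#'
#' Sorted by ascending p, ties broken by descending enrichment ratio.
#'
#' @param results Output of [run_ora()].
#' @param n Number of top rows to return.
#' @return The top `n` rows.
#' @export
rank_pathways <- function(results, n = 10) {
  stopifnot(nrow(results) >= 1)
  ord <- order(results$p, -results$ratio)
  head(results[ord, , drop = FALSE], n)
}
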