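# Independent brute-force oracles used across the suite. Each is written
# from the definition of the statistic, not from the package code paths.

# Exact HWE p by direct enumeration of every heterozygote count compatible
# with the allele counts, probabilities from the closed-form conditional
# distribution (log-factorial form).
oracle_hwe <- function(n_hom_minor, n_het, n_hom_major) {
  n <- n_hom_minor + n_het + n_hom_major
  if (n < 1) return(1)
  nm <- 2 * n_hom_minor + n_het
  if (nm > n) nm <- 2 * n - nm          # orient to rarer allele
  if (nm == 0) return(1)
  hets <- seq(nm %% 2, nm, by = 2)
  lp <- vapply(hets, function(h) {
    a <- (nm - h) / 2; b <- n - a - h
    lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1) +
      h * log(2) + lgamma(nm + 1) + lgamma(2 * n - nm + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  po <- pr[match(n_het, hets)]
  if (is.na(po)) return(1)
  sum(pr[pr <= po * (1 + 1e-12)])
}

# BH adjusted p-values by the literal min-over-tails definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- sort(p)
  q <- numeric(m)
  for (i in seq_len(m))
    q[o[i]] <- min(1, min(ps[i:m] * m / (i:m)))
  q
}

# Greedy clumping by the literal procedure, written independently: walk
# variants in ascending p (ties by chrom then pos); keep each survivor and
# delete its correlated neighbours.
oracle_clump <- function(ids, chrom, pos, p, dosage, r2 = 0.1,
                         window = 200000) {
  remaining <- order(p, chrom, pos)
  kept <- character(0)
  while (length(remaining) > 0) {
    i <- remaining[1]
    kept <- c(kept, ids[i])
    drop <- logical(length(remaining))
    for (k in seq_along(remaining)) {
      j <- remaining[k]
      if (j == i) { drop[k] <- TRUE; next }
      if (chrom[j] == chrom[i] && abs(pos[j] - pos[i]) <= window) {
        r <- suppressWarnings(cor(dosage[, i], dosage[, j],
                                  use = "pairwise.complete.obs"))
        if (!is.na(r) && r^2 > r2) drop[k] <- TRUE
      }
    }
    remaining <- remaining[!drop]
  }
  kept
}

# All permutations of 1..n (n small).
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in oracle_perms(n - 1L))
    for (k in 0:(n - 1L))
      out[[length(out) + 1L]] <- append(sub, n, after = k)
  out
}

# Exact r x c test by enumerating the free cells with expand.grid
# (independent of the package's recursive filler).
oracle_rxc <- function(tab) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(1)
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  lconst <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(N + 1)
  lp <- function(m) lconst - sum(lgamma(m + 1))
  free <- expand.grid(rep(list(0:max(rs)), (nrow(tab) - 1) *
                            (ncol(tab) - 1)))
  lp_obs <- lp(tab)
  total <- 0
  for (r in seq_len(nrow(free))) {
    m <- matrix(0, nrow(tab), ncol(tab))
    m[seq_len(nrow(tab) - 1), seq_len(ncol(tab) - 1)] <-
      as.numeric(free[r, ])
    m[nrow(tab), seq_len(ncol(tab) - 1)] <-
      cs[seq_len(ncol(tab) - 1)] - colSums(m[, seq_len(ncol(tab) - 1),
                                             drop = FALSE])[
        seq_len(ncol(tab) - 1)]
    m[, ncol(tab)] <- rs - rowSums(m)
    if (any(m < 0)) next
    l <- lp(m)
    if (l <= lp_obs + 1e-12) total <- total + exp(l)
  }
  min(1, total)
}

# small genotype fixture: deterministic dosage panel for QC/PRS tests
make_toy_geno <- function(n = 20, m = 10, seed = 1, maf = 0.3,
                          chrom = rep("1", m), pos = seq_len(m) * 1000) {
  set.seed(seed)
  dos <- matrix(rbinom(n * m, 2, maf), n, m,
                dimnames = list(sprintf("S%02d", 1:n),
                                sprintf("v%02d", 1:m)))
  geno_matrix(dos,
              data.frame(id = colnames(dos), chrom = chrom, pos = pos,
                         a1 = rep("A", m), a2 = rep("G", m),
                         info = rep(0.99, m), stringsAsFactors = FALSE),
              data.frame(id = rownames(dos), stringsAsFactors = FALSE))
}
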