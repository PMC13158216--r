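toy_design <- function(grp) model.matrix(~grp)

test_that("gene filter removes non-autosomal and unexpressed genes", {
  set.seed(60)
  counts <- matrix(rpois(40 * 10, 50), 40, 10,
                   dimnames = list(sprintf("g%02d", 1:40), NULL))
  chrom <- rep("2", 40); chrom[5] <- "X"; chrom[6] <- "Y"
  counts[7, ] <- 0                          # all-zero gene
  grp <- factor(rep(c("a", "b"), each = 5))
  flt <- dge_filter_genes(counts, chrom, grp)
  expect_false(any(c("g05", "g06", "g07") %in% rownames(flt$counts)))
  expect_true("g01" %in% rownames(flt$counts))
  expect_equal(unname(flt$report["non_autosomal"]), 2)
})

test_that("TMM factors are 1 for identical and depth-scaled columns", {
  set.seed(61)
  base <- rpois(500, 60)
  counts <- cbind(s1 = base, s2 = base, s3 = base)
  expect_equal(unname(tmm_factors(counts)), rep(1, 3))
  counts2 <- cbind(s1 = base, s2 = 2 * base)   # pure depth change
  f <- tmm_factors(counts2)
  expect_equal(unname(f[1] / f[2]), 1, tolerance = 1e-6)
})

test_that("TMM compensates an asymmetric composition shift", {
  set.seed(62)
  mu <- rlnorm(1000, log(50), 1)
  a <- rpois(1000, mu)
  b <- rpois(1000, mu)
  up <- sample(1000, 200)
  b[up] <- rpois(200, mu[up] * 6)           # 20% strongly up in b
  counts <- cbind(a = a, b = b)
  f <- tmm_factors(counts)
  # b's non-DE genes are diluted; its factor must drop below a's
  expect_lt(f["b"] / f["a"], 0.95)
})

test_that("TMM agrees with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(63)
  counts <- matrix(rnbinom(2000 * 8, mu = rlnorm(2000, 4, 1), size = 5),
                   2000, 8)
  counts <- counts[rowSums(counts) > 0, ]
  ours <- tmm_factors(counts)
  ref <- edgeR::calcNormFactors(counts, method = "TMM")
  expect_equal(unname(ours), unname(ref), tolerance = 0.02)
})

test_that("NB GLM with phi = 0 matches the Poisson GLM", {
  set.seed(64)
  grp <- factor(rep(c("low", "high"), c(10, 9)), levels = c("low", "high"))
  y <- rpois(19, exp(3 + 0.5 * (grp == "high")))
  X <- toy_design(grp)
  off <- rep(0, 19)
  fit <- nb_glm_fit(y, X, off, phi = 0)
  ref <- glm(y ~ grp, family = poisson())
  expect_lt(max(abs(fit$beta - coef(ref))), 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
})

test_that("intercept-only fit recovers the closed form", {
  y <- rep(7, 12)
  X <- matrix(1, 12, 1)
  off <- rep(log(2), 12)
  fit <- nb_glm_fit(y, X, off, phi = 0.1)
  expect_equal(unname(fit$beta), log(7) - log(2), tolerance = 1e-7)
})

test_that("group coefficient recovers a planted fold change", {
  set.seed(65)
  grp <- factor(rep(c("low", "high"), each = 30),
                levels = c("low", "high"))
  mu <- ifelse(grp == "high", 4000, 2000)   # LFC = 1 (log2), deep counts
  y <- rnbinom(60, mu = mu, size = 1 / 0.005)
  fit <- nb_glm_fit(y, toy_design(grp), rep(0, 60), phi = 0.005)
  expect_equal(unname(fit$beta[2]) / log(2), 1, tolerance = 0.1)
  # independent IRLS cross-check at the same fixed dispersion
  ref <- glm(y ~ grp, family = MASS::negative.binomial(theta = 1 / 0.005))
  expect_lt(max(abs(fit$beta - coef(ref))), 1e-6)
})

test_that("dispersion estimation recovers truth and shrinks", {
  set.seed(66)
  grp <- factor(rep(c("low", "high"), c(10, 9)), levels = c("low", "high"))
  X <- toy_design(grp)
  mu <- rlnorm(600, log(200), 1)
  counts <- matrix(rnbinom(600 * 19, mu = rep(mu, 19), size = 1 / 0.4),
                   600, 19)
  keep <- rowSums(counts) > 0
  off <- log(colSums(counts))
  d <- estimate_dispersions(counts[keep, ], X, off)
  expect_gt(d$common, 0.3); expect_lt(d$common, 0.5)
  # Poisson data give near-zero common dispersion
  cp <- matrix(rpois(600 * 19, rep(mu, 19)), 600, 19)
  dp <- estimate_dispersions(cp[rowSums(cp) > 0, ], X, log(colSums(cp)))
  expect_lte(dp$common, 0.05)
  # a single gene is fully shrunk to the common value
  one <- counts[1, , drop = FALSE]
  d1 <- estimate_dispersions(one, X, off)
  expect_equal(d1$genewise, d1$common, tolerance = 1e-9)
})

test_that("LRT behaves on null and dominant-signal genes", {
  set.seed(67)
  grp <- factor(rep(c("low", "high"), c(10, 9)), levels = c("low", "high"))
  X <- toy_design(grp); X0 <- X[, 1, drop = FALSE]
  off <- rep(0, 19)
  y_null <- rep(50, 19)                     # identical means
  f1 <- nb_glm_fit(y_null, X, off, 0.1)
  f0 <- nb_glm_fit(y_null, X0, off, 0.1)
  lt <- lrt_test(f1, f0)
  expect_lt(lt$lrt, 1e-6); expect_gt(lt$p, 0.999)

  cfg <- sim_config(seed = 68, n_genes = 150, n_de_genes = 0, lfc_sd = 0,
                    nonauto_gene_rate = 0)
  sc <- simulate_counts(cfg, grp)
  counts <- sc$counts
  counts[1, ] <- rnbinom(19, mu = ifelse(grp == "high", 80000, 10000),
                         size = 100)        # planted LFC = 3, deep counts
  deg <- run_dge(counts, sc$genes$chrom, grp)
  expect_equal(deg$gene[1], rownames(counts)[1])
  expect_equal(deg$logFC[deg$gene == rownames(counts)[1]], 3,
               tolerance = 0.25)
})

test_that("swapping group labels negates LFCs and keeps p-values", {
  grp <- factor(rep(c("low", "high"), c(10, 9)), levels = c("low", "high"))
  cfg <- sim_config(seed = 69, n_genes = 80, n_de_genes = 10,
                    nonauto_gene_rate = 0)
  sc <- simulate_counts(cfg, grp)
  d1 <- run_dge(sc$counts, sc$genes$chrom, grp)
  grp_sw <- factor(ifelse(grp == "high", "low", "high"),
                   levels = c("low", "high"))
  d2 <- run_dge(sc$counts, sc$genes$chrom, grp_sw)
  m <- match(d1$gene, d2$gene)
  expect_equal(d1$logFC, -d2$logFC[m], tolerance = 1e-6)
  expect_equal(d1$p, d2$p[m], tolerance = 1e-8)
})

test_that("covariates enter as factors and aliased columns are dropped", {
  grp <- factor(rep(c("low", "high"), c(10, 9)), levels = c("low", "high"))
  cfg <- sim_config(seed = 70, n_genes = 60, n_de_genes = 0,
                    nonauto_gene_rate = 0)
  sc <- simulate_counts(cfg, grp)
  sex <- rep(c("M", "F"), length.out = 19)
  age <- c(rep(45, 10), rep(72, 9))         # age decade aliases group
  expect_warning(
    deg <- run_dge(sc$counts, sc$genes$chrom, grp, sex = sex, age = age),
    "aliased")
  expect_true(all(is.finite(deg$p)))
})

test_that("volcano table mirrors the DEG table", {
  grp <- factor(rep(c("low", "high"), c(5, 5)), levels = c("low", "high"))
  cfg <- sim_config(seed = 71, n_genes = 40, n_de_genes = 5,
                    nonauto_gene_rate = 0)
  sc <- simulate_counts(cfg, grp)
  deg <- run_dge(sc$counts, sc$genes$chrom, grp)
  v <- volcano_table(deg)
  expect_equal(nrow(v), nrow(deg))
  expect_equal(v$neg_log10_p, -log10(deg$p))
  expect_equal(v$deg, deg$p < 0.05)
  empty <- volcano_table(deg[0, ])
  expect_equal(nrow(empty), 0)
})
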