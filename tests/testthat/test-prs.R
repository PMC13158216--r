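make_stats <- function(g, beta = NULL, p = NULL, info = NULL,
                       a1 = g$variants$a2, a2 = g$variants$a1) {
  m <- nrow(g$variants)
  data.frame(SNP = g$variants$id, CHR = g$variants$chrom,
             BP = g$variants$pos, A1 = a1, A2 = a2,
             BETA = beta %||% rep(0.1, m),
             P = p %||% rep(0.5, m),
             INFO = info %||% rep(0.99, m), stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("harmonization aligns alleles, flips signs, drops low INFO", {
  g <- make_toy_geno(n = 10, m = 4)        # target a1 = A, a2 = G
  st <- make_stats(g, beta = c(0.2, 0.2, 0.2, 0.2))
  st$A1 <- c("G", "A", "C", "G")           # direct, swapped, complement,
  st$A2 <- c("A", "G", "T", "A")           # .. and low-INFO direct
  st$INFO[4] <- 0.79
  h <- harmonize_sumstats(st, g)
  expect_equal(h$id, c("v01", "v02", "v03"))
  expect_equal(h$beta, c(0.2, -0.2, 0.2))
  expect_equal(h$match, c("direct", "swapped", "complement"))
  rep <- attr(h, "report")
  expect_equal(unname(rep["info_removed"]), 1)
})

test_that("ambiguous summary-stat alleles cannot complement-match", {
  g <- make_toy_geno(n = 10, m = 2)
  st <- make_stats(g)
  st$A1 <- c("T", "G"); st$A2 <- c("A", "A")  # A/T ambiguous; direct G/A
  h <- harmonize_sumstats(st, g)
  expect_equal(h$id, "v02")
  expect_equal(unname(attr(h, "report")["allele_mismatch"]), 1)
})

test_that("zero overlap raises an error", {
  g <- make_toy_geno(n = 10, m = 2)
  st <- make_stats(g)
  st$BP <- st$BP + 7
  expect_error(harmonize_sumstats(st, g), class = "nddprs_empty_overlap")
})

test_that("clumping keeps the stronger of two correlated variants", {
  g <- make_toy_geno(n = 50, m = 2, pos = c(10000, 20000))
  g$dosage[, 2] <- g$dosage[, 1]                 # r2 = 1
  st <- make_stats(g, p = c(1e-4, 1e-8))
  h <- harmonize_sumstats(st, g)
  kept <- clump_variants(h, g)
  expect_equal(kept, "v02")
  # outside the window both survive
  g2 <- make_toy_geno(n = 50, m = 2, pos = c(10000, 300000))
  g2$dosage[, 2] <- g2$dosage[, 1]
  h2 <- harmonize_sumstats(make_stats(g2, p = c(1e-4, 1e-8)), g2)
  expect_setequal(clump_variants(h2, g2), c("v01", "v02"))
  # single variant is always retained
  g3 <- make_toy_geno(n = 20, m = 1)
  h3 <- harmonize_sumstats(make_stats(g3), g3)
  expect_equal(clump_variants(h3, g3), "v01")
})

test_that("clumping equals the brute-force greedy oracle on random panels", {
  for (s in 1:15) {
    cfg <- sim_config(seed = 600 + s, n_cases = 30, n_controls = 30,
                      n_variants = 20, n_blocks = 2, n_causal = 5,
                      within_block_r = 0.7,
                      missing_rate = 0, ambiguous_rate = 0,
                      nonauto_rate = 0)
    g <- simulate_genotypes(cfg)
    st <- simulate_summary_stats(cfg, g)
    h <- harmonize_sumstats(st, g, info_min = 0)
    expect_equal(sort(clump_variants(h, g)),
                 sort(oracle_clump(h$id, h$chrom, h$pos, h$p,
                                   g$dosage[, h$id])))
  }
})

test_that("scores match direct arithmetic and the dot-product oracle", {
  g <- make_toy_geno(n = 3, m = 1)
  g$dosage[, 1] <- c(0, 1, 2)
  st <- make_stats(g, beta = 0.1, p = 0.001)
  h <- harmonize_sumstats(st, g)
  sc <- prs_score(h, g, "v01", 0.05)
  expect_equal(sc$score, c(0, 0.05, 0.1))
  expect_equal(sc$raw_score, c(0, 0.1, 0.2))

  # 5-variant panel vs independent dot product
  g5 <- make_toy_geno(n = 12, m = 5)
  beta <- c(0.3, -0.2, 0.05, 0.4, -0.1)
  st5 <- make_stats(g5, beta = beta, p = rep(0.001, 5))
  h5 <- harmonize_sumstats(st5, g5)
  sc5 <- prs_score(h5, g5, h5$id, 0.05)
  expect_equal(sc5$raw_score, as.numeric(g5$dosage %*% beta))
  expect_equal(sc5$score, as.numeric(g5$dosage %*% beta) / (2 * 5))

  # all-null effects give all-zero scores
  st0 <- make_stats(g5, beta = rep(0, 5), p = rep(0.001, 5))
  h0 <- harmonize_sumstats(st0, g5)
  expect_equal(prs_score(h0, g5, h0$id, 0.05)$score, rep(0, 12))
})

test_that("missing dosages are mean-imputed with non-missing denominator", {
  g <- make_toy_geno(n = 4, m = 2)
  g$dosage[, 1] <- c(0, 2, NA, 2); g$dosage[, 2] <- c(1, 1, 1, 1)
  st <- make_stats(g, beta = c(0.5, 0.5), p = c(0.001, 0.001))
  h <- harmonize_sumstats(st, g)
  sc <- prs_score(h, g, h$id, 0.05)
  imputed <- mean(c(0, 2, 2))
  expect_equal(sc$raw_score[3], 0.5 * imputed + 0.5 * 1)
  expect_equal(sc$n_nonmissing, c(2, 2, 1, 2))
  expect_equal(sc$score[3], (0.5 * imputed + 0.5 * 1) / (2 * 1))
})

test_that("no variant under threshold flags the score undefined", {
  g <- make_toy_geno(n = 5, m = 2)
  st <- make_stats(g, p = c(0.5, 0.9))
  h <- harmonize_sumstats(st, g)
  sc <- prs_score(h, g, h$id, 0.01)
  expect_false(attr(sc, "defined"))
  expect_true(all(is.na(sc$score)))
})

test_that("variant inclusion is monotone in the threshold", {
  cfg <- sim_config(seed = 21, n_variants = 400, n_blocks = 40)
  g <- simulate_genotypes(cfg)
  st <- simulate_summary_stats(cfg, g)
  cl <- simulate_clinical(cfg, attr(st, "true_score"))
  pr <- prs_pipeline(st, g, diagnosis = cl$diagnosis)
  expect_true(all(diff(pr$n_variants) >= 0))
  expect_true(pr$best_threshold %in% c(0.01, 0.03, 0.05, 1))
})

test_that("flipping target allele order preserves score contrasts", {
  # flipping every allele pair negates harmonized betas and reflects
  # dosages, so scores shift by a sample-independent constant; centered
  # scores must be identical on complete data
  cfg <- sim_config(seed = 22, n_variants = 100, n_blocks = 10,
                    n_causal = 30, ambiguous_rate = 0, missing_rate = 0)
  g <- simulate_genotypes(cfg)
  st <- simulate_summary_stats(cfg, g)
  h1 <- harmonize_sumstats(st, g)
  s1 <- prs_score(h1, g, h1$id, 1)

  gf <- g                                   # swap a1/a2, dosage -> 2 - d
  gf$variants$a1 <- g$variants$a2
  gf$variants$a2 <- g$variants$a1
  gf$dosage <- 2 - g$dosage
  h2 <- harmonize_sumstats(st, gf)
  s2 <- prs_score(h2, gf, h2$id, 1)
  expect_equal(h2$beta, -h1$beta)
  expect_equal(s1$score - mean(s1$score), s2$score - mean(s2$score),
               tolerance = 1e-12)
})

test_that("Nagelkerke R2 behaves at its reference points", {
  set.seed(30)
  score <- rnorm(200)
  y <- rbinom(200, 1, 0.5)                  # independent
  nk <- nagelkerke_r2(score, y)
  expect_lt(nk$r2, 0.05)
  expect_true(nk$converged)
  # perfect separation is flagged
  y2 <- as.integer(score > 0)
  nk2 <- nagelkerke_r2(score, y2)
  expect_false(nk2$converged)
  expect_gt(nk2$r2, 0.9)
  # identical likelihoods give exactly zero
  nk0 <- nagelkerke_r2(rep(c(0, 0), 100), y)
  expect_equal(nk0$r2, 0)
})

test_that("threshold selection maximizes R2 among converged fits", {
  set.seed(31)
  y <- rbinom(120, 1, 0.5)
  good <- y + rnorm(120, sd = 0.8)
  noise1 <- rnorm(120); noise2 <- rnorm(120)
  scores <- cbind(`0.01` = noise1, `0.03` = good, `1` = noise2)
  sel <- select_threshold(scores, y)
  expect_equal(attr(sel, "best_threshold"), 0.03)
  expect_error(select_threshold(scores[, 1, drop = FALSE], rep(1, 120)),
               class = "nddprs_invalid_config")
})

test_that("heritable simulation yields detectable variance explained", {
  cfg <- sim_config(seed = 23)
  g <- simulate_genotypes(cfg)
  st <- simulate_summary_stats(cfg, g)
  cl <- simulate_clinical(cfg, attr(st, "true_score"))
  g$samples$diagnosis <- cl$diagnosis
  qc <- run_geno_qc(g)
  pr <- prs_pipeline(st, qc$geno)
  r2_dense <- pr$selection$r2_nagelkerke[pr$selection$threshold == 1]
  # null 95th percentile for Nagelkerke R2 at n = 70 is ~0.08
  expect_gt(r2_dense, 0.08)
})
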