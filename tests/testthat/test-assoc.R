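test_that("spearman is invariant under monotone transforms", {
  set.seed(40)
  x <- rnorm(15); y <- rnorm(15)
  s0 <- spearman_test(x, y)
  expect_equal(spearman_test(exp(x), y)$rho, s0$rho)
  expect_equal(spearman_test(x, 2 * y + 1)$p, s0$p)
  expect_equal(spearman_test(x, 2 * x + 1)$rho, 1)
  expect_equal(spearman_test(1:8, 8:1)$rho, -1)
})

test_that("exact spearman p equals full permutation enumeration", {
  x <- c(1, 2, 3, 4, 5, 6, 7)
  y <- c(2, 1, 4, 3, 7, 7, 5)              # one tie
  st <- spearman_test(x, y)
  expect_equal(st$method, "exact_permutation")
  rx <- rank(x); ry <- rank(y)
  robs <- cor(rx, ry)
  rs <- vapply(oracle_perms(7), function(pp) cor(rx, ry[pp]), numeric(1))
  expect_equal(st$p, mean(abs(rs) >= abs(robs) - 1e-9))
  expect_equal(st$rho, robs)
})

test_that("degenerate spearman inputs are flagged undefined", {
  expect_equal(spearman_test(rep(1, 6), 1:6)$method, "undefined")
  expect_equal(spearman_test(1:2, 2:1)$method, "undefined")
})

test_that("BH adjustment equals the step-up oracle", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(0.05, 6)), rep(0.05, 6))
  set.seed(41)
  for (i in 1:200) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "nddprs_validation_error")
})

test_that("welch t from summaries equals welch t from raw vectors", {
  set.seed(42)
  x <- rnorm(9, 70, 8); y <- rnorm(10, 64, 11)
  a <- welch_t(x, y)
  b <- welch_t(n1 = 9, mean1 = mean(x), sd1 = sd(x),
               n2 = 10, mean2 = mean(y), sd2 = sd(y))
  expect_equal(a$t, b$t); expect_equal(a$p, b$p); expect_equal(a$df, b$df)
  ref <- t.test(x, y)
  expect_equal(a$p, ref$p.value)
  expect_equal(unname(a$t), unname(ref$statistic))
  # identical groups
  eq <- welch_t(c(1, 2, 3), c(3, 2, 1))
  expect_equal(eq$t, 0); expect_equal(eq$p, 1)
  # both variances zero
  dg <- welch_t(c(2, 2), c(2, 2))
  expect_equal(dg$p, 1); expect_equal(dg$flag, "degenerate")
})

test_that("exact r x c test matches Fisher and the enumeration oracle", {
  expect_equal(exact_rxc(matrix(c(6, 3, 7, 3), 2, byrow = TRUE)), 1)
  expect_equal(exact_rxc(matrix(c(5, 0, 0, 5), 2)), 2 / choose(10, 5))
  expect_equal(exact_rxc(matrix(c(3, 0, 5, 0), 2)), 1)  # zero margin
  set.seed(43)
  for (i in 1:60) {
    t2 <- matrix(rpois(4, 4), 2)
    if (any(rowSums(t2) == 0) || any(colSums(t2) == 0)) next
    expect_equal(exact_rxc(t2), fisher.test(t2)$p.value, tolerance = 1e-9)
  }
  for (i in 1:20) {
    t23 <- matrix(rpois(6, 2), 2, 3)
    if (any(rowSums(t23) == 0) || any(colSums(t23) == 0)) next
    expect_equal(exact_rxc(t23), oracle_rxc(t23), tolerance = 1e-9)
  }
  expect_error(exact_rxc(matrix(c(1.5, 1, 1, 1), 2)),
               class = "nddprs_validation_error")
  expect_error(exact_rxc(matrix(20, 8, 8, byrow = TRUE),
                         max_tables = 100),
               class = "nddprs_enumeration_cap")
})

test_that("median split assigns ties and the median patient to low", {
  s19 <- setNames(sample(seq(0.01, 0.19, 0.01)), sprintf("p%d", 1:19))
  sp <- median_split(s19)
  expect_equal(unname(table(sp)["high"]), 9L)
  expect_equal(unname(table(sp)["low"]), 10L)
  sp4 <- median_split(c(a = 1, b = 2, c = 3, d = 4))
  expect_equal(as.character(sp4), c("low", "low", "high", "high"))
  tied <- median_split(c(a = 1, b = 2, c = 2, d = 2, e = 3))
  expect_equal(as.character(tied), c("low", "low", "low", "low", "high"))
  expect_warning(median_split(c(a = 1, b = 1)), "identical")
})

test_that("association battery recovers a planted negative correlation", {
  signs <- numeric(60)
  for (i in seq_along(signs)) {
    cfg <- sim_config(seed = 7000 + i, prs_ars_rho = -0.5)
    ts <- setNames(rnorm(72), sprintf("S%03d", 1:72))
    cl <- simulate_clinical(cfg, ts)
    doc <- !is.na(cl$cpeq_3mo)
    prs <- data.frame(patient_id = cl$patient_id[doc],
                      adhd_prs = ts[cl$patient_id[doc]])
    dibs <- data.frame(patient_id = cl$patient_id[doc],
                       dibs_pos = cl$dibs_pos_max[doc],
                       dibs_neg = cl$dibs_neg_max[doc],
                       dibs_gen = cl$dibs_gen_max[doc])
    at <- build_ars_table(cl[doc, ])
    res <- run_association_battery(prs, at, dibs)
    signs[i] <- res$rho[res$variable == "ars_pos"]
  }
  expect_gt(mean(signs < 0), 0.9)
})

test_that("battery applies BH within the configured family", {
  cfg <- sim_config(seed = 50)
  ts <- setNames(rnorm(72), sprintf("S%03d", 1:72))
  cl <- simulate_clinical(cfg, ts)
  doc <- !is.na(cl$cpeq_3mo)
  prs <- data.frame(patient_id = cl$patient_id[doc],
                    adhd_prs = ts[cl$patient_id[doc]],
                    asd_prs = rnorm(sum(doc)))
  dibs <- data.frame(patient_id = cl$patient_id[doc],
                     dibs_pos = cl$dibs_pos_max[doc],
                     dibs_neg = cl$dibs_neg_max[doc],
                     dibs_gen = cl$dibs_gen_max[doc])
  at <- build_ars_table(cl[doc, ])
  per <- run_association_battery(prs, at, dibs, family = "per_prs")
  glob <- run_association_battery(prs, at, dibs, family = "global")
  expect_equal(nrow(per), 12)
  for (f in c("adhd_prs", "asd_prs")) {
    idx <- per$family == f
    expect_equal(per$p_adj[idx], bh_adjust(per$p[idx]))
  }
  expect_equal(glob$p_adj, bh_adjust(glob$p))
  expect_true(all(per$p_adj >= per$p - 1e-12))
  # mismatched patient ids fail fast
  bad <- prs; bad$patient_id <- paste0("zz", bad$patient_id)
  expect_error(run_association_battery(bad, at, dibs),
               class = "nddprs_join_error")
})

test_that("demographics table uses the right test per variable type", {
  set.seed(51)
  clin <- data.frame(sex = sample(c("M", "F"), 19, TRUE),
                     age = rnorm(19, 67, 9), doi = rnorm(19, 40, 8),
                     cpeq_3mo = rlnorm(19, 6, 0.7))
  grp <- factor(rep(c("low", "high"), c(10, 9)))
  dt <- demographics_table(clin, grp)
  expect_setequal(dt$variable, c("sex", "age", "doi", "cpeq_3mo"))
  expect_equal(dt$test[dt$variable == "sex"], "freeman_halton")
  w <- welch_t(clin$age[grp == "low"], clin$age[grp == "high"])
  expect_equal(dt$p[dt$variable == "age"], w$p)
})
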