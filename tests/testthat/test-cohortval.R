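test_that("signature scores are mean z-scores over the listed genes", {
  set.seed(1)
  m <- matrix(abs(rnorm(15, 6, 2)), 3, 5,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:5)))
  x <- expr_matrix(m, "log2p1")
  sc <- signature_score(x, c("g1", "g2", "g3"))
  z <- t(scale(t(m)))
  expect_equal(sc, colMeans(z), tolerance = 1e-12)
  # single gene: score is a monotone transform of its expression
  s1 <- signature_score(x, "g2")
  expect_equal(cor(s1, m[2, ], method = "spearman"), 1)
  expect_error(signature_score(x, "absent"), "present")
})

test_that("AUC equals exhaustive Mann-Whitney pair counting", {
  score <- c(5, 4, 2.5, 3, 2.5)
  lab <- c("case", "case", "case", "ctrl", "ctrl")
  r <- roc_auc(score, lab, positive_class = "case")
  expect_equal(r$auc, oracle_auc(score, as.integer(lab == "case")))
  # perfectly separated
  expect_equal(roc_auc(c(3, 2, 1, 0), c("case", "case", "ctrl", "ctrl"),
                       "case")$auc, 1)
  # all tied
  expect_equal(roc_auc(rep(1, 6), rep(c("case", "ctrl"), 3), "case")$auc, 0.5)
  expect_error(roc_auc(1:3, rep("case", 3), "case"), "classes")
})

test_that("the ROC curve steps from (0,0) to (1,1) and matches pROC's AUC", {
  set.seed(2)
  score <- rnorm(30)
  lab <- rep(c("case", "ctrl"), 15)
  score[lab == "case"] <- score[lab == "case"] + 1
  r <- roc_auc(score, lab, "case")
  expect_equal(r$curve$sensitivity[1], 0)
  expect_equal(r$curve$specificity[1], 1)
  expect_equal(tail(r$curve$sensitivity, 1), 1)
  expect_equal(tail(r$curve$specificity, 1), 0)
  ref <- pROC::roc(response = lab, predictor = score, levels = c("ctrl", "case"),
                   direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  # complement symmetry for tie-free scores
  expect_equal(roc_auc(-score, lab, "case")$auc, 1 - r$auc, tolerance = 1e-12)
})

test_that("Hedges' g matches its closed form and is antisymmetric", {
  # construct groups with exact mean 1 vs 0 and sd exactly 1
  case <- as.numeric(scale(rnorm(10))) + 1
  ctrl <- as.numeric(scale(rnorm(10)))
  e <- hedges_g(case, ctrl)
  expect_equal(e$g, 1 - 3 / 71, tolerance = 1e-12)   # J * d with d = 1
  expect_equal(e$g, 0.9577, tolerance = 1e-4)
  expect_equal(e$var_g, 20 / 100 + e$g^2 / 40, tolerance = 1e-12)
  swapped <- hedges_g(ctrl, case)
  expect_equal(swapped$g, -e$g)
  expect_equal(swapped$var_g, e$var_g)
  expect_equal(hedges_g(c(1, 2, 3), c(2, 1, 3))$g, 0)
  expect_error(hedges_g(rep(1, 5), rep(1, 5)), "zero pooled variance")
})

test_that("DerSimonian-Laird pooling matches hand-evaluated closed forms", {
  # single study
  m1 <- pool_random_effects(data.frame(g = 0.8, var_g = 0.04))
  expect_equal(m1$pooled_g, 0.8)
  expect_equal(m1$tau2, 0)
  expect_equal(m1$ci_low, 0.8 - qnorm(0.975) * 0.2, tolerance = 1e-12)
  # three identical studies: no heterogeneity
  m3 <- pool_random_effects(data.frame(g = rep(0.6, 3), var_g = rep(0.09, 3)))
  expect_equal(m3$pooled_g, 0.6)
  expect_equal(m3$Q, 0)
  expect_equal(m3$I2, 0)
  # two discordant studies, hand-evaluated:
  # w = 25 each, gbar = 1, Q = 25*0.25*2 = 12.5,
  # tau2 = (12.5 - 1)/(50 - 1250/50) = 0.46, w* = 1/0.5 = 2 each, pooled = 1
  m2 <- pool_random_effects(data.frame(g = c(0.5, 1.5), var_g = c(0.04, 0.04)))
  expect_equal(m2$Q, 12.5, tolerance = 1e-12)
  expect_equal(m2$tau2, 0.46, tolerance = 1e-12)
  expect_equal(m2$pooled_g, 1, tolerance = 1e-12)
  expect_equal(m2$I2, 100 * (12.5 - 1) / 12.5, tolerance = 1e-12)
  expect_error(pool_random_effects(list()), "no effects")
})

test_that("pooling agrees with metafor's DerSimonian-Laird estimator", {
  set.seed(3)
  g <- rnorm(5, 0.8, 0.3)
  v <- runif(5, 0.02, 0.2)
  mine <- pool_random_effects(data.frame(g = g, var_g = v))
  ref <- metafor::rma(yi = g, vi = v, method = "DL")
  expect_equal(mine$pooled_g, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(mine$tau2, ref$tau2, tolerance = 1e-10)
  expect_equal(mine$Q, ref$QE, tolerance = 1e-10)
  expect_equal(mine$I2, ref$I2, tolerance = 1e-6)
  # the pooled estimate is a convex combination of the study effects
  expect_true(mine$pooled_g >= min(g) && mine$pooled_g <= max(g))
})

test_that("between-study variance vanishes as effects converge", {
  tau2s <- vapply(c(1, 0.3, 0.1, 0.01), function(spread) {
    g <- 0.8 + c(-1, 0, 1) * spread
    pool_random_effects(data.frame(g = g, var_g = rep(0.05, 3)))$tau2
  }, 0)
  expect_true(all(diff(tau2s) <= 0))
  expect_equal(tau2s[4], 0, tolerance = 1e-3)
})

test_that("pooled CIs cover a common planted effect across seeded replicates", {
  g_true <- 0.8
  n <- 20
  covered <- vapply(1:50, function(rep) {
    set.seed(rep)
    eff <- lapply(1:3, function(i) {
      hedges_g(rnorm(n, g_true, 1), rnorm(n, 0, 1))
    })
    m <- pool_random_effects(eff)
    m$ci_low <= g_true && g_true <= m$ci_high
  }, TRUE)
  expect_gte(mean(covered), 0.9)
})

test_that("per-gene meta-analysis across synthetic cohorts recovers the planted shift", {
  cohorts <- lapply(1:3, function(i) {
    co <- make_bulk_cohort(bulk_cohort_spec(
      50, 20, 20, de_genes = 1L, de_lfc = 1, noise_sd = 0.5, seed = 10 + i))
    list(expr = to_log2p1(co$expr), labels = co$labels)
  })
  out <- meta_analyze_gene(cohorts, "g0001")
  expect_equal(nrow(out$per_cohort), 3)
  # planted log2 shift 1 at noise 0.5 is a standardized effect near 2
  expect_gt(out$pooled$pooled_g, 1)
  expect_true(out$pooled$ci_low <= out$pooled$pooled_g &&
                out$pooled$pooled_g <= out$pooled$ci_high)
})

test_that("marker correlations are Spearman with t-approximation p-values", {
  set.seed(4)
  tv <- abs(rnorm(6, 5, 2))
  m <- rbind(target = tv, pos = tv * 2 + 1, neg = max(tv) - tv,
             other = abs(rnorm(6, 5, 2)))
  colnames(m) <- paste0("s", 1:6)
  x <- expr_matrix(m, "log2p1")
  res <- marker_correlation(x, "target", c("pos", "neg", "other"))
  expect_equal(res$rho[res$marker == "pos"], 1)
  expect_equal(res$rho[res$marker == "neg"], -1)
  expect_equal(res$rho[res$marker == "other"],
               oracle_spearman(tv, m["other", ]), tolerance = 1e-12)
  expect_error(marker_correlation(x, "missing", "pos"), "not found")
})
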