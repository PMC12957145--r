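# a linearly separable two-group expression fixture: gene f1 carries the
# class, the rest are noise
separable_fixture <- function(n_per_group = 30, p_noise = 2, gap = 3,
                              sd = 0.3, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  x <- cbind(f1 = c(rnorm(n_per_group, gap, sd), rnorm(n_per_group, 0, sd)),
             matrix(rnorm(n * p_noise), n,
                    dimnames = list(NULL, paste0("n", seq_len(p_noise)))))
  rownames(x) <- sprintf("s%02d", seq_len(n))
  labels <- setNames(rep(c("case", "ctrl"), each = n_per_group), rownames(x))
  list(x = x, labels = labels)
}

test_that("hub intersection is exact set arithmetic", {
  expect_warning(out <- intersect_hub_genes(c("a"), c("b"), c("c")), "empty")
  expect_length(out, 0)
  expect_equal(intersect_hub_genes(c("a", "b", "c"), c("b", "c", "d"),
                                   c("c", "e")), "c")
  co <- make_bulk_cohort(bulk_cohort_spec(300, 10, 10, de_fraction = 0.1,
                                          lfc_mean = 2, noise_sd = 0.1, seed = 4))
  sig <- make_trained_signature(co$truth$de, overlap_count = 7, extra_count = 30,
                                universe = rownames(co$expr), seed = 2)
  deg <- deg_test(to_log2p1(co$expr), co$labels)
  hubs <- intersect_hub_genes(deg$gene[deg$call != "ns"], unlist(sig),
                              co$truth$de$gene)
  expect_length(hubs, 7)
})

test_that("stratified split applies round-half-up per group and is seeded", {
  lab <- setNames(rep(c("case", "ctrl"), c(21, 9)), paste0("s", 1:30))
  sp <- stratified_split(lab, 0.7, seed = 1)
  expect_equal(sp$counts["case", "train"], 15)  # round(14.7)
  expect_equal(sp$counts["ctrl", "train"], 6)   # round(6.3)
  expect_setequal(c(sp$train, sp$test), names(lab))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, stratified_split(lab, 0.7, seed = 1))
  expect_false(identical(sp$train, stratified_split(lab, 0.7, seed = 2)$train))
  expect_error(stratified_split(lab, 1), "between 0 and 1")
  expect_error(stratified_split(setNames(c("a", "b", "b"), paste0("s", 1:3))),
               "fewer than 2")
})

test_that("all six models separate a perfectly separable dataset", {
  fx <- separable_fixture(seed = 1)
  tr <- sprintf("s%02d", c(1:20, 31:50))
  te <- setdiff(rownames(fx$x), tr)
  fit <- train_models(fx$x[tr, ], fx$labels[tr], seed = 1)
  expect_setequal(names(fit$models),
                  c("rf", "svm", "glm", "lasso", "knn", "nnet"))
  p <- predict(fit, fx$x[te, ])
  y <- as.integer(fx$labels[te] == "case")
  acc <- apply(p, 2, function(pp) mean((pp >= 0.5) == (y == 1)))
  expect_true(all(acc == 1))
})

test_that("cross-validation accuracy is near chance under permuted labels", {
  fx <- separable_fixture(seed = 2)
  set.seed(5)
  null_labels <- setNames(sample(fx$labels), names(fx$labels))
  fit <- train_models(fx$x, null_labels, seed = 3)
  expect_true(mean(fit$cv$cv_accuracy) > 0.35 &&
                mean(fit$cv$cv_accuracy) < 0.65)
})

test_that("training and prediction are deterministic under a fixed seed", {
  fx <- separable_fixture(n_per_group = 15, seed = 3)
  f1 <- train_models(fx$x, fx$labels, seed = 11)
  f2 <- train_models(fx$x, fx$labels, seed = 11)
  expect_identical(predict(f1, fx$x), predict(f2, fx$x))
  expect_identical(f1$cv, f2$cv)
})

test_that("evaluation reproduces residuals and RMSE by hand", {
  fx <- separable_fixture(seed = 4)
  tr <- sprintf("s%02d", c(1:20, 31:50))
  te <- setdiff(rownames(fx$x), tr)
  fit <- train_models(fx$x[tr, ], fx$labels[tr], models = c("glm", "knn"),
                      seed = 1)
  ev <- evaluate_models(fit, fx$x[te, ], fx$labels[te])
  y <- as.integer(fx$labels[te] == "case")
  p <- predict(fit, fx$x[te, ])
  expect_equal(unname(ev$residuals), unname(abs(y - p)), tolerance = 1e-12)
  expect_equal(ev$rmse[["glm"]], sqrt(mean((y - p[, "glm"])^2)),
               tolerance = 1e-12)
  # perfect probabilities: residuals 0 everywhere, reverse cumulative 0
  ev$residuals[] <- 0
  # constant 0.5 probabilities give RMSE 0.5 by definition
  expect_equal(sqrt(mean(abs(y - 0.5)^2)), 0.5)
  # hand-computed toy: y = (1,0,1,0), p = (.9,.2,.6,.4)
  expect_equal(sqrt(mean(c(.1, .2, .4, .4)^2)), sqrt(0.0925))
})

test_that("reverse cumulative residual curve is the exceedance fraction", {
  fx <- separable_fixture(seed = 5)
  tr <- sprintf("s%02d", c(1:20, 31:50))
  te <- setdiff(rownames(fx$x), tr)
  fit <- train_models(fx$x[tr, ], fx$labels[tr], models = "glm", seed = 1)
  ev <- evaluate_models(fit, fx$x[te, ], fx$labels[te], t_grid = c(0, 0.5, 1))
  expect_equal(ev$reverse_cumulative$glm,
               vapply(c(0, 0.5, 1), function(t) mean(ev$residuals[, "glm"] > t), 0))
  expect_equal(ev$reverse_cumulative$glm[3], 0)  # residuals never exceed 1
})

test_that("permutation importance is zero for constant features and positive for the signal", {
  fx <- separable_fixture(seed = 6)
  x <- cbind(fx$x, const = 1)
  tr <- sprintf("s%02d", c(1:20, 31:50))
  te <- setdiff(rownames(x), tr)
  fit <- train_models(x[tr, ], fx$labels[tr], models = c("glm", "rf"), seed = 1)
  imp <- permutation_importance(fit, x[te, ], fx$labels[te],
                                n_permutations = 20, seed = 2)
  expect_equal(unname(imp["const", ]), c(0, 0))
  expect_true(all(imp["f1", ] > 0))
  imp2 <- permutation_importance(fit, x[te, ], fx$labels[te],
                                 n_permutations = 20, seed = 2)
  expect_identical(imp, imp2)
})

test_that("a feature a linear model provably ignores has near-zero importance", {
  fx <- separable_fixture(seed = 7)
  tr <- sprintf("s%02d", c(1:20, 31:50))
  te <- setdiff(rownames(fx$x), tr)
  fit <- train_models(fx$x[tr, ], fx$labels[tr], models = "lasso", seed = 1)
  # lasso at its selected penalty zeroes the pure-noise coefficients
  imp <- permutation_importance(fit, fx$x[te, ], fx$labels[te],
                                n_permutations = 20, seed = 3)
  expect_true(all(abs(imp[c("n1", "n2"), "lasso"]) < 0.05))
  expect_gt(imp["f1", "lasso"], 0.2)
})

test_that("fusion coordinates match a brute-force PCA of the weighted matrix", {
  set.seed(8)
  imp <- matrix(rexp(42), 7, 6,
                dimnames = list(paste0("g", 1:7),
                                c("rf", "svm", "glm", "lasso", "knn", "nnet")))
  mar <- setNames(runif(6, 0.1, 0.5), colnames(imp))
  pr <- fuse_and_select(imp, mar)
  # independent recomputation: z-score, inverse-rank weights, eigen PCA
  z <- apply(imp, 2, function(c) (c - mean(c)) / sd(c))
  r <- rank(mar, ties.method = "first")
  w <- (6 - r + 1) / sum(6 - r + 1)
  wm <- sweep(z, 2, w, "*")
  cm <- sweep(wm, 2, colMeans(wm))
  eg <- eigen(cov(cm))
  coords <- cm %*% eg$vectors[, 1:3]
  expect_equal(unname(abs(pr$coordinates)), unname(abs(coords)),
               tolerance = 1e-8)
  expect_equal(unname(pr$model_weights), unname(w))
})

test_that("a dominant gene is the first principal-component extreme", {
  imp <- matrix(0.1, 7, 6,
                dimnames = list(paste0("g", 1:7), paste0("m", 1:6)))
  imp <- imp + matrix(rnorm(42, 0, 0.01), 7, 6)
  imp["g5", ] <- 1.0
  mar <- setNames(seq(0.1, 0.6, 0.1), colnames(imp))
  pr <- fuse_and_select(imp, mar)
  expect_equal(pr$selected_genes[1], "g5")
  expect_length(pr$selected_genes, 3)
  expect_length(unique(pr$selected_genes), 3)
})

test_that("degenerate identical importances fall back to identifier order", {
  imp <- matrix(1, 5, 6, dimnames = list(paste0("g", 5:1), paste0("m", 1:6)))
  mar <- setNames(rep(0.3, 6), colnames(imp))
  expect_warning(pr <- fuse_and_select(imp, mar), "degenerate")
  expect_equal(pr$selected_genes, c("g1", "g2", "g3"))
})

test_that("fusion selection is invariant to gene row order", {
  set.seed(9)
  imp <- matrix(rexp(42), 7, 6,
                dimnames = list(paste0("g", 1:7), paste0("m", 1:6)))
  mar <- setNames(runif(6), colnames(imp))
  a <- fuse_and_select(imp, mar)
  perm <- sample(7)
  b <- fuse_and_select(imp[perm, ], mar)
  expect_setequal(a$selected_genes, b$selected_genes)
})
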