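make_two_module_cohort <- function(seed = 1, loading = 0.9, noise = 0.1) {
  make_bulk_cohort(bulk_cohort_spec(
    180, 15, 15,
    module_spec = list(list(size = 40, loading = loading),
                       list(size = 40, loading = loading)),
    noise_sd = noise, seed = seed))
}

test_that("variance filter keeps the highest-variance genes", {
  set.seed(3)
  m <- matrix(rnorm(80, 5, 1) * rep(seq(0.2, 2, length.out = 8), 10), 8, 10)
  m <- abs(m)
  x <- toy_expr(m)
  expect_identical(unclass(variance_filter(x, 1)), unclass(x))
  kept <- variance_filter(x, 0.5)
  expect_equal(nrow(kept), 4)
  v <- apply(unclass(x), 1, var)
  expect_setequal(rownames(kept), rownames(x)[order(-v)][1:4])
})

test_that("the scale-free fit equals an independent recomputation of the binned regression", {
  set.seed(9)
  k <- c(rexp(60, 2), rexp(40, 0.2))
  sf <- scale_free_fit(k, n_bins = 10)
  breaks <- unique(quantile(k, seq(0, 1, length.out = 11)))
  bin <- cut(k, breaks, include.lowest = TRUE)
  cnt <- tabulate(bin, nlevels(bin))
  wd <- tapply(k, bin, function(v) diff(range(v)))
  dens <- cnt / (length(k) * wd)
  km <- tapply(k, bin, mean)
  fit <- lm(log10(as.numeric(dens)) ~ log10(as.numeric(km)))
  expect_equal(sf$fit, -sign(coef(fit)[[2]]) * summary(fit)$r.squared,
               tolerance = 1e-12)
})

test_that("mean connectivity decreases strictly with the soft-threshold power", {
  set.seed(4)
  m <- matrix(abs(rnorm(600, 5, 1)), 30, 20)
  st <- suppressMessages(pick_soft_threshold(toy_expr(m), powers = 1:10))
  expect_true(all(diff(st$table$mean_connectivity) < 0))
  expect_true(st$beta_selected %in% 1:10)
})

test_that("the selection rule returns the smallest power reaching the target fit", {
  co <- make_bulk_cohort(modular_cohort_spec(seed = 1))
  filt <- variance_filter(to_log2p1(co$expr), 0.25)
  st <- pick_soft_threshold(filt)
  expect_true(st$reached_target)
  expect_gte(st$fit_selected, 0.90)
  below <- st$table$fit[st$table$power < st$beta_selected]
  expect_true(all(below < 0.90, na.rm = TRUE))
})

test_that("topological overlap matches the element-wise formula", {
  # disconnected graph: no overlap anywhere
  a0 <- diag(4)
  expect_true(all(tom_similarity(a0)[upper.tri(a0)] == 0))
  # fully connected triangle: complete overlap
  a1 <- matrix(1, 3, 3)
  expect_equal(tom_similarity(a1)[1, 2], 1)
  # random adjacency vs brute force
  set.seed(11)
  r <- matrix(runif(25), 5, 5)
  a <- (r + t(r)) / 2
  diag(a) <- 0
  expect_equal(unname(tom_similarity(a)), oracle_tom(a), tolerance = 1e-12)
  expect_error(tom_similarity(matrix(runif(9), 3, 3)), "symmetric")
})

test_that("TOM values stay within [0,1] and symmetric for random unsigned adjacencies", {
  for (s in 1:5) {
    set.seed(s)
    r <- matrix(runif(100), 10, 10)
    a <- (r + t(r)) / 2
    diag(a) <- 0
    tom <- tom_similarity(a)
    expect_true(isSymmetric(tom, tol = 1e-12))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
})

test_that("planted modules are recovered against the generator truth", {
  co <- make_two_module_cohort(seed = 1)
  filt <- to_log2p1(co$expr)  # keep all genes: background is part of the test
  st <- suppressMessages(pick_soft_threshold(filt))
  tom <- tom_similarity(adjacency_matrix(filt, st$beta_selected))
  mods <- detect_modules(tom, filt, min_module_size = 30)
  found <- sort(unique(mods$modules[mods$modules > 0]))
  expect_length(found, 2)
  truth <- co$truth$modules$module[match(names(mods$modules),
                                         co$truth$modules$gene)]
  expect_gte(mclust::adjustedRandIndex(mods$modules, truth), 0.9)
})

test_that("clusters below the minimum size are left unassigned", {
  co <- make_two_module_cohort(seed = 2)
  filt <- to_log2p1(co$expr)
  st <- suppressMessages(pick_soft_threshold(filt))
  tom <- tom_similarity(adjacency_matrix(filt, st$beta_selected))
  mods <- suppressWarnings(detect_modules(tom, filt, min_module_size = 60))
  expect_true(all(mods$modules == 0))
})

test_that("two clusters carrying the same latent factor merge at height 0.25", {
  # two blocks driven by one shared factor: eigengenes correlate ~1
  set.seed(5)
  n <- 20
  fac <- rnorm(n)
  m <- rbind(matrix(rep(fac, 40), 40, n, byrow = TRUE) + rnorm(40 * n, 0, 0.1) + 6,
             matrix(rep(fac, 40), 40, n, byrow = TRUE) + rnorm(40 * n, 0, 0.1) + 9)
  x <- toy_expr(abs(m))
  # force an artificial split: label first/second half as distinct modules
  pre <- setNames(rep(1:2, each = 40), rownames(x))
  me <- module_eigengenes(x, pre)
  expect_gte(cor(me[, 1], me[, 2]), 0.75)  # the merge criterion applies
  tom <- tom_similarity(adjacency_matrix(x, 6))
  mods <- detect_modules(tom, x, min_module_size = 30, merge_height = 0.25)
  expect_length(unique(mods$modules[mods$modules > 0]), 1)
})

test_that("module labels are invariant to gene order up to relabeling", {
  co <- make_two_module_cohort(seed = 3)
  filt <- to_log2p1(co$expr)
  tom <- tom_similarity(adjacency_matrix(filt, 6))
  mods1 <- detect_modules(tom, filt, min_module_size = 30)
  set.seed(99)
  perm <- sample(nrow(filt))
  xp <- expr_matrix(unclass(filt)[perm, ], "log2p1")
  tomp <- tom_similarity(adjacency_matrix(xp, 6))
  mods2 <- detect_modules(tomp, xp, min_module_size = 30)
  common <- names(mods1$modules)
  expect_equal(mclust::adjustedRandIndex(mods1$modules[common],
                                         mods2$modules[common]), 1)
})

test_that("the eigengene explains at least as much module variance as any single gene", {
  co <- make_two_module_cohort(seed = 4)
  filt <- to_log2p1(co$expr)
  tom <- tom_similarity(adjacency_matrix(filt, 6))
  mods <- detect_modules(tom, filt, min_module_size = 30)
  lab <- mods$modules[mods$modules > 0][1]
  z <- t(scale(t(unclass(filt)[mods$modules == lab, ])))
  ev_of <- function(v) sum(cor(v, t(z))^2)
  me_var <- ev_of(mods$eigengenes[, paste0("ME", lab)])
  single <- apply(z, 1, ev_of)
  expect_gte(me_var, max(single) - 1e-8)
})

test_that("module-trait correlation behaves at the two extremes", {
  co <- make_two_module_cohort(seed = 5)
  filt <- to_log2p1(co$expr)
  tom <- tom_similarity(adjacency_matrix(filt, 6))
  mods <- detect_modules(tom, filt, min_module_size = 30)
  me <- mods$eigengenes
  # trait equal to an eigengene: perfect correlation
  mt <- module_trait_correlation(me, setNames(data.frame(t1 = me[, 1]),
                                              "t1"))
  expect_equal(mt$r[mt$module == colnames(me)[1]], 1, tolerance = 1e-12)
  expect_error(module_trait_correlation(me, rep(1, nrow(me))), "constant")
  # independent random traits: small correlations, mostly insignificant
  ps <- vapply(1:20, function(s) {
    set.seed(100 + s)
    tr <- rnorm(nrow(me))
    row <- module_trait_correlation(me, tr)
    c(abs(row$r[1]), row$p[1])
  }, numeric(2))
  expect_gte(mean(ps[2, ] > 0.05), 0.9)
})

test_that("a group-shifted module factor makes that module the top trait hit", {
  co <- make_bulk_cohort(bulk_cohort_spec(
    200, 15, 15,
    module_spec = list(list(size = 40, loading = 0.9, trait_shift = 1.5),
                       list(size = 40, loading = 0.9)),
    noise_sd = 0.1, seed = 6))
  filt <- to_log2p1(co$expr)
  tom <- tom_similarity(adjacency_matrix(filt, 6))
  mods <- detect_modules(tom, filt, min_module_size = 30)
  trait <- as.numeric(co$labels[colnames(filt)] == "case")
  mt <- module_trait_correlation(mods, trait)
  top_module <- mt$module[which.max(abs(mt$r))]
  shifted_genes <- co$truth$modules$gene[co$truth$modules$module == 1]
  top_genes <- names(mods$modules)[paste0("ME", mods$modules) == top_module]
  expect_gte(length(intersect(top_genes, shifted_genes)) /
               length(shifted_genes), 0.9)
})
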