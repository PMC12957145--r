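#' Three-way hub-gene intersection
#'
#' Candidate hub genes are the genes present in all three inputs: the
#' cohort's differentially expressed genes, the trained-immunity signature,
#' and the trait-associated co-expression module genes (a Venn-style
#' integration).
#'
#' @param deg_genes,signature_genes,module_genes character vectors.
#' @return sorted character vector; empty (with a warning) when the
#'   intersection is empty.
#' @export
intersect_hub_genes <- function(deg_genes, signature_genes, module_genes) {
  stopifnot(length(deg_genes) > 0, length(signature_genes) > 0,
            length(module_genes) > 0)
  hub <- sort(intersect(intersect(unique(deg_genes), unique(signature_genes)),
                        unique(module_genes)))
  if (!length(hub)) warning("empty three-way intersection")
  hub
}

# round half away from zero (R's round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

#' Stratified train/test split
#'
#' Samples each group independently without replacement at `train_fraction`
#' (round half up), so group proportions are preserved in both partitions.
#'
#' @param labels named group labels per sample.
#' @param train_fraction fraction in the training set (default 0.7); must
#'   leave at least one test sample per group.
#' @param seed integer seed.
#' @return list with `train` and `test` (sample names), and `counts`
#'   (per-group train/test table).
#' @export
stratified_split <- function(labels, train_fraction = 0.7, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be strictly between 0 and 1")
  }
  if (is.null(names(labels))) names(labels) <- paste0("s", seq_along(labels))
  set.seed(seed)
  train <- character(0)
  counts <- list()
  for (g in sort(unique(as.character(labels)))) {
    ids <- names(labels)[labels == g]
    if (length(ids) < 2) stop("group '", g, "' has fewer than 2 samples")
    n_tr <- round_half_up(train_fraction * length(ids))
    n_tr <- max(1L, min(length(ids) - 1L, n_tr))
    train <- c(train, sample(ids, n_tr))
    counts[[g]] <- c(train = n_tr, test = length(ids) - n_tr)
  }
  list(train = train, test = setdiff(names(labels), train),
       counts = do.call(rbind, counts))
}

# stratified k-fold assignment; guarantees both classes in every fold or errors
make_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (g in levels(y)) {
    idx <- sample(which(y == g))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  for (f in seq_len(k)) {
    if (nlevels(droplevels(y[fold != f])) < 2) {
      stop("cannot build ", k, "-fold stratified CV: a fold's training part is single-class")
    }
  }
  fold
}

# ---- model wrappers -------------------------------------------------------
# Each wrapper fits one classifier on scaled features `xs` (samples x genes)
# and returns a closure predicting P(case) on scaled new data.

fit_single_model <- function(type, xs, y01, pars, seed) {
  force(xs); force(y01); force(pars); force(seed)  # closures outlive the caller's loop
  y <- factor(y01, levels = c(0, 1))
  set.seed(seed)
  switch(type,
    rf = {
      m <- randomForest::randomForest(xs, y, ntree = 300, mtry = pars$mtry)
      function(new) unname(stats::predict(m, new, type = "prob")[, "1"])
    },
    svm = {
      m <- e1071::svm(xs, y, kernel = "radial", cost = pars$cost,
                      gamma = pars$gamma, probability = TRUE)
      function(new) {
        pr <- attr(stats::predict(m, new, probability = TRUE), "probabilities")
        unname(pr[, "1"])
      }
    },
    glm = {
      df <- data.frame(y = y01, xs)
      m <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
      function(new) {
        p <- suppressWarnings(stats::predict(m, data.frame(new), type = "response"))
        unname(pmin(pmax(p, 0), 1))
      }
    },
    lasso = {
      m <- glmnet::glmnet(xs, y, family = "binomial", alpha = 1,
                          lambda = pars$lambda_seq)
      lam <- pars$lambda
      function(new) as.numeric(stats::predict(m, new, s = lam, type = "response"))
    },
    knn = {
      function(new) {
        set.seed(seed)  # tie-breaking in knn is randomized
        pred <- class::knn(xs, new, cl = y, k = pars$k, prob = TRUE)
        win <- attr(pred, "prob")
        ifelse(pred == "1", win, 1 - win)
      }
    },
    nnet = {
      m <- nnet::nnet(xs, y01, size = pars$size, decay = pars$decay,
                      maxit = 300, trace = FALSE, entropy = TRUE)
      function(new) as.numeric(stats::predict(m, new))
    },
    stop("unknown model type: ", type)
  )
}

default_grids <- function(p, n) {
  list(
    rf = lapply(unique(pmin(c(1L, max(1L, floor(sqrt(p))), p), p)),
                function(m) list(mtry = m)),
    svm = lapply(c(0.25, 1, 4), function(co) list(cost = co, gamma = 1 / p)),
    glm = list(list()),
    lasso = list(list()),  # lambda selected by inner CV over the glmnet path
    knn = lapply(unique(pmin(c(3L, 5L, 7L), n - 1L)), function(k) list(k = k)),
    nnet = lapply(c(1L, 3L), function(s) list(size = s, decay = 0.1))
  )
}

#' Train the six-model classification ensemble
#'
#' Fits random forest, radial-kernel SVM, logistic regression, LASSO
#' logistic regression, k-nearest neighbors, and a single-hidden-layer
#' neural network on gene-expression features. Features are centered and
#' scaled using training-set statistics only; hyperparameters are chosen by
#' stratified 5-fold cross-validation (accuracy) over small fixed grids.
#' All randomness is seeded.
#'
#' @param x feature matrix, samples x genes (or an [expr_matrix()], which is
#'   transposed), training samples only.
#' @param labels named group labels for the training samples; the second
#'   factor level is the positive class.
#' @param models subset of `c("rf","svm","glm","lasso","knn","nnet")`.
#' @param n_folds cross-validation folds (default 5).
#' @param seed integer seed.
#' @param case optional label value to treat as the positive class.
#' @return object of class `ensemble_fit`: per-model prediction closures,
#'   chosen hyperparameters, CV accuracies, and the scaling statistics.
#' @export
train_models <- function(x, labels,
                         models = c("rf", "svm", "glm", "lasso", "knn", "nnet"),
                         n_folds = 5, seed = 1, case = NULL) {
  if (inherits(x, "expr_matrix")) x <- t(unclass(x))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  colnames(x) <- make.names(colnames(x))
  f <- align_labels(t(x), labels, case = case)
  y01 <- as.integer(f == levels(f)[2L])
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  folds <- make_folds(f, n_folds, seed)
  grids <- default_grids(ncol(x), nrow(x))

  fits <- list(); cv <- list()
  for (type in models) {
    grid <- grids[[type]]
    if (type == "lasso") {
      set.seed(seed + 11L)
      cvfit <- glmnet::cv.glmnet(xs, factor(y01), family = "binomial",
                                 alpha = 1, foldid = folds, nfolds = n_folds,
                                 type.measure = "class")
      pars <- list(lambda = cvfit$lambda.min, lambda_seq = cvfit$lambda)
      acc <- 1 - min(cvfit$cvm)
    } else {
      accs <- vapply(grid, function(pars) {
        hits <- 0L
        for (fd in seq_len(n_folds)) {
          tr <- folds != fd
          pred <- fit_single_model(type, xs[tr, , drop = FALSE], y01[tr],
                                   pars, seed + 101L * fd)(xs[!tr, , drop = FALSE])
          hits <- hits + sum((pred >= 0.5) == (y01[!tr] == 1L))
        }
        hits / length(y01)
      }, 0)
      pars <- grid[[which.max(accs)]]
      acc <- max(accs)
    }
    fits[[type]] <- list(type = type, pars = pars,
                         predict = fit_single_model(type, xs, y01, pars,
                                                    seed + 997L))
    cv[[type]] <- data.frame(model = type, cv_accuracy = acc,
                             stringsAsFactors = FALSE)
  }
  structure(list(models = fits, center = ctr, scale = scl,
                 levels = levels(f), positive = levels(f)[2L],
                 features = colnames(x), cv = do.call(rbind, cv), seed = seed),
            class = "ensemble_fit")
}

#' Predict positive-class probabilities from an ensemble
#' @param object an `ensemble_fit`.
#' @param newdata samples x genes matrix on the original (unscaled) feature
#'   scale.
#' @param ... unused.
#' @return samples x models matrix of probabilities.
#' @export
predict.ensemble_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "expr_matrix")) newdata <- t(unclass(newdata))
  newdata <- as.matrix(newdata)
  colnames(newdata) <- make.names(colnames(newdata))
  newdata <- newdata[, object$features, drop = FALSE]
  xs <- scale(newdata, center = object$center, scale = object$scale)
  p <- vapply(object$models, function(m) m$predict(xs),
              numeric(nrow(newdata)))
  if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(NULL, names(object$models)))
  rownames(p) <- rownames(newdata)
  p
}

#' Evaluate ensemble models on a held-out test set
#'
#' Computes per-sample probability residuals `|y - p|`, the RMSE of the
#' probabilities, and the reverse cumulative residual distribution (fraction
#' of samples with residual exceeding each threshold).
#'
#' @param fit an `ensemble_fit`.
#' @param x_test samples x genes test matrix.
#' @param labels_test named labels for the test samples (both classes
#'   required).
#' @param t_grid residual thresholds for the reverse cumulative curve.
#' @return object of class `model_evaluation`: `residuals` (samples x
#'   models), `rmse`, `mean_abs_residual`, `reverse_cumulative` (data.frame
#'   threshold x model fractions), `probabilities`.
#' @export
evaluate_models <- function(fit, x_test, labels_test,
                            t_grid = seq(0, 1, by = 0.01)) {
  if (inherits(x_test, "expr_matrix")) x_test <- t(unclass(x_test))
  ids <- rownames(x_test)
  lab <- if (!is.null(names(labels_test)) && !is.null(ids)) labels_test[ids] else labels_test
  if (length(unique(as.character(lab))) < 2) stop("test set must contain both classes")
  y01 <- as.integer(as.character(lab) == fit$positive)
  p <- stats::predict(fit, x_test)
  res <- abs(sweep(-p, 1, y01, "+"))
  rmse <- sqrt(colMeans(res^2))
  rc <- vapply(colnames(res),
               function(m) vapply(t_grid, function(t) mean(res[, m] > t), 0),
               numeric(length(t_grid)))
  structure(list(residuals = res, rmse = rmse,
                 mean_abs_residual = colMeans(res),
                 reverse_cumulative = data.frame(threshold = t_grid, rc),
                 probabilities = p, y = y01),
            class = "model_evaluation")
}

#' Partial dependence of a model's prediction on one gene
#'
#' Sweeps the gene over a grid spanning its observed range while all other
#' features keep their observed values, and averages the predicted
#' positive-class probability at each grid point.
#'
#' @param fit an `ensemble_fit`.
#' @param x samples x genes matrix (original scale).
#' @param gene feature name.
#' @param model model name (default first model).
#' @param n_grid grid resolution.
#' @return data.frame with `value` and `mean_probability`.
#' @export
partial_dependence <- function(fit, x, gene, model = names(fit$models)[1],
                               n_grid = 25) {
  if (inherits(x, "expr_matrix")) x <- t(unclass(x))
  colnames(x) <- make.names(colnames(x))
  gene <- make.names(gene)
  stopifnot(gene %in% colnames(x), model %in% names(fit$models))
  grid <- seq(min(x[, gene]), max(x[, gene]), length.out = n_grid)
  mp <- vapply(grid, function(v) {
    xg <- x
    xg[, gene] <- v
    mean(stats::predict(fit, xg)[, model])
  }, 0)
  data.frame(value = grid, mean_probability = mp)
}

#' Permutation importance of each gene under each model
#'
#' The importance of gene `g` under a model is the mean, over `n_permutations`
#' seeded shuffles of column `g` on the evaluation partition, of the increase
#' in `1 - AUC` of the predicted probabilities relative to the unpermuted
#' baseline. A feature that is constant on the partition has importance
#' exactly 0 (shuffling is a no-op).
#'
#' @param fit an `ensemble_fit`.
#' @param x samples x genes evaluation matrix (original scale).
#' @param labels named labels for the evaluation samples.
#' @param n_permutations shuffles per gene (default 50).
#' @param seed integer seed.
#' @return genes x models importance matrix.
#' @export
permutation_importance <- function(fit, x, labels, n_permutations = 50,
                                   seed = 1) {
  if (inherits(x, "expr_matrix")) x <- t(unclass(x))
  x <- as.matrix(x)
  colnames(x) <- make.names(colnames(x))
  ids <- rownames(x)
  lab <- if (!is.null(names(labels)) && !is.null(ids)) labels[ids] else labels
  y01 <- as.integer(as.character(lab) == fit$positive)
  base_p <- stats::predict(fit, x)
  base_metric <- apply(base_p, 2, function(p) 1 - auc_mw(p, y01))
  imp <- matrix(0, ncol(x), length(fit$models),
                dimnames = list(colnames(x), names(fit$models)))
  for (g in seq_len(ncol(x))) {
    if (stats::sd(x[, g]) == 0) next  # no-op shuffle, importance exactly 0
    set.seed(seed + g)
    perms <- replicate(n_permutations, sample.int(nrow(x)))
    deltas <- matrix(0, n_permutations, length(fit$models))
    for (b in seq_len(n_permutations)) {
      xp <- x
      xp[, g] <- x[perms[, b], g]
      p <- stats::predict(fit, xp)
      deltas[b, ] <- apply(p, 2, function(pp) 1 - auc_mw(pp, y01)) - base_metric
    }
    imp[g, ] <- colMeans(deltas)
  }
  imp
}

#' Fuse per-model importances and select principal-component extremes
#'
#' Importances are z-scored across genes within each model, re-weighted by
#' the models' relative ranking (models ranked by mean absolute test
#' residual, best first; linear inverse-rank weights
#' `w_m = (M - r_m + 1) / sum(M - r + 1)`), and the gene x model weighted
#' matrix is decomposed by PCA (genes as observations, centered, not
#' re-scaled). The gene with the largest absolute coordinate along each of
#' PC1-PC3 is selected (distinct genes; next-largest taken when a gene
#' repeats).
#'
#' @param importance genes x models matrix from [permutation_importance()].
#' @param evaluation a `model_evaluation` (supplies the model ranking), or a
#'   named numeric vector of mean absolute residuals.
#' @return object of class `prioritization_result`: `coordinates` (genes x
#'   PCs), `explained_variance`, `model_weights`, `selected_genes`.
#' @export
fuse_and_select <- function(importance, evaluation) {
  imp <- as.matrix(importance)
  mar <- if (inherits(evaluation, "model_evaluation")) {
    evaluation$mean_abs_residual
  } else evaluation
  mar <- mar[colnames(imp)]
  m_models <- ncol(imp)
  r <- rank(mar, ties.method = "first")
  w <- (m_models - r + 1) / sum(m_models - r + 1)

  z <- apply(imp, 2, function(col) {
    s <- stats::sd(col)
    if (is.na(s) || s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  rownames(z) <- rownames(imp)
  weighted <- sweep(z, 2, w, "*")

  if (nrow(imp) < 3) {
    warning("fewer than 3 genes; selecting all")
    return(structure(list(coordinates = weighted, explained_variance = NULL,
                          model_weights = w,
                          selected_genes = sort(rownames(imp))),
                     class = "prioritization_result"))
  }
  centered <- scale(weighted, center = TRUE, scale = FALSE)
  if (sum(centered^2) < 1e-12) {
    warning("degenerate importance matrix (all genes identical); ",
            "falling back to gene-identifier order")
    return(structure(list(coordinates = centered, explained_variance = rep(0, 3),
                          model_weights = w,
                          selected_genes = utils::head(sort(rownames(imp)), 3)),
                     class = "prioritization_result"))
  }
  pc <- stats::prcomp(weighted, center = TRUE, scale. = FALSE)
  n_pc <- min(3L, ncol(pc$x))
  coords <- pc$x[, seq_len(n_pc), drop = FALSE]
  selected <- character(0)
  for (j in seq_len(n_pc)) {
    ord <- order(-abs(coords[, j]), rownames(coords))
    pick <- rownames(coords)[ord[!rownames(coords)[ord] %in% selected][1L]]
    selected <- c(selected, pick)
  }
  structure(list(coordinates = coords,
                 explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_pc)],
                 model_weights = w, selected_genes = selected),
            class = "prioritization_result")
}
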