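#' Reference-signature cell-fraction deconvolution
#'
#' Estimates per-sample cell-type fractions by constrained least squares:
#' for each sample `b` restricted to the signature genes, solve
#' `min_w ||S w - b||^2` subject to `w >= 0` (nonnegative least squares),
#' then normalize `w` to sum to 1. Deterministic and exact on noiseless
#' mixtures; the solver is deliberately simple and pluggable.
#'
#' @param x a linear-scale [expr_matrix()].
#' @param signature genes x cell-types nonnegative reference matrix (at
#'   least two cell types; rownames are gene identifiers).
#' @return object of class `cell_fractions`: list with `fractions`
#'   (samples x cell-types, rows sum to 1), `residual_norm` per sample,
#'   `n_genes_used`.
#' @export
deconvolve <- function(x, signature) {
  if (expr_scale(x) != "linear") stop("deconvolution expects linear-scale values")
  stopifnot(is.matrix(signature), ncol(signature) >= 2)
  common <- intersect(rownames(x), rownames(signature))
  if (length(common) < 2) stop("no usable genes shared with the signature")
  s <- signature[common, , drop = FALSE]
  m <- unclass(x)[common, , drop = FALSE]
  k <- ncol(s)
  frac <- matrix(NA_real_, ncol(m), k,
                 dimnames = list(colnames(m), colnames(s)))
  resid <- stats::setNames(numeric(ncol(m)), colnames(m))
  for (j in seq_len(ncol(m))) {
    b <- m[, j]
    if (all(b == 0)) {
      warning("all-zero sample ", colnames(m)[j], "; uniform fractions assigned")
      frac[j, ] <- 1 / k
      resid[j] <- 0
      next
    }
    sol <- pracma::lsqnonneg(s, b)
    w <- sol$x
    if (sum(w) == 0) {
      warning("degenerate fit for sample ", colnames(m)[j], "; uniform fractions assigned")
      frac[j, ] <- 1 / k
    } else {
      frac[j, ] <- w / sum(w)
    }
    resid[j] <- sqrt(sum((s %*% w - b)^2))
  }
  structure(list(fractions = frac, residual_norm = resid,
                 n_genes_used = length(common)),
            class = "cell_fractions")
}

#' Drop zero-variance cell-type columns
#'
#' Cell types estimated at a constant fraction across all samples carry no
#' correlation information and are removed before the association analyses.
#'
#' @param fractions a `cell_fractions` object or samples x cell-types matrix.
#' @return matrix with the constant columns removed (removed names reported
#'   via a message).
#' @export
drop_zero_variance <- function(fractions) {
  f <- if (inherits(fractions, "cell_fractions")) fractions$fractions else fractions
  stopifnot(nrow(f) >= 1)
  v <- apply(f, 2, stats::var)
  if (nrow(f) == 1L) v[] <- 0
  drop <- which(v == 0)
  if (length(drop) == ncol(f)) stop("all cell-type columns have zero variance")
  if (length(drop)) {
    message("dropping zero-variance cell types: ",
            paste(colnames(f)[drop], collapse = ", "))
    f <- f[, -drop, drop = FALSE]
  }
  f
}

#' Spearman correlations among cell-type fractions
#'
#' Pairwise Spearman rank correlation (average ranks for ties) across
#' samples, with the diagonal set to 1.
#'
#' @param fractions samples x cell-types matrix (zero-variance columns
#'   already removed).
#' @return symmetric correlation matrix.
#' @export
cell_correlations <- function(fractions) {
  f <- if (inherits(fractions, "cell_fractions")) fractions$fractions else fractions
  if (nrow(f) < 3) stop("at least 3 samples required for correlations")
  r <- stats::cor(f, method = "spearman")
  diag(r) <- 1
  r
}

#' Pseudocount-regularized cell-fraction ratios
#'
#' For every sample and ordered pair of cell types (A, B) computes
#' `ratio = (f_A + eps) / (f_B + eps)` and its log2, with pseudocount
#' `eps = 1e-6` preventing division by zero when a fraction vanishes. When
#' sample group labels are supplied, each pair's log2 ratios are compared
#' between groups by a Wilcoxon rank-sum test with Benjamini-Hochberg
#' adjustment across pairs.
#'
#' @param fractions samples x cell-types matrix or `cell_fractions`.
#' @param eps pseudocount (default 1e-6).
#' @param labels optional named group labels per sample (two groups).
#' @return list with `ratios` (long data.frame: sample, a, b, ratio,
#'   log2_ratio) and, when labels are given, `tests` (data.frame per pair
#'   with Wilcoxon p and BH-adjusted p).
#' @export
fraction_ratios <- function(fractions, eps = 1e-6, labels = NULL) {
  f <- if (inherits(fractions, "cell_fractions")) fractions$fractions else fractions
  ct <- colnames(f)
  pairs <- expand.grid(a = ct, b = ct, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  long <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    ratio <- (f[, pairs$a[i]] + eps) / (f[, pairs$b[i]] + eps)
    data.frame(sample = rownames(f), a = pairs$a[i], b = pairs$b[i],
               ratio = ratio, log2_ratio = log2(ratio),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out <- list(ratios = long)
  if (!is.null(labels)) {
    g <- factor(labels[rownames(f)])
    if (nlevels(g) != 2) stop("exactly two groups required for ratio tests")
    tests <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      lr <- log2((f[, pairs$a[i]] + eps) / (f[, pairs$b[i]] + eps))
      p <- suppressWarnings(
        stats::wilcox.test(lr[g == levels(g)[2]], lr[g == levels(g)[1]])$p.value)
      data.frame(a = pairs$a[i], b = pairs$b[i],
                 median_diff = stats::median(lr[g == levels(g)[2]]) -
                   stats::median(lr[g == levels(g)[1]]),
                 p = p, stringsAsFactors = FALSE)
    }))
    tests$p_adj <- stats::p.adjust(tests$p, method = "BH")
    out$tests <- tests
  }
  out
}

#' Score immune subfunctions per sample
#'
#' Each gene set is scored as the mean, over its member genes present in the
#' matrix, of the gene's across-sample z-scored `log2(x + 1)` expression.
#' Genes constant across samples (undefined z-score) are skipped; sets with
#' fewer than 2 usable member genes are skipped with a warning.
#'
#' @param x a log2p1-scale [expr_matrix()].
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @return samples x sets score matrix.
#' @export
score_subfunctions <- function(x, gene_sets) {
  if (!length(gene_sets)) stop("empty gene-set collection")
  if (expr_scale(x) != "log2p1") stop("subfunction scoring expects log2(x+1) values")
  m <- unclass(x)
  z <- t(scale(t(m)))
  usable <- rownames(m)[apply(m, 1, stats::sd) > 0]
  scores <- list()
  for (s in names(gene_sets)) {
    members <- intersect(gene_sets[[s]], usable)
    if (length(members) < 2) {
      warning("set '", s, "' has fewer than 2 usable genes; skipped")
      next
    }
    scores[[s]] <- colMeans(z[members, , drop = FALSE])
  }
  if (!length(scores)) stop("no gene set could be scored")
  do.call(cbind, scores)
}

#' Subfunction synergy network
#'
#' Spearman correlations among per-sample subfunction scores; an undirected
#' edge connects each pair with correlation at or above `edge_threshold`
#' (signed: anticorrelation never creates an edge).
#'
#' @param scores samples x sets matrix from [score_subfunctions()].
#' @param edge_threshold minimum Spearman rho for an edge (default 0.6).
#' @return list with `rho` (correlation matrix), `edges` (data.frame a, b,
#'   rho), `degree` (named vector of incident-edge counts).
#' @export
subfunction_network <- function(scores, edge_threshold = 0.6) {
  stopifnot(nrow(scores) >= 3, ncol(scores) >= 2)
  rho <- stats::cor(scores, method = "spearman")
  diag(rho) <- 1
  nm <- colnames(rho)
  idx <- which(upper.tri(rho) & rho >= edge_threshold, arr.ind = TRUE)
  edges <- data.frame(a = nm[idx[, 1]], b = nm[idx[, 2]],
                      rho = rho[idx], stringsAsFactors = FALSE)
  degree <- stats::setNames(integer(length(nm)), nm)
  for (i in seq_len(nrow(edges))) {
    degree[edges$a[i]] <- degree[edges$a[i]] + 1L
    degree[edges$b[i]] <- degree[edges$b[i]] + 1L
  }
  list(rho = rho, edges = edges, degree = degree)
}
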