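#' Per-sample gene-signature score
#'
#' Aggregates the selected genes as the mean, across genes, of each gene's
#' across-sample z-scored `log2(x + 1)` expression. With one gene the score
#' is simply that gene's z-score profile.
#'
#' @param x a log2p1-scale [expr_matrix()].
#' @param genes character vector of gene identifiers; at least one must be
#'   present in the matrix.
#' @return named numeric vector of scores, one per sample.
#' @export
signature_score <- function(x, genes) {
  if (expr_scale(x) != "log2p1") stop("signature_score expects log2(x+1) values")
  m <- unclass(x)
  present <- intersect(genes, rownames(m))
  if (!length(present)) stop("none of the signature genes are present")
  z <- t(scale(t(m[present, , drop = FALSE])))
  if (any(!is.finite(z))) stop("constant signature gene; z-score undefined")
  colMeans(z)
}

# internal Mann-Whitney AUC with half-credit for ties
auc_mw <- function(score, y01) {
  pos <- score[y01 == 1]; neg <- score[y01 == 0]
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' ROC curve and AUC of a score against binary labels
#'
#' The AUC is the Mann-Whitney probability estimate with half-credit for
#' ties: `[#(s_case > s_ctrl) + 0.5 * #ties] / (n_case * n_ctrl)`. Curve
#' points come from a threshold sweep over the unique scores, yielding a
#' step function from (0, 0) to (1, 1) in (1 - specificity, sensitivity)
#' space.
#'
#' @param score numeric score per sample.
#' @param labels group labels per sample.
#' @param positive_class label value counted as positive (case).
#' @param auto_direction when `TRUE`, flip the score if AUC < 0.5 (as some
#'   tools force); default `FALSE` reports the stated direction as-is.
#' @return object of class `roc_result`: list with `auc`, `curve`
#'   (data.frame threshold, sensitivity, specificity), `positive_class`,
#'   `flipped`.
#' @export
roc_auc <- function(score, labels, positive_class, auto_direction = FALSE) {
  lab <- as.character(labels)
  if (!positive_class %in% lab) stop("positive_class not present in labels")
  if (length(unique(lab)) < 2) stop("both classes must be present")
  y01 <- as.integer(lab == positive_class)
  flipped <- FALSE
  auc <- auc_mw(score, y01)
  if (auto_direction && auc < 0.5) {
    score <- -score
    auc <- auc_mw(score, y01)
    flipped <- TRUE
  }
  th <- c(Inf, sort(unique(score), decreasing = TRUE), -Inf)
  curve <- do.call(rbind, lapply(th, function(t) {
    pred <- score >= t
    data.frame(threshold = t,
               sensitivity = sum(pred & y01 == 1) / sum(y01 == 1),
               specificity = sum(!pred & y01 == 0) / sum(y01 == 0))
  }))
  structure(list(auc = auc, curve = curve, positive_class = positive_class,
                 flipped = flipped),
            class = "roc_result")
}

#' Hedges' g standardized mean difference
#'
#' `d = (mean_case - mean_ctrl) / s_pooled`, corrected for small-sample bias
#' by `J = 1 - 3 / (4 df - 1)` with `df = n_case + n_ctrl - 2`; the
#' sampling variance is
#' `(n_case + n_ctrl) / (n_case * n_ctrl) + g^2 / (2 (n_case + n_ctrl))`.
#'
#' @param case,ctrl numeric vectors of per-sample values (each length >= 2).
#' @return list with `g`, `var_g`, `n_case`, `n_ctrl`.
#' @export
hedges_g <- function(case, ctrl) {
  n1 <- length(case); n2 <- length(ctrl)
  stopifnot(n1 >= 2, n2 >= 2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(case) + (n2 - 1) * stats::var(ctrl)) / df
  if (sp2 == 0) stop("zero pooled variance; standardized difference undefined")
  d <- (mean(case) - mean(ctrl)) / sqrt(sp2)
  j <- 1 - 3 / (4 * df - 1)
  g <- j * d
  list(g = g, var_g = (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2)),
       n_case = n1, n_ctrl = n2)
}

#' DerSimonian-Laird random-effects pooling of standardized mean differences
#'
#' Fixed-effect weights `w_i = 1 / var_i` give the heterogeneity statistic
#' `Q = sum w_i (g_i - g_bar)^2`; the between-study variance is
#' `tau2 = max(0, (Q - (k - 1)) / (sum w - sum w^2 / sum w))`; random-effect
#' weights `1 / (var_i + tau2)` give the pooled estimate, a 95% normal CI,
#' and `I2 = max(0, 100 (Q - (k - 1)) / Q)`.
#'
#' @param effects list of effects from [hedges_g()] (each with `g`,
#'   `var_g`), or a data.frame with columns `g` and `var_g`.
#' @return object of class `meta_result`: `pooled_g`, `ci_low`, `ci_high`,
#'   `tau2`, `Q`, `I2`, `se`, `weights` (random-effects, normalized), `k`.
#' @export
pool_random_effects <- function(effects) {
  if (is.data.frame(effects)) {
    g <- effects$g; v <- effects$var_g
  } else {
    g <- vapply(effects, `[[`, 0, "g")
    v <- vapply(effects, `[[`, 0, "var_g")
  }
  k <- length(g)
  if (k == 0) stop("no effects to pool")
  stopifnot(all(v > 0))
  z975 <- stats::qnorm(0.975)
  if (k == 1) {
    se <- sqrt(v)
    return(structure(list(pooled_g = g, ci_low = g - z975 * se,
                          ci_high = g + z975 * se, tau2 = 0, Q = 0, I2 = 0,
                          se = se, weights = 1, k = 1L),
                     class = "meta_result"))
  }
  w <- 1 / v
  gbar <- sum(w * g) / sum(w)
  q <- sum(w * (g - gbar)^2)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (v + tau2)
  pooled <- sum(ws * g) / sum(ws)
  se <- sqrt(1 / sum(ws))
  i2 <- if (q > 0) max(0, 100 * (q - (k - 1)) / q) else 0
  structure(list(pooled_g = pooled, ci_low = pooled - z975 * se,
                 ci_high = pooled + z975 * se, tau2 = tau2, Q = q, I2 = i2,
                 se = se, weights = ws / sum(ws), k = as.integer(k)),
            class = "meta_result")
}

#' Per-cohort gene effects pooled across cohorts
#'
#' Convenience wrapper: computes the Hedges' g of one gene's expression
#' (case vs control) in each cohort and pools the effects by
#' [pool_random_effects()].
#'
#' @param cohorts list of lists, each with `expr` (log2p1 [expr_matrix()])
#'   and `labels` (named group labels with levels ctrl/case order).
#' @param gene gene identifier.
#' @param case label value of the case group (default `"case"`).
#' @return list with `per_cohort` (data.frame) and `pooled` (`meta_result`).
#' @export
meta_analyze_gene <- function(cohorts, gene, case = "case") {
  eff <- lapply(cohorts, function(co) {
    m <- unclass(co$expr)
    if (!gene %in% rownames(m)) stop("gene absent from a cohort: ", gene)
    lab <- as.character(co$labels[colnames(m)])
    hedges_g(m[gene, lab == case], m[gene, lab != case])
  })
  per <- data.frame(cohort = names(eff) %||% seq_along(eff),
                    g = vapply(eff, `[[`, 0, "g"),
                    var_g = vapply(eff, `[[`, 0, "var_g"))
  list(per_cohort = per, pooled = pool_random_effects(eff))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spearman correlation of a target gene with marker genes
#'
#' Two-sided Spearman correlations (average ranks for ties) between the
#' target gene and each marker, with p-values from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` and a significance flag at
#' p < 0.05. Constant markers are reported as `NA` with a warning.
#'
#' @param x an [expr_matrix()].
#' @param target target gene identifier.
#' @param markers character vector of marker gene identifiers.
#' @return data.frame with `marker`, `rho`, `p`, `significant`.
#' @export
marker_correlation <- function(x, target, markers) {
  m <- unclass(x)
  if (!target %in% rownames(m)) stop("target gene not found")
  markers <- intersect(markers, rownames(m))
  if (!length(markers)) stop("no marker gene found in the matrix")
  n <- ncol(m)
  if (n < 4) stop("at least 4 samples required")
  tv <- m[target, ]
  if (stats::sd(tv) == 0) stop("constant target gene")
  res <- lapply(markers, function(mk) {
    mv <- m[mk, ]
    if (stats::sd(mv) == 0) {
      warning("constant marker ", mk, "; correlation undefined")
      return(data.frame(marker = mk, rho = NA_real_, p = NA_real_,
                        significant = NA))
    }
    rho <- stats::cor(tv, mv, method = "spearman")
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    data.frame(marker = mk, rho = rho, p = p, significant = p < 0.05)
  })
  do.call(rbind, res)
}
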