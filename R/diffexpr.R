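#' Two-group differential expression with moderated or Welch t-statistics
#'
#' Tests each gene for a difference in group means on the `log2(x + 1)`
#' scale. The default `"moderated"` method shrinks per-gene pooled variances
#' toward a common prior with an empirical-Bayes posterior
#' `s2_tilde = (d0 * s0^2 + d * s2_g) / (d0 + d)`, where the prior
#' degrees of freedom `d0` and prior variance `s0^2` are estimated by moment
#' matching on the log sample variances; the moderated t is referred to a
#' t-distribution on `d0 + d` degrees of freedom. `"welch"` is the ordinary
#' unequal-variance two-sample t-test.
#'
#' A gene is called `up` when `p < p_threshold` and `log2fc > lfc_threshold`,
#' `down` when `p < p_threshold` and `log2fc < -lfc_threshold`, otherwise
#' `ns`. The fold-change threshold default 0.585 = log2(1.5) corresponds to
#' a 1.5-fold change. Calls use the nominal p-value; Benjamini-Hochberg
#' adjusted p-values are reported alongside.
#'
#' @param x an [expr_matrix()] with `scale = "log2p1"`.
#' @param labels group labels per sample (two groups, each with >= 2
#'   samples); the first factor level is the reference (control).
#' @param p_threshold nominal p-value cutoff for calls.
#' @param lfc_threshold |log2 fold change| cutoff for calls.
#' @param method `"moderated"` (empirical-Bayes) or `"welch"`.
#' @param case optional label value to treat as the case group.
#' @return data.frame with columns `gene`, `log2fc` (case minus control
#'   mean), `stat`, `p`, `p_adj`, `call`.
#' @export
deg_test <- function(x, labels, p_threshold = 0.05, lfc_threshold = 0.585,
                     method = c("moderated", "welch"), case = NULL) {
  method <- match.arg(method)
  if (expr_scale(x) != "log2p1") {
    stop("deg_test expects a log2(x+1)-scale matrix; apply to_log2p1() first")
  }
  f <- align_labels(x, labels, case = case)
  grp2 <- levels(f)[2L]  # case
  i2 <- which(f == grp2); i1 <- which(f != grp2)
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  m <- unclass(x)
  m1 <- rowMeans(m[, i1, drop = FALSE]); m2 <- rowMeans(m[, i2, drop = FALSE])
  v1 <- apply(m[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(m[, i2, drop = FALSE], 1, stats::var)
  lfc <- m2 - m1

  if (method == "moderated") {
    d <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
    eb <- squeeze_var(s2, d)
    se <- sqrt(eb$var_post * (1 / n1 + 1 / n2))
    stat <- lfc / se
    df_total <- eb$df_prior + d
    p <- 2 * stats::pt(-abs(stat), df = df_total)
  } else {
    se2 <- v1 / n1 + v2 / n2
    stat <- lfc / sqrt(se2)
    df_w <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(stat), df = df_w)
    zero <- se2 == 0
    if (any(zero)) {
      warning(sum(zero), " zero-variance gene(s) under welch; p set to 1")
      stat[zero] <- 0
      p[zero] <- 1
    }
  }
  p_adj <- stats::p.adjust(p, method = "BH")
  call <- rep("ns", nrow(m))
  call[p < p_threshold & lfc > lfc_threshold] <- "up"
  call[p < p_threshold & lfc < -lfc_threshold] <- "down"
  data.frame(gene = rownames(m), log2fc = lfc, stat = stat, p = p,
             p_adj = p_adj, call = call, stringsAsFactors = FALSE)
}

#' Empirical-Bayes squeezing of per-gene sample variances
#'
#' Moment matching on `log(s2)`: with `e_g = log(s2_g) - digamma(d/2) +
#' log(d/2)`, the excess of `var(e_g)` over `trigamma(d/2)` identifies the
#' prior degrees of freedom through `trigamma(d0/2)`, and `mean(e_g)` then
#' identifies the prior variance. Posterior variances are the weighted
#' combination `(d0 * s0^2 + d * s2_g) / (d0 + d)`.
#'
#' @param s2 per-gene sample variances (pooled within groups).
#' @param df residual degrees of freedom of each `s2` (scalar).
#' @return list with `var_prior`, `df_prior` (possibly `Inf`), `var_post`.
#' @export
squeeze_var <- function(s2, df) {
  stopifnot(df >= 1, all(s2 >= 0))
  ok <- s2 > 0
  if (sum(ok) < 2) {
    return(list(var_prior = mean(s2), df_prior = 0,
                var_post = s2))
  }
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  ev <- stats::var(e)
  excess <- ev - trigamma(df / 2)
  if (is.na(excess) || excess <= 0) {
    # variances no more dispersed than chi-square sampling alone: infinite
    # prior df, every gene squeezed to the common value
    df_prior <- Inf
    var_prior <- exp(mean(e))
    var_post <- rep(var_prior, length(s2))
  } else {
    df_prior <- 2 * trigamma_inverse(excess)
    var_prior <- exp(mean(e) + digamma(df_prior / 2) - log(df_prior / 2))
    var_post <- (df_prior * var_prior + df * s2) / (df_prior + df)
  }
  list(var_prior = var_prior, df_prior = df_prior, var_post = var_post)
}

# Newton inversion of trigamma on (0, Inf); monotone decreasing.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}
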