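#' Rank genes by a two-group signal-to-noise statistic
#'
#' For each gene, `(mean_case - mean_ctrl) / (sd_case' + sd_ctrl')` where
#' each group standard deviation is floored at
#' `max(0.2 * |group mean|, 0.2)` (the usual stabilization for
#' near-constant genes). Genes are ordered by the statistic, descending,
#' with ties broken by gene identifier.
#'
#' @param x a log2p1-scale [expr_matrix()].
#' @param labels group labels per sample (first level = control).
#' @param case optional label value of the case group.
#' @return object of class `ranked_list`: data.frame `gene`, `stat` in rank
#'   order, with attribute `ranking_mode = "group_stat"`.
#' @export
rank_by_group_statistic <- function(x, labels, case = NULL) {
  f <- align_labels(x, labels, case = case)
  i2 <- f == levels(f)[2L]
  if (sum(i2) < 2 || sum(!i2) < 2) stop("each group needs at least 2 samples")
  m <- unclass(x)
  m1 <- rowMeans(m[, !i2, drop = FALSE]); m2 <- rowMeans(m[, i2, drop = FALSE])
  s1 <- apply(m[, !i2, drop = FALSE], 1, stats::sd)
  s2 <- apply(m[, i2, drop = FALSE], 1, stats::sd)
  s1 <- pmax(s1, 0.2 * abs(m1), 0.2)
  s2 <- pmax(s2, 0.2 * abs(m2), 0.2)
  stat <- (m2 - m1) / (s1 + s2)
  ord <- order(-stat, rownames(m))
  structure(data.frame(gene = rownames(m)[ord], stat = stat[ord],
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("ranked_list", "data.frame"),
            ranking_mode = "group_stat")
}

#' Rank genes by Spearman correlation with a target gene
#'
#' Linear-scale expression is floored at `log_floor` before log2
#' transformation (truncating minimal values avoids undefined logs), then
#' every other gene's Spearman correlation with the target across samples
#' is computed; genes are ordered by correlation, descending, the target
#' itself excluded.
#'
#' @param x a linear-scale [expr_matrix()].
#' @param target target gene identifier.
#' @param log_floor truncation level on the linear scale (default 1e-3).
#' @return a `ranked_list` (attribute `ranking_mode =
#'   "spearman_to_target"`).
#' @export
rank_by_target_correlation <- function(x, target, log_floor = 1e-3) {
  if (expr_scale(x) != "linear") stop("expects linear-scale values (log applied internally)")
  m <- unclass(x)
  if (!target %in% rownames(m)) stop("target gene not found")
  if (ncol(m) < 4) stop("at least 4 samples required")
  lg <- log2(pmax(m, log_floor))
  tv <- lg[target, ]
  if (stats::sd(tv) == 0) stop("constant target gene")
  others <- setdiff(rownames(lg), target)
  rho <- apply(lg[others, , drop = FALSE], 1,
               function(v) stats::cor(tv, v, method = "spearman"))
  rho[is.na(rho)] <- 0  # constant genes carry no association
  ord <- order(-rho, others)
  structure(data.frame(gene = others[ord], stat = rho[ord],
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("ranked_list", "data.frame"),
            ranking_mode = "spearman_to_target")
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list accumulating `P_hit` (set members, weighted by
#' `|stat|^weight_p` and normalized) against `P_miss` (non-members, uniform);
#' the enrichment score is the signed maximum deviation of
#' `P_hit - P_miss`. With `weight_p = 0` this is the classic unweighted KS
#' statistic. The leading edge contains the set members at or before a
#' positive extremum (at or after a negative one).
#'
#' @param ranked a `ranked_list` (or data.frame with `gene` and `stat`).
#' @param gene_set character vector; must share at least one gene with the
#'   list and not cover it entirely.
#' @param weight_p weighting exponent (default 1).
#' @return list with `es`, `running` (deviation per position),
#'   `hit_positions`, `leading_edge`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  genes <- ranked$gene
  stat <- ranked$stat
  n <- length(genes)
  hit <- genes %in% gene_set
  nh <- sum(hit)
  if (nh == 0) stop("gene set has no gene in the ranked list")
  if (nh == n) stop("gene set covers the whole ranked list")
  w <- abs(stat)^weight_p
  w[!hit] <- 0
  if (sum(w) == 0) w[hit] <- 1  # all member stats zero: fall back to equal mass
  p_hit <- cumsum(w) / sum(w)
  p_miss <- cumsum(!hit) / (n - nh)
  running <- p_hit - p_miss
  stopifnot(abs(running[n]) < 1e-9)  # conservation: both CDFs end at 1
  i_ext <- which.max(abs(running))
  es <- running[i_ext]
  leading <- if (es >= 0) genes[hit & seq_len(n) <= i_ext] else
    genes[hit & seq_len(n) >= i_ext]
  list(es = es, running = running, hit_positions = which(hit),
       leading_edge = leading)
}

#' Permutation significance for gene-set enrichment
#'
#' For each set, the null distribution of the enrichment score is built by
#' gene-label permutation: resampling `|S|` genes without replacement from
#' the ranked universe and recomputing the score (statistics keep their
#' positions). The one-sided permutation p uses the same-sign null scores
#' with an add-one correction; NES is the score divided by the mean
#' magnitude of same-sign null scores; q is the GSEA-style FDR — the
#' fraction of pooled same-sign null NES at least as extreme, divided by
#' the fraction of observed same-sign NES at least as extreme, capped at 1.
#'
#' @param ranked a `ranked_list`.
#' @param gene_sets named list of character vectors.
#' @param n_permutations permutations per set (default 1000; fewer than 100
#'   triggers a warning).
#' @param weight_p weighting exponent passed to [enrichment_score()].
#' @param seed integer seed.
#' @return data.frame per set: `set`, `size`, `es`, `nes`, `p_perm`, `q`,
#'   `leading_edge` (comma-separated).
#' @export
gsea_significance <- function(ranked, gene_sets, n_permutations = 1000,
                              weight_p = 1, seed = 1) {
  if (n_permutations < 100) warning("fewer than 100 permutations; p-values are coarse")
  genes <- ranked$gene
  n <- length(genes)
  keep <- vapply(gene_sets, function(s) {
    k <- sum(genes %in% s)
    k >= 2 && k < n
  }, TRUE)
  if (any(!keep)) {
    warning("skipping sets with < 2 matched genes (or full coverage): ",
            paste(names(gene_sets)[!keep], collapse = ", "))
  }
  gene_sets <- gene_sets[keep]
  if (!length(gene_sets)) stop("no valid gene set")

  set.seed(seed)
  res <- lapply(names(gene_sets), function(nmset) {
    s <- gene_sets[[nmset]]
    obs <- enrichment_score(ranked, s, weight_p)
    k <- length(obs$hit_positions)
    null_es <- vapply(seq_len(n_permutations), function(b) {
      enrichment_score(ranked, sample(genes, k), weight_p)$es
    }, 0)
    same <- if (obs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
    denom <- mean(abs(same))
    nes <- if (length(same) && denom > 0) obs$es / denom else NA_real_
    null_nes <- if (length(same) && denom > 0) same / denom else numeric(0)
    list(set = nmset, size = k, es = obs$es, nes = nes, p_perm = p,
         null_nes = null_nes,
         leading_edge = paste(obs$leading_edge, collapse = ","))
  })

  nes_obs <- vapply(res, function(r) r$nes, 0)
  pooled <- unlist(lapply(res, `[[`, "null_nes"))
  q <- vapply(seq_along(res), function(i) {
    v <- nes_obs[i]
    if (is.na(v)) return(NA_real_)
    same_null <- pooled[sign(pooled) == sign(v)]
    same_obs <- nes_obs[!is.na(nes_obs) & sign(nes_obs) == sign(v)]
    num <- if (length(same_null)) mean(abs(same_null) >= abs(v)) else 0
    den <- mean(abs(same_obs) >= abs(v))
    min(1, num / max(den, .Machine$double.eps))
  }, 0)

  data.frame(set = vapply(res, `[[`, "", "set"),
             size = vapply(res, `[[`, 0L, "size"),
             es = vapply(res, `[[`, 0, "es"),
             nes = nes_obs,
             p_perm = vapply(res, `[[`, 0, "p_perm"),
             q = q,
             leading_edge = vapply(res, `[[`, "", "leading_edge"),
             stringsAsFactors = FALSE)
}
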