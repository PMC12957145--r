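# Independent brute-force oracles used across tests. These deliberately
# re-derive each quantity from its definition, not from the package code.

# exhaustive Mann-Whitney AUC by pair counting
oracle_auc <- function(score, y01) {
  pos <- score[y01 == 1]; neg <- score[y01 == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# element-wise TOM formula
oracle_tom <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# Spearman rho: average ranks then Pearson
oracle_spearman <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

# weighted KS enrichment score by explicit running sum
oracle_es <- function(genes, stat, set, p = 1) {
  n <- length(genes)
  hit <- genes %in% set
  nr <- sum(abs(stat[hit])^p)
  run <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    cur <- cur + if (hit[i]) abs(stat[i])^p / nr else -1 / (n - sum(hit))
    run[i] <- cur
  }
  run[which.max(abs(run))]
}

# small deterministic expression fixture (genes x samples, linear scale)
toy_expr <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  expr_matrix(m, "linear")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
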