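#' Fold change of a gene between groups within one cell type
#'
#' Ratio of group means of the gene's (linear-scale, normalized) expression
#' within the stated cell type, regularized with a pseudocount:
#' `(mean_a + eps) / (mean_b + eps)`, `eps = 1e-6`; significance by
#' Wilcoxon rank-sum.
#'
#' @param cells data.frame with at least `celltype`, `group`, and the gene
#'   column (see [make_cell_population()]).
#' @param gene gene column name.
#' @param celltype cell-type annotation to subset to.
#' @param group_a,group_b group labels (fold change is a over b).
#' @param eps pseudocount (default 1e-6).
#' @return list with `fold_change`, `p`, `n_a`, `n_b`.
#' @export
celltype_fold_change <- function(cells, gene, celltype, group_a, group_b,
                                 eps = 1e-6) {
  if (!celltype %in% cells$celltype) stop("cell type not found: ", celltype)
  sub <- cells[cells$celltype == celltype, ]
  a <- sub[[gene]][sub$group == group_a]
  b <- sub[[gene]][sub$group == group_b]
  if (length(a) < 10 || length(b) < 10) {
    stop("at least 10 cells per group required within the cell type")
  }
  p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
  list(fold_change = (mean(a) + eps) / (mean(b) + eps), p = p,
       n_a = length(a), n_b = length(b))
}

#' Smoothed expression profile along pseudotime
#'
#' Sorts cells by pseudotime and applies a sliding-window mean of
#' `max(5, round(window_fraction * n))` cells, returning the window
#' pseudotime midpoints and mean expression.
#'
#' @param cells cell table with `pseudotime` and the gene column.
#' @param gene gene column name.
#' @param window_fraction window size as a fraction of the cells (default
#'   0.1).
#' @return data.frame with `pseudotime` and `mean_expression`.
#' @export
pseudotime_profile <- function(cells, gene, window_fraction = 0.1) {
  ok <- !is.na(cells$pseudotime)
  sub <- cells[ok, ]
  n <- nrow(sub)
  if (n < 50) stop("at least 50 cells with pseudotime required")
  ord <- order(sub$pseudotime)
  pt <- sub$pseudotime[ord]
  ex <- sub[[gene]][ord]
  w <- max(5L, round_half_up(window_fraction * n))
  if (w > n) {
    warning("window larger than the number of cells; returning the global mean")
    return(data.frame(pseudotime = mean(pt), mean_expression = mean(ex)))
  }
  starts <- seq_len(n - w + 1L)
  data.frame(
    pseudotime = vapply(starts, function(i) mean(pt[i:(i + w - 1L)]), 0),
    mean_expression = vapply(starts, function(i) mean(ex[i:(i + w - 1L)]), 0))
}

#' Stratify cells into high/low expression groups
#'
#' Ranks cells by the gene's expression and assigns the top
#' `round(upper * n)` to the high stratum and the bottom
#' `round(lower * n)` to the low stratum (defaults 40%/40%); intermediate
#' cells are excluded to sharpen group separation. Ties at a boundary are
#' resolved by stable cell-id order and counted in a message.
#'
#' @param cells cell table with `cell_id` and the gene column.
#' @param gene gene column name.
#' @param upper,lower quantile fractions (upper + lower <= 1).
#' @return object of class `strata_assignment`: data.frame `cell_id`,
#'   `stratum` (high/low/excluded) plus attributes `upper`, `lower`.
#' @export
stratify_by_expression <- function(cells, gene, upper = 0.40, lower = 0.40) {
  stopifnot(upper > 0, lower > 0, upper + lower <= 1 + 1e-12)
  n <- nrow(cells)
  if (n < 10) stop("at least 10 cells required")
  ex <- cells[[gene]]
  if (length(unique(ex)) == 1L) stop("all expression values equal; stratification is meaningless")
  n_hi <- round_half_up(upper * n)
  n_lo <- min(round_half_up(lower * n), n - n_hi)
  ord <- order(-ex, cells$cell_id)  # descending expression, stable by id
  exo <- ex[ord]
  ties <- sum(exo[n_hi] == exo[n_hi + 1L], exo[n - n_lo] == exo[n - n_lo + 1L])
  if (ties > 0) message(ties, " boundary tie(s) resolved by cell-id order")
  stratum <- rep("excluded", n)
  stratum[ord[seq_len(n_hi)]] <- "high"
  stratum[ord[seq.int(n - n_lo + 1L, n)]] <- "low"
  structure(data.frame(cell_id = cells$cell_id, stratum = stratum,
                       stringsAsFactors = FALSE),
            class = c("strata_assignment", "data.frame"),
            upper = upper, lower = lower, gene = gene)
}

#' Differential expression between expression strata
#'
#' For each gene, compares high vs low cells by Wilcoxon rank-sum with
#' `log2FC = log2((mean_high + eps) / (mean_low + eps))`, `eps = 1e-6`, and
#' calls up/down/ns under the usual thresholds. When `by_group` is set, the
#' analysis is repeated separately within each disease group. A gene that
#' is zero in every cell is skipped with a warning; the stratifying gene
#' itself is flagged (`self = TRUE`), since its call is guaranteed by
#' construction.
#'
#' @param cells cell table.
#' @param assignment a `strata_assignment` from [stratify_by_expression()].
#' @param genes gene column names to test.
#' @param p_threshold,lfc_threshold call thresholds (defaults 0.05, 0.585).
#' @param eps pseudocount (default 1e-6).
#' @param by_group when `TRUE`, results are computed per `group` level.
#' @return data.frame with `group` (or `"all"`), `gene`, `log2fc`, `p`,
#'   `p_adj`, `call`, `self`.
#' @export
strata_differential_expression <- function(cells, assignment, genes,
                                           p_threshold = 0.05,
                                           lfc_threshold = 0.585,
                                           eps = 1e-6, by_group = FALSE) {
  stopifnot(inherits(assignment, "strata_assignment"))
  strat <- assignment$stratum[match(cells$cell_id, assignment$cell_id)]
  self_gene <- attr(assignment, "gene")
  chunks <- if (by_group) split(seq_len(nrow(cells)), cells$group) else
    list(all = seq_len(nrow(cells)))
  out <- list()
  for (grp in names(chunks)) {
    idx <- chunks[[grp]]
    hi <- idx[strat[idx] == "high"]
    lo <- idx[strat[idx] == "low"]
    if (!length(hi) || !length(lo)) stop("a stratum is empty within group ", grp)
    rows <- lapply(genes, function(g) {
      a <- cells[[g]][hi]; b <- cells[[g]][lo]
      if (all(a == 0) && all(b == 0)) {
        warning("gene ", g, " zero in all cells; skipped")
        return(NULL)
      }
      p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
      lfc <- log2((mean(a) + eps) / (mean(b) + eps))
      data.frame(group = grp, gene = g, log2fc = lfc, p = p,
                 self = identical(g, self_gene), stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab)) next
    tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
    tab$call <- "ns"
    tab$call[tab$p < p_threshold & tab$log2fc > lfc_threshold] <- "up"
    tab$call[tab$p < p_threshold & tab$log2fc < -lfc_threshold] <- "down"
    out[[grp]] <- tab[, c("group", "gene", "log2fc", "p", "p_adj", "call", "self")]
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
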