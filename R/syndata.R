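#' Specification of a synthetic case/control bulk cohort
#'
#' Describes a two-group bulk expression cohort generated on the log2 scale:
#' per-gene baseline means, optional co-expression modules driven by shared
#' latent factors, planted differential genes shifted between groups, and
#' Gaussian noise. Values are back-transformed to the linear scale via
#' `2^x - 1` so that the downstream `log2(x + 1)` transform inverts the
#' generator exactly (up to truncation at zero).
#'
#' @param n_genes number of genes.
#' @param n_case,n_ctrl samples per group (each at least 2).
#' @param de_fraction fraction of genes planted as differential.
#' @param lfc_mean target |log2 fold change| for planted genes (case minus
#'   control on the log2 scale); up/down split evenly.
#' @param de_lfc optional vector of per-gene |log2FC| values for the planted
#'   genes (recycled); overrides `lfc_mean` to let effect sizes differ.
#' @param de_genes optional integer indices of the genes to plant as
#'   differential (overrides `de_fraction` sampling; useful to place
#'   differential genes inside a module).
#' @param module_spec list of modules, each a list with `size`, `loading`
#'   (latent-factor coefficient on the log2 scale), and optional
#'   `trait_shift` added to the module factor in case samples.
#' @param noise_sd standard deviation of log2-scale Gaussian noise.
#' @param seed integer seed; generation is bit-reproducible given the spec.
#' @return object of class `bulk_cohort_spec`.
#' @export
bulk_cohort_spec <- function(n_genes, n_case, n_ctrl, de_fraction = 0,
                             lfc_mean = 1, de_lfc = NULL, de_genes = NULL,
                             module_spec = list(), noise_sd = 0.3, seed = 1) {
  stopifnot(n_genes >= 1, n_case >= 2, n_ctrl >= 2,
            de_fraction >= 0, de_fraction <= 1, noise_sd >= 0, lfc_mean >= 0)
  if (!is.null(de_genes)) stopifnot(all(de_genes >= 1), all(de_genes <= n_genes))
  sizes <- vapply(module_spec, function(m) as.integer(m$size), 0L)
  if (length(sizes) && sum(sizes) > n_genes) {
    stop("module sizes exceed the number of genes")
  }
  structure(list(n_genes = as.integer(n_genes), n_case = as.integer(n_case),
                 n_ctrl = as.integer(n_ctrl), de_fraction = de_fraction,
                 lfc_mean = lfc_mean, de_lfc = de_lfc,
                 de_genes = if (is.null(de_genes)) NULL else as.integer(de_genes),
                 module_spec = module_spec, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "bulk_cohort_spec")
}

#' Default modular cohort used throughout the co-expression examples
#'
#' Five planted modules of 60 genes (latent-factor loading 0.9) among 2000
#' genes, 30 cases and 30 controls, log2-scale noise 0.3. This is the
#' reference configuration for the soft-threshold selection checks.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [bulk_cohort_spec()].
#' @return a `bulk_cohort_spec`.
#' @export
modular_cohort_spec <- function(seed = 1, ...) {
  args <- list(n_genes = 2000, n_case = 30, n_ctrl = 30, de_fraction = 0,
               module_spec = replicate(5, list(size = 60, loading = 0.9),
                                       simplify = FALSE),
               noise_sd = 0.3, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(bulk_cohort_spec, args)
}

#' Generate a synthetic bulk cohort
#'
#' On the log2 scale each value is
#' `baseline(gene) + loading * factor(module, sample) + shift(gene, group) +
#' noise`, where the module factor is a shared standard-normal draw per
#' sample and planted differential genes receive a group-mean shift of
#' `+lfc` (up genes, case samples) or `-lfc` (down genes). Values are
#' returned on the linear scale as `pmax(2^x - 1, 0)`.
#'
#' @param spec a [bulk_cohort_spec()].
#' @return list with `expr` (linear-scale [expr_matrix()]), `labels` (named
#'   vector, `"ctrl"`/`"case"`), and `truth`: `de` (data.frame gene,
#'   direction, lfc) and `modules` (data.frame gene, module; 0 = background).
#' @export
make_bulk_cohort <- function(spec) {
  stopifnot(inherits(spec, "bulk_cohort_spec"))
  set.seed(spec$seed)
  ng <- spec$n_genes
  n <- spec$n_case + spec$n_ctrl
  genes <- sprintf("g%04d", seq_len(ng))
  samples <- c(sprintf("case%02d", seq_len(spec$n_case)),
               sprintf("ctrl%02d", seq_len(spec$n_ctrl)))
  is_case <- c(rep(TRUE, spec$n_case), rep(FALSE, spec$n_ctrl))

  baseline <- stats::runif(ng, 3, 8)
  x <- matrix(baseline, ng, n)

  module_of <- integer(ng)
  pos <- 1L
  for (m in seq_along(spec$module_spec)) {
    ms <- spec$module_spec[[m]]
    idx <- seq.int(pos, pos + ms$size - 1L)
    pos <- pos + as.integer(ms$size)
    module_of[idx] <- m
    fac <- stats::rnorm(n)
    shift <- if (is.null(ms$trait_shift)) 0 else ms$trait_shift
    fac <- fac + shift * as.numeric(is_case)
    x[idx, ] <- x[idx, ] + ms$loading * rep(fac, each = length(idx))
  }

  n_de <- if (!is.null(spec$de_genes)) length(spec$de_genes) else
    round(spec$de_fraction * ng)
  de <- data.frame(gene = character(0), direction = character(0),
                   lfc = numeric(0), stringsAsFactors = FALSE)
  if (n_de > 0) {
    de_idx <- if (!is.null(spec$de_genes)) spec$de_genes else sample.int(ng, n_de)
    dir_up <- rep(c(TRUE, FALSE), length.out = n_de)
    lfc <- if (is.null(spec$de_lfc)) rep(spec$lfc_mean, n_de) else
      rep_len(spec$de_lfc, n_de)
    signed <- ifelse(dir_up, lfc, -lfc)
    x[de_idx, is_case] <- x[de_idx, is_case] + signed
    de <- data.frame(gene = genes[de_idx],
                     direction = ifelse(dir_up, "up", "down"),
                     lfc = signed, stringsAsFactors = FALSE)
  }

  if (spec$noise_sd > 0) x <- x + stats::rnorm(ng * n, sd = spec$noise_sd)

  lin <- pmax(2^x - 1, 0)
  dimnames(lin) <- list(genes, samples)
  list(expr = expr_matrix(lin, "linear"),
       labels = stats::setNames(ifelse(is_case, "case", "ctrl"), samples),
       truth = list(de = de,
                    modules = data.frame(gene = genes, module = module_of,
                                         stringsAsFactors = FALSE)))
}

#' Specification of a synthetic cell-mixture cohort
#'
#' @param signature genes x cell-types nonnegative reference matrix with
#'   dimnames.
#' @param fractions_truth samples x cell-types nonnegative weights; each row
#'   must sum to 1.
#' @param noise_sd additive Gaussian noise on the mixed linear values.
#' @param seed integer seed.
#' @return object of class `mixture_spec`.
#' @export
mixture_spec <- function(signature, fractions_truth, noise_sd = 0, seed = 1) {
  stopifnot(is.matrix(signature), ncol(signature) >= 2, all(signature >= 0))
  if (any(fractions_truth < 0)) stop("truth fractions must be nonnegative")
  rs <- rowSums(fractions_truth)
  if (any(abs(rs - 1) > 1e-8)) stop("each truth-fraction row must sum to 1")
  if (!identical(colnames(signature), colnames(fractions_truth))) {
    stop("signature and truth cell-type names must match")
  }
  structure(list(signature = signature, fractions_truth = fractions_truth,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "mixture_spec")
}

#' Generate bulk samples as noisy mixtures of reference cell profiles
#'
#' Each sample column is `signature %*% truth_fractions + noise`, truncated
#' at zero, emulating what a reference-signature deconvolution should invert.
#'
#' @param spec a [mixture_spec()].
#' @return list with `expr` (linear [expr_matrix()]) and `truth` fractions.
#' @export
make_mixture_cohort <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  set.seed(spec$seed)
  mixed <- spec$signature %*% t(spec$fractions_truth)
  if (spec$noise_sd > 0) {
    mixed <- mixed + stats::rnorm(length(mixed), sd = spec$noise_sd)
  }
  mixed <- pmax(mixed, 0)
  colnames(mixed) <- rownames(spec$fractions_truth)
  list(expr = expr_matrix(mixed, "linear"), truth = spec$fractions_truth)
}

#' Random block-structured reference signature for tests and simulations
#'
#' Each cell type gets a block of marker genes with high expression on a low
#' shared background, guaranteeing the pairwise-distinguishability the
#' deconvolution step requires.
#'
#' @param n_markers marker genes per cell type.
#' @param celltypes character vector of cell-type names.
#' @param marker_high,background expression level of markers / background.
#' @param seed integer seed.
#' @return genes x cell-types matrix.
#' @export
make_signature <- function(n_markers = 20, celltypes = paste0("ct", 1:5),
                           marker_high = 100, background = 5, seed = 1) {
  set.seed(seed)
  k <- length(celltypes)
  ng <- n_markers * k
  sig <- matrix(stats::runif(ng * k, 0.5 * background, 1.5 * background), ng, k)
  for (j in seq_len(k)) {
    idx <- seq.int((j - 1L) * n_markers + 1L, j * n_markers)
    sig[idx, j] <- stats::runif(n_markers, 0.5 * marker_high, 1.5 * marker_high)
  }
  dimnames(sig) <- list(sprintf("mk%03d", seq_len(ng)), celltypes)
  sig
}

#' Generate a trained-immunity differential signature overlapping cohort DEGs
#'
#' Emulates the external macrophage-training signature: up/down gene lists
#' sharing exactly `overlap_count` genes with the cohort's planted
#' differential genes (matching direction), plus `extra_count` genes disjoint
#' from the cohort truth.
#'
#' @param cohort_truth the `truth$de` data.frame from [make_bulk_cohort()].
#' @param overlap_count genes shared with the cohort truth.
#' @param extra_count additional genes absent from the cohort truth; drawn
#'   from `universe` minus the truth set, extended with invented identifiers
#'   if the universe is too small.
#' @param universe character vector of candidate gene identifiers.
#' @param seed integer seed.
#' @return list with `up` and `down` character vectors.
#' @export
make_trained_signature <- function(cohort_truth, overlap_count, extra_count,
                                   universe, seed = 1) {
  stopifnot(overlap_count >= 0, extra_count >= 0)
  if (overlap_count > nrow(cohort_truth)) {
    stop("overlap_count exceeds the number of planted cohort DE genes")
  }
  set.seed(seed)
  ov <- if (overlap_count > 0) {
    cohort_truth[sample.int(nrow(cohort_truth), overlap_count), ]
  } else cohort_truth[0, ]
  pool <- setdiff(universe, cohort_truth$gene)
  if (extra_count > length(pool)) {
    pool <- c(pool, sprintf("xg%04d", seq_len(extra_count - length(pool))))
  }
  extra <- if (extra_count > 0) sample(pool, extra_count) else character(0)
  half <- length(extra) %/% 2L
  list(up = sort(c(ov$gene[ov$direction == "up"], utils::head(extra, half))),
       down = sort(c(ov$gene[ov$direction == "down"],
                     utils::tail(extra, length(extra) - half))))
}

#' Specification of a synthetic annotated cell population
#'
#' Emulates a pseudotime-ordered macrophage population: per-cell target-gene
#' expression follows a monotone trend in pseudotime with optional per-group
#' scaling (e.g. a 2-fold higher plateau in disease), Gaussian noise, and
#' dropout zeroing.
#'
#' @param n_cells number of cells.
#' @param groups per-cell disease label (recycled).
#' @param celltypes per-cell annotation (recycled).
#' @param pseudotime_truth per-cell pseudotime in \[0, 1\]; drawn uniformly
#'   when `NULL`.
#' @param target_gene name of the focal gene column.
#' @param trend function mapping pseudotime in \[0, 1\] to expected
#'   expression on the (nonnegative) normalized scale.
#' @param group_scale named multiplier of the trend per group (default 1).
#' @param noise_sd additive noise standard deviation.
#' @param dropout_rate probability a value is zeroed, in \[0, 1).
#' @param n_null_genes independent nuisance genes (no link to the target).
#' @param n_linked_genes genes generated as `0.8 * target + noise`.
#' @param seed integer seed.
#' @return object of class `cell_population_spec`.
#' @export
cell_population_spec <- function(n_cells, groups = "disease",
                                 celltypes = "macrophage",
                                 pseudotime_truth = NULL,
                                 target_gene = "MT1",
                                 trend = function(t) 2 + 3 * t,
                                 group_scale = NULL, noise_sd = 0.2,
                                 dropout_rate = 0, n_null_genes = 0,
                                 n_linked_genes = 0, seed = 1) {
  stopifnot(n_cells >= 1, dropout_rate >= 0, dropout_rate < 1, noise_sd >= 0)
  if (!is.null(pseudotime_truth)) {
    stopifnot(length(pseudotime_truth) == n_cells,
              all(pseudotime_truth >= 0 & pseudotime_truth <= 1))
  }
  structure(list(n_cells = as.integer(n_cells),
                 groups = rep_len(as.character(groups), n_cells),
                 celltypes = rep_len(as.character(celltypes), n_cells),
                 pseudotime_truth = pseudotime_truth,
                 target_gene = target_gene, trend = trend,
                 group_scale = group_scale, noise_sd = noise_sd,
                 dropout_rate = dropout_rate,
                 n_null_genes = as.integer(n_null_genes),
                 n_linked_genes = as.integer(n_linked_genes),
                 seed = as.integer(seed)),
            class = "cell_population_spec")
}

#' Generate a synthetic cell table
#'
#' @param spec a [cell_population_spec()].
#' @return data.frame with columns `cell_id`, `celltype`, `group`,
#'   `pseudotime`, the target gene, and any nuisance/linked gene columns.
#' @export
make_cell_population <- function(spec) {
  stopifnot(inherits(spec, "cell_population_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells
  pt <- if (is.null(spec$pseudotime_truth)) stats::runif(n) else spec$pseudotime_truth
  scale <- rep(1, n)
  if (!is.null(spec$group_scale)) {
    miss <- setdiff(unique(spec$groups), names(spec$group_scale))
    if (length(miss)) stop("group_scale missing groups: ", paste(miss, collapse = ", "))
    scale <- unname(spec$group_scale[spec$groups])
  }
  expr <- spec$trend(pt) * scale
  if (spec$noise_sd > 0) expr <- expr + stats::rnorm(n, sd = spec$noise_sd)
  expr <- pmax(expr, 0)
  if (spec$dropout_rate > 0) {
    expr[stats::runif(n) < spec$dropout_rate] <- 0
  }
  out <- data.frame(cell_id = sprintf("c%05d", seq_len(n)),
                    celltype = spec$celltypes, group = spec$groups,
                    pseudotime = pt, stringsAsFactors = FALSE)
  out[[spec$target_gene]] <- expr
  if (spec$n_null_genes > 0) {
    for (j in seq_len(spec$n_null_genes)) {
      out[[sprintf("null%02d", j)]] <- pmax(stats::rnorm(n, 2, 1), 0)
    }
  }
  if (spec$n_linked_genes > 0) {
    for (j in seq_len(spec$n_linked_genes)) {
      out[[sprintf("linked%02d", j)]] <-
        pmax(0.8 * expr + stats::rnorm(n, sd = spec$noise_sd + 0.05), 0)
    }
  }
  out
}
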