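#' Keep the most variable genes
#'
#' Retains the `ceiling(keep_fraction * n_genes)` genes of highest
#' across-sample variance (the usual pre-filter before network
#' construction; the default keeps the top 25%). Ties are broken by gene
#' identifier order.
#'
#' @param x an [expr_matrix()].
#' @param keep_fraction fraction of genes to keep, in (0, 1].
#' @return an [expr_matrix()] restricted to the retained genes, in their
#'   original row order.
#' @export
variance_filter <- function(x, keep_fraction = 0.25) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  m <- unclass(x)
  n_keep <- ceiling(keep_fraction * nrow(m))
  if (n_keep < 1) stop("variance filter would retain no genes")
  v <- apply(m, 1, stats::var)
  ord <- order(-v, rownames(m))
  keep <- sort(ord[seq_len(n_keep)])
  expr_matrix(m[keep, , drop = FALSE], expr_scale(x))
}

#' Unsigned soft-threshold adjacency
#'
#' `a_ij = |cor(gene_i, gene_j)|^power` with zero diagonal (self-adjacency
#' is excluded from connectivity).
#'
#' @param x an [expr_matrix()] (genes x samples).
#' @param power soft-thresholding exponent (beta).
#' @return symmetric genes x genes adjacency matrix in \[0, 1\].
#' @export
adjacency_matrix <- function(x, power) {
  stopifnot(power >= 1)
  r <- stats::cor(t(unclass(x)))
  if (any(is.na(r))) stop("constant genes produce undefined correlations; filter first")
  a <- abs(r)^power
  diag(a) <- 0
  a
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the connectivities into `n_bins` equal-count bins, estimates the
#' frequency density of each bin as `count / (N * width)` — where the width
#' is the range actually spanned by the bin's connectivities, so a bin
#' straddling a sparsely populated stretch of the connectivity axis is not
#' diluted — and regresses `log10(density)` on `log10(mean connectivity)`
#' across bins. The fit index is the signed R-squared,
#' `-sign(slope) * R^2`, so that a power-law-like decay (density falling
#' with connectivity) scores positively.
#'
#' @param k numeric vector of node connectivities.
#' @param n_bins number of equal-count bins.
#' @return list with `fit` (signed R-squared), `slope`, and the per-bin
#'   table used for the regression.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  stopifnot(length(k) >= n_bins)
  breaks <- unique(stats::quantile(k, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 4) {
    stop("connectivities too discrete to bin for the scale-free fit")
  }
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = nlevels(bin))
  width <- as.numeric(tapply(k, bin, function(v) diff(range(v))))
  fallback <- diff(breaks)
  bad <- is.na(width) | width == 0
  width[bad] <- fallback[bad]
  dens <- counts / (length(k) * width)
  kmean <- as.numeric(tapply(k, bin, mean))
  ok <- counts > 0 & is.finite(dens) & dens > 0 & !is.na(kmean) & kmean > 0
  if (sum(ok) < 3) stop("too few usable bins for the scale-free fit")
  fit <- stats::lm(log10(dens[ok]) ~ log10(kmean[ok]))
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2L])
  list(fit = -sign(slope) * r2, slope = slope,
       bins = data.frame(k_mean = as.numeric(kmean[ok]),
                         density = as.numeric(dens[ok])))
}

#' Select a soft-thresholding power for approximate scale-free topology
#'
#' Scans candidate powers, computing for each the unsigned adjacency, the
#' node connectivities `k_i = sum_j a_ij`, and the signed scale-free fit
#' index of [scale_free_fit()]. The selected power is the smallest one whose
#' fit reaches `r2_target`; if none does, the power with the maximum fit is
#' taken and a message is emitted.
#'
#' @param x an [expr_matrix()] (typically after [variance_filter()]).
#' @param powers integer powers to scan.
#' @param r2_target minimum acceptable signed R-squared (default 0.90).
#' @param n_bins bins for [scale_free_fit()].
#' @return object of class `soft_threshold`: list with `table` (power, fit,
#'   mean_connectivity), `beta_selected`, `fit_selected`, `reached_target`.
#' @export
pick_soft_threshold <- function(x, powers = 1:20, r2_target = 0.90,
                                n_bins = 10) {
  m <- unclass(x)
  if (nrow(m) < 20) stop("at least 20 genes required")
  if (ncol(m) < 4) stop("at least 4 samples required")
  r <- stats::cor(t(m))
  if (any(is.na(r))) stop("constant genes produce undefined correlations; filter first")
  absr <- abs(r)
  diag(absr) <- 0
  fit <- meank <- rep(NA_real_, length(powers))
  for (i in seq_along(powers)) {
    k <- rowSums(absr^powers[i])
    meank[i] <- mean(k)
    fit[i] <- tryCatch(scale_free_fit(k, n_bins)$fit, error = function(e) NA_real_)
  }
  tab <- data.frame(power = powers, fit = fit, mean_connectivity = meank)
  hit <- which(!is.na(fit) & fit >= r2_target)
  if (length(hit)) {
    sel <- hit[1L]
    reached <- TRUE
  } else {
    sel <- which.max(fit)
    reached <- FALSE
    message("no power reached fit >= ", r2_target,
            "; falling back to the maximum-fit power ", powers[sel])
  }
  structure(list(table = tab, beta_selected = powers[sel],
                 fit_selected = fit[sel], reached_target = reached),
            class = "soft_threshold")
}

#' Topological overlap similarity
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over shared neighbors and unit diagonal. Two
#' genes overlap strongly when they are adjacent and share neighbors.
#'
#' @param adjacency symmetric matrix with values in \[0, 1\] (diagonal
#'   ignored).
#' @return symmetric TOM with unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(a < 0) || any(a - diag(diag(a)) > 1)) {
    stop("adjacency values must lie in [0, 1]")
  }
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

# --- dendrogram bookkeeping for the dynamic cut ----------------------------

# For each internal node of an hclust tree, precompute member leaves and
# merge height. Nodes are rows of hc$merge.
hclust_nodes <- function(hc) {
  n <- length(hc$height)
  members <- vector("list", n)
  for (i in seq_len(n)) {
    ch <- hc$merge[i, ]
    members[[i]] <- c(if (ch[1] < 0) -ch[1] else members[[ch[1]]],
                      if (ch[2] < 0) -ch[2] else members[[ch[2]]])
  }
  list(members = members, height = hc$height, merge = hc$merge)
}

# Recursively split a subtree: a node is divided when both children are
# large enough to stand as modules and the merge joining them sits clearly
# above the children (gap in 1-TOM units), i.e. the two branches are
# distinct shapes in the tree rather than one tight clump.
split_branch <- function(node, nodes, min_size, split_gap) {
  if (node < 0) return(list(-node))
  ch <- nodes$merge[node, ]
  size <- function(x) if (x < 0) 1L else length(nodes$members[[x]])
  height <- function(x) if (x < 0) 0 else nodes$height[x]
  s1 <- size(ch[1]); s2 <- size(ch[2])
  gap <- nodes$height[node] - max(height(ch[1]), height(ch[2]))
  if (s1 >= min_size && s2 >= min_size && gap >= split_gap) {
    c(split_branch(ch[1], nodes, min_size, split_gap),
      split_branch(ch[2], nodes, min_size, split_gap))
  } else {
    list(if (node < 0) -node else nodes$members[[node]])
  }
}

#' Detect co-expression modules from a topological overlap matrix
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' followed by a tree-shape-based dynamic cut: the dendrogram is first cut
#' at `cut_height` (default 99% of the top merge height, so that genes with
#' no topological overlap stay unassigned as late-merging singletons), and
#' each resulting branch is recursively split wherever two sub-branches of
#' at least `min_module_size` genes are separated from their joining merge
#' by a height gap of at least `split_gap`. Clusters smaller than
#' `min_module_size` are left unassigned (module 0). Modules whose
#' eigengenes are closer than `merge_height` in correlation dissimilarity
#' (`1 - cor`) are then merged iteratively until stable.
#'
#' @param tom topological overlap matrix from [tom_similarity()].
#' @param expr the filtered [expr_matrix()] the TOM was built from (used for
#'   eigengenes); same genes, same order.
#' @param min_module_size minimum genes per module (default 30).
#' @param merge_height eigengene dissimilarity below which modules merge
#'   (default 0.25, i.e. eigengene correlation above 0.75).
#' @param cut_height static cut height; default `0.99 * max merge height`.
#' @param split_gap minimum branch-separation gap for the recursive split.
#' @return object of class `module_assignment`: list with `modules` (named
#'   integer vector, 0 = unassigned), `eigengenes` (samples x modules, unit
#'   variance, sign-oriented), `merge_history` (data.frame of merged label
#'   pairs), `dendrogram` (the hclust object).
#' @export
detect_modules <- function(tom, expr, min_module_size = 30,
                           merge_height = 0.25, cut_height = NULL,
                           split_gap = 0.1) {
  stopifnot(nrow(tom) == nrow(expr))
  genes <- rownames(tom)
  n <- nrow(tom)
  if (n < min_module_size) {
    warning("fewer genes than min_module_size; all genes unassigned")
    return(structure(list(modules = stats::setNames(integer(n), genes),
                          eigengenes = NULL,
                          merge_history = data.frame(from = integer(0), into = integer(0)),
                          dendrogram = NULL),
                     class = "module_assignment"))
  }
  d <- 1 - tom
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  if (is.null(cut_height)) cut_height <- 0.99 * max(hc$height)
  pre <- stats::cutree(hc, h = cut_height)
  nodes <- hclust_nodes(hc)

  # map each preliminary cluster to its subtree root, then split recursively
  clusters <- list()
  for (cl in unique(pre)) {
    idx <- which(pre == cl)
    if (length(idx) == 1L) {
      clusters <- c(clusters, list(idx))
      next
    }
    inside <- vapply(seq_along(nodes$members),
                     function(i) length(nodes$members[[i]]) == length(idx) &&
                       all(nodes$members[[i]] %in% idx), TRUE)
    root <- which(inside)[1L]
    clusters <- c(clusters, split_branch(root, nodes, min_module_size, split_gap))
  }

  clusters <- clusters[order(-lengths(clusters))]
  modules <- stats::setNames(integer(n), genes)
  lab <- 0L
  for (cl in clusters) {
    if (length(cl) >= min_module_size) {
      lab <- lab + 1L
      modules[cl] <- lab
    }
  }
  if (lab == 0L) {
    warning("no cluster reached min_module_size; all genes unassigned")
    return(structure(list(modules = modules, eigengenes = NULL,
                          merge_history = data.frame(from = integer(0), into = integer(0)),
                          dendrogram = hc),
                     class = "module_assignment"))
  }

  # iterative eigengene merge
  history <- data.frame(from = integer(0), into = integer(0))
  repeat {
    me <- module_eigengenes(expr, modules)
    if (ncol(me) < 2) break
    dis <- 1 - stats::cor(me)
    diag(dis) <- Inf
    if (min(dis) >= merge_height) break
    pair <- which(dis == min(dis), arr.ind = TRUE)[1L, ]
    from <- as.integer(sub("^ME", "", colnames(me)[max(pair)]))
    into <- as.integer(sub("^ME", "", colnames(me)[min(pair)]))
    modules[modules == from] <- into
    history <- rbind(history, data.frame(from = from, into = into))
  }
  # relabel consecutively by decreasing size
  sizes <- sort(table(modules[modules > 0]), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  modules[modules > 0] <- relab[as.character(modules[modules > 0])]
  structure(list(modules = modules,
                 eigengenes = module_eigengenes(expr, modules),
                 merge_history = history, dendrogram = hc),
            class = "module_assignment")
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of the
#' module's gene-standardized expression (samples as observations), scaled
#' to unit variance and sign-oriented so that it correlates nonnegatively
#' with the module's mean standardized profile.
#'
#' @param expr an [expr_matrix()] (genes x samples).
#' @param modules named integer vector of module labels (0 = unassigned),
#'   or a `module_assignment`.
#' @return samples x modules matrix with columns `ME1`, `ME2`, ...
#' @export
module_eigengenes <- function(expr, modules) {
  if (inherits(modules, "module_assignment")) modules <- modules$modules
  m <- unclass(expr)
  labs <- sort(unique(modules[modules > 0]))
  me <- matrix(NA_real_, ncol(m), length(labs),
               dimnames = list(colnames(m), paste0("ME", labs)))
  for (j in seq_along(labs)) {
    sub <- m[modules == labs[j], , drop = FALSE]
    z <- t(scale(t(sub)))          # standardize each gene across samples
    z <- z[stats::complete.cases(z), , drop = FALSE]
    sv <- svd(t(z), nu = 1, nv = 0)
    e <- sv$u[, 1L]
    if (stats::cor(e, colMeans(z)) < 0) e <- -e
    me[, j] <- e / stats::sd(e)
  }
  me
}

#' Correlate module eigengenes with clinical traits
#'
#' Pearson correlation of each eigengene with each numeric trait (binary
#' group traits coded 0/1), with two-sided p-values from the t
#' approximation.
#'
#' @param eigengenes samples x modules matrix (or a `module_assignment`,
#'   from which the eigengenes are taken).
#' @param traits numeric vector or samples x traits matrix/data.frame.
#' @return data.frame with columns `module`, `trait`, `r`, `p`; the
#'   strongest positive and negative modules per trait carry `top = TRUE`.
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  if (inherits(eigengenes, "module_assignment")) eigengenes <- eigengenes$eigengenes
  tr <- as.matrix(traits)
  if (is.null(colnames(tr))) colnames(tr) <- paste0("trait", seq_len(ncol(tr)))
  if (any(apply(tr, 2, stats::sd) == 0)) stop("constant trait")
  n <- nrow(eigengenes)
  stopifnot(nrow(tr) == n)
  out <- expand.grid(module = colnames(eigengenes), trait = colnames(tr),
                     stringsAsFactors = FALSE)
  out$r <- mapply(function(m, t) stats::cor(eigengenes[, m], tr[, t]),
                  out$module, out$trait)
  tstat <- out$r * sqrt((n - 2) / pmax(1 - out$r^2, .Machine$double.eps))
  out$p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  out$top <- FALSE
  for (t in unique(out$trait)) {
    i <- which(out$trait == t)
    out$top[i[which.max(out$r[i])]] <- TRUE
    out$top[i[which.min(out$r[i])]] <- TRUE
  }
  out
}
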