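#' Pipeline configuration
#'
#' Collects every tunable threshold of the discovery flow in one validated
#' object. Defaults are the pipeline's operating point: nominal p 0.05 and
#' |log2FC| 0.585 (1.5-fold) for differential calls, top-25% variance
#' filter, minimum module size 30 with eigengene merge height 0.25,
#' pseudocount 1e-6, Spearman edge threshold 0.6, 70/30 stratified split,
#' 50 importance permutations, 1000 enrichment permutations with FDR q
#' 0.25, and 40%/40% high/low cell strata.
#'
#' @param seed global seed; per-stage seeds are derived from it
#'   deterministically.
#' @param p_threshold,lfc_threshold differential-call thresholds.
#' @param keep_fraction variance-filter fraction.
#' @param min_module_size,merge_height module detection parameters.
#' @param eps pseudocount for ratio and fold-change statistics.
#' @param edge_threshold subfunction-network Spearman threshold.
#' @param train_fraction training fraction of the stratified split.
#' @param n_permutations importance permutations per gene.
#' @param gsea_nperm enrichment permutations per gene set.
#' @param q_threshold enrichment FDR cutoff.
#' @param upper,lower high/low stratification quantiles.
#' @param stages stages to run, in order.
#' @return object of class `run_config` (a named list).
#' @export
run_config <- function(seed = 1, p_threshold = 0.05, lfc_threshold = 0.585,
                       keep_fraction = 0.25, min_module_size = 30,
                       merge_height = 0.25, eps = 1e-6, edge_threshold = 0.6,
                       train_fraction = 0.7, n_permutations = 50,
                       gsea_nperm = 1000, q_threshold = 0.25,
                       upper = 0.40, lower = 0.40,
                       stages = c("deg", "wgcna", "intersect", "prioritize",
                                  "validate", "gsea", "sc")) {
  cfg <- list(seed = as.integer(seed), p_threshold = p_threshold,
              lfc_threshold = lfc_threshold, keep_fraction = keep_fraction,
              min_module_size = min_module_size, merge_height = merge_height,
              eps = eps, edge_threshold = edge_threshold,
              train_fraction = train_fraction,
              n_permutations = n_permutations, gsea_nperm = gsea_nperm,
              q_threshold = q_threshold, upper = upper, lower = lower,
              stages = stages)
  stopifnot(cfg$p_threshold > 0, cfg$p_threshold <= 1,
            cfg$lfc_threshold >= 0,
            cfg$keep_fraction > 0, cfg$keep_fraction <= 1,
            cfg$min_module_size >= 2,
            cfg$merge_height >= 0, cfg$merge_height < 1,
            cfg$eps > 0, abs(cfg$edge_threshold) <= 1,
            cfg$train_fraction > 0, cfg$train_fraction < 1,
            cfg$n_permutations >= 1, cfg$gsea_nperm >= 1,
            cfg$q_threshold > 0, cfg$q_threshold <= 1,
            cfg$upper > 0, cfg$lower > 0, cfg$upper + cfg$lower <= 1)
  structure(cfg, class = "run_config")
}

#' Write / read a flat key=value configuration file
#' @param config a [run_config()].
#' @param path file path.
#' @return `write_config` returns the path; `read_config` a `run_config`.
#' @export
write_config <- function(config, path) {
  vals <- vapply(config, function(v) {
    paste(if (is.character(v)) v else format(v, digits = 17), collapse = ",")
  }, "")
  writeLines(paste0(names(config), "=", vals), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  kv <- strsplit(readLines(path, warn = FALSE), "=", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, function(x) {
    v <- strsplit(x[2], ",", fixed = TRUE)[[1L]]
    if (x[1] == "stages") v else as.numeric(v)
  }), vapply(kv, `[[`, "", 1L))
  do.call(run_config, vals)
}

# per-stage seeds expanded from the global one (kept well below 2^31)
stage_seed <- function(seed, stage) {
  offsets <- c(sim = 1L, deg = 2L, wgcna = 3L, intersect = 4L,
               prioritize = 5L, validate = 6L, gsea = 7L, sc = 8L)
  (as.integer(seed) %% 2000000L) * 1000L + offsets[[stage]]
}

#' Generate the default simulated study inputs
#'
#' Builds the full synthetic input bundle the discovery flow expects: a
#' discovery cohort (two co-expression modules of 60 genes; the first is
#' trait-shifted so its genes are differential, and its first gene carries
#' an additional strong planted effect — the biomarker the pipeline should
#' recover), a trained-immunity signature overlapping the first seven
#' module genes, three smaller validation cohorts with the same planted
#' structure, a cell-mixture cohort with its reference signature, and a
#' pseudotime-ordered macrophage population with a 2-fold disease plateau
#' of the target gene.
#'
#' @param seed integer seed.
#' @return named list of inputs (`discovery`, `signature_sets`,
#'   `validation`, `mixture`, `mixture_signature`, `cells`, `truth`).
#' @export
simulate_study <- function(seed = 1) {
  mk <- function(s, n_case, n_ctrl) {
    make_bulk_cohort(bulk_cohort_spec(
      n_genes = 500, n_case = n_case, n_ctrl = n_ctrl,
      de_genes = 1L, de_lfc = 1.5,
      module_spec = list(list(size = 60, loading = 0.9, trait_shift = 1.2),
                         list(size = 60, loading = 0.9)),
      noise_sd = 0.4, seed = s))
  }
  discovery <- mk(stage_seed(seed, "sim"), 30, 30)
  validation <- lapply(1:3, function(i) mk(stage_seed(seed, "sim") + i, 20, 20))
  # trained signature: first 7 module-1 genes (all shifted up in cases)
  hub_truth <- data.frame(gene = sprintf("g%04d", 1:7), direction = "up",
                          stringsAsFactors = FALSE)
  background <- with(discovery$truth$modules, gene[module == 0])
  sig_sets <- make_trained_signature(hub_truth, overlap_count = 7,
                                     extra_count = 50,
                                     universe = background,
                                     seed = stage_seed(seed, "sim") + 10L)
  sig <- make_signature(n_markers = 15, celltypes = paste0("ct", 1:4),
                        seed = stage_seed(seed, "sim") + 20L)
  set.seed(stage_seed(seed, "sim") + 21L)
  truth_frac <- t(apply(matrix(stats::rgamma(20 * 4, 2), 20, 4), 1,
                        function(w) w / sum(w)))
  dimnames(truth_frac) <- list(sprintf("mix%02d", 1:20), colnames(sig))
  mixture <- make_mixture_cohort(mixture_spec(sig, truth_frac, noise_sd = 0.05,
                                              seed = stage_seed(seed, "sim") + 22L))
  cells <- make_cell_population(cell_population_spec(
    n_cells = 1500,
    groups = rep(c("disease", "control"), length.out = 1500),
    celltypes = "macrophage",
    target_gene = "g0001",
    trend = function(t) 1 + 3 * stats::plogis(10 * (t - 0.5)),
    group_scale = c(disease = 2, control = 1),
    noise_sd = 0.3, dropout_rate = 0.1,
    n_null_genes = 5, n_linked_genes = 2,
    seed = stage_seed(seed, "sc")))
  list(discovery = discovery, signature_sets = sig_sets,
       validation = validation, mixture = mixture, mixture_signature = sig,
       cells = cells,
       truth = list(biomarker = "g0001", hub_genes = hub_truth$gene,
                    module_genes = discovery$truth$modules))
}

#' Run the end-to-end discovery pipeline
#'
#' Executes, in order: differential expression, co-expression module
#' detection with module-trait correlation, three-way hub intersection,
#' ensemble machine-learning prioritization, cross-cohort ROC and
#' random-effects meta-analytic validation, pre-ranked enrichment, and
#' single-cell stratification. Each stage's outputs are written as TSV
#' artifacts under `out_dir` together with a manifest of seeds, parameter
#' values and file checksums; a stage failure halts the run with an error
#' naming the stage.
#'
#' @param config a [run_config()].
#' @param out_dir artifact directory (created if missing).
#' @param inputs named list of inputs as produced by [simulate_study()];
#'   when `NULL` and `simulate = TRUE`, inputs are simulated from the
#'   config seed.
#' @param simulate generate inputs with [simulate_study()] when none given.
#' @return invisible list of per-stage results (`deg`, `modules`,
#'   `module_trait`, `hubs`, `prioritization`, `validation`, `gsea`, `sc`,
#'   `manifest`).
#' @export
run_discovery <- function(config = run_config(), out_dir = tempfile("trainmark_"),
                          inputs = NULL, simulate = is.null(inputs)) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(inputs)) {
    if (!simulate) stop("no inputs given and simulate = FALSE")
    inputs <- simulate_study(config$seed)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  need <- function(stage, what) {
    if (is.null(res[[what]])) {
      stop("stage '", stage, "' needs output of a stage that did not run: ", what)
    }
  }
  run <- function(stage, expr) {
    if (!stage %in% config$stages) return(invisible(NULL))
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  lg <- to_log2p1(inputs$discovery$expr)
  labels <- inputs$discovery$labels

  run("deg", {
    res$deg <- deg_test(lg, labels, p_threshold = config$p_threshold,
                         lfc_threshold = config$lfc_threshold)
    utils::write.table(res$deg, file.path(out_dir, "deg.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })
  run("wgcna", {
    filt <- variance_filter(lg, config$keep_fraction)
    st <- pick_soft_threshold(filt)
    tom <- tom_similarity(adjacency_matrix(filt, st$beta_selected))
    mods <- detect_modules(tom, filt, min_module_size = config$min_module_size,
                           merge_height = config$merge_height)
    trait <- as.numeric(labels[colnames(filt)] == "case")
    mt <- module_trait_correlation(mods, trait)
    res$soft_threshold <- st
    res$modules <- mods
    res$module_trait <- mt
    utils::write.table(data.frame(gene = names(mods$modules),
                                  module = mods$modules),
                       file.path(out_dir, "modules.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(mt, file.path(out_dir, "module_trait.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })
  run("intersect", {
    need("intersect", "deg"); need("intersect", "modules")
    deg_genes <- res$deg$gene[res$deg$call != "ns"]
    top_mod <- res$module_trait$module[which.max(res$module_trait$r)]
    mod_genes <- names(res$modules$modules)[
      paste0("ME", res$modules$modules) == top_mod]
    res$hubs <- intersect_hub_genes(deg_genes,
                                     unlist(inputs$signature_sets),
                                     mod_genes)
    writeLines(res$hubs, file.path(out_dir, "hub_genes.txt"))
  })
  run("prioritize", {
    need("prioritize", "hubs")
    if (length(res$hubs) < 3) {
      warning("fewer than 3 hub candidates; skipping model-based ranking")
      res$prioritization <- structure(list(selected_genes = res$hubs),
                                      class = "prioritization_result")
    } else {
      feats <- t(unclass(lg)[res$hubs, , drop = FALSE])
      sp <- stratified_split(labels, config$train_fraction,
                             seed = stage_seed(config$seed, "prioritize"))
      fit <- train_models(feats[sp$train, , drop = FALSE], labels[sp$train],
                          seed = stage_seed(config$seed, "prioritize"))
      ev <- evaluate_models(fit, feats[sp$test, , drop = FALSE], labels[sp$test])
      imp <- permutation_importance(fit, feats[sp$test, , drop = FALSE],
                                    labels[sp$test],
                                    n_permutations = config$n_permutations,
                                    seed = stage_seed(config$seed, "prioritize"))
      res$prioritization <- fuse_and_select(imp, ev)
      res$importance <- imp
      res$evaluation <- ev
      utils::write.table(data.frame(gene = rownames(imp), imp),
                         file.path(out_dir, "importance.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    writeLines(res$prioritization$selected_genes,
               file.path(out_dir, "selected_genes.txt"))
  })
  run("validate", {
    need("validate", "prioritization")
    sel <- res$prioritization$selected_genes
    rocs <- lapply(inputs$validation, function(co) {
      sc <- signature_score(to_log2p1(co$expr), sel)
      roc_auc(sc, co$labels[names(sc)], positive_class = "case")
    })
    meta <- meta_analyze_gene(
      lapply(inputs$validation, function(co) list(expr = to_log2p1(co$expr),
                                                  labels = co$labels)),
      gene = sel[1L])
    res$validation <- list(auc = vapply(rocs, `[[`, 0, "auc"), meta = meta)
    utils::write.table(
      data.frame(cohort = seq_along(rocs), auc = res$validation$auc),
      file.path(out_dir, "validation_auc.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    utils::write.table(meta$per_cohort, file.path(out_dir, "meta_effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })
  run("gsea", {
    ranked <- rank_by_group_statistic(lg, labels)
    res$gsea <- gsea_significance(ranked, inputs$signature_sets,
                                   n_permutations = config$gsea_nperm,
                                   seed = stage_seed(config$seed, "gsea"))
    res$gsea$significant <- res$gsea$q < config$q_threshold
    utils::write.table(res$gsea, file.path(out_dir, "gsea.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })
  run("sc", {
    cells <- inputs$cells
    target <- inputs$truth$biomarker
    fc <- celltype_fold_change(cells, target, "macrophage",
                               "disease", "control", eps = config$eps)
    prof <- pseudotime_profile(cells, target)
    strata <- stratify_by_expression(cells, target, config$upper, config$lower)
    de <- strata_differential_expression(
      cells, strata, setdiff(names(cells)[-(1:4)], character(0)),
      p_threshold = config$p_threshold, lfc_threshold = config$lfc_threshold,
      eps = config$eps, by_group = TRUE)
    res$sc <- list(fold_change = fc, profile = prof, strata = strata, de = de)
    utils::write.table(de, file.path(out_dir, "sc_strata_de.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.tsv"]
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  attr(manifest, "seed") <- config$seed
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  res$manifest <- manifest
  res$out_dir <- out_dir
  invisible(res)
}
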