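#' Construct an expression matrix with a declared scale
#'
#' An `expr_matrix` is a plain numeric matrix (genes as rows, samples as
#' columns) carrying a `scale` attribute that records whether the values are
#' on the linear scale or have already been `log2(x + 1)` transformed.
#' Tracking the scale explicitly prevents accidental double transformation,
#' which silently compresses fold changes.
#'
#' @param x numeric matrix, genes in rows, samples in columns; must have
#'   row and column names.
#' @param scale `"linear"` or `"log2p1"`.
#' @return the matrix with class `expr_matrix` and a `scale` attribute.
#' @export
expr_matrix <- function(x, scale = c("linear", "log2p1")) {
  scale <- match.arg(scale)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix requires gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicate gene identifiers; collapse them first (see read_expression)")
  }
  if (any(!is.finite(x))) stop("expression values must be finite")
  if (any(x < 0)) stop("expression values must be nonnegative")
  structure(x, scale = scale, class = c("expr_matrix", class(unclass(x))))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (scale: %s)\n",
              nrow(x), ncol(x), expr_scale(x)))
  invisible(x)
}

#' Scale of an expression matrix
#' @param x an `expr_matrix`.
#' @return `"linear"` or `"log2p1"`.
#' @export
expr_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) "linear" else s
}

#' log2(x + 1) transform an expression matrix
#'
#' Refuses to transform a matrix already marked `log2p1`: the transform is
#' applied exactly once, immediately after loading linear-scale values.
#'
#' @param x an `expr_matrix` on the linear scale.
#' @return an `expr_matrix` with `scale = "log2p1"`.
#' @export
to_log2p1 <- function(x) {
  if (expr_scale(x) == "log2p1") {
    stop("matrix is already log2(x+1) transformed; refusing to transform twice")
  }
  if (any(x < 0)) stop("negative values cannot be log2(x+1) transformed")
  expr_matrix(log2(unclass(x) + 1), scale = "log2p1")
}

#' Read a gene x sample expression table from TSV/CSV
#'
#' Duplicate gene identifiers are collapsed by keeping, for each identifier,
#' the row with the highest mean expression (the usual probe-to-gene rule).
#'
#' @param path file path; tab- or comma-separated with a header row of sample
#'   IDs and gene identifiers in the first column.
#' @param scale declared scale of the stored values.
#' @param sep field separator; guessed from the extension when `NULL`.
#' @return an `expr_matrix`.
#' @export
read_expression <- function(path, scale = c("linear", "log2p1"), sep = NULL) {
  scale <- match.arg(scale)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyDuplicated(genes)) {
    means <- rowMeans(m)
    keep <- unlist(lapply(split(seq_along(genes), genes), function(i) i[which.max(means[i])]))
    keep <- sort(unname(keep))
    m <- m[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  rownames(m) <- genes
  expr_matrix(m, scale = scale)
}

#' Write an expression matrix as TSV (genes as rows)
#' @param x an `expr_matrix` (or plain matrix).
#' @param path output file path.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample labels from a two-column TSV (sample_id, group)
#' @param path file path.
#' @return named character vector of group labels, names are sample IDs.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Write sample labels as a two-column TSV
#' @param labels named vector of group labels.
#' @param path output file path.
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(sample_id = names(labels), group = as.character(labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene identifiers.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    f[-(1:2)][nzchar(f[-(1:2)])]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1L]][1L], "")
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output file path.
#' @param description description field per set (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# internal: coerce labels to a factor aligned with matrix columns.
# `case` names the positive/disease level. When not given, a level matching
# a conventional control alias (control/ctrl/healthy/normal/untrained/wt)
# becomes the reference; otherwise the first factor level is the reference.
align_labels <- function(x, labels, case = NULL) {
  if (!is.null(names(labels)) && !is.null(colnames(x))) {
    if (!all(colnames(x) %in% names(labels))) {
      stop("labels missing for some samples")
    }
    labels <- labels[colnames(x)]
  } else if (length(labels) != ncol(x)) {
    stop("labels length does not match number of samples")
  }
  f <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  if (nlevels(f) != 2L) stop("exactly two groups required")
  if (is.null(case)) {
    aliases <- c("control", "ctrl", "healthy", "normal", "untrained", "wt")
    ref <- levels(f)[tolower(levels(f)) %in% aliases]
    if (length(ref) == 1L) case <- setdiff(levels(f), ref)
  }
  if (!is.null(case)) {
    if (!case %in% levels(f)) stop("`case` is not a label level")
    f <- stats::relevel(f, ref = setdiff(levels(f), case))
  }
  f
}
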