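#' Read an expression matrix and its sample-to-group labels
#'
#' Expects a UTF-8, tab-delimited matrix file whose header row holds sample
#' identifiers and whose first column holds probe or gene identifiers, plus a
#' two-column tab-delimited labels file mapping each sample to one of exactly
#' two group labels. Files may be gzip-compressed (any connection
#' [utils::read.delim()] accepts).
#'
#' Genes with missing values are dropped with a warning (complete-case
#' filtering), so downstream correlations in both groups use all samples of
#' the group.
#'
#' @param matrix_path Path to the tab-delimited expression matrix.
#' @param labels_path Path to the two-column (sample_id, group) labels file.
#' @param min_group_size Minimum samples per group; Pearson correlation from
#'   fewer than 3 samples is degenerate (always |r| = 1 for n = 2), so the
#'   default refuses groups smaller than 3.
#' @return A `coex_expression` object: a list with `values` (numeric matrix,
#'   genes x samples), `group_of` (named character vector over samples) and
#'   `groups` (the two group labels, in order of first appearance).
#' @export
load_expression <- function(matrix_path, labels_path, min_group_size = 3L) {
  raw <- utils::read.delim(matrix_path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("expression matrix must have an id column and at least one sample column")
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in expression matrix header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  ids <- trimws(as.character(raw[[1L]]))
  values <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(values))
    stop("non-numeric cells in expression matrix")
  rownames(values) <- ids
  colnames(values) <- sample_ids

  lab <- utils::read.delim(labels_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(lab) < 2L) stop("labels file must have two columns: sample_id, group")
  group_of <- stats::setNames(trimws(as.character(lab[[2L]])),
                              trimws(as.character(lab[[1L]])))
  missing_lab <- setdiff(sample_ids, names(group_of))
  if (length(missing_lab))
    stop("samples missing from labels file: ", paste(missing_lab, collapse = ", "))
  group_of <- group_of[sample_ids]  # preserve file order of samples

  new_expression(values, group_of, min_group_size = min_group_size)
}

#' Construct and validate an expression object
#'
#' @param values Numeric matrix, rows = genes (or probes), columns = samples,
#'   with dimnames set.
#' @param group_of Named character vector mapping each column of `values` to
#'   one of exactly two group labels.
#' @param min_group_size Minimum samples required per group (default 3).
#' @return A validated `coex_expression` object.
#' @export
new_expression <- function(values, group_of, min_group_size = 3L) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs row (gene) and column (sample) names")
  rownames(values) <- normalize_symbol(rownames(values))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene/probe ids after symbol normalization")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  group_of <- group_of[colnames(values)]
  if (anyNA(names(group_of)) || anyNA(group_of))
    stop("every sample needs a group label")
  groups <- unique(unname(group_of))
  if (length(groups) != 2L)
    stop("exactly two group labels required, got: ", paste(groups, collapse = ", "))
  sizes <- table(factor(group_of, levels = groups))
  if (any(sizes < min_group_size))
    stop(sprintf("group '%s' has %d samples; at least %d required",
                 names(sizes)[which.min(sizes)], min(sizes), min_group_size))
  incomplete <- rowSums(!is.finite(values)) > 0L
  if (any(incomplete)) {
    warning(sprintf("dropping %d gene(s) with missing values", sum(incomplete)))
    values <- values[!incomplete, , drop = FALSE]
  }
  structure(list(values = values, group_of = group_of, groups = groups),
            class = "coex_expression")
}

#' @export
print.coex_expression <- function(x, ...) {
  sizes <- table(factor(x$group_of, levels = x$groups))
  cat(sprintf("Expression matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(sizes), sizes), collapse = ", ")))
  invisible(x)
}

#' Collapse probe-level rows to gene level by averaging
#'
#' Each gene's intensity in each sample becomes the arithmetic mean of its
#' probes' intensities in that sample; a gene interrogated by a single probe is
#' passed through unchanged.
#'
#' @param raw A `coex_expression` object keyed by probe id.
#' @param probe_map Data frame or two-column matrix with columns
#'   (probe_id, gene_id); every probe in `raw` must appear exactly once.
#' @return A `coex_expression` object keyed by gene, one row per gene.
#' @export
collapse_probes <- function(raw, probe_map) {
  stopifnot(inherits(raw, "coex_expression"))
  pm <- as.data.frame(probe_map, stringsAsFactors = FALSE)
  if (ncol(pm) < 2L) stop("probe map needs columns (probe_id, gene_id)")
  map <- stats::setNames(normalize_symbol(pm[[2L]]),
                         normalize_symbol(pm[[1L]]))
  if (anyDuplicated(names(map)))
    stop("probe map assigns some probes more than once")
  orphans <- setdiff(rownames(raw$values), names(map))
  if (length(orphans))
    stop("probes with no gene assignment: ", paste(orphans, collapse = ", "))
  gene <- map[rownames(raw$values)]
  collapsed <- rowsum(raw$values, group = gene, reorder = TRUE) /
    as.vector(table(gene)[sort(unique(gene))])
  new_expression(collapsed, raw$group_of)
}

#' Split an expression object into its two group sub-matrices
#'
#' @param m A `coex_expression` object.
#' @return Named list of two numeric matrices (one per group label, in the
#'   object's group order) partitioning the samples; gene order identical.
#' @export
split_groups <- function(m) {
  stopifnot(inherits(m, "coex_expression"))
  out <- lapply(m$groups, function(g) {
    m$values[, names(m$group_of)[m$group_of == g], drop = FALSE]
  })
  stats::setNames(out, m$groups)
}

#' Write an expression object and its labels to tab-delimited files
#'
#' Inverse of [load_expression()]; the matrix file has an `id` first column
#' and sample-id header, the labels file has (sample_id, group) rows.
#'
#' @param m A `coex_expression` object.
#' @param matrix_path,labels_path Output paths.
#' @return Invisibly, `matrix_path`.
#' @export
write_expression <- function(m, matrix_path, labels_path) {
  stopifnot(inherits(m, "coex_expression"))
  df <- data.frame(id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(m$group_of), group = unname(m$group_of)),
    labels_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(matrix_path)
}
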