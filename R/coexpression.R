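#' Absolute Pearson correlation of two expression profiles
#'
#' The coexpression level of a gene pair within one group: |cor(x, y)|, a
#' scalar in [0, 1] where high values indicate a strong positive *or* negative
#' biological relationship. Values exceeding 1 by floating-point rounding are
#' clamped.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return |Pearson r| in [0, 1].
#' @export
abs_pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("profiles must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate gene: zero-variance profile, correlation undefined")
  min(abs(stats::cor(x, y)), 1)
}

#' Pairwise coexpression levels of candidate genes in two groups
#'
#' Computes |Pearson r| for every unordered pair (i < j, lexicographic) of the
#' candidate genes, once per group. Genes with zero variance in either group
#' are removed first (with a message) and the pair universe rebuilt from the
#' survivors, since their correlation is undefined.
#'
#' @param disease,normal Numeric sub-matrices (genes x samples) containing all
#'   candidate genes as rows; at least 3 samples each.
#' @param genes Character vector of candidate gene ids.
#' @return A data frame of class `coex_table` with one row per pair and
#'   columns `gene_i`, `gene_j`, `c_normal`, `c_disease`.
#' @export
pairwise_coexpression <- function(disease, normal, genes) {
  stopifnot(is.matrix(disease), is.matrix(normal))
  if (ncol(disease) < 3L || ncol(normal) < 3L)
    stop("each group needs at least 3 samples")
  missing <- setdiff(genes, intersect(rownames(disease), rownames(normal)))
  if (length(missing))
    stop("genes absent from a group sub-matrix: ", paste(missing, collapse = ", "))
  genes <- sort(unique(genes))
  sd_d <- apply(disease[genes, , drop = FALSE], 1L, stats::sd)
  sd_n <- apply(normal[genes, , drop = FALSE], 1L, stats::sd)
  degenerate <- sd_d == 0 | sd_n == 0
  if (any(degenerate)) {
    message(sprintf("removed %d zero-variance gene(s): %s", sum(degenerate),
                    paste(genes[degenerate], collapse = ", ")))
    genes <- genes[!degenerate]
  }
  if (length(genes) < 2L) stop("fewer than 2 genes survive variance filtering")

  # profiles in columns for stats::cor; |r| clamped to 1 at the boundary
  r_d <- abs(stats::cor(t(disease[genes, , drop = FALSE])))
  r_n <- abs(stats::cor(t(normal[genes, , drop = FALSE])))
  idx <- which(upper.tri(r_d), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  out <- data.frame(
    gene_i = genes[idx[, "row"]],
    gene_j = genes[idx[, "col"]],
    c_normal = pmin(r_n[idx], 1),
    c_disease = pmin(r_d[idx], 1),
    stringsAsFactors = FALSE
  )
  class(out) <- c("coex_table", "data.frame")
  out
}

#' Write a coexpression table as TSV
#'
#' Columns: gene_i, gene_j, c_normal, c_disease (6 decimal places), plus any
#' classification columns already appended.
#'
#' @param table A `coex_table` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_coex_table <- function(table, path) {
  out <- as.data.frame(table)
  for (col in c("c_normal", "c_disease"))
    out[[col]] <- sprintf("%.6f", out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
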