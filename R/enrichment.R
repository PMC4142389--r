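#' Load a gene-set collection
#'
#' Accepts GMT format (set_name TAB description TAB gene1 TAB gene2 ...) or a
#' two-column TSV (set_name, gene). Gene symbols are upper-cased and
#' whitespace-stripped to match expression gene ids.
#'
#' @param path Path to the collection file.
#' @param format "gmt" (default for files ending .gmt), "tsv", or "auto".
#' @return A `coex_genesets` object: named list of unique gene vectors.
#' @export
load_gene_sets <- function(path, format = c("auto", "gmt", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  if (format == "gmt") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) stop("empty gene-set file: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- vapply(fields, length, 1L) < 3L
    if (any(bad)) stop("GMT lines with fewer than 3 fields: ",
                       paste(which(bad), collapse = ", "))
    sets <- lapply(fields, function(f) unique(normalize_symbol(f[-(1:2)])))
    names(sets) <- vapply(fields, `[`, character(1L), 1L)
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) stop("empty gene-set file: ", path)
    sets <- lapply(split(normalize_symbol(df[[2L]]), trimws(df[[1L]])), unique)
  }
  if (anyDuplicated(names(sets))) stop("duplicate set names")
  if (any(vapply(sets, length, 1L) == 0L)) stop("empty gene set")
  structure(sets, class = "coex_genesets")
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of drawing at least `k = |candidates ∩ annot_set|` annotated
#' genes when drawing `|candidates|` genes from a universe containing
#' `|annot_set|` annotated genes — the classical gene-set
#' overrepresentation test.
#'
#' @param candidates,annot_set Character vectors of gene symbols.
#' @param universe_size Number of genes in the annotation universe; must be at
#'   least as large as either set.
#' @return Upper-tail p-value P(X >= k).
#' @export
hypergeometric_enrichment <- function(candidates, annot_set, universe_size) {
  candidates <- unique(candidates); annot_set <- unique(annot_set)
  if (length(candidates) > universe_size || length(annot_set) > universe_size)
    stop("universe smaller than a gene set")
  k <- length(intersect(candidates, annot_set))
  stats::phyper(k - 1L, m = length(annot_set),
                n = universe_size - length(annot_set),
                k = length(candidates), lower.tail = FALSE)
}

#' All unordered pairs of annotated candidate genes
#'
#' @param annot_set Character vector of genes in one gene set.
#' @param candidates Ordered character vector of candidate genes.
#' @return Two-column character matrix (gene_i, gene_j), i < j lexicographic,
#'   canonical with the coexpression table; zero rows when fewer than two
#'   annotated candidates exist.
#' @export
annotated_pairs <- function(annot_set, candidates) {
  genes <- sort(intersect(unique(annot_set), unique(candidates)))
  if (length(genes) < 2L)
    return(matrix(character(0L), ncol = 2L,
                  dimnames = list(NULL, c("gene_i", "gene_j"))))
  idx <- utils::combn(length(genes), 2L)
  cbind(gene_i = genes[idx[1L, ]], gene_j = genes[idx[2L, ]])
}

pair_key <- function(gene_i, gene_j) paste(gene_i, gene_j, sep = "\r")

#' Map annotated pairs onto the group-specific coexpression classes
#'
#' Counts how many annotated pairs fall into each of the four specific pair
#' classes: a = normal-specific strong, b = normal-specific weak, c =
#' disease-specific strong, d = disease-specific weak. By the class
#' identities, a = d and b = c on every input. Annotated pairs outside the
#' classified pair universe are dropped with a message.
#'
#' @param annotated Two-column matrix of pairs (see [annotated_pairs()]).
#' @param cls A classified `coex_table` (see [classify_pairs()]).
#' @return List with integer counts `a`, `b`, `c`, `d`.
#' @export
map_pairs <- function(annotated, cls) {
  stopifnot(all(c("normal_specific_strong", "normal_specific_weak") %in% names(cls)))
  keys <- pair_key(cls$gene_i, cls$gene_j)
  akeys <- pair_key(annotated[, 1L], annotated[, 2L])
  hit <- akeys %in% keys
  if (any(!hit))
    message(sprintf("%d annotated pair(s) outside the classified universe; dropped",
                    sum(!hit)))
  idx <- match(akeys[hit], keys)
  list(a = sum(cls$normal_specific_strong[idx]),
       b = sum(cls$normal_specific_weak[idx]),
       c = sum(cls$disease_specific_strong[idx]),
       d = sum(cls$disease_specific_weak[idx]))
}

#' One-sided Fisher's exact test on mapped pair counts
#'
#' Exact hypergeometric upper tail in cell `a` of the 2x2 table
#' [[a, b], [c, d]]: the probability, with margins fixed, of a table whose
#' `a` cell is at least as large as observed. Tests whether annotated pairs
#' are preferentially normal-specific strongly coexpressed.
#'
#' @param counts List with nonnegative integers `a`, `b`, `c`, `d`
#'   (see [map_pairs()]).
#' @return One-sided p-value; an all-zero table returns 1 by convention.
#' @export
fisher_one_sided <- function(counts) {
  cells <- c(counts$a, counts$b, counts$c, counts$d)
  stopifnot(all(cells >= 0))
  if (sum(cells) == 0L) {
    message("all-zero mapped pair table; p = 1 by convention")
    return(1)
  }
  tab <- matrix(cells, nrow = 2L, byrow = TRUE)
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, order-preserving with the input and clamped to
#' at most 1.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Gene-set enrichment of group-specific coexpressed pairs
#'
#' For each gene set: annotate the candidate genes, form all annotated pairs,
#' map them to the four specific pair classes, and test with the one-sided
#' Fisher's exact test; FDR control across sets by Benjamini-Hochberg. Sets
#' with fewer than two annotated candidate genes yield no pairs and are
#' reported with p = 1 rather than dropped, keeping the multiple-testing
#' family explicit.
#'
#' @param collection A `coex_genesets` object or named list of gene vectors.
#' @param fit A `coexshift` fit, or a classified `coex_table`.
#' @param universe_size Annotation universe size for the hypergeometric
#'   gene-level enrichment column; defaults to the number of candidate genes
#'   (use the measured-gene count of the platform when available).
#' @param fdr_threshold Significance threshold on the FDR (default 0.05).
#' @return A data frame of class `coexshift_enrichment`, one row per set:
#'   set, annotated_gene_count, annotated_pair_count, a, b, c, d, hyper_p,
#'   fisher_p, fdr, significant.
#' @export
enrich_pairs <- function(collection, fit, universe_size = NULL,
                         fdr_threshold = 0.05) {
  if (length(collection) == 0L) stop("empty gene-set collection")
  cls <- if (inherits(fit, "coexshift")) fit$pairs else fit
  candidates <- sort(unique(c(cls$gene_i, cls$gene_j)))
  if (is.null(universe_size)) universe_size <- length(candidates)
  rows <- lapply(names(collection), function(nm) {
    gs <- normalize_symbol(collection[[nm]])
    ann <- annotated_pairs(gs, candidates)
    cnt <- if (nrow(ann)) map_pairs(ann, cls) else list(a = 0L, b = 0L, c = 0L, d = 0L)
    p <- if (nrow(ann)) suppressMessages(fisher_one_sided(cnt)) else 1
    data.frame(set = nm,
               annotated_gene_count = length(intersect(gs, candidates)),
               annotated_pair_count = nrow(ann),
               a = cnt$a, b = cnt$b, c = cnt$c, d = cnt$d,
               hyper_p = hypergeometric_enrichment(candidates, gs,
                                                   max(universe_size, length(gs))),
               fisher_p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$fisher_p)
  out$significant <- out$fdr < fdr_threshold
  class(out) <- c("coexshift_enrichment", "data.frame")
  out
}

#' @export
print.coexshift_enrichment <- function(x, digits = 4L, ...) {
  cat(sprintf("Gene-set mapping of group-specific coexpressed pairs (%d sets, %d significant)\n\n",
              nrow(x), sum(x$significant)))
  df <- as.data.frame(x)
  df$hyper_p <- signif(df$hyper_p, digits)
  df$fisher_p <- signif(df$fisher_p, digits)
  df$fdr <- signif(df$fdr, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an enrichment table as TSV
#'
#' Columns mirror the mapped-pair report: set, a, b, c, d, fisher_p, fdr,
#' significant (plus gene/pair counts and the hypergeometric column).
#'
#' @param enr A `coexshift_enrichment` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment <- function(enr, path) {
  utils::write.table(as.data.frame(enr), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
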