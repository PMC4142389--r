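#' Load a transcription-factor target reference
#'
#' Reads a two-column tab-delimited file of (TF, target_gene) rows — the shape
#' of genome-wide TF binding-prediction extracts — into a named list of target
#' sets. Duplicate rows are collapsed; gene and TF symbols are upper-cased and
#' whitespace-stripped so they match expression gene ids deterministically.
#'
#' @param path Path to the TF-target TSV.
#' @return A `coex_reference` object: named list TF -> character vector of
#'   unique target gene symbols.
#' @export
load_tf_targets <- function(path) {
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L)
    stop("empty TF-target reference: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("TF-target reference needs two columns (TF, gene)")
  tf <- normalize_symbol(df[[1L]])
  tg <- normalize_symbol(df[[2L]])
  bad <- !nzchar(tf) | !nzchar(tg) | is.na(tf) | is.na(tg)
  if (any(bad)) stop("rows with missing fields in TF-target reference: ",
                     paste(which(bad), collapse = ", "))
  ref <- lapply(split(tg, tf), function(x) sort(unique(x)))
  structure(ref, class = "coex_reference")
}

# exact matching after upper-case + whitespace strip
normalize_symbol <- function(x) toupper(trimws(as.character(x)))

#' Common targets of a set of transcription factors
#'
#' Intersects the target sets of all requested TFs; the result is the
#' candidate gene set regulated concurrently by every one of them.
#'
#' @param ref A `coex_reference` (see [load_tf_targets()]) or a plain named
#'   list of character vectors.
#' @param tfs Character vector of TF names; each must exist in `ref`.
#' @return Sorted character vector of common target symbols (possibly empty).
#' @export
common_targets <- function(ref, tfs) {
  tfs <- normalize_symbol(tfs)
  if (length(tfs) == 0L) stop("at least one TF required")
  unknown <- setdiff(tfs, names(ref))
  if (length(unknown))
    stop("TF(s) not in reference: ", paste(unknown, collapse = ", "))
  sort(Reduce(intersect, ref[tfs]))
}

#' Restrict candidate genes to those measured on the array
#'
#' @param candidates Character vector of candidate gene symbols.
#' @param m A `coex_expression` object (post probe collapsing).
#' @return Sorted, duplicate-free vector of candidates present among the
#'   measured genes; errors if fewer than 2 survive (no pairs can be formed).
#' @export
restrict_to_measured <- function(candidates, m) {
  stopifnot(inherits(m, "coex_expression"))
  candidates <- unique(normalize_symbol(candidates))
  kept <- sort(intersect(candidates, normalize_symbol(rownames(m$values))))
  dropped <- length(candidates) - length(kept)
  if (dropped > 0L)
    message(sprintf("%d candidate gene(s) not measured; dropped", dropped))
  if (length(kept) < 2L)
    stop("fewer than 2 candidate genes are measured; cannot form gene pairs")
  kept
}
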