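#' Build a coexpression network from mapped pairs
#'
#' Nodes are the union of endpoint genes; edges carry the per-group
#' coexpression levels and the class label. An empty pair set gives a valid
#' empty network.
#'
#' @param set_name Name of the gene set the pairs were mapped from (stored as
#'   a graph attribute).
#' @param pairs Two-column matrix or data frame of gene pairs.
#' @param table A classified `coex_table` containing those pairs.
#' @param class_label Class the pairs belong to (edge attribute, default
#'   "normal_specific_strong").
#' @param shared_genes Optional character vector of genes present in more
#'   than one exported network; flagged as the node attribute
#'   `member_of_both_networks`.
#' @return An undirected [igraph::graph] with the attributes above.
#' @export
build_network <- function(set_name, pairs, table,
                          class_label = "normal_specific_strong",
                          shared_genes = character(0L)) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0L) {
    message(sprintf("gene set '%s': no mapped pairs; empty network", set_name))
    g <- igraph::make_empty_graph(0L, directed = FALSE)
  } else {
    keys <- pair_key(table$gene_i, table$gene_j)
    idx <- match(pair_key(pairs[, 1L], pairs[, 2L]), keys)
    if (anyNA(idx)) stop("pairs absent from the coexpression table")
    edges <- data.frame(from = pairs[, 1L], to = pairs[, 2L],
                        c_normal = table$c_normal[idx],
                        c_disease = table$c_disease[idx],
                        class = class_label, stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  }
  if (igraph::vcount(g) > 0L)
    igraph::V(g)$member_of_both_networks <-
      igraph::V(g)$name %in% shared_genes
  igraph::graph_attr(g, "set_name") <- set_name
  g
}

#' Write a coexpression network to SIF or GraphML
#'
#' SIF rows are "gene_i coexpressed_with gene_j"; GraphML preserves node and
#' edge attributes and round-trips through [igraph::read_graph()].
#'
#' @param net An [igraph::graph] (see [build_network()]).
#' @param path Output path.
#' @param format "sif" or "graphml".
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    if (igraph::ecount(net) == 0L) {
      writeLines(character(0L), path)
    } else {
      el <- igraph::as_edgelist(net)
      writeLines(paste(el[, 1L], "coexpressed_with", el[, 2L], sep = "\t"), path)
    }
  } else {
    igraph::write_graph(net, path, format = "graphml")
  }
  invisible(path)
}

#' Export one network per gene set for a chosen pair class
#'
#' @param enr A `coexshift_enrichment` table (for the set names).
#' @param fit A `coexshift` fit.
#' @param collection The gene-set collection used for `enr`.
#' @param dir Output directory (created if needed).
#' @param class_label Which specific pair class to export.
#' @param formats Character vector of formats (see [write_network()]).
#' @return Invisibly, character vector of files written, named
#'   `<set>__<class>.<ext>` (set names sanitised for the filesystem).
#' @export
export_networks <- function(enr, fit, collection, dir,
                            class_label = "normal_specific_strong",
                            formats = c("sif", "graphml")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cls <- fit$pairs
  candidates <- fit$genes
  mapped <- lapply(enr$set, function(nm) {
    ann <- annotated_pairs(normalize_symbol(collection[[nm]]), candidates)
    keys <- pair_key(cls$gene_i, cls$gene_j)
    idx <- match(pair_key(ann[, 1L], ann[, 2L]), keys)
    keep <- !is.na(idx) & cls[[class_label]][idx]
    keep[is.na(keep)] <- FALSE
    ann[keep, , drop = FALSE]
  })
  names(mapped) <- enr$set
  per_set <- unique_by_set(mapped)
  shared <- unique(per_set[duplicated(per_set)])
  files <- character(0L)
  for (nm in enr$set) {
    net <- suppressMessages(
      build_network(nm, mapped[[nm]], cls, class_label, shared))
    safe <- gsub("[^A-Za-z0-9._-]+", "_", nm)
    for (fmt in formats) {
      ext <- if (fmt == "sif") "sif" else "graphml"
      f <- file.path(dir, sprintf("%s__%s.%s", safe, class_label, ext))
      write_network(net, f, fmt)
      files <- c(files, f)
    }
  }
  invisible(files)
}

# genes listed once per set, so duplicated() marks cross-set sharing
unique_by_set <- function(mapped) {
  unlist(lapply(mapped, function(m) unique(as.vector(m))))
}
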