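#' Specification for a synthetic differential-coexpression dataset
#'
#' The generator emulates a small two-group microarray study: a block of
#' genes shares a single latent factor per group, giving equicorrelation
#' `rho_normal` among normal samples and `rho_disease` among disease samples;
#' the remaining genes are independent noise. Defaults mirror a typical
#' CD34+ study design with 8 normal and 9 disease samples.
#'
#' @param n_genes Total number of genes.
#' @param n_block Size of the correlated block (`<= n_genes`).
#' @param rho_normal,rho_disease Within-block target correlations in [0, 1).
#' @param n_normal,n_disease Sample counts (>= 3 each).
#' @param noise_sd Residual standard deviation of the expression scale.
#' @param seed Integer random seed; every generator output is deterministic
#'   given the seed.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 60L, n_block = 12L,
                           rho_normal = 0.85, rho_disease = 0,
                           n_normal = 8L, n_disease = 9L,
                           noise_sd = 1, seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes), n_block = as.integer(n_block),
               rho_normal = rho_normal, rho_disease = rho_disease,
               n_normal = as.integer(n_normal), n_disease = as.integer(n_disease),
               noise_sd = noise_sd, seed = as.integer(seed))
  if (spec$n_block > spec$n_genes) stop("n_block must not exceed n_genes")
  if (spec$n_normal < 3L || spec$n_disease < 3L)
    stop("sample counts must be >= 3")
  if (any(c(spec$rho_normal, spec$rho_disease) < 0) ||
      any(c(spec$rho_normal, spec$rho_disease) >= 1))
    stop("correlations must lie in [0, 1)")
  if (spec$noise_sd <= 0) stop("noise_sd must be positive")
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic two-group expression matrix
#'
#' Block genes are drawn as `sqrt(rho) * z_s + sqrt(1 - rho) * eps_gs` per
#' sample s (one shared latent factor per group), scaled by `noise_sd` and
#' shifted by a gene-specific baseline; non-block genes are independent.
#' Genes are named G0001..; block genes come first. Deterministic given
#' `spec$seed`.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `expression` (a `coex_expression`) and `block` (the
#'   block gene ids).
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  block <- genes[seq_len(spec$n_block)]
  samples <- c(sprintf("N%02d", seq_len(spec$n_normal)),
               sprintf("D%02d", seq_len(spec$n_disease)))
  group_of <- stats::setNames(rep(c("normal", "disease"),
                                  c(spec$n_normal, spec$n_disease)), samples)
  baseline <- stats::rnorm(spec$n_genes, mean = 8, sd = 1.5)

  draw_group <- function(n_samples, rho) {
    z <- stats::rnorm(n_samples)                      # shared latent factor
    eps <- matrix(stats::rnorm(spec$n_genes * n_samples),
                  nrow = spec$n_genes)
    x <- eps
    in_block <- seq_len(spec$n_block)
    if (spec$n_block > 0L)
      x[in_block, ] <- sqrt(rho) * matrix(z, spec$n_block, n_samples,
                                          byrow = TRUE) +
        sqrt(1 - rho) * eps[in_block, , drop = FALSE]
    baseline + spec$noise_sd * x
  }
  values <- cbind(draw_group(spec$n_normal, spec$rho_normal),
                  draw_group(spec$n_disease, spec$rho_disease))
  dimnames(values) <- list(genes, samples)
  list(expression = new_expression(values, group_of), block = block)
}

#' Generate a synthetic TF-target reference
#'
#' Each TF targets a random subset of the genes (fraction `coverage`), but
#' the correlated block is forced into every TF's target set, so the common
#' targets of all TFs are guaranteed to contain the block and candidate
#' selection recovers it.
#'
#' @param genes Character vector of all gene ids.
#' @param block Character vector of block gene ids (subset of `genes`).
#' @param tfs Character vector of TF names.
#' @param coverage Fraction of genes each TF targets, in (0, 1].
#' @param seed Integer random seed.
#' @return A `coex_reference` (named list TF -> targets).
#' @export
generate_reference <- function(genes, block, tfs = c("E2F1", "E2F2", "E2F3", "MYC"),
                               coverage = 0.5, seed = 1L) {
  stopifnot(all(block %in% genes), coverage > 0, coverage <= 1)
  set.seed(seed)
  n_pick <- max(1L, round(coverage * length(genes)))
  ref <- lapply(tfs, function(tf) {
    sort(unique(c(block, sample(genes, n_pick))))
  })
  structure(stats::setNames(ref, normalize_symbol(tfs)),
            class = "coex_reference")
}

#' Write a TF-target reference as two-column TSV
#'
#' @param ref A `coex_reference`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tf_targets <- function(ref, path) {
  df <- data.frame(tf = rep(names(ref), lengths(ref)),
                   gene = unlist(ref, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Generate a synthetic gene-set collection
#'
#' One "signal" set is drawn from the correlated block (topped up with
#' non-block genes only when the block is smaller than `set_size`, and always
#' holding at least half its genes from the block); the remaining sets are
#' random draws from all genes. Deterministic given `seed`.
#'
#' @param genes Character vector of all gene ids.
#' @param block Character vector of block gene ids.
#' @param n_sets Number of sets (>= 1; the first is the signal set).
#' @param set_size Genes per set (`<= length(genes)`).
#' @param seed Integer random seed.
#' @return A `coex_genesets` named list; the signal set is named
#'   "signal_block".
#' @export
generate_gene_sets <- function(genes, block, n_sets = 8L, set_size = 10L,
                               seed = 1L) {
  stopifnot(set_size <= length(genes), n_sets >= 1L)
  set.seed(seed)
  n_sig <- min(length(block), set_size)
  signal <- sort(c(sample(block, n_sig),
                   sample(setdiff(genes, block), set_size - n_sig)))
  sets <- list(signal_block = signal)
  if (n_sets > 1L) {
    for (i in seq_len(n_sets - 1L))
      sets[[sprintf("random_set_%02d", i)]] <- sort(sample(genes, set_size))
  }
  structure(sets, class = "coex_genesets")
}

#' Write a gene-set collection in GMT format
#'
#' @param sets A `coex_genesets` named list.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(unname(lines), path)
  invisible(path)
}

#' Write a full synthetic input bundle to a directory
#'
#' Produces `expression.tsv`, `labels.tsv`, `tf_targets.tsv` and
#' `gene_sets.gmt` — everything [run_pipeline()] needs.
#'
#' @param dir Output directory (created if needed).
#' @param spec A `synthetic_spec`; its seed also drives the reference and
#'   gene-set draws (offset so the three stages use distinct streams).
#' @param tfs TF names for the reference.
#' @param n_sets,set_size Gene-set collection shape.
#' @return Invisibly, named list of the file paths plus the block gene ids.
#' @export
simulate_inputs <- function(dir, spec = synthetic_spec(),
                            tfs = c("E2F1", "E2F2", "E2F3", "MYC"),
                            n_sets = 8L, set_size = 10L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_expression(spec)
  genes <- rownames(sim$expression$values)
  # coverage 0.8 over 4 TFs keeps ~0.41 of background genes in the common
  # target set, so candidates mix block and background as in a real screen
  ref <- generate_reference(genes, sim$block, tfs = tfs,
                            coverage = 0.8, seed = spec$seed + 1000L)
  sets <- generate_gene_sets(genes, sim$block, n_sets = n_sets,
                             set_size = set_size, seed = spec$seed + 2000L)
  paths <- list(expression = file.path(dir, "expression.tsv"),
                labels = file.path(dir, "labels.tsv"),
                tf_targets = file.path(dir, "tf_targets.tsv"),
                gene_sets = file.path(dir, "gene_sets.gmt"))
  write_expression(sim$expression, paths$expression, paths$labels)
  write_tf_targets(ref, paths$tf_targets)
  write_gene_sets(sets, paths$gene_sets)
  invisible(c(paths, list(block = sim$block)))
}
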