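#' Run the full differential-coexpression pipeline from files
#'
#' Stages: load expression + labels -> optional probe collapsing -> candidate
#' selection (common TF targets restricted to measured genes) -> pairwise
#' coexpression -> KS cutoff -> classification + chi-square -> gene-set
#' enrichment -> network export. Writes `report.json`, `pairs.tsv`,
#' `enrichment.tsv` and `networks/*` to the output directory. The report
#' carries no timestamps, so identical inputs yield byte-identical reports;
#' stage progress is logged to stderr.
#'
#' @param config Named list (see the fields below) or path to a YAML file with
#'   the same fields: `expression`, `labels`, `tf_targets`, `gene_sets`
#'   (paths; `probe_map` optional), `tfs` (character vector or comma-separated
#'   string), `disease` (group label, default the second seen), `cutoff`
#'   (optional numeric override), `fdr_threshold` (default 0.05),
#'   `output_dir`.
#' @param ... Field overrides taking precedence over the config file.
#' @return Invisibly, the run report (named list, also written as JSON).
#' @export
run_pipeline <- function(config, ...) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  config <- utils::modifyList(config, list(...))
  for (f in c("expression", "labels", "tf_targets", "gene_sets"))
    if (is.null(config[[f]])) stop("config field missing: ", f)
  fdr_threshold <- config$fdr_threshold %||% 0.05
  if (fdr_threshold <= 0 || fdr_threshold >= 1)
    stop("fdr_threshold must lie in (0, 1)")
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(fmt, ...) message(sprintf(paste0("[coexshift] ", fmt), ...))

  stage("loading expression: %s", config$expression)
  expr <- load_expression(config$expression, config$labels)
  if (!is.null(config$probe_map)) {
    stage("collapsing probes via %s", config$probe_map)
    pm <- utils::read.delim(config$probe_map, header = FALSE,
                            stringsAsFactors = FALSE)
    expr <- collapse_probes(expr, pm)
  }
  stage("%d genes x %d samples", nrow(expr$values), ncol(expr$values))

  ref <- load_tf_targets(config$tf_targets)
  tfs <- config$tfs %||% names(ref)
  if (is.character(tfs) && length(tfs) == 1L && grepl(",", tfs))
    tfs <- strsplit(tfs, ",")[[1L]]
  candidates <- common_targets(ref, tfs)
  stage("%d common targets of %s", length(candidates), paste(tfs, collapse = "+"))
  genes <- restrict_to_measured(candidates, expr)
  stage("%d candidate genes measured", length(genes))

  fit <- coexshift(expr, genes = genes, disease = config$disease,
                   cutoff = config$cutoff)
  stage("D = %.4f, C = %.4f, KS p = %.3g; chi2 = %.2f (p = %.3g)",
        fit$ks$D, fit$cutoff, fit$ks$p_value,
        fit$chi2$statistic, fit$chi2$p_value)

  sets <- load_gene_sets(config$gene_sets)
  enr <- enrich_pairs(sets, fit, universe_size = nrow(expr$values),
                      fdr_threshold = fdr_threshold)
  stage("%d gene sets, %d significant at FDR < %g",
        nrow(enr), sum(enr$significant), fdr_threshold)

  write_coex_table(fit$pairs, file.path(out_dir, "pairs.tsv"))
  write_enrichment(enr, file.path(out_dir, "enrichment.tsv"))
  export_networks(enr, fit, sets, file.path(out_dir, "networks"))

  report <- list(
    n_genes_measured = nrow(expr$values),
    n_samples = ncol(expr$values),
    groups = as.list(table(factor(expr$group_of, levels = expr$groups))),
    tfs = as.list(tfs),
    n_common_targets = length(candidates),
    n_candidate_genes = length(genes),
    n_pairs = nrow(fit$pairs),
    ks = list(D = fit$ks$D, C = fit$ks$C, p_value = fit$ks$p_value),
    cutoff_used = fit$cutoff,
    class_counts = fit$counts,
    chi2 = fit$chi2,
    fdr_threshold = fdr_threshold,
    enrichment = as.data.frame(enr)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage("report written to %s", file.path(out_dir, "report.json"))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Subcommands:
#' \describe{
#'   \item{run}{`coexshift run --config cfg.yaml [--cutoff F] [--fdr Q]` —
#'     execute the pipeline.}
#'   \item{simulate}{`coexshift simulate --seed N --out DIR
#'     [--rho-normal F] [--rho-disease F]` — write a synthetic input bundle.}
#'   \item{version}{print the package version.}
#' }
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit code: 0 on success, 2 on usage errors, 1 on stage
#'   failures.
#' @export
coexshift_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: coexshift run --config FILE [--cutoff F] [--fdr Q] [--out DIR]",
    "       coexshift simulate --seed N --out DIR [--rho-normal F] [--rho-disease F]",
    "       coexshift version", sep = "\n")
  if (length(argv) == 0L || argv[1L] %in% c("--help", "-h")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  cmd <- argv[1L]
  opts <- parse_flags(argv[-1L])
  if (!is.null(opts$error)) {
    message(opts$error, "\n", usage)
    return(invisible(2L))
  }
  flags <- opts$flags
  code <- switch(cmd,
    version = { cat(as.character(utils::packageVersion("coexshift")), "\n"); 0L },
    simulate = {
      if (is.null(flags$seed) || is.null(flags$out)) {
        message("simulate requires --seed and --out\n", usage); 2L
      } else {
        spec <- synthetic_spec(
          seed = as.integer(flags$seed),
          rho_normal = as.numeric(flags[["rho-normal"]] %||% 0.85),
          rho_disease = as.numeric(flags[["rho-disease"]] %||% 0))
        simulate_inputs(flags$out, spec)
        0L
      }
    },
    run = {
      if (is.null(flags$config) || !file.exists(flags$config %||% "")) {
        message("run requires an existing --config file\n", usage); 2L
      } else {
        extra <- list()
        if (!is.null(flags$cutoff)) extra$cutoff <- as.numeric(flags$cutoff)
        if (!is.null(flags$fdr)) extra$fdr_threshold <- as.numeric(flags$fdr)
        if (!is.null(flags$out)) extra$output_dir <- flags$out
        ok <- tryCatch(
          { do.call(run_pipeline, c(list(flags$config), extra)); TRUE },
          error = function(e) { message("pipeline failed: ", conditionMessage(e)); FALSE })
        if (ok) 0L else 1L
      }
    },
    { message("unknown subcommand: ", cmd, "\n", usage); 2L })
  invisible(code)
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      return(list(error = paste("unexpected argument:", a)))
    if (i + 1L > length(args))
      return(list(error = paste("flag needs a value:", a)))
    flags[[substring(a, 3L)]] <- args[i + 1L]
    i <- i + 2L
  }
  list(flags = flags)
}
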