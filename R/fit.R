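#' Fit a disease-specific coexpression cutoff model
#'
#' The central estimator of the package. For every unordered pair of the
#' candidate genes it computes the coexpression level — the absolute Pearson
#' correlation of the two expression profiles — separately in the two sample
#' groups, contrasts the two empirical survival functions of those levels with
#' the two-sample Kolmogorov-Smirnov statistic, and takes the level of maximum
#' deviation as the disease-specific cutoff C. Pairs with level >= C are
#' classified "strong", below it "weak", in each group; pairs strong in
#' exactly one group form the group-specific classes, and a chi-square test
#' reports whether the strong/weak proportions differ between groups.
#'
#' @param expr A `coex_expression` object (see [load_expression()],
#'   [new_expression()]) or a plain numeric genes x samples matrix, in which
#'   case `groups` must be supplied.
#' @param groups Optional named character vector mapping sample ids to the two
#'   group labels (ignored when `expr` already carries labels).
#' @param genes Candidate gene ids to analyse; default all measured genes.
#' @param disease Which group label is the disease group; default the second
#'   label in order of appearance.
#' @param cutoff Optional fixed cutoff overriding the data-derived C (the KS
#'   scan is still performed and reported).
#' @return An object of class `coexshift`: list with elements `pairs` (the
#'   classified `coex_table`), `ks` (a `ks_cutoff`), `cutoff` (the one used
#'   for classification), `counts`, `chi2`, `genes`, `groups` (named:
#'   normal/disease labels) and `call`.
#' @seealso [enrich_pairs()] for gene-set mapping, [run_pipeline()] for the
#'   file-driven workflow.
#' @examples
#' sim <- generate_expression(synthetic_spec(n_genes = 30, n_block = 8, seed = 1))
#' fit <- coexshift(sim$expression, disease = "disease")
#' fit
#' coef(fit)
#' @export
coexshift <- function(expr, groups = NULL, genes = NULL, disease = NULL,
                      cutoff = NULL) {
  if (!inherits(expr, "coex_expression")) {
    if (is.null(groups)) stop("supply 'groups' when 'expr' is a plain matrix")
    expr <- new_expression(as.matrix(expr), groups)
  }
  if (is.null(disease)) disease <- expr$groups[2L]
  if (!disease %in% expr$groups)
    stop("'disease' must be one of: ", paste(expr$groups, collapse = ", "))
  normal <- setdiff(expr$groups, disease)
  subm <- split_groups(expr)

  if (is.null(genes)) genes <- rownames(expr$values)
  genes <- restrict_to_measured(genes, expr)

  tab <- pairwise_coexpression(disease = subm[[disease]],
                               normal = subm[[normal]], genes = genes)
  ks <- ks_max_deviation(c_d = tab$c_disease, c_n = tab$c_normal)
  C <- if (is.null(cutoff)) ks$C else cutoff
  tab <- classify_pairs(tab, C)
  counts <- count_classes(tab)
  structure(list(pairs = tab, ks = ks, cutoff = C, counts = counts,
                 chi2 = chi2_proportions(counts),
                 genes = sort(unique(c(tab$gene_i, tab$gene_j))),
                 groups = c(normal = normal, disease = disease),
                 call = match.call()),
            class = "coexshift")
}

#' @export
print.coexshift <- function(x, ...) {
  cat("Differential coexpression cutoff model\n\n")
  cat(sprintf("  %d candidate genes, %d gene pairs (groups: normal = '%s', disease = '%s')\n",
              length(x$genes), nrow(x$pairs), x$groups["normal"], x$groups["disease"]))
  cat(sprintf("  KS max deviation D = %.4f, p = %.3g\n", x$ks$D, x$ks$p_value))
  cat(sprintf("  Cutoff C = %.4f%s\n", x$cutoff,
              if (x$cutoff != x$ks$C) " (user override)" else ""))
  cat(sprintf("  Strong pairs: %d (normal) vs %d (disease); chi-square = %.1f, p = %.3g\n",
              x$counts$strong_normal, x$counts$strong_disease,
              x$chi2$statistic, x$chi2$p_value))
  invisible(x)
}

#' @export
coef.coexshift <- function(object, ...) {
  c(C = object$cutoff, D = object$ks$D)
}

#' Summarize a fitted coexpression cutoff model
#'
#' @param object A `coexshift` fit.
#' @param ... Unused.
#' @return A `summary.coexshift` list with the class-count table, specific
#'   pair counts and test results.
#' @export
summary.coexshift <- function(object, ...) {
  cnt <- object$counts
  structure(list(
    fit = object,
    class_table = matrix(c(cnt$strong_normal, cnt$weak_normal,
                           cnt$strong_disease, cnt$weak_disease),
                         nrow = 2L, byrow = TRUE,
                         dimnames = list(unname(object$groups[c("normal", "disease")]),
                                         c("strong", "weak"))),
    n_normal_specific_strong = sum(object$pairs$normal_specific_strong),
    n_disease_specific_strong = sum(object$pairs$disease_specific_strong)),
    class = "summary.coexshift")
}

#' @export
print.summary.coexshift <- function(x, ...) {
  print(x$fit)
  cat("\nClass counts:\n")
  print(x$class_table)
  cat(sprintf("\nGroup-specific strong pairs: %d normal-specific, %d disease-specific\n",
              x$n_normal_specific_strong, x$n_disease_specific_strong))
  invisible(x)
}

#' Classify new gene pairs at the fitted cutoff
#'
#' @param object A `coexshift` fit.
#' @param newdata Data frame with columns `c_normal` and `c_disease` (levels
#'   in [0, 1]); default the training pairs.
#' @param ... Unused.
#' @return The classified table (see [classify_pairs()]).
#' @export
predict.coexshift <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$pairs)
  classify_pairs(newdata, object$cutoff)
}

#' Plot the fitted survival functions and their deviation
#'
#' Left panel: empirical survival functions Prob(level >= c) of the
#' coexpression levels in each group, with the cutoff C marked. Right panel:
#' absolute deviation |F_disease - F_normal| against the level, peaking at D.
#'
#' @param x A `coexshift` fit.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.coexshift <- function(x, ...) {
  grid <- x$ks$grid
  f_d <- survival_on_grid(x$pairs$c_disease, grid)
  f_n <- survival_on_grid(x$pairs$c_normal, grid)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(grid, f_n, type = "s", col = "blue", xlab = "coexpression level",
                 ylab = "Prob(level >= c)", main = "Survival functions", ...)
  graphics::lines(grid, f_d, type = "s", col = "red")
  graphics::abline(v = x$cutoff, lty = 2)
  graphics::legend("topright", legend = unname(x$groups), col = c("blue", "red"),
                   lty = 1, bty = "n")
  graphics::plot(grid, abs(f_d - f_n), type = "l", xlab = "coexpression level",
                 ylab = "|F_d - F_n|", main = sprintf("Deviation (D = %.4f)", x$ks$D))
  graphics::abline(v = x$ks$C, lty = 2)
  invisible(x)
}
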