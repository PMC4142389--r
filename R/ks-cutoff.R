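#' Empirical survival value
#'
#' Fraction of sample values greater than or equal to `c` — the empirical
#' survival function F(c) = Prob(level >= c), with ties included via the `>=`.
#'
#' @param sample Non-empty numeric vector of observed levels.
#' @param c Query level(s); vectorized.
#' @return Probability in [0, 1] per query point.
#' @export
survival_value <- function(sample, c) {
  if (length(sample) == 0L) stop("empty sample")
  vapply(c, function(ci) mean(sample >= ci), numeric(1L))
}

# counts of values >= each grid point, via one sort; equals
# survival_value(sample, grid) but O((n + g) log) instead of O(n * g)
survival_on_grid <- function(sample, grid) {
  s <- sort(sample)
  # findInterval with left.open counts values strictly below each grid point
  below <- findInterval(grid, s, left.open = TRUE)
  1 - below / length(s)
}

#' Maximum deviation of two empirical survival functions
#'
#' The core of the disease-specific cutoff: both groups' coexpression levels
#' are reduced to empirical survival functions F(c) = Prob(level >= c),
#' evaluated on the sorted union of all observed levels (survival functions
#' are step functions, so deviation extrema occur at observed points). The
#' maximum absolute deviation D is the classical two-sample Kolmogorov-Smirnov
#' statistic; the smallest grid value attaining D is reported as the cutoff C.
#'
#' @param c_d,c_n Non-empty numeric vectors of levels (disease, normal group).
#' @return An object of class `ks_cutoff`: list with `D`, `C`, `p_value`
#'   (asymptotic, see [ks_asymptotic_pvalue()]), `n_disease`, `n_normal`, and
#'   the evaluation `grid`.
#' @export
ks_max_deviation <- function(c_d, c_n) {
  if (length(c_d) == 0L || length(c_n) == 0L) stop("empty level set")
  grid <- sort(unique(c(c_d, c_n)))
  dev <- abs(survival_on_grid(c_d, grid) - survival_on_grid(c_n, grid))
  D <- max(dev)
  C <- grid[which(dev == D)[1L]]  # smallest grid value attaining D
  structure(list(D = D, C = C,
                 p_value = ks_asymptotic_pvalue(D, length(c_d), length(c_n)),
                 n_disease = length(c_d), n_normal = length(c_n), grid = grid),
            class = "ks_cutoff")
}

#' @export
print.ks_cutoff <- function(x, ...) {
  cat(sprintf(
    "Two-sample KS cutoff: D = %.4f at C = %.4f (n = %d vs %d), p = %.3g\n",
    x$D, x$C, x$n_disease, x$n_normal, x$p_value))
  invisible(x)
}

#' Asymptotic two-sample Kolmogorov-Smirnov p-value
#'
#' Evaluates the Kolmogorov series
#' p = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2) with
#' lambda = D * sqrt(n m / (n + m)), truncated once terms fall below 1e-300,
#' clamped to [0, 1]. No small-sample bias correction is applied, so late
#' digits may differ from implementations that use one.
#'
#' @param D Maximum deviation in [0, 1].
#' @param n,m Sizes of the two level sets.
#' @return p-value in [0, 1].
#' @export
ks_asymptotic_pvalue <- function(D, n, m) {
  stopifnot(D >= 0, D <= 1, n >= 1, m >= 1)
  lambda <- D * sqrt(n * m / (n + m))
  if (lambda == 0) return(1)
  p <- 0
  for (k in seq_len(10000L)) {
    term <- exp(-2 * k^2 * lambda^2)
    p <- p + (-1)^(k - 1) * term
    if (term < 1e-300) break
  }
  min(max(2 * p, 0), 1)
}
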