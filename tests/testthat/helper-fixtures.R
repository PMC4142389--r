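# in-code fixtures shared across test files

# random two-group expression object: genes G01.., samples split n_a + n_b
make_expr <- function(n_genes = 6L, n_a = 4L, n_b = 4L, seed = 42L) {
  set.seed(seed)
  values <- matrix(rnorm(n_genes * (n_a + n_b), mean = 8),
                   nrow = n_genes,
                   dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                                   sprintf("S%02d", seq_len(n_a + n_b))))
  groups <- setNames(rep(c("normal", "disease"), c(n_a, n_b)),
                     colnames(values))
  new_expression(values, groups)
}

# write a tab-delimited matrix + labels pair to tempfiles, return paths
write_fixture_files <- function(expr) {
  mp <- tempfile(fileext = ".tsv"); lp <- tempfile(fileext = ".tsv")
  write_expression(expr, mp, lp)
  list(matrix = mp, labels = lp)
}

# random classified pair table over n_genes (no expression needed)
make_classified <- function(n_genes = 10L, C = 0.5, seed = 1L) {
  set.seed(seed)
  genes <- sprintf("G%02d", seq_len(n_genes))
  idx <- utils::combn(n_genes, 2L)
  tab <- data.frame(gene_i = genes[idx[1L, ]], gene_j = genes[idx[2L, ]],
                    c_normal = runif(ncol(idx)), c_disease = runif(ncol(idx)),
                    stringsAsFactors = FALSE)
  classify_pairs(tab, C)
}

# exact one-sided Fisher p by enumerating all tables with the observed margins
enum_fisher_upper <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  if (N == 0L) return(1)
  a_range <- max(0L, r1 + c1 - N):min(r1, c1)
  probs <- choose(c1, a_range) * choose(N - c1, r1 - a_range) / choose(N, r1)
  sum(probs[a_range >= a])
}
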