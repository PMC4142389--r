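test_that("hypergeometric enrichment agrees with combinatorial enumeration", {
  universe <- sprintf("u%02d", 1:20)
  cand <- universe[1:10]
  annot <- universe[c(1:8, 11, 12)]  # overlap k = 8
  want <- sum(vapply(8:10, function(j)
    choose(10, j) * choose(10, 10 - j), numeric(1L))) / choose(20, 10)
  expect_equal(hypergeometric_enrichment(cand, annot, 20L), want,
               tolerance = 1e-12)

  # degenerate upper tails
  expect_equal(hypergeometric_enrichment(cand, universe, 20L), 1)
  expect_equal(hypergeometric_enrichment(universe[1:5], universe[6:10], 20L), 1)
  expect_error(hypergeometric_enrichment(universe, universe[1:3], 5L), "universe")

  # random cases over small universes vs direct enumeration
  set.seed(77)
  for (rep in 1:25) {
    N <- sample(8:25, 1L)
    u <- sprintf("g%02d", seq_len(N))
    cs <- sample(u, sample(2:N, 1L))
    as_ <- sample(u, sample(2:N, 1L))
    k <- length(intersect(cs, as_))
    jmax <- min(length(cs), length(as_))
    want <- sum(vapply(k:jmax, function(j)
      choose(length(as_), j) * choose(N - length(as_), length(cs) - j),
      numeric(1L))) / choose(N, length(cs))
    expect_equal(hypergeometric_enrichment(cs, as_, N), want, tolerance = 1e-10)
  }
})

test_that("annotated pairs enumerate all i<j combinations of annotated candidates", {
  cand <- sprintf("G%02d", 1:10)
  expect_identical(nrow(annotated_pairs(cand[1:4], cand)), 6L)
  expect_identical(nrow(annotated_pairs(cand[1L], cand)), 0L)
  expect_identical(nrow(annotated_pairs(character(0L), cand)), 0L)

  set.seed(8)
  annot <- sample(c(cand, sprintf("X%02d", 1:5)), 8L)
  got <- annotated_pairs(annot, cand)
  genes <- sort(intersect(annot, cand))
  want <- NULL
  for (i in seq_along(genes)) for (j in seq_along(genes))
    if (i < j) want <- rbind(want, c(genes[i], genes[j]))
  expect_equal(unname(got), unname(want))
  expect_true(all(got[, 1L] < got[, 2L]))
})

test_that("pair mapping counts intersections with the specific classes", {
  cls <- make_classified(n_genes = 10L, C = 0.5, seed = 4L)
  # a set whose pairs are exactly the normal-specific strong ones
  nss <- cls[cls$normal_specific_strong, c("gene_i", "gene_j")]
  cnt <- map_pairs(as.matrix(nss), cls)
  expect_identical(cnt$a, nrow(nss))
  expect_identical(cnt$b, 0L)
  expect_identical(cnt$c, 0L)
  expect_identical(cnt$d, nrow(nss))

  # disjoint pairs are dropped with a message and count nothing
  alien <- matrix(c("Z1", "Z2"), ncol = 2L)
  expect_message(cnt0 <- map_pairs(alien, cls), "dropped")
  expect_identical(unlist(cnt0), c(a = 0L, b = 0L, c = 0L, d = 0L))

  # random sets vs independent set-intersection tallies; a = d and b = c always
  set.seed(42)
  for (rep in 1:10) {
    pick <- cls[sample(nrow(cls), 20L), ]
    ann <- as.matrix(pick[, c("gene_i", "gene_j")])
    got <- map_pairs(ann, cls)
    expect_identical(got$a, sum(pick$normal_specific_strong))
    expect_identical(got$b, sum(pick$normal_specific_weak))
    expect_identical(got$c, sum(pick$disease_specific_strong))
    expect_identical(got$d, sum(pick$disease_specific_weak))
    expect_identical(got$a, got$d)
    expect_identical(got$b, got$c)
  }
})

test_that("one-sided Fisher test reproduces exact hypergeometric tails", {
  p1 <- fisher_one_sided(list(a = 6L, b = 0L, c = 0L, d = 6L))
  expect_equal(p1, 1 / 924, tolerance = 1e-12)   # C(12,6) tables, only one at a=6
  expect_equal(round(p1, 3L), 0.001)
  p2 <- fisher_one_sided(list(a = 8L, b = 2L, c = 2L, d = 8L))
  expect_equal(round(p2, 3L), 0.012)
  expect_message(p0 <- fisher_one_sided(list(a = 0L, b = 0L, c = 0L, d = 0L)),
                 "convention")
  expect_equal(p0, 1)
})

test_that("Fisher p decreases with enrichment and is symmetric under reversal", {
  # symmetry: (a,b,c,d) vs (d,c,b,a) share the a-enriched tail
  set.seed(55)
  for (rep in 1:15) {
    cells <- as.integer(sample(0:8, 4L, replace = TRUE))
    if (sum(cells) == 0L) cells[1L] <- 1L
    p_fwd <- fisher_one_sided(list(a = cells[1L], b = cells[2L],
                                   c = cells[3L], d = cells[4L]))
    p_rev <- fisher_one_sided(list(a = cells[4L], b = cells[3L],
                                   c = cells[2L], d = cells[1L]))
    expect_equal(p_fwd, p_rev, tolerance = 1e-12)
  }
  # symmetric tables (a = d, b = c): p monotone in a - b at fixed a + b
  for (total in c(6L, 9L, 12L)) {
    ps <- vapply(0:total, function(a)
      fisher_one_sided(list(a = a, b = total - a, c = total - a, d = a)),
      numeric(1L))
    expect_true(all(diff(ps) <= 1e-12))
  }
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(c(0.5, 0.5, 0.5)), c(0.5, 0.5, 0.5))
  expect_error(bh_fdr(c(0.2, 1.2)), "\\[0, 1\\]")
  set.seed(10)
  p <- runif(20)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p) && all(adj <= 1))
  # rejection set at level q matches the classical step-up rule
  q <- 0.2
  o <- order(p)
  k <- max(c(0L, which(p[o] <= q * seq_along(p) / length(p))))
  classical <- if (k > 0L) sort(o[seq_len(k)]) else integer(0L)
  expect_identical(which(adj <= q), classical)
})

test_that("gene-set enrichment reports every set and flags by FDR", {
  cls <- make_classified(n_genes = 12L, C = 0.5, seed = 9L)
  cand <- sort(unique(c(cls$gene_i, cls$gene_j)))
  # signal set = genes of normal-specific strong pairs; plus a tiny set
  nss_genes <- unique(unlist(cls[cls$normal_specific_strong,
                                 c("gene_i", "gene_j")]))[1:6]
  sets <- list(signal = nss_genes, tiny = cand[1L],
               broad = cand[seq_len(8L)])
  enr <- suppressMessages(enrich_pairs(sets, cls, universe_size = 100L))
  expect_identical(nrow(enr), 3L)
  expect_identical(enr$set, c("signal", "tiny", "broad"))
  # a sub-pair set yields no pairs but stays in the family with p = 1
  expect_identical(enr$annotated_pair_count[enr$set == "tiny"], 0L)
  expect_equal(enr$fisher_p[enr$set == "tiny"], 1)
  expect_equal(enr$fdr, bh_fdr(enr$fisher_p))
  expect_identical(enr$significant, enr$fdr < 0.05)
  expect_true(all(enr$a == enr$d) && all(enr$b == enr$c))
})

test_that("GMT and two-column gene-set files load identically", {
  sets <- list(alpha = c("G01", "G02", "G03"), beta = c("G02", "G04"))
  gmt <- tempfile(fileext = ".gmt")
  write_gene_sets(structure(sets, class = "coex_genesets"), gmt)
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("alpha\tG01", "alpha\tG02", "alpha\tG03",
               "beta\tG02", "beta\tG04"), tsv)
  from_gmt <- load_gene_sets(gmt)
  from_tsv <- load_gene_sets(tsv)
  expect_identical(lapply(from_gmt, sort)[order(names(from_gmt))],
                   lapply(from_tsv, sort)[order(names(from_tsv))])
  empty <- tempfile(fileext = ".gmt")
  writeLines(character(0L), empty)
  expect_error(load_gene_sets(empty), "empty")
})
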