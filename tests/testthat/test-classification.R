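test_that("strong/weak uses >= C and specific flags follow the identities", {
  # the EFNA5-EPHA4 shape: strong in normal, essentially uncorrelated in disease
  tab <- data.frame(gene_i = "EFNA5", gene_j = "EPHA4",
                    c_normal = 0.720, c_disease = 0.013)
  cls <- classify_pairs(tab, 0.440)
  expect_identical(cls$class_normal, "strong")
  expect_identical(cls$class_disease, "weak")
  expect_true(cls$normal_specific_strong)
  expect_true(cls$disease_specific_weak)
  expect_false(cls$disease_specific_strong)

  # boundary: a level exactly at the cutoff is strong
  at <- classify_pairs(data.frame(gene_i = "A", gene_j = "B",
                                  c_normal = 0.5, c_disease = 0.49), 0.5)
  expect_identical(at$class_normal, "strong")
  expect_identical(at$class_disease, "weak")

  # all levels below the cutoff leave zero strong pairs
  low <- make_classified(n_genes = 6L, C = 1, seed = 2L)
  expect_identical(count_classes(low),
                   list(strong_normal = 0L, weak_normal = 15L,
                        strong_disease = 0L, weak_disease = 15L))
})

test_that("random classifications match a four-branch reference conditional", {
  set.seed(12)
  for (rep in 1:10) {
    C <- runif(1)
    cls <- make_classified(n_genes = 8L, C = C, seed = rep)
    for (k in seq_len(nrow(cls))) {
      sn <- cls$c_normal[k] >= C; sd_ <- cls$c_disease[k] >= C
      want <- if (sn && !sd_) "ns" else if (!sn && sd_) "ds"
              else if (sn && sd_) "both" else "neither"
      expect_identical(cls$normal_specific_strong[k], want == "ns")
      expect_identical(cls$disease_specific_strong[k], want == "ds")
    }
    # set identities hold exactly
    expect_identical(cls$normal_specific_strong, cls$disease_specific_weak)
    expect_identical(cls$disease_specific_strong, cls$normal_specific_weak)
  }
})

test_that("class counts tally an independent loop and rows sum to the total", {
  cls <- make_classified(n_genes = 15L, C = 0.4, seed = 6L)  # 105 pairs
  cnt <- count_classes(cls)
  sn <- 0L; sd_ <- 0L
  for (k in seq_len(nrow(cls))) {
    if (cls$class_normal[k] == "strong") sn <- sn + 1L
    if (cls$class_disease[k] == "strong") sd_ <- sd_ + 1L
  }
  expect_identical(cnt$strong_normal, sn)
  expect_identical(cnt$strong_disease, sd_)
  expect_identical(cnt$strong_normal + cnt$weak_normal, nrow(cls))
  expect_identical(cnt$strong_disease + cnt$weak_disease, nrow(cls))
})

test_that("raising the cutoff never increases a strong count", {
  tab <- make_classified(n_genes = 12L, C = 0, seed = 3L)
  cuts <- seq(0, 1, by = 0.1)
  strong_n <- strong_d <- integer(0L)
  for (C in cuts) {
    cnt <- count_classes(classify_pairs(tab, C))
    strong_n <- c(strong_n, cnt$strong_normal)
    strong_d <- c(strong_d, cnt$strong_disease)
  }
  expect_true(all(diff(strong_n) <= 0L))
  expect_true(all(diff(strong_d) <= 0L))
})

test_that("chi-square on class proportions matches the closed form", {
  # homogeneous table: no signal
  flat <- chi2_proportions(list(strong_normal = 5L, weak_normal = 5L,
                                strong_disease = 5L, weak_disease = 5L))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  # oracle: sum (O - E)^2 / E over the four cells, no continuity correction
  set.seed(14)
  for (rep in 1:20) {
    cells <- as.integer(rpois(4L, lambda = 40) + 1L)
    cnt <- list(strong_normal = cells[1L], weak_normal = cells[2L],
                strong_disease = cells[3L], weak_disease = cells[4L])
    obs <- matrix(cells, 2L, byrow = TRUE)
    expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
    stat <- sum((obs - expected)^2 / expected)
    got <- chi2_proportions(cnt)
    expect_equal(got$statistic, stat, tolerance = 1e-10)
    expect_equal(got$p_value, pchisq(stat, df = 1L, lower.tail = FALSE),
                 tolerance = 1e-10)
    # invariant under swapping the two group rows
    swapped <- chi2_proportions(list(strong_normal = cells[3L],
                                     weak_normal = cells[4L],
                                     strong_disease = cells[1L],
                                     weak_disease = cells[2L]))
    expect_equal(swapped$statistic, got$statistic)
  }
  expect_error(chi2_proportions(list(strong_normal = 0L, weak_normal = 0L,
                                     strong_disease = 3L, weak_disease = 4L)),
               "marginal")
})
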