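#' Classify gene pairs as strongly or weakly coexpressed in each group
#'
#' A pair is "strong" in a group when its coexpression level is greater than
#' or equal to the cutoff `C` in that group, "weak" otherwise. Group-specific
#' flags follow: a pair strong in normal and weak in disease is
#' normal-specific strong — identically, disease-specific weak — and vice
#' versa.
#'
#' @param table A `coex_table` data frame (see [pairwise_coexpression()]).
#' @param C Cutoff level in [0, 1].
#' @return The table with columns appended: `class_normal`, `class_disease`
#'   ("strong"/"weak") and logical flags `normal_specific_strong`,
#'   `disease_specific_strong`, `normal_specific_weak`,
#'   `disease_specific_weak`.
#' @export
classify_pairs <- function(table, C) {
  stopifnot(is.data.frame(table), C >= 0, C <= 1)
  strong_n <- table$c_normal >= C
  strong_d <- table$c_disease >= C
  table$class_normal <- ifelse(strong_n, "strong", "weak")
  table$class_disease <- ifelse(strong_d, "strong", "weak")
  table$normal_specific_strong <- strong_n & !strong_d
  table$disease_specific_strong <- strong_d & !strong_n
  # weak in exactly one group mirrors strength in the other
  table$normal_specific_weak <- table$disease_specific_strong
  table$disease_specific_weak <- table$normal_specific_strong
  class(table) <- unique(c("coex_table", class(table)))
  table
}

#' Count strong/weak pairs per group
#'
#' @param cls A classified `coex_table` (see [classify_pairs()]).
#' @return List with integer counts `strong_normal`, `weak_normal`,
#'   `strong_disease`, `weak_disease`; each row (group) sums to the total
#'   pair count.
#' @export
count_classes <- function(cls) {
  stopifnot(all(c("class_normal", "class_disease") %in% names(cls)))
  list(strong_normal = sum(cls$class_normal == "strong"),
       weak_normal = sum(cls$class_normal == "weak"),
       strong_disease = sum(cls$class_disease == "strong"),
       weak_disease = sum(cls$class_disease == "weak"))
}

#' Chi-square test on strong/weak proportions between groups
#'
#' Pearson chi-square (df = 1, no continuity correction) on the 2x2 table
#' [[strong_normal, weak_normal], [strong_disease, weak_disease]], testing
#' whether the proportion of strongly coexpressed pairs differs between the
#' groups.
#'
#' @param counts A class-count list (see [count_classes()]).
#' @return List with `statistic` and `p_value`.
#' @export
chi2_proportions <- function(counts) {
  tab <- matrix(c(counts$strong_normal, counts$weak_normal,
                  counts$strong_disease, counts$weak_disease),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("normal", "disease"), c("strong", "weak")))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    stop("zero marginal in class-count table; chi-square undefined")
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value))
}
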