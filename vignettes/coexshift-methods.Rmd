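---
title: "Differential coexpression via a disease-specific cutoff: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential coexpression via a disease-specific cutoff: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexshift)
```

## The problem

Differential *expression* analysis asks which genes shift in mean between two
phenotypes. Differential *coexpression* asks a different question: do the
same genes stop (or start) moving together? For genes co-regulated by a
shared set of transcription factors — here the motivating system is the
common targets of E2F1–3 and MYC in CD34+ cells, contrasting healthy donors
with chronic myelogenous leukemia (CML) patients — a loss of pairwise
correlation in the disease state can signal impaired regulatory wiring even
when no single gene is differentially expressed.

Rather than testing each pair separately, the method compares the *whole
distribution* of pairwise coexpression between the groups and derives a
single, data-driven cutoff that best separates them.

## The model

For candidate genes $i < j$ the coexpression level in each group is the
absolute Pearson correlation of their expression profiles:

$$C_d(i,j) = |\mathrm{cor}(x_{di}, x_{dj})|, \qquad
  C_n(i,j) = |\mathrm{cor}(x_{ni}, x_{nj})|,$$

a scalar in $[0,1]$ where direction is deliberately folded away: strong
negative co-regulation is still co-regulation. Each group's levels form an
empirical survival function $F(c) = \Pr(C \ge c)$. The two functions are
contrasted with the two-sample Kolmogorov–Smirnov statistic

$$D = \max_c\, |F_d(c) - F_n(c)|,$$

and the level $C$ at which the maximum is attained is the
**disease-specific cutoff**: the coexpression level at which the two
phenotypes disagree most about what counts as "coexpressed". Pairs with
level $\ge C$ are *strong*, below it *weak*, per group. A pair strong in
normal and weak in disease is *normal-specific strong* — identically, as a
set, *disease-specific weak* — and symmetrically for the disease group.
A Pearson chi-square on the 2×2 strong/weak × group table (df = 1, no
continuity correction) tests whether the class proportions shifted.

Gene sets (e.g. curated process networks) are then mapped onto the specific
pair classes: all $\binom{k}{2}$ pairs of a set's annotated candidate genes
are counted into cells $a$ (normal-specific strong), $b$ (normal-specific
weak), $c$ (disease-specific strong), $d$ (disease-specific weak); by the
class identities $a = d$ and $b = c$ always. A one-sided Fisher's exact test
(upper tail in $a$) asks whether the set's pairs are preferentially
coexpressed in the normal group, with Benjamini–Hochberg FDR control across
sets.

## Numerical and design choices

Several details are open in a verbal description of this procedure; the
package fixes them as follows.

* **Evaluation grid.** Empirical survival functions are step functions, so
  $D$ is attained at an observed level; the grid is the sorted union of both
  groups' observed levels, with no interpolation. `ks_max_deviation()` is
  exactly the classical two-sample KS statistic (the test suite checks
  equality with `stats::ks.test()` to 1e-12 on random samples up to
  n = 500).
* **Tie-break for C.** When several grid values attain $D$, the smallest is
  reported. This is deterministic and symmetric between the groups.
* **Boundary convention.** "Strong" uses $\ge C$, so a pair sitting exactly
  at the cutoff is strong; ties are likewise included in the survival
  function via $\Pr(C \ge c)$.
* **KS p-value.** The asymptotic Kolmogorov series
  $p = 2\sum_{k\ge1}(-1)^{k-1} e^{-2k^2\lambda^2}$ with
  $\lambda = D\sqrt{nm/(n+m)}$, truncated below 1e-300 and clamped to
  $[0,1]$; no small-sample bias terms, so late digits can differ from
  implementations that add them. Gene pairs sharing genes are not
  independent, so this p-value is an overall descriptive summary, not an
  exact test.
* **Chi-square without continuity correction.** On published class counts of
  the motivating CML study ([[7436, 16000], [6083, 17353]]) the uncorrected
  statistic reproduces the reported $\chi^2 \approx 190$,
  $p \approx 2.74\times10^{-43}$; Yates' correction does not.
* **Zero-variance genes** are removed before pairing (correlation is
  undefined; assigning $|r| = 0$ would silently distort both distributions),
  and correlations marginally exceeding 1 by floating point are clamped.
* **Missing values.** Genes with any missing value are dropped
  (complete-case) so both groups' correlations use all of their samples and
  the two level sets stay comparable on a common pair universe.
* **Probe collapsing** averages probe intensities per gene on the normalized
  scale as provided; the package does not re-normalize.
* **Symbol matching** is exact string equality after upper-casing and
  whitespace stripping — deterministic and testable, at the cost of not
  resolving aliases.
* **FDR.** Benjamini–Hochberg step-up rather than a Storey-type estimator:
  Storey-family FDRs depend on null-proportion estimation whose tuning
  cannot be recovered from a list of p-values (identical p-values can even
  receive different estimates), while the classical step-up rule is exactly
  reproducible; significance is declared at FDR < 0.05. Sets with fewer than two annotated candidates
  yield no pairs and are kept in the family with $p = 1$ rather than
  dropped, so the multiple-testing family is explicit.
* **Fisher tail convention** is fixed to cell $a$: the alternative is "more
  normal-specific strongly coexpressed pairs".
* **Annotation universe.** The hypergeometric gene-level enrichment defaults
  to the measured-gene count as universe (the pipeline passes it
  explicitly); the original annotation service's proprietary universe is not
  available, and the mapped-pair Fisher test — the primary statistic — does
  not depend on it.
* **Config format.** The pipeline driver reads a single YAML file with flag
  overrides (flags win), which keeps one canonical record per run; the
  report JSON carries no timestamps so identical inputs give byte-identical
  reports.

## What the synthetic generator emulates — and what it does not

`generate_expression()` draws a two-group study shaped like a small
microarray cohort: defaults of 8 normal and 9 disease samples mirror the
CD34+ CML design whose small-sample $|r|$ behaviour the method must
tolerate. A block of `n_block` genes shares a single latent factor per
group,

$$x_{gs} = \mu_g + \sigma\left(\sqrt{\rho}\, z_s + \sqrt{1-\rho}\,
\varepsilon_{gs}\right),$$

giving equicorrelation $\rho_\text{normal}$ within the block among normal
samples and $\rho_\text{disease}$ among disease samples; non-block genes are
independent noise around a gene-specific baseline. With the default
$\rho_\text{normal} = 0.85$, $\rho_\text{disease} = 0$ the block is exactly
the method's implicit target: pairs strongly coexpressed in one state and
decorrelated in the other. The companion generators force the block into
every TF's target set (so candidate selection provably recovers it; TF
coverage 0.8 over four TFs leaves roughly 40% of background genes in the
common-target set, keeping the block a minority of candidates as in a real
screen) and plant one "signal" gene set drawn from the block among random
decoys.

The generator deliberately omits: platform/probe-level noise models, VSN or
any normalization artefacts, batch effects, heavy-tailed or dependent
background correlation, and overlapping co-regulation blocks. Passing the
recovery tests therefore shows the pipeline is correct and well-powered
under its own assumptions — not that those assumptions hold for any given
real dataset.

## Problem sizes used in the tests

The shipped test-suite fits use 8–60 genes (one 217-gene matrix to confirm
the 23,436-pair universe), the KS equivalence property uses 200 random
sample pairs with sizes up to 500, Fisher enumeration covers all 2×2 tables
with margins ≤ 12, hypergeometric enumeration covers universes ≤ 25, and the
parameter-recovery study runs 50 seeded replicates of the default 60-gene /
12-block / 8 + 9-sample condition. These sizes were chosen so every property
is exercised at scales where independent enumeration oracles are exact.

## Worked example

```{r example}
sim <- generate_expression(synthetic_spec(n_genes = 60, n_block = 12, seed = 3))
fit <- coexshift(sim$expression, disease = "disease")
fit
sets <- generate_gene_sets(rownames(sim$expression$values), sim$block,
                           n_sets = 8, set_size = 10, seed = 2003)
enrich_pairs(sets, fit)
```

The planted block drives a larger strong-pair count in the normal group, a
small chi-square p, and a minimal Fisher p for the planted set; `plot(fit)`
shows the two survival curves and the deviation peak at $C$.

## Known limitations

* Pair-level dependence (pairs share genes) means the KS and chi-square
  p-values are descriptive of the overall structural difference rather than
  exact error rates; the original method shares this property.
* Exactly two groups; no covariate adjustment; Pearson only (no rank or
  partial correlations, no shrinkage).
* The cutoff is a point estimate; no uncertainty interval is attached to
  $C$ or $D$ beyond the asymptotic p-value.
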