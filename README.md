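# coexshift

Differential coexpression analysis between two phenotype groups via a
disease-specific cutoff.

## What it does, and for whom

For a set of candidate genes — typically the common targets of several
transcription factors (the motivating system is E2F1–3 + MYC targets in
CD34+ cells, healthy vs. chronic myelogenous leukemia) — `coexshift`
compares not the genes' expression levels but their *coexpression
structure*: do gene pairs that move together in one phenotype stop moving
together in the other?

For every unordered pair of candidate genes *i < j* the coexpression level
in each group is the absolute Pearson correlation

&nbsp;&nbsp;&nbsp;&nbsp;*C*<sub>d</sub>(i,j) = |cor(x<sub>di</sub>, x<sub>dj</sub>)|,&nbsp;&nbsp;
*C*<sub>n</sub>(i,j) = |cor(x<sub>ni</sub>, x<sub>nj</sub>)|.

The two sets of levels form empirical survival functions
*F*(c) = Prob(*C* ≥ c), contrasted with the two-sample Kolmogorov–Smirnov
statistic

&nbsp;&nbsp;&nbsp;&nbsp;*D* = max<sub>c</sub> |*F*<sub>d</sub>(c) − *F*<sub>n</sub>(c)|.

The level attaining *D* is the **disease-specific cutoff C**: pairs with
level ≥ C are *strongly* coexpressed, below it *weakly*, per group. A
chi-square test (df = 1, no continuity correction) reports whether the
strong/weak proportions shifted between groups, and gene sets are tested for
preferential coexpression in one group by mapping their annotated gene pairs
onto the group-specific classes and applying a one-sided Fisher's exact test
with Benjamini–Hochberg FDR control.

The package is aimed at systems-biology analysts with a normalized
expression matrix, a TF→target reference, and a gene-set collection (GMT);
everything is also runnable on built-in synthetic data.

## Worked example

```r
library(coexshift)

sim <- generate_expression(synthetic_spec(n_genes = 60, n_block = 12, seed = 3))
fit <- coexshift(sim$expression, disease = "disease")
fit
#> Differential coexpression cutoff model
#>
#>   60 candidate genes, 1770 gene pairs (groups: normal = 'normal', disease = 'disease')
#>   KS max deviation D = 0.0836, p = 8.44e-06
#>   Cutoff C = 0.3527
#>   Strong pairs: 750 (normal) vs 602 (disease); chi-square = 26.2, p = 3.06e-07
```

The synthetic matrix plants a 12-gene block equicorrelated at 0.85 among the
8 normal samples and uncorrelated among the 9 disease samples. The fit finds
the survival functions deviate most (D = 0.0836) at level C = 0.3527, and at
that cutoff the normal group carries 750 strong pairs against 602 in the
disease group — a shift the chi-square test calls highly significant. Mapping
gene sets onto the group-specific pairs:

```r
sets <- generate_gene_sets(rownames(sim$expression$values), sim$block,
                           n_sets = 8, set_size = 10, seed = 2003)
enrich_pairs(sets, fit)
#> Gene-set mapping of group-specific coexpressed pairs (8 sets, 3 significant)
#>
#>            set annotated_gene_count annotated_pair_count  a  b  c  d ...  fisher_p       fdr significant
#>   signal_block                   10                   45 21  4  4 21 ... 1.308e-06 1.047e-05        TRUE
#>  random_set_01                   10                   45 10 16 16 10 ... 9.744e-01 9.744e-01       FALSE
#>  ...
```

`a` counts a set's pairs that are strong in normal and weak in disease
(normal-specific strong; identically, disease-specific weak — hence a = d),
`b`/`c` the mirror class. The planted set attains by far the smallest
one-sided Fisher p. `plot(fit)` draws the two survival curves and the
deviation peak; `summary(fit)`, `coef(fit)` (C and D) and
`predict(fit, newdata)` complete the S3 surface.

File-driven runs use `run_pipeline()` (YAML config) or the CLI launcher:

```sh
Rscript inst/scripts/coexshift simulate --seed 7 --out demo
Rscript inst/scripts/coexshift run --config cfg.yaml   # writes report.json,
                                   # pairs.tsv, enrichment.tsv, networks/*.sif|graphml
```

## Documentation

The methods vignette (`vignettes/coexshift-methods.Rmd`) describes the
model, its assumptions, every numerical convention (grid, tie-breaks,
boundary and tail conventions, FDR choice), what the synthetic generator
does and does not emulate, and known limitations.
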