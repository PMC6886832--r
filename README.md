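# metabosig

Unsupervised extraction of metabolic signatures from nonnegative
metabolite-abundance matrices, for metabolomics studies that profile a few
hundred metabolites across a small number of samples (e.g. targeted
LC-MS/MS of tissue from two diet or disease groups) and want to describe
the data as a small set of coordinated metabolite patterns rather than one
metabolite at a time.

## The model

Given a nonnegative matrix **X** (metabolites × samples), the package fits
a rank-*k* nonnegative matrix factorization

&nbsp;&nbsp;&nbsp;&nbsp;**X ≈ W H**,&nbsp;&nbsp; **W** ≥ 0 (metabolites × *k*),&nbsp;&nbsp; **H** ≥ 0 (*k* × samples),

by classical multiplicative updates under the Frobenius (default) or
generalized Kullback–Leibler objective. Each column of **W** is a
*signature*: a relative-weight profile over metabolites normalized to sum
to 1, with the removed scale carried by the sample loadings **H**. Around
the factorization the package provides:

* **Rank selection** — for each candidate *k*, a consensus matrix over
  seeded random restarts (samples co-cluster when they share a
  maximum-loading signature) is summarized by the cophenetic correlation
  coefficient between `1 − consensus` and its average-linkage dendrogram;
  the most stable (smallest, on ties) rank is chosen.
* **Sample clustering** — hierarchical clustering of samples by their
  signature proportions (correlation distance, average linkage), with
  group-purity scores and Newick export.
* **Pathway overrepresentation** — exact one-sided hypergeometric tests of
  a signature's top-weighted metabolites against a GMT pathway library,
  with Benjamini–Hochberg adjustment.
* **Differential analysis** — per-metabolite two-group comparison (pooled
  two-sided t by default; Welch and Mann–Whitney available), means ± SD,
  and fold changes reported larger-over-smaller with a direction flag.
* **A synthetic-study generator** — planted signatures, one dominant
  signature per group, multiplicative log-normal noise, and planted
  per-metabolite fold changes, so every stage is testable without any
  external download.

## Worked example

```r
library(metabosig)

st  <- generate_study(study_config(seed = 1))   # 280 metabolites, 6 + 6 samples
st$matrix
#> metabolite_matrix: 280 metabolites x 12 samples
#> groups: A (n = 6), B (n = 6)

fit <- nmf_factorize(st$matrix, k = 4, seed = 1, n_starts = 5)
dom <- dominant_signature(fit$loadings)
table(dominant = dom$signature, group = attr(st$matrix, "groups"))
#>         group
#> dominant A B
#>       P1 6 0
#>       P2 0 6

cl <- cluster_samples(fit$loadings, cut_k = 2, groups = attr(st$matrix, "groups"))
cl
#> cluster_assignment: 12 samples, correlation distance, average linkage, cut at k = 2
#> group purity: A = 1.00, B = 1.00

tab <- fold_change(st$matrix)
tab[1:3, c("metabolite", "mean_ref", "mean_other", "fold_change", "direction", "p_value")]
#>   metabolite mean_ref mean_other fold_change direction  p_value
#> 1     met001    1.179      0.274        4.30        up 3.34e-06
#> 2     met002    0.989      0.294        3.37        up 6.02e-05
#> 3     met003    1.167      0.370        3.16        up 1.79e-05
```

Every sample's dominant signature matches its group, the two-way dendrogram
cut separates the groups perfectly, and the three metabolites carrying
planted fold changes of 4.31, 3.26 and 3.16 are recovered at 4.30, 3.37 and
3.16 with small two-group p-values. `run_pipeline(pipeline_config(...))`
chains all stages (simulation or TSV input → rank selection → factorization
→ clustering → enrichment → differential table) and writes TSV/Newick/JSON
outputs plus a seeded run manifest.

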