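---
title: "Methods: signature extraction, rank selection and group comparison in metabosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature extraction, rank selection and group comparison in metabosig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabosig)
```

## The problem

Targeted metabolomics of tissue typically yields a few hundred metabolite
abundances over a dozen samples. With far more variables than replicates,
per-metabolite statistics alone are fragile, and supervised multivariate
methods can only confirm structure that is already hypothesized.
`metabosig` takes the unsupervised route: it describes the abundance
matrix as a small set of nonnegative *metabolic signatures* — coordinated
relative-weight profiles over metabolites — plus per-sample loadings
saying how much of each signature each sample carries. Group differences
then appear as differences in signature make-up, and per-metabolite
two-group statistics complement the factor-level picture.

## Factorization model

For a nonnegative matrix $X \in \mathbb{R}_{\ge 0}^{m \times n}$
(metabolites $\times$ samples) and rank $k$, `nmf_factorize()` minimizes
either $\tfrac12\lVert X - WH\rVert_F^2$ or the generalized
Kullback–Leibler divergence $\sum_{ij} \big(x_{ij}\log\frac{x_{ij}}{(WH)_{ij}}
- x_{ij} + (WH)_{ij}\big)$ over $W \ge 0$, $H \ge 0$ by the classical
multiplicative update rules. Numerical choices:

* **Initialization.** Both factors start from uniform draws on $(0, 1]$
  scaled by $\sqrt{\bar{X}/k}$, so the initial product is on the scale of
  the data. Strictly positive starts matter because multiplicative updates
  can never revive an entry that reaches exactly zero. This scaling also
  makes the entire update trajectory exactly equivariant under
  $X \to cX$, which is why rescaled data give identical normalized
  signatures with loadings scaled by $c$.
* **Epsilon policy.** A small constant ($10^{-12}$) is added to update
  denominators only; the data are never perturbed.
* **Convergence.** The objective is recorded every sweep; every 10 sweeps
  the relative decrease is compared with `rel_tol` (default $10^{-6}$);
  `max_iter` defaults to 2000. The recorded trace is non-increasing up to
  numerical slack, and tests enforce that.
* **Identifiability conventions.** Signature columns are ordered by
  descending total loading, then rescaled to sum to 1 with the scale moved
  into the loadings (`normalize_signatures()`), so the product is
  unchanged and repeated runs are comparable. A signature column summing
  to zero is an error, never silently renormalized.
* **Local minima.** Multiplicative updates are monotone but not global:
  on clean low-rank data we observe two basins (near-exact recovery versus
  a visibly worse fit). `n_starts` runs several seeded starts and keeps
  the lowest final objective; the default is 1 because run-to-run
  variability is itself the signal for consensus analysis, while the
  pipeline's final fit uses 10 starts.

## Rank selection by consensus stability

`consensus_matrix()` repeats the factorization with seeds
`base_seed + 1, ..., base_seed + n_runs` (default 50 restarts), assigns
each sample to its maximum-loading signature, and averages the 0/1
co-assignment (connectivity) matrices. `cophenetic_coefficient()` turns
`1 − consensus` into an average-linkage dendrogram and correlates original
with cophenetic distances; `select_rank()` picks the candidate rank with
the highest coefficient, smallest rank on ties. Restart consensus (rather
than resampling of metabolites) is used because it is the standard
companion of cophenetic rank selection for NMF; average linkage is the
customary linkage and complete/single are available behind a flag.
When every pairwise distance is equal the dendrogram is degenerate and the
coefficient is returned as `NA`, never silently as 0. For transparency,
`cluster_samples()` also reports the cophenetic correlation of the direct
clustering of the loading profiles.

**A structural caveat worth knowing.** Max-loading consensus measures the
stability of the induced *sample partition*, not the algebraic rank. If
the samples form $G$ well-separated groups, the partition is typically
stable at every rank $\ge G$ — and often below the true rank too, because
the merge of the two closest groups is itself deterministic across
restarts. The coefficient curve is then flat near 1 and the
smallest-rank tie rule selects approximately $G$. On this package's
default two-group synthetic design the sweep selects rank 2 with
coefficient 1.0 even though four signatures are planted (the four are
still recoverable: fitting at $k = 4$ recovers them and clusters the
samples perfectly). Studies that report both a larger signature count and
a high cophenetic coefficient on two-group data are therefore best read as
having chosen the rank on other grounds; this limitation is inherent to
the procedure, and the package reports the full per-rank curve so users
can see it.

## The synthetic-study generator

`generate_study()` emulates the study design the package is organized
around: $m = 280$ metabolites, two groups of 6 samples, $k = 4$ planted
signatures, one distinct dominant signature per group (the default map
sends group A to P2 and group B to P4) with the remaining signatures as
shared background.

* **Signatures.** Each column draws a support of
  `signature_sparsity` (default 0.25) of the metabolites with
  exponential-scale weights; off-support metabolites receive weights four
  orders of magnitude smaller, and the column is normalized to sum to 1
  exactly.
* **Loadings.** Each sample's total loading is `loading_scale`
  (default 100, an arbitrary abundance scale) times a log-normal factor
  with CV `sample_scale_cv` (default 0.1, mimicking residual per-sample
  normalization error). The group's dominant signature takes exactly the
  `dominance` fraction (default 0.7) of the total; the remainder is split
  across the other signatures by a symmetric Dirichlet draw. Dominance
  0.7 reflects "predominant but mixed" signature composition rather than
  near-pure samples.
* **Noise.** Multiplicative log-normal noise with median 1 and CV
  `noise_cv` (default 0.1, a typical targeted LC-MS/MS coefficient of
  variation) is applied entrywise. Relative-abundance data are positive
  with roughly proportional error, which the log-normal captures without
  risking negative values.
* **Planted fold changes.** After factor mixing, the group-A entries of
  selected metabolite rows are multiplied by the planted ratio. These
  metabolites are given *signature-neutral* baseline weights (identical
  weight in every signature column) so that their expected group-mean
  ratio equals the planted ratio exactly; without that, group-asymmetric
  signature structure would bias the realized ratio away from the planted
  value by an arbitrary factor. The defaults plant 4.31, 3.26 and 3.16 —
  reference magnitudes for strong metabolite declines — on the first
  three metabolites.

What the generator does *not* emulate: missing values, censoring at the
detection limit, heteroscedastic per-metabolite error, batch structure,
outlier samples, or correlated noise across metabolites beyond the shared
loadings. Passing tests on this generator therefore demonstrate
correctness of the algorithms under the stated model, not robustness to
everything real LC-MS/MS data can do. In particular the clean two-group
design clusters perfectly, whereas real cohorts may contain outliers
(e.g. one control clustering with the cases).

## Overrepresentation analysis

`ora_test()` is the exact one-sided hypergeometric upper tail
$P(\text{overlap} \ge \text{observed})$ — equivalently a one-sided Fisher
exact test — never a normal approximation. `enrich_signature()` takes a
signature's top metabolites (below), intersects the library universe with
the measured metabolites (metabolites never measured cannot be hits),
tests every pathway, and applies Benjamini–Hochberg adjustment across
pathways while retaining raw p-values. Because "top metabolites of
signature P against signature Q" can mean either all of P's top
metabolites or only those not shared with Q, both modes are provided
(`mode = "all"` / `"exclusive"`); neither is privileged.

## Top metabolites and sample clustering

`top_metabolites()` sorts by descending weight (ties by identifier) and
truncates either at cumulative mass $q$ (default rule, $q = 0.5$) or at a
weight floor. A mass rule adapts to how concentrated a signature is,
which a fixed count cannot; note that a $q$-mass prefix intentionally
drops the low-weight tail of a signature's support.
`cluster_samples()` normalizes loading columns to proportions before
computing distances — the scientific object is the sample's signature
make-up, not its absolute abundance — which also makes the clustering
invariant to per-sample rescaling. Correlation distance is the default
for the same reason; Euclidean is available.

## Differential analysis

`two_group_test()` implements the pooled-variance two-sided t test as the
default (with Welch and exact-for-small-n Mann–Whitney as alternatives),
vectorized over metabolites. Degenerate inputs are handled explicitly:
when both groups have zero variance the p-value is 0 if the means differ
and `NA` if every value is identical. `fold_change()` reports the ratio
of group means larger-over-smaller (so declines appear as magnitudes
above 1) with a separate `direction` flag relative to the reference
group, group means ± SD, and BH-adjusted p-values alongside raw ones. A
zero group mean yields an explicit undefined-ratio flag; ratios are never
patched with an epsilon.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script work at the design scale of the
package (280 × 12 matrices; 50-restart consensus sweeps over ranks 2–7;
200 replicate simulations for fold-change recovery; smaller matrices for
property-style tests where size is irrelevant). These sizes were chosen
as representative of the targeted-metabolomics setting the package
addresses; the full suite completes in roughly a minute on a laptop-class
CPU.

## Known limitations

* Rank selection reflects sample-partition stability, as discussed above.
* No sparsity-penalized, orthogonal or semi-NMF variants; no bootstrap
  support values on dendrograms; no quantitative (weighted) enrichment or
  topology-based pathway scores.
* Mann–Whitney falls back to the tie-corrected normal approximation when
  ties make the exact distribution unavailable.
* The KL objective shares the Frobenius code path's convergence checks;
  extremely sparse matrices may need a larger `max_iter`.
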