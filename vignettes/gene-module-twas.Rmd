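---
title: "Gene-module analysis of TWAS summary statistics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-module analysis of TWAS summary statistics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Transcriptome-wide association studies (TWAS) test, gene by gene, whether
genetically predicted expression associates with a trait. Genes do not act
alone: they are organized in co-expression modules, and modern models of
complex-trait architecture predict that module-level signal is often more
interpretable (and more robust) than single-gene hits. `modulewas`
implements a module-level reading of TWAS results: gene-level statistics
are projected into a latent space of gene modules learned by a PLIER-style
nonnegative matrix factorization, and three analyses operate in that
space — a correlation-aware competitive test for module-trait association,
a signature-reversal drug-repurposing score, and a consensus clustering of
traits by their module profiles.

## The latent space and the projection

A trained latent model consists of a nonnegative gene-by-module loading
matrix $Z$ and the ridge penalty $\lambda_2$ used during training. Any
genes-by-entities matrix $M$ (TWAS z-scores, p-value transforms, drug
perturbation profiles) is mapped to module space by the ridge projection

$$\hat M = (Z^\top Z + \lambda_2 I)^{-1} Z^\top M,$$

solved as a symmetric positive-definite linear system, never by forming
the inverse. The training penalty is reused verbatim — re-estimating it
would change the geometry of the space the model was trained in — though
`project_matrix()` accepts an override for sensitivity analysis. Input
matrices are aligned to the model's gene axis first; genes the model knows
but the data lack are zero-filled by default (a zero z-score contributes
nothing to the dot products), with an `intersect` policy available when
dropping those genes is preferred. Whether inputs should be standardized
per column before projection is left to the caller: the projection is
applied to the matrix as given.

## The module-trait regression

For one module $\ell$ and one trait, the gene-level response is
$m_i = -\log_{10} p_i$ from the multi-tissue TWAS (p-values clamped at
$10^{-300}$ so the design stays finite), and the competitive model is

$$m = \beta_0 + s\,\beta_s + \sum_j x_j \beta_j + \epsilon,\qquad
\epsilon \sim \mathrm{MVN}(0, \sigma^2 \Sigma),$$

where $s$ marks the module's member genes — the top `ceiling(fraction *
n_genes)` genes by loading (1% by default), with ties broken by loading
then gene id — and the covariates $x_j$ are the two gene properties that
drive gene-level statistics mechanically: gene size (the number of
principal components retained by the multi-tissue test) and gene density
(that count over the number of tissues). The null $\beta_s = 0$ is tested
against the one-sided alternative $\beta_s > 0$ with a Student-t reference
on $n - p$ degrees of freedom, since $\sigma^2$ is estimated.
Benjamini-Hochberg adjustment is applied across the whole run by default
(`per_trait` is available).

Covariates are standardized before fitting; this affects only the scale
of their coefficients, not the member-effect inference. Covariates that
are constant in a given gene universe (possible in small synthetic
panels, where every gene may retain the same PC count) are dropped with a
message rather than erroring: the rank-deficiency error is reserved for
genuine collinearity.

### Why generalized least squares

TWAS statistics of nearby genes are correlated — they share eQTLs, or
their eQTLs are in LD — so the errors $\epsilon$ cannot be treated as
independent. The error covariance uses the correlation between the
genes' association sums of squares under the null. For gene $i$, the
predicted-expression matrix across its $p_i$ tissues is reduced to the
$k_i$ principal components whose eigenvalues pass the strict
condition-number rule $\max(\lambda)/\lambda < 30$; then

$$R_{ij} = \frac{2\,\mathrm{Tr}(C_{ij} C_{ij}^\top)}
{\sqrt{2k_i}\,\sqrt{2k_j}},$$

where $C_{ij}$ is the PC cross-correlation matrix assembled from the
tissue-level correlations. Those, in turn, come entirely from the eQTL
weights and the reference-panel SNP covariance $\Gamma$:
$\mathrm{Cor}(t_k, t_l) = w_k^\top \Gamma\, w_l / \sqrt{(w_k^\top \Gamma
w_k)(w_l^\top \Gamma w_l)}$. No individual-level data are needed; the
individual-level computation exists in the package too
(`predict_expression()`, `reduce_pcs()`, `smultixcan_p()`) and serves as
the independent oracle in the test suite — the analytic and
individual-level routes agree exactly because both are driven by the same
realized covariance.

Only the member-gene submatrix $R_\ell$ enters the fit: the error
covariance is block-structured, $R_\ell$ on members, identity elsewhere,
zero cross-block. This is the minimal structure consistent with
accounting for correlation among the top genes only; it is conservative,
and it is what makes the test cheap enough to run for every (module,
trait) pair. When $R_\ell$ is numerically indefinite it is shrunk toward
the identity with the smallest $\delta \in \{10^{-4}, 10^{-3}, 10^{-2},
10^{-1}\}$ that restores positive definiteness; the applied `repair_delta`
is carried into every result row so poorly conditioned modules can be
flagged or excluded, which is the practical handle for reproducing the
exclusion of badly calibrated modules rather than a hard-coded rule.

The fit itself whitens the member block with the Cholesky factor of
$R_\ell$ and solves ordinary least squares on the whitened system;
`gls_fit()` is validated against a dense inverse-covariance oracle, and
`regress_all()` reuses one whitened design per module across all traits.

### Calibration at desk scale

`calibrate_regression()` measures the empirical type-I error of the
one-sided test on scenario A (below) by drawing phenotypes independent of
the genotypes and running the full summary pipeline per replicate,
vectorized across replicates. The response $-\log_{10} p$ is
exponentially distributed under the null — strongly skewed — so the
normal-theory t-test is only as good as the central-limit averaging over
member genes allows. A design analysis run before the package was built
showed that with only a handful of effectively independent member genes
the one-sided 5% test rejects at 6–7%, while ~20 independent LD blocks
among the members bring it into the low 5s; biobank-scale analyses, with
member sets of a couple of hundred genes, sit in the comfortable regime. Scenario A therefore
gives the tested module 80 member genes in 20 LD blocks of 4 (within-block
latent correlation 0.9), with the 220 background genes in blocks of their
own — a competitive test's background is genome-wide and dominated by
unlinked genes. Replacing $R_\ell$ with the identity on this design
demonstrates the inflation the correlation model exists to prevent.

## Drug repurposing by signature reversal

A compound whose transcriptional response opposes a disease's
genetically-predicted expression pattern is a repurposing candidate. With
trait signatures $M^t$ (per-tissue signed z-scores, traits by features)
and compound profiles $L$ (compounds by features), the raw score is
$D^{t,k} = -1 \cdot L\, (M^{t,k})^\top$, where $M^{t,k}$ keeps, per trait,
only the $k$ features of largest magnitude (ties resolved by magnitude
then id). The grid of $k$ is $\{$all, 50, 100, 250, 500$\}$ in gene space
and $\{$all, 5, 10, 25, 50$\}$ in module space, reflecting the roughly
tenfold dimension reduction. Within each tissue and trait, compound ranks
(midranks on ties) are averaged over the grid; the final score takes the
elementwise maximum across tissues, in that order. Rank aggregation makes
the result invariant to monotone transformations of the raw scores within
each $k$; the tissue maximum lets each disease pick its most informative
tissue. In module space the all-module score decomposes additively, and
`lv_contributions()` reports which modules drive a particular
compound-trait prediction — the interpretability payoff of working in
module space. `evaluate_drug_scores()` computes AUROC (midrank ties) and
average precision against a labelled gold standard, with a
permuted-score baseline giving the chance level and its 95% range.

## Consensus clustering of traits

Trait profiles in module space are clustered by evidence accumulation.
Preprocessing (for real association matrices): p-values become z-scores
via $\Phi^{-1}(1 - p/2)$; traits mapping to one ontology term are
combined by Stouffer's method with weights $\sqrt{\text{GWAS sample
size}}$ (the square-root form moderates the dominance of very large
cohorts; plain $n$ can be supplied instead); each trait's scores are
divided by their sum to damp highly polygenic traits; then the matrix is
projected. Combining precedes normalization, as given.

The ensemble covers three representations (raw, top-50 PCA, 50-component
UMAP; components capped at $n-1$ with a message) times five algorithm
families: k-means, spectral clustering and Gaussian mixtures over $k \in
[2, \lfloor\sqrt n\rfloor]$ with five seeded runs each; hierarchical
clustering with ward, complete, average and single linkages per $k$; and
DBSCAN over a minPts grid (a Fibonacci-spaced subsample of 2..125 by
default, the full range by configuration) with epsilon taken at the
10th-90th percentile (5 points) of the mean minPts-nearest-neighbour
distance — the deterministic realization of choosing epsilon "by
observing the distribution". DBSCAN noise points become singleton
clusters, preserving pairwise-disagreement semantics; partitions with a
single cluster or all points noise are dropped; surviving DBSCAN
partitions are resampled with replacement up to the mean count of the
other four families so no family dominates the ensemble.

The evidence-accumulation distance is the exact fraction of partitions
separating each trait pair. Consensus partitions come from normalized
spectral clustering of the similarity $\exp(-\gamma D^2)$, with
$\gamma \in \{0.5, 1, 2, 5\}/\mathrm{median}(D^2_{\text{offdiag}})$ by
default — a data-scaled grid, since no universal kernel width exists for
evidence-accumulation distances. Per $k$, the winner
maximizes the median adjusted Rand index against the full ensemble;
solutions at or below the 75th percentile of agreement are then discarded
(strictly-greater, so equal agreements keep nothing), and
`clustering_tree_edges()` tabulates how traits flow between clusters of
consecutive retained resolutions.

## Interpreting clusters

`discriminative_lvs()` explains a cluster by iteratively fitting a
depth-one classification tree (cluster vs rest, classes weighted
inversely to frequency so small clusters can win the root) on the
trait-by-module matrix, recording the root module and its threshold,
selecting it only when the threshold is positive and exceeds one standard
deviation of that module's values across all traits, removing the module
regardless, and repeating (20 iterations by default). The standard
deviation is taken across all traits of the input matrix, and the matrix
is used raw — both points where a convention had to be fixed; they are
recorded in the report. Only the root split is consumed, so capping the
tree depth at one is behaviourally identical to training deeper trees and
reading the root.

## Synthetic data and what passing tests mean

The generators plant known truth at desk scale: block-correlated dosage
panels (two latent Gaussian allele draws thresholded at per-SNP MAF),
per-gene per-tissue weight models confined to one LD block each (so
cross-gene correlation is controlled by block assignment), sparse
nonnegative loading matrices with clearly elevated member genes, full
TWAS runs (per-SNP GWAS statistics, per-tissue summary z-scores,
multi-tissue p-values) over simulated phenotypes, reversal compounds, and
separated trait clusters. Three pre-registered scenarios fix the study
conditions: **A** for regression calibration and power (2000 individuals,
300 genes, member structure as motivated above, one planted module-trait
effect at $h^2 = 0.05$), **B** for drug-reversal recovery (1000
individuals, 100 genes, 30 modules, one trait at $h^2 = 0.3$, one of 30
compounds carrying the negated signature plus unit noise), and **C** for
cluster recovery and interpretation (50 traits, 3 clusters, 3
discriminative modules each, separation 4, plus a structureless copy for
the null control). Genes without a model in a tissue carry a zero z-score
in that tissue's matrix — the neutral value of the scoring dot products.

What the synthetic data do not emulate: real minor-allele-frequency
spectra and LD decay (blocks are exchangeable and compound-symmetric),
population structure and relatedness, the empirical distribution of
PhenomeXcan/LINCS statistics, tissue-specific genotype covariances
(one panel covariance serves all tissues), and ontology structure beyond
a flat mapping table. Passing tests therefore demonstrate internal
statistical correctness — calibration, recovery of planted effects,
agreement with closed-form and Monte-Carlo oracles — not performance on
any real cohort; reproducing real-cohort results requires the external
TWAS, perturbation and gold-standard resources themselves and is out of
scope here.

## Numerical choices

Eigenvalues below $10^{-12}$ are treated as null space everywhere the
condition-number rule applies (the rule alone would keep spuriously tiny
or negative eigenvalues). The projection and the GLS both factorize
symmetric positive-definite systems via Cholesky. Member/top-k ties break
deterministically (loading or magnitude, then id). Ranks use midranks
where a statistic is computed (AUROC, rank averaging) and deterministic
order where a set is selected. The spectral consensus uses the
symmetric-normalized Laplacian with row-normalized eigenvectors and
seeded k-means (10 starts); degenerate similarity matrices (all
off-diagonal entries equal) raise an error suggesting a different
$\gamma$. All stochastic steps consume explicit integer seeds; UMAP runs
single-threaded so results do not depend on thread count. Test and
acceptance problem sizes (e.g. 5000 calibration replicates, 20000
Monte-Carlo draws, 100 reversal replicates, 50 cluster replicates) are
the package's chosen desk-scale study sizes.

## Worked example

```{r example}
library(modulewas)

scB <- simulate_scenario("B", seed = 1)

# module-space drug scoring
mt_lv <- lapply(scB$twas$z_tissues, function(m) {
  t(project_matrix(t(m), scB$latent_model))
})
l_lv <- t(project_matrix(t(scB$drugs), scB$latent_model))
scores <- score_drug_pairs(mt_lv, l_lv, space = "lv")
evaluate_drug_scores(scores, scB$gold, seed = 1)

# which modules drive the top prediction?
lv_contributions(project_matrix(t(scB$twas$signatures),
                                scB$latent_model),
                 l_lv, "drug01", "trait10")
```

## Known limitations

The error covariance of the regression ignores correlation among
non-member genes and between members and non-members; this is the
conservative simplification the method is built on, and the calibration
study quantifies its adequacy under the scenario conditions only. The
analytic correlation matrix is exact for the individual-level multi-tissue
model but an approximation for its summary-level counterpart. The
$-\log_{10} p$ response is skewed, so very small member sets push the
one-sided test above its nominal level regardless of the covariance
model. DBSCAN's role in the ensemble depends on the epsilon grid rule;
other deterministic rules would yield somewhat different ensembles.
Consensus solutions depend on the $\gamma$ grid scale when the distance
matrix is nearly degenerate.
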