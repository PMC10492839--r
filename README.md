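# modulewas

Gene-module analysis of TWAS summary statistics.

Transcriptome-wide association studies (TWAS) score genes one at a time,
but genes act in co-expression modules. `modulewas` projects gene-trait
association statistics and drug-induced transcriptional profiles into a
shared latent space of gene modules (the nonnegative loading matrix `Z`
of a PLIER-style factorization, with its training ridge penalty
`lambda2`) and analyses traits and drugs there. It is aimed at
statistical geneticists who have TWAS summary results (per-tissue signed
z-scores and multi-tissue p-values), eQTL prediction weights with a
reference genotype panel, and optionally compound perturbation
signatures.

Core machinery, in the field's standard notation:

* **Projection.** `Mhat = (Z'Z + lambda2 I)^-1 Z' M` maps any gene-rows
  matrix into module space (`project_matrix()`).
* **Module-trait regression.** A competitive generalized least squares
  test of `m = b0 + s*beta_s + covariates + eps`,
  `eps ~ MVN(0, sigma^2 Sigma)`, where `m` is the per-gene `-log10(p)`
  vector, `s` marks the module's top-loaded genes (top 1% by default),
  the covariates are gene size (retained PC count) and gene density
  (PCs/tissues), and `Sigma` carries the member-gene correlation
  submatrix `R_l` computed analytically from the eQTL weights and the
  panel SNP covariance via the sum-of-squares correlation
  `R_ij = 2 Tr(C_ij C_ij') / (sqrt(2 k_i) sqrt(2 k_j))`. One-sided test
  of `beta_s > 0`, BH-adjusted (`build_gene_correlation()`,
  `lv_submatrix()`, `gls_fit()`, `regress_all()`).
* **Drug repurposing.** Signature-reversal scores
  `D = -1 * L Mhat'` over a grid of signature sizes, rank-averaged per
  tissue, then the maximum across tissues; per-module contributions
  explain each prediction; AUROC / average precision against a gold
  standard with a permuted-score baseline (`score_drug_pairs()`,
  `lv_contributions()`, `evaluate_drug_scores()`).
* **Consensus clustering.** An ensemble of k-means / spectral / Gaussian
  mixture / hierarchical / DBSCAN partitions over raw, PCA and UMAP
  representations; the evidence-accumulation distance (fraction of
  partitions separating each trait pair); spectral consensus on
  `exp(-gamma D^2)` selected by median adjusted Rand index against the
  ensemble; agreement filtering and clustering-tree edges
  (`generate_ensemble()`, `eac_distance()`, `consensus_partition()`).
* **Interpretation.** Iterative depth-one decision trees extract the
  modules that discriminate each trait cluster
  (`discriminative_lvs()`).
* **Synthetic data.** Generators with planted ground truth (LD-blocked
  panels, eQTL models, latent loadings, full TWAS, reversal compounds,
  trait clusters) and three named scenarios A/B/C
  (`simulate_scenario()`).

## Worked example

Score a planted reversal compound in module space and inspect what
drives the prediction:

```r
library(modulewas)
scB <- simulate_scenario("B", seed = 1)

mt_lv <- lapply(scB$twas$z_tissues, function(m)
  t(project_matrix(t(m), scB$latent_model)))
l_lv <- t(project_matrix(t(scB$drugs), scB$latent_model))
scores <- score_drug_pairs(mt_lv, l_lv, space = "lv")

rank(-scores$final[, "trait10"])["drug01"]
#> drug01
#>      1
evaluate_drug_scores(scores, scB$gold, seed = 1)
#> <drug_evaluation> AUROC 0.9875, AP 1 (permuted baseline AP 0.1145)
```

`trait10` is the trait with the planted module effect and `drug01` the
compound carrying its negated signature: it ranks first among 30
compounds, the indicated pair tops the precision-recall ordering, and
randomly permuted scores sit at the chance level (~0.11 average
precision). The regression side looks like:

```r
scA <- simulate_scenario("A", seed = 31)
corr <- build_gene_correlation(scA$models, scA$panel)
res <- regress_all(scA$twas, scA$latent_model, corr, fraction = 0.265)
head(res[order(res$pval), c("lv", "trait", "beta", "pval", "fdr")], 1)
#> lv    trait    beta      pval       fdr
#> LV01  trait06  1.109676  3.486e-13  2.510e-11
```

The planted module-trait pair (`LV01`, `trait06`) tops the table by many
orders of magnitude.

## Command line

A thin CLI wraps the package functions
(`inst/cli/modulewas`): `simulate`, `project`, `correlate`, `regress`,
`drugscore`, `cluster`, `interpret`, all tab-separated in and out, all
stochastic commands seeded and bit-reproducible. See `?run_cli`.
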