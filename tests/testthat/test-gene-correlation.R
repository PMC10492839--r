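test_that("tissue-model correlations match exact special cases and the
           individual-level computation", {
  panel <- factorial_panel()
  models <- tibble::tibble(
    gene = c("gA", "gA", "gB", "gB", "gC"),
    tissue = c("t1", "t2", "t1", "t1", "t1"),
    snp_id = c("snp01", "snp02", "snp03", "snp04", "snp05"),
    weight = c(1, 0.5, 1, -2, 1.5))
  models <- rbind(models,
                  tibble::tibble(gene = "gB", tissue = "t2",
                                 snp_id = c("snp03", "snp04"),
                                 weight = c(0.3, 0.7)))

  # same gene and tissue: exactly 1
  expect_equal(cross_gene_tissue_correlation(models, panel, "gA", "t1",
                                             "gA", "t1"), 1)
  # disjoint SNPs in exactly uncorrelated blocks: exactly 0
  expect_equal(cross_gene_tissue_correlation(models, panel, "gA", "t1",
                                             "gB", "t1"), 0)

  # random overlapping case: equals the empirical correlation of the
  # individual-level predicted expression (the panel is the population)
  set.seed(21)
  panel2 <- generate_panel(n_individuals = 400, block_sizes = c(6, 6),
                           within_block_r = 0.6, seed = 22)
  models2 <- generate_models(panel2, n_genes = 2, n_tissues = 2,
                             snps_per_model = 3,
                             gene_blocks = c(1L, 1L), seed = 23)
  analytic <- cross_gene_tissue_correlation(models2, panel2, "g001", "t1",
                                            "g002", "t2")
  pe1 <- predict_expression(panel2, models2, "g001")
  pe2 <- predict_expression(panel2, models2, "g002")
  expect_equal(analytic, stats::cor(pe1$T[, "t1"], pe2$T[, "t2"]),
               tolerance = 1e-10)
})

test_that("PC cross-correlation matches its definition and the
           individual-level PC matrices", {
  set.seed(24)
  panel <- generate_panel(n_individuals = 500, block_sizes = c(8, 8),
                          within_block_r = 0.5, seed = 25)
  models <- generate_models(panel, n_genes = 2, n_tissues = 3,
                            snps_per_model = 3, gene_blocks = c(1L, 1L),
                            seed = 26)
  pe1 <- reduce_pcs(predict_expression(panel, models, "g001"))
  pe2 <- reduce_pcs(predict_expression(panel, models, "g002"))

  # self: identity of size k
  cross_self <- crossprod(pe1$T) / (nrow(panel$X) - 1)
  C_self <- pc_cross_correlation(pe1, pe1, cross_self)
  expect_equal(C_self, diag(pe1$k), tolerance = 1e-8)

  # zero cross block: zero matrix
  expect_equal(pc_cross_correlation(pe1, pe2,
                                    matrix(0, pe1$p, pe2$p)),
               matrix(0, pe1$k, pe2$k))

  # random case: equals Cor(P_i, P_j) from the individual-level scores
  cross <- crossprod(pe1$T, pe2$T) / (nrow(panel$X) - 1)
  C <- pc_cross_correlation(pe1, pe2, cross)
  expect_equal(C, stats::cor(pe1$P, pe2$P), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pc_cross_correlation(pe1, pe2, matrix(0, 2, 2)),
               "dimension")
})

test_that("sum-of-squares correlation has the right closed-form
           boundaries", {
  expect_equal(ssm_correlation(diag(3)), 1)
  expect_equal(ssm_correlation(matrix(0, 2, 4)), 0)
  set.seed(27)
  C <- matrix(runif(6, -0.4, 0.4), 2, 3)
  # direct evaluation of the trace formula
  expect_equal(ssm_correlation(C),
               2 * sum(diag(C %*% t(C))) / (sqrt(2 * 2) * sqrt(2 * 3)),
               tolerance = 1e-12)
  expect_error(ssm_correlation(matrix(numeric(0), 0, 2)), "positive")
})

test_that("the assembled correlation matrix is exact on orthogonal
           blocks and bounded in general", {
  panel <- factorial_panel()
  models <- tibble::tibble(
    gene = c("gA", "gB", "gC", "gC2"),
    tissue = "t1",
    snp_id = c("snp01", "snp03", "snp05", "snp05"),
    weight = c(1, 1, 2, -1))
  corr <- build_gene_correlation(models, panel)
  # independent blocks: exact identity off-diagonal zeros for gA/gB
  expect_equal(corr$R["gA", "gB"], 0)
  # duplicated SNP support (proportional models): correlation 1
  expect_equal(abs(corr$R["gC", "gC2"]), 1, tolerance = 1e-8)
  expect_equal(diag(corr$R), rep(1, 4), ignore_attr = TRUE)

  set.seed(28)
  panel2 <- generate_panel(n_individuals = 300, block_sizes = rep(5, 4),
                           within_block_r = 0.7, seed = 29)
  models2 <- generate_models(panel2, n_genes = 8, n_tissues = 2,
                             snps_per_model = 3,
                             gene_blocks = rep(1:4, each = 2), seed = 30)
  corr2 <- build_gene_correlation(models2, panel2)
  expect_true(isSymmetric(corr2$R, tol = 1e-10))
  expect_true(all(corr2$R >= -1e-8 & corr2$R <= 1 + 1e-8))
  # invariance to gene relabeling: permuting the gene list permutes R
  corr3 <- build_gene_correlation(models2, panel2,
                                  genes = rev(sort(unique(models2$gene))))
  expect_equal(corr3$R[rownames(corr2$R), colnames(corr2$R)], corr2$R,
               tolerance = 1e-12)
})

test_that("module submatrices repair indefiniteness and report the
           shrinkage", {
  model <- tiny_latent_model(n_genes = 200, n_lvs = 2, members = 2)
  # identity correlation: no repair needed
  ids <- rownames(model$Z)
  R <- diag(1, 200)
  dimnames(R) <- list(ids, ids)
  corr <- structure(list(R = R,
                         gene_meta = tibble::tibble(gene = ids, k = 1,
                                                    p = 1)),
                    class = "gene_correlation")
  sub <- lv_submatrix(corr, model, "LV01", top_gene_fraction = 0.01)
  expect_length(sub$genes, 2L)  # ceil(0.01 * 200)
  expect_equal(sub$repair_delta, 0)
  expect_equal(sub$R, diag(1, 2), ignore_attr = TRUE)

  # an indefinite submatrix gets the smallest working shrinkage
  R2 <- R
  mem <- top_lv_genes(model, "LV02", 0.015)  # 3 members
  R2[mem, mem] <- 1  # rank-1 block, eigenvalues {3, 0, 0}
  corr2 <- corr; corr2$R <- R2
  sub2 <- lv_submatrix(corr2, model, "LV02", top_gene_fraction = 0.015)
  expect_gt(sub2$repair_delta, 0)
  ev <- eigen(sub2$R, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 1e-8)
  expect_error(lv_submatrix(corr, model, "LV99"), "unknown")
})
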