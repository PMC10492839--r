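#' Correlation between predicted expression of two tissue models
#'
#' Analytic correlation of the predicted expression of gene `i` in tissue
#' `k` and gene `j` in tissue `l`, computed from the eQTL weights and the
#' reference-panel SNP covariance:
#' `sum_ab w_a w_b Gamma_ab / sqrt(var_k var_l)` with per-model variances
#' `w' Gamma w`. No individual-level prediction is performed.
#'
#' @param models Prediction-model table (`gene`, `tissue`, `snp_id`,
#'   `weight`).
#' @param panel A [genotype_panel()].
#' @param gene_i,tissue_i,gene_j,tissue_j The two models.
#' @param gwas_snps Optional SNP restriction (SNPs present in the GWAS).
#' @return The correlation scalar.
#' @export
cross_gene_tissue_correlation <- function(models, panel, gene_i, tissue_i,
                                          gene_j, tissue_j,
                                          gwas_snps = NULL) {
  mi <- model_snps(models, panel, gene_i, tissue_i, gwas_snps)
  mj <- model_snps(models, panel, gene_j, tissue_j, gwas_snps)
  if (nrow(mi) == 0L || nrow(mj) == 0L) stop("empty model after SNP filtering")
  vi <- as.numeric(crossprod(
    mi$weight, panel$Gamma[mi$snp_id, mi$snp_id, drop = FALSE] %*% mi$weight))
  vj <- as.numeric(crossprod(
    mj$weight, panel$Gamma[mj$snp_id, mj$snp_id, drop = FALSE] %*% mj$weight))
  if (vi < 1e-12 || vj < 1e-12) {
    stop("zero predicted-expression variance: correlation undefined")
  }
  cv <- as.numeric(crossprod(
    mi$weight, panel$Gamma[mi$snp_id, mj$snp_id, drop = FALSE] %*% mj$weight))
  cv / sqrt(vi * vj)
}

#' Cross-correlation between the retained PCs of two genes
#'
#' Maps a tissue-by-tissue correlation block to PC space:
#' `diag(lambda_i)^(-1/2) V_i' cross V_j diag(lambda_j)^(-1/2)`, where `V`
#' and `lambda` are the retained eigenvectors/eigenvalues of each gene's
#' tissue correlation matrix.
#'
#' @param pe_i,pe_j Reduced `predicted_expression` objects.
#' @param cross Tissue-by-tissue correlation matrix between the two genes
#'   (dimension `p_i` x `p_j`).
#' @return A `k_i` x `k_j` matrix.
#' @export
pc_cross_correlation <- function(pe_i, pe_j, cross) {
  stopifnot(isTRUE(pe_i$reduced), isTRUE(pe_j$reduced))
  if (nrow(cross) != pe_i$p || ncol(cross) != pe_j$p) {
    stop("cross block dimensions do not match the tissue counts")
  }
  diag(1 / sqrt(pe_i$lambda), pe_i$k) %*% crossprod(pe_i$V, cross %*% pe_j$V) %*%
    diag(1 / sqrt(pe_j$lambda), pe_j$k)
}

#' Correlation between the association sums of squares of two genes
#'
#' Under the null, the model sums of squares of the per-gene multi-tissue
#' regressions are correlated according to
#' `2 Tr(C C') / (sqrt(2 k_i) sqrt(2 k_j))`, where `C` is the PC
#' cross-correlation of [pc_cross_correlation()]. This is the entry of the
#' gene-gene correlation matrix used by the GLS regression.
#'
#' @param C A `k_i` x `k_j` PC cross-correlation matrix.
#' @return The correlation scalar (in `[0, 1]` up to numerical error).
#' @export
ssm_correlation <- function(C) {
  stopifnot(is.matrix(C))
  k_i <- nrow(C); k_j <- ncol(C)
  if (k_i == 0L || k_j == 0L) stop("PC counts must be positive")
  if (any(!is.finite(C))) stop("non-finite PC cross-correlation")
  2 * sum(C * C) / (sqrt(2 * k_i) * sqrt(2 * k_j))
}

#' Build the analytic gene-gene correlation matrix
#'
#' Assembles the full symmetric gene-gene correlation matrix from the eQTL
#' prediction weights and the reference-panel covariance: per gene, the
#' tissue correlation matrix is computed analytically and reduced by the
#' condition-number rule; per gene pair, the tissue cross-block is mapped
#' to PC space and collapsed to the sum-of-squares correlation. Genes with
#' no usable model are dropped with a message. The diagonal is forced to
#' exactly 1.
#'
#' @param models Prediction-model table.
#' @param panel A [genotype_panel()].
#' @param gwas_snps Optional SNP restriction (one correlation matrix per
#'   group of traits sharing a SNP set).
#' @param genes Gene ids to include (default: all genes in `models`).
#' @param threshold Condition-number threshold for the PC reduction.
#' @return An object of class `gene_correlation`: list with the matrix `R`
#'   and `gene_meta`, a tibble of per-gene retained PC count `k` and tissue
#'   count `p`.
#' @export
build_gene_correlation <- function(models, panel, gwas_snps = NULL,
                                   genes = NULL, threshold = 30) {
  if (is.null(genes)) genes <- sort(unique(models$gene))
  info <- list()
  for (g in genes) {
    gi <- tryCatch(gene_pc_info(models, panel, g, gwas_snps, threshold),
                   error = function(e) NULL)
    if (is.null(gi)) {
      rlang::inform(paste0("build_gene_correlation: dropping gene ",
                           sQuote(g), " (no usable model)"))
      next
    }
    info[[g]] <- gi
  }
  if (length(info) < 1L) stop("no genes with usable models")
  ids <- names(info)
  m <- length(ids)
  R <- diag(1, m)
  dimnames(R) <- list(ids, ids)
  if (m > 1L) {
    for (a in 1:(m - 1L)) {
      ia <- info[[a]]
      for (b in (a + 1L):m) {
        ib <- info[[b]]
        cross <- cross_block(ia, ib, panel)
        C <- diag(1 / sqrt(ia$lambda), ia$k) %*%
          crossprod(ia$V, cross %*% ib$V) %*% diag(1 / sqrt(ib$lambda), ib$k)
        R[a, b] <- R[b, a] <- 2 * sum(C * C) / (sqrt(2 * ia$k) * sqrt(2 * ib$k))
      }
    }
  }
  meta <- tibble::tibble(gene = ids,
                         k = vapply(info, function(x) x$k, integer(1)),
                         p = vapply(info, function(x) x$p, integer(1)))
  structure(list(R = R, gene_meta = meta), class = "gene_correlation")
}

# Per-gene analytic PC decomposition: tissue correlation matrix from the
# weights and Gamma, reduced by the strict condition-number rule.
gene_pc_info <- function(models, panel, gene, gwas_snps, threshold) {
  tissues <- sort(unique(models$tissue[models$gene == gene]))
  subs <- list()
  for (tis in tissues) {
    s <- model_snps(models, panel, gene, tis, gwas_snps)
    if (nrow(s) == 0L) next
    v <- as.numeric(crossprod(
      s$weight, panel$Gamma[s$snp_id, s$snp_id, drop = FALSE] %*% s$weight))
    if (v < 1e-12) next
    subs[[tis]] <- list(snp_id = s$snp_id, weight = s$weight, var = v)
  }
  p <- length(subs)
  if (p == 0L) stop("no usable tissue model")
  Ct <- diag(1, p)
  if (p > 1L) {
    for (a in 1:(p - 1L)) for (b in (a + 1L):p) {
      cv <- as.numeric(crossprod(
        subs[[a]]$weight,
        panel$Gamma[subs[[a]]$snp_id, subs[[b]]$snp_id, drop = FALSE] %*%
          subs[[b]]$weight))
      Ct[a, b] <- Ct[b, a] <- cv / sqrt(subs[[a]]$var * subs[[b]]$var)
    }
  }
  e <- eigen(Ct, symmetric = TRUE)
  keep <- e$values > 1e-12 & (max(e$values) / e$values < threshold)
  if (!any(keep)) stop("all eigenvalues below numeric tolerance")
  list(gene = gene, tissues = names(subs), subs = subs, p = p,
       V = e$vectors[, keep, drop = FALSE], lambda = e$values[keep],
       k = as.integer(sum(keep)))
}

# Tissue-by-tissue correlation block between two genes' models.
cross_block <- function(ia, ib, panel) {
  out <- matrix(0, ia$p, ib$p)
  for (a in seq_len(ia$p)) for (b in seq_len(ib$p)) {
    cv <- as.numeric(crossprod(
      ia$subs[[a]]$weight,
      panel$Gamma[ia$subs[[a]]$snp_id, ib$subs[[b]]$snp_id, drop = FALSE] %*%
        ib$subs[[b]]$weight))
    out[a, b] <- cv / sqrt(ia$subs[[a]]$var * ib$subs[[b]]$var)
  }
  out
}

#' Extract (and repair) the member-gene correlation submatrix of a module
#'
#' Subsets the gene-gene correlation matrix to a module's member set (the
#' top-loaded genes of [top_lv_genes()]). When the submatrix is numerically
#' indefinite it is shrunk toward the identity,
#' `R <- (1 - delta) R + delta I`, with the smallest
#' `delta in {1e-4, 1e-3, 1e-2, 1e-1}` restoring a smallest eigenvalue of
#' at least `1e-8`; the applied shrinkage is reported so poorly conditioned
#' modules can be flagged or excluded downstream.
#'
#' @param corr A [build_gene_correlation()] result.
#' @param model A [latent_model()].
#' @param lv_id Module id.
#' @param top_gene_fraction Member-set fraction (default 0.01).
#' @return An object of class `lv_subcorrelation`: `lv_id`, member `genes`,
#'   the (possibly repaired) matrix `R`, and `repair_delta`.
#' @export
lv_submatrix <- function(corr, model, lv_id, top_gene_fraction = 0.01) {
  stopifnot(inherits(corr, "gene_correlation"))
  members <- top_lv_genes(model, lv_id, top_gene_fraction)
  members <- members[members %in% rownames(corr$R)]
  if (length(members) < 2L) {
    stop("module ", sQuote(lv_id), " has fewer than 2 member genes with ",
         "correlation entries")
  }
  Rl <- corr$R[members, members, drop = FALSE]
  delta <- 0
  if (min(eigen(Rl, symmetric = TRUE, only.values = TRUE)$values) < 1e-8) {
    for (d in c(1e-4, 1e-3, 1e-2, 1e-1)) {
      cand <- (1 - d) * Rl + d * diag(1, nrow(Rl))
      if (min(eigen(cand, symmetric = TRUE,
                    only.values = TRUE)$values) >= 1e-8) {
        Rl <- cand; delta <- d
        break
      }
    }
    if (delta == 0) stop("could not repair the member correlation submatrix")
    dimnames(Rl) <- list(members, members)
  }
  structure(list(lv_id = lv_id, genes = members, R = Rl,
                 repair_delta = delta),
            class = "lv_subcorrelation")
}
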