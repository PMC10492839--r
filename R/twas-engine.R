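#' Construct a genotype reference panel
#'
#' Wraps an individuals-by-SNP dosage matrix (0-2 scale) together with its
#' SNP covariance matrix `Gamma = (X - Xbar)'(X - Xbar) / (n - 1)`, the
#' quantity every summary-level computation in the package consumes. The
#' panel plays the role of the reference panel of eQTL-based TWAS methods.
#'
#' @param X Numeric individuals-by-SNP matrix with SNP column names;
#'   entries in `[0, 2]`.
#' @param blocks Optional integer vector of per-SNP block labels (used by
#'   the synthetic generators to record LD structure).
#' @return An object of class `genotype_panel` with elements `X`, `snp_ids`,
#'   `Gamma` and `blocks`.
#' @export
genotype_panel <- function(X, blocks = NULL) {
  stopifnot(is.matrix(X), is.numeric(X))
  if (is.null(colnames(X))) stop("X must have SNP column names")
  assert_unique_ids(colnames(X), "SNP")
  if (min(X) < 0 || max(X) > 2) stop("dosages must lie in [0, 2]")
  structure(list(X = X, snp_ids = colnames(X), Gamma = stats::cov(X),
                 blocks = blocks),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", nrow(x$X), " individuals x ", ncol(x$X),
      " SNPs\n", sep = "")
  invisible(x)
}

# SNPs usable for one (gene, tissue) model: present in the model, the panel
# and (when given) the GWAS SNP list.
model_snps <- function(models, panel, gene, tissue, gwas_snps = NULL) {
  rows <- models$gene == gene & models$tissue == tissue
  sub <- models[rows, , drop = FALSE]
  keep <- sub$snp_id %in% panel$snp_ids
  if (!is.null(gwas_snps)) keep <- keep & sub$snp_id %in% gwas_snps
  sub[keep, , drop = FALSE]
}

#' Predicted expression of one gene across tissues
#'
#' Builds the individuals-by-tissues predicted-expression matrix of a gene
#' from its per-tissue eQTL weight models: each tissue column is the
#' weighted dosage sum `t = sum_a w_a X_a`, subsequently standardized to
#' mean 0 and standard deviation 1. Zero-variance columns are dropped with
#' a message. SNPs missing from the panel (or from `gwas_snps`, when the
#' summary statistics cover only a subset) are excluded before prediction.
#'
#' @param panel A [genotype_panel()].
#' @param models Prediction-model table: a data frame with columns
#'   `gene`, `tissue`, `snp_id`, `weight`.
#' @param gene Gene id.
#' @param gwas_snps Optional character vector restricting usable SNPs.
#' @return An object of class `predicted_expression` holding the
#'   standardized matrix `T` (n x tissues), the unstandardized column
#'   standard deviations `raw_sd`, and bookkeeping fields. Run
#'   [reduce_pcs()] before any principal-component consumer.
#' @export
predict_expression <- function(panel, models, gene, gwas_snps = NULL) {
  tissues <- sort(unique(models$tissue[models$gene == gene]))
  if (length(tissues) == 0L) stop("gene ", sQuote(gene), " has no model")
  n <- nrow(panel$X)
  cols <- list()
  raw_sd <- numeric(0)
  for (tis in tissues) {
    sub <- model_snps(models, panel, gene, tis, gwas_snps)
    if (nrow(sub) == 0L) next
    t_raw <- as.numeric(panel$X[, sub$snp_id, drop = FALSE] %*% sub$weight)
    s <- stats::sd(t_raw)
    if (!is.finite(s) || s < 1e-12) {
      rlang::inform(paste0("predict_expression: dropping zero-variance ",
                           "tissue ", sQuote(tis), " for gene ", sQuote(gene)))
      next
    }
    cols[[tis]] <- (t_raw - mean(t_raw)) / s
    raw_sd[tis] <- s
  }
  if (length(cols) == 0L) {
    stop("gene ", sQuote(gene), " has no usable tissue model")
  }
  T_mat <- do.call(cbind, cols)
  colnames(T_mat) <- names(cols)
  structure(list(gene = gene, T = T_mat, tissues = names(cols),
                 raw_sd = raw_sd, n = n, p = ncol(T_mat), reduced = FALSE),
            class = "predicted_expression")
}

#' Reduce a predicted-expression matrix to its well-conditioned PCs
#'
#' Eigendecomposes the tissue-tissue correlation matrix of the standardized
#' predicted expression and retains the eigenvalues satisfying the strict
#' condition-number rule `max(lambda) / lambda < threshold`. The retained
#' principal-component score matrix `P` has standardized columns. Applying
#' the reduction twice is a no-op.
#'
#' @param pe A `predicted_expression` object.
#' @param threshold Condition-number threshold (default 30).
#' @return The input with fields `V` (tissue-by-PC eigenvectors), `lambda`
#'   (retained eigenvalues), `k` (retained PC count), and `P` (n-by-k
#'   standardized scores) filled in.
#' @export
reduce_pcs <- function(pe, threshold = 30) {
  stopifnot(inherits(pe, "predicted_expression"))
  if (isTRUE(pe$reduced)) return(pe)
  if (!(threshold > 1)) stop("threshold must exceed 1")
  C <- crossprod(pe$T) / (pe$n - 1)
  e <- eigen(C, symmetric = TRUE)
  pos <- e$values > 1e-12
  if (!any(pos)) stop("all eigenvalues below numeric tolerance for gene ",
                      sQuote(pe$gene))
  keep <- pos & (max(e$values) / e$values < threshold)
  lambda <- e$values[keep]
  V <- e$vectors[, keep, drop = FALSE]
  pe$V <- V
  pe$lambda <- lambda
  pe$k <- length(lambda)
  pe$P <- pe$T %*% V %*% diag(1 / sqrt(lambda), nrow = pe$k)
  colnames(pe$P) <- paste0("PC", seq_len(pe$k))
  pe$reduced <- TRUE
  pe
}

#' Summary-level per-tissue association z-score
#'
#' The summary-statistics approximation to the individual-level univariate
#' TWAS z-score: `z = sum_a w_a (sigma_a / sigma_l) (beta_a / se(beta_a))`,
#' where `sigma_a` is the SNP standard deviation in the reference panel and
#' `sigma_l = sqrt(w' Gamma w)` is the predicted-expression standard
#' deviation implied by the panel covariance.
#'
#' @param gwas Data frame of GWAS summary statistics with columns `snp_id`,
#'   `beta`, `se`. Its SNP set defines the usable SNPs.
#' @param models Prediction-model table (see [predict_expression()]).
#' @param panel A [genotype_panel()].
#' @param gene,tissue Which model to score.
#' @return The signed z-score, or `NA` (with a message) when the model's
#'   predicted expression has zero variance in the panel.
#' @export
spredixcan_z <- function(gwas, models, panel, gene, tissue) {
  sub <- model_snps(models, panel, gene, tissue, gwas_snps = gwas$snp_id)
  if (nrow(sub) == 0L) {
    stop("no usable SNPs for gene ", sQuote(gene), " tissue ", sQuote(tissue))
  }
  G <- panel$Gamma[sub$snp_id, sub$snp_id, drop = FALSE]
  var_l <- as.numeric(crossprod(sub$weight, G %*% sub$weight))
  if (var_l < 1e-12) {
    rlang::inform(paste0("spredixcan_z: zero predicted-expression variance, ",
                         "skipping gene ", sQuote(gene), " tissue ",
                         sQuote(tissue)))
    return(NA_real_)
  }
  idx <- match(sub$snp_id, gwas$snp_id)
  sigma_a <- sqrt(diag(G))
  sum(sub$weight * (sigma_a / sqrt(var_l)) *
        (gwas$beta[idx] / gwas$se[idx]))
}

#' Multi-tissue association test via principal components
#'
#' The joint multi-tissue statistic: per-tissue marginal z-scores of the
#' phenotype on each standardized predicted-expression column are combined
#' through the pseudo-inverse of the tissue correlation matrix restricted
#' to the retained PCs, `z' Cor(T)^+ z`, which is chi-squared with `k`
#' degrees of freedom under the null. The residual variance of each
#' marginal regression stands in for the joint error variance (the
#' conservative approximation inherited from the summary-level derivation).
#'
#' @param y Centered phenotype vector (length n).
#' @param pe A reduced `predicted_expression` (see [reduce_pcs()]).
#' @return A one-row tibble with `statistic`, `dof`, `p_value`.
#' @export
smultixcan_p <- function(y, pe) {
  stopifnot(inherits(pe, "predicted_expression"), isTRUE(pe$reduced))
  n <- pe$n
  if (length(y) != n) stop("phenotype length does not match the panel")
  if (n <= pe$k) stop("need more individuals than retained PCs")
  y <- y - mean(y)
  z <- marginal_z(pe$T, y)
  u <- crossprod(pe$V, z) / sqrt(pe$lambda)
  stat <- sum(u^2)
  tibble::tibble(statistic = stat, dof = pe$k,
                 p_value = stats::pchisq(stat, df = pe$k, lower.tail = FALSE))
}

# Marginal regression z-scores of y on each standardized column of T.
marginal_z <- function(T_mat, y) {
  n <- nrow(T_mat)
  tty <- as.numeric(crossprod(T_mat, y))   # t'y; t't = n - 1 (standardized)
  gamma <- tty / (n - 1)
  sigma2 <- (sum(y^2) - gamma * tty) / (n - 2)
  gamma / sqrt(sigma2 / (n - 1))
}
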