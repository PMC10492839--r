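# Shared in-code fixtures: tiny exact panels and constructors.

# 8-individual panel whose dosage columns are exactly orthogonal (built
# from a 2^3 full factorial with interactions), so the SNP covariance is
# exactly block diagonal for any block split.
factorial_panel <- function(blocks = c(1L, 1L, 2L, 2L, 3L, 3L, 3L)) {
  f <- as.matrix(expand.grid(a = c(-1, 1), b = c(-1, 1), c = c(-1, 1)))
  M <- cbind(f[, 1], f[, 2], f[, 3],
             f[, 1] * f[, 2], f[, 1] * f[, 3], f[, 2] * f[, 3],
             f[, 1] * f[, 2] * f[, 3])
  X <- M + 1  # dosages in {0, 2}
  colnames(X) <- sprintf("snp%02d", seq_len(ncol(X)))
  genotype_panel(X, blocks = blocks)
}

# Random correlation-like SPD matrix with unit diagonal.
rand_unit_spd <- function(k, jitter = 0.5) {
  A <- matrix(stats::rnorm(k * k), k)
  S <- crossprod(A) / k + jitter * diag(k)
  stats::cov2cor(S)
}

# predicted_expression whose standardized columns have EXACTLY the sample
# correlation C (n rows).
pe_with_correlation <- function(C, n = 50, gene = "g1") {
  p <- nrow(C)
  T0 <- matrix(stats::rnorm(n * p), n, p)
  T0 <- sweep(T0, 2L, colMeans(T0))
  W <- solve(chol(crossprod(T0) / (n - 1)))
  T_std <- T0 %*% W %*% chol(C)
  colnames(T_std) <- paste0("t", seq_len(p))
  structure(list(gene = gene, T = T_std, tissues = colnames(T_std),
                 raw_sd = rep(1, p), n = n, p = p, reduced = FALSE),
            class = "predicted_expression")
}

# Small latent model with known member structure.
tiny_latent_model <- function(n_genes = 20, n_lvs = 4, members = 3,
                              seed = 7) {
  generate_latent_model(n_genes = n_genes, n_lvs = n_lvs,
                        members_per_lv = members, lambda2 = 0.5,
                        seed = seed)
}

# Hand-built trait ensemble from a labels matrix.
as_trait_ensemble <- function(lab) {
  meta <- tibble::tibble(algorithm = "manual",
                         representation = "raw",
                         params = as.character(seq_len(ncol(lab))),
                         seed = NA_integer_)
  structure(list(labels = lab, meta = meta), class = "trait_ensemble")
}

# Closed-form adjusted Rand index from the contingency table (independent
# of the package implementation).
ari_closed_form <- function(p1, p2) {
  tab <- table(p1, p2)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_i <- sum(ch2(rowSums(tab)))
  sum_j <- sum(ch2(colSums(tab)))
  n <- length(p1)
  expected <- sum_i * sum_j / ch2(n)
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

# Dense-matrix GLS oracle: explicit inverse-covariance normal equations.
gls_oracle <- function(X, m, Sigma) {
  Si <- solve(Sigma)
  XtSiX <- t(X) %*% Si %*% X
  coef <- solve(XtSiX, t(X) %*% Si %*% m)
  resid <- m - X %*% coef
  sigma2 <- as.numeric(t(resid) %*% Si %*% resid) / (nrow(X) - ncol(X))
  se <- sqrt(sigma2 * diag(solve(XtSiX)))
  list(coef = as.numeric(coef), se = se, sigma2 = sigma2)
}
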