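#' Build the competitive regression design for one module and trait
#'
#' Assembles the gene-level design of the module-trait regression: the
#' response `m = -log10(p)` (p-values clamped below at `1e-300` so the
#' design stays finite), the binary member indicator `s` marking the
#' module's top-loaded genes, and the two gene-property covariates of the
#' MAGMA-style competitive test: gene size (retained PC count) and gene
#' density (PC count over tissue count). Covariates are standardized for
#' numerical stability; this leaves the member-effect inference unchanged.
#' Constant covariates are dropped with a message.
#'
#' @param trait_pvals Named numeric vector of per-gene p-values for one
#'   trait (or a data frame with columns `gene`, `pval`).
#' @param model A [latent_model()].
#' @param lv_id Module id.
#' @param gene_meta Data frame with columns `gene`, `k`, `p` (per-gene
#'   retained PC count and tissue count).
#' @param fraction Member-set fraction (default 0.01).
#' @return A tibble of class `regression_input` with columns `gene`, `m`,
#'   `in_lv`, and the surviving covariates; attributes record the module id
#'   and member set.
#' @export
build_design <- function(trait_pvals, model, lv_id, gene_meta,
                         fraction = 0.01) {
  if (is.data.frame(trait_pvals)) {
    p <- stats::setNames(trait_pvals$pval, trait_pvals$gene)
  } else {
    p <- trait_pvals
  }
  if (is.null(names(p))) stop("trait_pvals must be named by gene")
  genes <- intersect(rownames(model$Z), intersect(names(p), gene_meta$gene))
  if (length(genes) < 3L) stop("too few genes shared across inputs")
  p <- p[genes]
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (stats::sd(p) < .Machine$double.eps) {
    warning("all gene p-values are identical; the design is degenerate")
  }
  m <- -log10(pmax(p, 1e-300))
  members <- intersect(top_lv_genes(model, lv_id, fraction), genes)
  meta <- gene_meta[match(genes, gene_meta$gene), ]
  covs <- list(gene_size = as.numeric(meta$k),
               gene_density = as.numeric(meta$k) / as.numeric(meta$p))
  keep <- vapply(covs, function(x) stats::sd(x) > 1e-12, logical(1))
  if (any(!keep)) {
    rlang::inform(paste0("build_design: dropping constant covariate(s): ",
                         paste(names(covs)[!keep], collapse = ", ")))
  }
  covs <- lapply(covs[keep], function(x) as.numeric(scale(x)))
  out <- tibble::tibble(gene = genes, m = unname(m),
                        in_lv = as.integer(genes %in% members))
  for (nm in names(covs)) out[[nm]] <- covs[[nm]]
  attr(out, "lv_id") <- lv_id
  attr(out, "members") <- members
  class(out) <- c("regression_input", class(out))
  out
}

#' Fit the correlation-aware competitive module-trait regression
#'
#' Generalized least squares fit of
#' `m = b0 + s * beta_s + covariates + eps`, `eps ~ MVN(0, sigma^2 Sigma)`,
#' where `Sigma` is block-structured: the module's member-gene correlation
#' submatrix on the members, identity elsewhere, zero cross-block — the
#' minimal structure consistent with accounting for correlation among top
#' genes only (a conservative simplification). The fit whitens the member
#' block with its Cholesky factor and solves ordinary least squares on the
#' whitened system. The member effect is tested one-sided
#' (`beta_s > 0`, Student-t with `n_genes - n_parameters` degrees of
#' freedom, since `sigma^2` is estimated).
#'
#' @param input A [build_design()] result.
#' @param corr An [lv_submatrix()] result for the same module, or `NULL`
#'   for an identity error covariance (plain OLS; used to demonstrate the
#'   inflation the correlation model prevents).
#' @return An object of class `lv_gls`; see [tidy.lv_gls()] and
#'   [glance.lv_gls()].
#' @export
gls_fit <- function(input, corr = NULL) {
  stopifnot(inherits(input, "regression_input"))
  genes <- input$gene
  cov_names <- setdiff(colnames(input), c("gene", "m", "in_lv"))
  X <- cbind(`(Intercept)` = 1, in_lv = input$in_lv)
  for (nm in cov_names) X <- cbind(X, stats::setNames(input[[nm]], NULL))
  colnames(X) <- c("(Intercept)", "in_lv", cov_names)
  member_idx <- which(input$in_lv == 1L)
  Rl <- NULL
  repair_delta <- 0
  if (!is.null(corr)) {
    stopifnot(inherits(corr, "lv_subcorrelation"))
    mem_genes <- genes[member_idx]
    if (!all(mem_genes %in% corr$genes)) {
      stop("member genes of the design are missing from the correlation ",
           "submatrix")
    }
    Rl <- corr$R[mem_genes, mem_genes, drop = FALSE]
    repair_delta <- corr$repair_delta
  }
  prep <- gls_prepare(X, member_idx, Rl)
  res <- gls_solve(prep, matrix(input$m, ncol = 1L))
  structure(list(
    coefficients = tibble::tibble(term = colnames(X),
                                  estimate = unname(res$coef[, 1L]),
                                  std_error = unname(res$se[, 1L])),
    beta_s = unname(res$coef["in_lv", 1L]),
    se = unname(res$se["in_lv", 1L]),
    statistic = unname(res$stat[1L]),
    p_one_sided = unname(res$p_one[1L]),
    df = prep$df, sigma2 = res$sigma2[1L],
    n_genes = nrow(X), n_members = length(member_idx),
    repair_delta = repair_delta,
    lv_id = attr(input, "lv_id"), trait_id = attr(input, "trait_id")),
    class = "lv_gls")
}

# Whitening preparation shared by the single fit, the bulk path and the
# calibration simulator. Rl = NULL means identity covariance.
gls_prepare <- function(X, member_idx, Rl) {
  n <- nrow(X)
  Wm <- NULL
  Xw <- X
  if (!is.null(Rl) && length(member_idx) > 0L) {
    Wm <- backsolve(chol(Rl), diag(length(member_idx)), transpose = TRUE)
    Xw[member_idx, ] <- Wm %*% X[member_idx, , drop = FALSE]
  }
  qr_x <- qr(Xw)
  if (qr_x$rank < ncol(Xw)) {
    bad <- colnames(Xw)[qr_x$pivot[(qr_x$rank + 1L):ncol(Xw)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  # (X'X)^-1 with the QR pivot undone on both axes
  A <- chol2inv(qr.R(qr_x))
  XtXi <- matrix(0, ncol(Xw), ncol(Xw))
  XtXi[qr_x$pivot, qr_x$pivot] <- A
  dimnames(XtXi) <- list(colnames(X), colnames(X))
  list(X = X, Xw = Xw, qr = qr_x, XtXi = XtXi, Wm = Wm,
       member_idx = member_idx, n = n, df = n - ncol(X))
}

# Solve for one or many response columns at once.
gls_solve <- function(prep, M) {
  Mw <- M
  if (!is.null(prep$Wm)) {
    Mw[prep$member_idx, ] <- prep$Wm %*% M[prep$member_idx, , drop = FALSE]
  }
  coef <- qr.coef(prep$qr, Mw)
  resid <- Mw - prep$Xw %*% coef
  sigma2 <- colSums(resid^2) / prep$df
  se <- sqrt(outer(diag(prep$XtXi), sigma2))
  rownames(se) <- colnames(prep$X)
  stat <- coef["in_lv", ] / se["in_lv", ]
  list(coef = coef, se = se, sigma2 = sigma2, stat = stat,
       p_one = stats::pt(stat, df = prep$df, lower.tail = FALSE))
}

#' @export
print.lv_gls <- function(x, ...) {
  cat("<lv_gls> module ", x$lv_id %||% "?", ": beta_s = ",
      signif(x$beta_s, 4), " (se ", signif(x$se, 4), "), one-sided p = ",
      signif(x$p_one_sided, 4), ", ", x$n_members, "/", x$n_genes,
      " member genes\n", sep = "")
  invisible(x)
}

#' Tidy a module-trait GLS fit
#'
#' @param x An `lv_gls` object.
#' @param ... Unused.
#' @return A tibble with one row per model term.
#' @export
tidy.lv_gls <- function(x, ...) {
  out <- x$coefficients
  out$statistic <- out$estimate / out$std_error
  out$p_value <- 2 * stats::pt(abs(out$statistic), df = x$df,
                               lower.tail = FALSE)
  out$p_value[out$term == "in_lv"] <- x$p_one_sided
  out
}

#' One-row summary of a module-trait GLS fit
#'
#' @param x An `lv_gls` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.lv_gls <- function(x, ...) {
  tibble::tibble(beta_s = x$beta_s, se = x$se, statistic = x$statistic,
                 p_one_sided = x$p_one_sided, df = x$df,
                 n_genes = x$n_genes, n_members = x$n_members,
                 repair_delta = x$repair_delta)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (a thin wrapper around
#' [stats::p.adjust()] kept as the package's single adjustment point).
#'
#' @param pvals Numeric vector of p-values.
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  stats::p.adjust(pvals, method = "BH")
}

#' Run the module-trait regression across all modules and traits
#'
#' Fits [gls_fit()] for every (module, trait) pair and adjusts the
#' one-sided p-values by Benjamini-Hochberg, either across the whole run
#' (default) or within each trait. Rows are ordered module-major, in the
#' order of `corrs`, then trait order of the p-value matrix.
#'
#' @param twas A `twas_result_set` (see [generate_twas()]) or a list with
#'   elements `pvals` (trait-by-gene matrix) and `gene_meta`.
#' @param model A [latent_model()].
#' @param corrs Named list of [lv_submatrix()] objects (names are module
#'   ids), or a [build_gene_correlation()] result from which submatrices
#'   are extracted for every module of the model.
#' @param fraction Member-set fraction.
#' @param fdr_family `"all"` or `"per_trait"`.
#' @return A tibble of class `lv_assoc` with columns `lv`, `trait`, `beta`,
#'   `se`, `statistic`, `pval`, `fdr`, `n_members`, `repair_delta`.
#' @export
regress_all <- function(twas, model, corrs, fraction = 0.01,
                        fdr_family = c("all", "per_trait")) {
  fdr_family <- match.arg(fdr_family)
  pvals <- twas$pvals
  gene_meta <- twas$gene_meta
  if (inherits(corrs, "gene_correlation")) {
    full <- corrs
    corrs <- lapply(colnames(model$Z), function(lv) {
      lv_submatrix(full, model, lv, top_gene_fraction = fraction)
    })
    names(corrs) <- colnames(model$Z)
  }
  traits <- rownames(pvals)
  rows <- vector("list", length(corrs))
  for (i in seq_along(corrs)) {
    lv <- names(corrs)[i]
    design <- build_design(stats::setNames(pvals[1L, ], colnames(pvals)),
                           model, lv, gene_meta, fraction)
    genes <- design$gene
    cov_names <- setdiff(colnames(design), c("gene", "m", "in_lv"))
    X <- cbind(`(Intercept)` = 1, in_lv = design$in_lv)
    for (nm in cov_names) X <- cbind(X, stats::setNames(design[[nm]], NULL))
    colnames(X) <- c("(Intercept)", "in_lv", cov_names)
    member_idx <- which(design$in_lv == 1L)
    mem_genes <- genes[member_idx]
    Rl <- corrs[[lv]]$R[mem_genes, mem_genes, drop = FALSE]
    prep <- gls_prepare(X, member_idx, Rl)
    M <- -log10(pmax(t(pvals[, genes, drop = FALSE]), 1e-300))
    res <- gls_solve(prep, M)
    rd <- corrs[[lv]]$repair_delta
    rows[[i]] <- tibble::tibble(
      lv = lv, trait = traits,
      beta = unname(res$coef["in_lv", ]), se = unname(res$se["in_lv", ]),
      statistic = unname(res$stat), pval = unname(res$p_one),
      n_members = length(member_idx), repair_delta = rd)
  }
  out <- dplyr::bind_rows(rows)
  out$fdr <- if (fdr_family == "all") {
    bh_adjust(out$pval)
  } else {
    stats::ave(out$pval, out$trait, FUN = bh_adjust)
  }
  out <- out[, c("lv", "trait", "beta", "se", "statistic", "pval", "fdr",
                 "n_members", "repair_delta")]
  class(out) <- c("lv_assoc", class(out))
  out
}

#' Null calibration of the module-trait regression
#'
#' Empirical type-I error of the one-sided member test under a null of no
#' genotype-phenotype association: phenotypes are drawn independently of
#' the panel, the per-gene multi-tissue association p-values are computed
#' exactly as the summary pipeline computes them, and the GLS (or, for
#' comparison, identity-covariance OLS) regression is fit for the chosen
#' module in every replicate. Mirrors the simulation design used to verify
#' that the model is approximately well-calibrated, and that ignoring the
#' member correlation inflates the test.
#'
#' @param scen A scenario bundle from [simulate_scenario()] (scenario "A"),
#'   or any list with `panel`, `models`, `latent_model` and a
#'   `top_gene_fraction` config entry.
#' @param lv_id Module to test (default the scenario's planted module).
#' @param n_replicates Number of null phenotype replicates.
#' @param alpha Nominal one-sided level.
#' @param use_identity If `TRUE`, replace the member correlation submatrix
#'   by the identity.
#' @param seed Integer seed for the phenotype draws.
#' @return A list of class `gls_calibration` with the rejection rate, the
#'   replicate p-values and the settings.
#' @export
calibrate_regression <- function(scen, lv_id = NULL, n_replicates = 1000,
                                 alpha = 0.05, use_identity = FALSE,
                                 seed = 1) {
  panel <- scen$panel; models <- scen$models; model <- scen$latent_model
  fraction <- scen$config$top_gene_fraction %||% 0.01
  if (is.null(lv_id)) lv_id <- scen$config$planted_lv %||% colnames(model$Z)[1L]
  genes <- sort(unique(models$gene))
  pes <- lapply(genes, function(g) {
    reduce_pcs(predict_expression(panel, models, g))
  })
  names(pes) <- genes
  gene_meta <- tibble::tibble(
    gene = genes,
    k = vapply(pes, function(x) x$k, integer(1)),
    p = vapply(pes, function(x) x$p, integer(1)))
  members <- intersect(top_lv_genes(model, lv_id, fraction), genes)
  Rl <- NULL
  if (!use_identity) {
    corr <- build_gene_correlation(models, panel, genes = members)
    sub <- corr$R[members, members, drop = FALSE]
    Rl <- sub
  }
  # design (trait-independent; placeholder response, discarded)
  dummy <- stats::setNames(seq(0.1, 0.9, length.out = length(genes)),
                           genes)
  design <- build_design(dummy, model, lv_id, gene_meta, fraction)
  cov_names <- setdiff(colnames(design), c("gene", "m", "in_lv"))
  X <- cbind(`(Intercept)` = 1, in_lv = design$in_lv)
  for (nm in cov_names) X <- cbind(X, stats::setNames(design[[nm]], NULL))
  colnames(X) <- c("(Intercept)", "in_lv", cov_names)
  member_idx <- which(design$in_lv == 1L)
  if (!is.null(Rl)) {
    mem_genes <- design$gene[member_idx]
    Rl <- Rl[mem_genes, mem_genes, drop = FALSE]
  }
  prep <- gls_prepare(X, member_idx, Rl)
  # vectorized null p-values, identical in law to smultixcan_p()
  M <- null_multixcan_logp(pes[design$gene], panel, n_replicates, seed)
  res <- gls_solve(prep, M)
  structure(list(rejection = mean(res$p_one < alpha),
                 p_one_sided = unname(res$p_one),
                 n_replicates = n_replicates, alpha = alpha,
                 use_identity = use_identity, lv_id = lv_id,
                 n_members = length(member_idx), seed = seed),
            class = "gls_calibration")
}

#' @export
print.gls_calibration <- function(x, ...) {
  cat("<gls_calibration> module ", x$lv_id, ": rejection ",
      format(x$rejection), " at alpha ", x$alpha, " over ",
      x$n_replicates, " null replicates (",
      if (x$use_identity) "identity covariance" else "member correlation",
      ")\n", sep = "")
  invisible(x)
}

# -log10 multi-tissue p-values for B independent null phenotypes, computed
# with the same per-tissue marginal z and PC pseudo-inverse as
# smultixcan_p(), but batched across replicates.
null_multixcan_logp <- function(pes, panel, B, seed) {
  n <- nrow(panel$X)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * B), n, B)
  Y <- sweep(Y, 2L, colMeans(Y))
  Tall <- do.call(cbind, lapply(pes, function(pe) pe$T))
  idx <- rep(seq_along(pes), vapply(pes, function(pe) pe$p, integer(1)))
  TtY <- crossprod(Tall, Y)
  gamma <- TtY / (n - 1)
  yty <- colSums(Y^2)
  sigma2 <- (matrix(yty, nrow(TtY), B, byrow = TRUE) - gamma * TtY) / (n - 2)
  Z <- gamma / sqrt(sigma2 / (n - 1))
  M <- matrix(NA_real_, length(pes), B)
  for (i in seq_along(pes)) {
    pe <- pes[[i]]
    U <- diag(1 / sqrt(pe$lambda), pe$k) %*%
      crossprod(pe$V, Z[idx == i, , drop = FALSE])
    stat <- colSums(U^2)
    logp <- stats::pchisq(stat, df = pe$k, lower.tail = FALSE, log.p = TRUE)
    M[i, ] <- pmin(-logp / log(10), 300)
  }
  rownames(M) <- names(pes)
  M
}

`%||%` <- function(a, b) if (is.null(a)) b else a
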