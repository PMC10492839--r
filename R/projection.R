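#' Project a genes-by-entities matrix into the gene-module space
#'
#' Ridge projection of gene-level statistics onto the latent loadings:
#' `Mhat = (Z'Z + lambda2 I)^-1 Z' M`, solved as a symmetric
#' positive-definite linear system (never by forming the inverse). The ridge
#' penalty is the one recorded at training time in the latent-model bundle;
#' it can be overridden for sensitivity analysis but is never re-estimated.
#'
#' @param m Genes-by-entities matrix (traits, drugs, ...) with gene row
#'   names. It is aligned to the model's gene axis with [align_genes()].
#' @param model A [latent_model()].
#' @param policy Gene alignment policy, see [align_genes()]. Under
#'   `"intersect"` the loading matrix is subset to the shared genes.
#' @param lambda2 Optional override of the model's training ridge penalty.
#' @return A modules-by-entities matrix of class `projected_matrix`, with a
#'   `"provenance"` attribute recording the policy and penalty used.
#' @export
project_matrix <- function(m, model, policy = c("zero_fill", "intersect"),
                           lambda2 = NULL) {
  policy <- match.arg(policy)
  stopifnot(inherits(model, "latent_model"))
  lambda2 <- if (is.null(lambda2)) model$lambda2 else lambda2
  if (!is.numeric(lambda2) || lambda2 < 0) stop("lambda2 must be >= 0")
  m_al <- align_genes(m, model, policy = policy)
  Z <- model$Z[rownames(m_al), , drop = FALSE]
  A <- crossprod(Z)
  diag(A) <- diag(A) + lambda2
  ch <- tryCatch(chol(A), error = function(e) {
    stop("Z'Z + lambda2 I is numerically singular; use lambda2 > 0 ",
         "(rank-deficient loadings cannot be projected with lambda2 = 0)")
  })
  rhs <- crossprod(Z, m_al)
  mhat <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
  dimnames(mhat) <- list(colnames(Z), colnames(m_al))
  attr(mhat, "provenance") <- list(policy = policy, lambda2 = lambda2,
                                   n_zero_filled = attr(m_al, "n_zero_filled"))
  class(mhat) <- c("projected_matrix", class(mhat))
  mhat
}
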