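#' Construct a latent gene-module model
#'
#' A latent model is the shared coordinate system of the package: a
#' nonnegative gene-by-module loading matrix `Z` (as produced by PLIER-style
#' factorizations), the ridge penalty `lambda2` that was used when the model
#' was trained (reused verbatim when projecting new data, see
#' [project_matrix()]), and an optional module-by-sample matrix `B` carrying
#' sample metadata for interpretation.
#'
#' @param Z Numeric gene-by-module matrix with row names (gene ids) and
#'   column names (module/LV ids). All entries must be nonnegative and no
#'   column may be entirely zero.
#' @param lambda2 Positive scalar: the ridge penalty of the training run.
#' @param B Optional module-by-sample matrix; its rows must match the
#'   columns of `Z`.
#' @return An object of class `latent_model`.
#' @export
latent_model <- function(Z, lambda2, B = NULL) {
  stopifnot(is.matrix(Z), is.numeric(Z))
  if (is.null(rownames(Z)) || is.null(colnames(Z))) {
    stop("Z must have gene row names and module column names")
  }
  assert_unique_ids(rownames(Z), "gene")
  assert_unique_ids(colnames(Z), "module")
  if (any(Z < 0)) {
    bad <- which(Z < 0, arr.ind = TRUE)[1L, ]
    stop("negative loading at gene ", sQuote(rownames(Z)[bad[1L]]),
         ", module ", sQuote(colnames(Z)[bad[2L]]),
         ": loadings must satisfy the nonnegativity constraint Z >= 0")
  }
  if (any(colSums(Z) == 0)) {
    stop("all-zero module column(s): ",
         paste(sQuote(colnames(Z)[colSums(Z) == 0]), collapse = ", "))
  }
  if (!is.numeric(lambda2) || length(lambda2) != 1L || !is.finite(lambda2) ||
      lambda2 <= 0) {
    stop("lambda2 must be a positive scalar")
  }
  if (!is.null(B)) {
    stopifnot(is.matrix(B))
    if (nrow(B) != ncol(Z) || !identical(rownames(B), colnames(Z))) {
      stop("rows of B must match the module columns of Z")
    }
  }
  structure(list(Z = Z, lambda2 = lambda2, B = B), class = "latent_model")
}

#' @export
print.latent_model <- function(x, ...) {
  cat("<latent_model> ", nrow(x$Z), " genes x ", ncol(x$Z),
      " modules, lambda2 = ", format(x$lambda2), "\n", sep = "")
  if (!is.null(x$B)) cat("  with B: ", ncol(x$B), " samples\n", sep = "")
  invisible(x)
}

#' Read a latent model bundle from a directory
#'
#' A bundle is a directory holding `loadings.tsv[.gz]` (the gene-by-module
#' matrix), `meta.yaml` (at minimum the training `lambda2`), and optionally
#' `B.tsv[.gz]`.
#'
#' @param bundle_path Directory path.
#' @return A [latent_model()].
#' @export
read_latent_model <- function(bundle_path) {
  loadings <- bundle_file(bundle_path, "loadings.tsv")
  if (is.null(loadings)) stop("no loadings.tsv[.gz] in ", bundle_path)
  meta_path <- file.path(bundle_path, "meta.yaml")
  if (!file.exists(meta_path)) stop("no meta.yaml in ", bundle_path)
  meta <- yaml::read_yaml(meta_path)
  if (is.null(meta$lambda2)) stop("meta.yaml lacks the lambda2 entry")
  Z <- read_labelled_matrix(loadings, orientation = "genes")
  attr(Z, "orientation") <- NULL
  b_path <- bundle_file(bundle_path, "B.tsv")
  B <- NULL
  if (!is.null(b_path)) {
    B <- read_labelled_matrix(b_path, orientation = "traits")
    attr(B, "orientation") <- NULL
  }
  latent_model(Z, as.numeric(meta$lambda2), B = B)
}

#' Write a latent model bundle to a directory
#'
#' @param model A [latent_model()].
#' @param bundle_path Directory path (created if necessary).
#' @return `bundle_path`, invisibly.
#' @export
write_latent_model <- function(model, bundle_path) {
  stopifnot(inherits(model, "latent_model"))
  dir.create(bundle_path, recursive = TRUE, showWarnings = FALSE)
  write_labelled_matrix(model$Z, file.path(bundle_path, "loadings.tsv"),
                        id_col = "gene")
  yaml::write_yaml(list(lambda2 = model$lambda2,
                        n_genes = nrow(model$Z),
                        n_modules = ncol(model$Z)),
                   file.path(bundle_path, "meta.yaml"))
  if (!is.null(model$B)) {
    write_labelled_matrix(model$B, file.path(bundle_path, "B.tsv"),
                          id_col = "module")
  }
  invisible(bundle_path)
}

bundle_file <- function(dir, base) {
  for (p in file.path(dir, c(base, paste0(base, ".gz")))) {
    if (file.exists(p)) return(p)
  }
  NULL
}

#' Top-loaded genes of a latent variable
#'
#' The member set of a module: the top `ceiling(fraction * n_genes)` genes
#' by loading, the rule shared by the correlation submatrix and the
#' regression design. Ties are broken by the larger loading first and then
#' by lexicographic gene id, so the set is deterministic.
#'
#' @param model A [latent_model()].
#' @param lv_id Module id (a column name of `Z`).
#' @param fraction Fraction of genes to take (default 0.01, the top 1%).
#' @return Character vector of gene ids, ordered by decreasing loading.
#' @export
top_lv_genes <- function(model, lv_id, fraction = 0.01) {
  stopifnot(inherits(model, "latent_model"))
  if (!lv_id %in% colnames(model$Z)) stop("unknown module id ", sQuote(lv_id))
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  load <- model$Z[, lv_id]
  n_top <- as.integer(ceiling(fraction * nrow(model$Z)))
  ord <- order(-load, rownames(model$Z), method = "radix")
  rownames(model$Z)[ord[seq_len(n_top)]]
}
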