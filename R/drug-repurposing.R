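#' Restrict a trait signature matrix to its top-k entries
#'
#' Per trait (row), keeps the `k` entries with the largest absolute
#' z-scores and zeroes the rest. Ties at the cutoff are broken in favour of
#' the larger magnitude and then by lexicographic gene/module id, so the
#' restriction is deterministic. `k = Inf` leaves the matrix unchanged.
#'
#' @param mt Trait-by-feature signed z-score matrix.
#' @param k Positive integer or `Inf` (all features).
#' @return The restricted matrix.
#' @export
topk_restrict <- function(mt, k) {
  stopifnot(is.matrix(mt))
  if (!is.numeric(k) || length(k) != 1L || k <= 0) {
    stop("k must be a positive integer or Inf")
  }
  if (is.infinite(k) || k >= ncol(mt)) return(mt)
  ids <- colnames(mt)
  out <- mt
  for (i in seq_len(nrow(mt))) {
    ord <- order(-abs(mt[i, ]), ids, method = "radix")
    out[i, ord[-seq_len(k)]] <- 0
  }
  out
}

#' Signature-reversal drug-disease scores
#'
#' Scores compound-trait pairs by transcriptional signature reversal: for
#' each tissue and each signature size `k`, the raw score matrix is the
#' negative product of the top-k-restricted trait signatures with the
#' compound profiles, so a compound that down-regulates what the disease
#' up-regulates (and vice versa) scores high. Within each tissue and trait,
#' compound ranks (midrank ties; a larger score gets a larger rank) are
#' averaged across the `k` grid; the final score is the elementwise maximum
#' of the rank-averaged matrices across tissues.
#'
#' @param mt A trait-by-feature signed z matrix, or a named list of such
#'   matrices (one per tissue). Features are genes (`space = "gene"`) or
#'   modules (`space = "lv"`).
#' @param l Compound-by-feature signed z matrix.
#' @param k_grid Signature sizes; default `c(Inf, 50, 100, 250, 500)` in
#'   gene space and `c(Inf, 5, 10, 25, 50)` in module space (`Inf` = all
#'   features).
#' @param space `"gene"` or `"lv"`; only sets the default grid and is
#'   recorded in the result.
#' @return An object of class `drug_scores`: `final` (compound-by-trait),
#'   `per_tissue` (rank-averaged matrices), `per_tissue_k` (raw score
#'   matrices), `k_grid`, `space`.
#' @export
score_drug_pairs <- function(mt, l, k_grid = NULL,
                             space = c("gene", "lv")) {
  space <- match.arg(space)
  if (is.matrix(mt)) mt <- list(tissue1 = mt)
  stopifnot(is.list(mt), length(mt) >= 1L, is.matrix(l))
  if (is.null(k_grid)) {
    k_grid <- if (space == "gene") c(Inf, 50, 100, 250, 500) else
      c(Inf, 5, 10, 25, 50)
  }
  shared <- Reduce(intersect, c(lapply(mt, colnames), list(colnames(l))))
  if (length(shared) == 0L) stop("no shared feature axis between the trait ",
                                 "and compound matrices")
  l <- l[, shared, drop = FALSE]
  per_tissue_k <- list()
  per_tissue <- list()
  for (tis in names(mt)) {
    m_t <- mt[[tis]][, shared, drop = FALSE]
    rank_sum <- NULL
    raw <- list()
    for (k in k_grid) {
      D_tk <- -1 * l %*% t(topk_restrict(m_t, k))  # compound x trait
      raw[[paste0("k", k)]] <- D_tk
      rk <- apply(D_tk, 2L, rank, ties.method = "average")
      rank_sum <- if (is.null(rank_sum)) rk else rank_sum + rk
    }
    per_tissue_k[[tis]] <- raw
    per_tissue[[tis]] <- rank_sum / length(k_grid)
  }
  final <- Reduce(pmax, per_tissue)
  structure(list(final = final, per_tissue = per_tissue,
                 per_tissue_k = per_tissue_k, k_grid = k_grid,
                 space = space),
            class = "drug_scores")
}

#' @export
print.drug_scores <- function(x, ...) {
  cat("<drug_scores> ", nrow(x$final), " compounds x ", ncol(x$final),
      " traits (", x$space, " space, ", length(x$per_tissue),
      " tissue(s), k grid ", paste(x$k_grid, collapse = "/"), ")\n",
      sep = "")
  invisible(x)
}

#' Tidy drug-disease scores
#'
#' @param x A `drug_scores` object.
#' @param ... Unused.
#' @return A tibble with one row per compound-trait pair.
#' @export
tidy.drug_scores <- function(x, ...) {
  tibble::tibble(compound = rep(rownames(x$final), ncol(x$final)),
                 trait = rep(colnames(x$final), each = nrow(x$final)),
                 score = as.numeric(x$final))
}

#' Per-module contributions to one drug-disease prediction
#'
#' Decomposes the all-module raw reversal score of a compound-trait pair
#' into additive per-module contributions
#' `-(lhat[compound, lv] * mhat[lv, trait])`, sorted so the modules that
#' drive the prediction (opposite direction between compound and disease)
#' come first. The contributions sum to the `k = all` raw module-space
#' score.
#'
#' @param mhat_t Module-by-trait projected TWAS matrix.
#' @param lhat Compound-by-module projected perturbation matrix.
#' @param compound,trait Pair to explain.
#' @return A tibble with columns `lv`, `contribution`, sorted decreasing.
#' @export
lv_contributions <- function(mhat_t, lhat, compound, trait) {
  if (!compound %in% rownames(lhat)) stop("unknown compound ",
                                          sQuote(compound))
  if (!trait %in% colnames(mhat_t)) stop("unknown trait ", sQuote(trait))
  lvs <- intersect(colnames(lhat), rownames(mhat_t))
  contrib <- -(lhat[compound, lvs] * mhat_t[lvs, trait])
  out <- tibble::tibble(lv = lvs, contribution = unname(contrib))
  out[order(-out$contribution, out$lv), ]
}

#' Evaluate drug-disease scores against a gold standard
#'
#' Computes the area under the ROC curve (midrank tie handling) and the
#' average precision of the final scores on a labelled set of
#' compound-trait pairs, together with a permuted-score baseline: the score
#' vector is randomly permuted `n_permutations` times and the metrics
#' recomputed, giving the chance level and its 95% range.
#'
#' @param scores A [score_drug_pairs()] result.
#' @param gold Data frame with columns `compound`, `trait`, `indicated`
#'   (logical). Every pair must be scored; both classes must be present.
#' @param n_permutations Number of score permutations for the baseline.
#' @param seed Integer seed for the permutations.
#' @return A list of class `drug_evaluation`: `summary` (one-row tibble),
#'   `pairs` (scored gold pairs), `permuted` (per-permutation metrics).
#' @export
evaluate_drug_scores <- function(scores, gold, n_permutations = 100,
                                 seed = 1) {
  stopifnot(inherits(scores, "drug_scores"))
  if (anyDuplicated(gold[, c("compound", "trait")])) {
    stop("duplicated compound-trait pairs in the gold standard")
  }
  ok <- gold$compound %in% rownames(scores$final) &
    gold$trait %in% colnames(scores$final)
  if (!all(ok)) stop("gold-standard pair(s) outside the scored set")
  s <- scores$final[cbind(gold$compound, gold$trait)]
  y <- as.logical(gold$indicated)
  if (all(y) || !any(y)) stop("gold standard must contain both classes")
  set.seed(seed)
  perm <- t(vapply(seq_len(n_permutations), function(i) {
    sp <- sample(s)
    c(auroc = auroc_midrank(sp, y), ap = average_precision(sp, y))
  }, c(auroc = 0, ap = 0)))
  summary <- tibble::tibble(
    auroc = auroc_midrank(s, y),
    average_precision = average_precision(s, y),
    baseline_auroc = mean(perm[, "auroc"]),
    baseline_ap = mean(perm[, "ap"]),
    baseline_ap_lo = unname(stats::quantile(perm[, "ap"], 0.025)),
    baseline_ap_hi = unname(stats::quantile(perm[, "ap"], 0.975)),
    n_indicated = sum(y), n_not_indicated = sum(!y),
    n_permutations = n_permutations)
  structure(list(summary = summary,
                 pairs = tibble::tibble(compound = gold$compound,
                                        trait = gold$trait, score = s,
                                        indicated = y),
                 permuted = tibble::as_tibble(perm)),
            class = "drug_evaluation")
}

#' @export
print.drug_evaluation <- function(x, ...) {
  cat("<drug_evaluation> AUROC ", signif(x$summary$auroc, 4), ", AP ",
      signif(x$summary$average_precision, 4), " (permuted baseline AP ",
      signif(x$summary$baseline_ap, 4), ")\n", sep = "")
  invisible(x)
}

# Wilcoxon/midrank AUROC.
auroc_midrank <- function(s, y) {
  r <- rank(s, ties.method = "average")
  n_pos <- sum(y); n_neg <- sum(!y)
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Average precision by step integration of the precision-recall curve;
# tie-broken deterministically by descending score then original index.
average_precision <- function(s, y) {
  ord <- order(-s, seq_along(s), method = "radix")
  yy <- y[ord]
  prec <- cumsum(yy) / seq_along(yy)
  sum(prec[yy]) / sum(yy)
}
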