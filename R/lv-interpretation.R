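#' Modules that discriminate one trait cluster from the rest
#'
#' Iterative root-split extraction: a depth-one classification tree is
#' trained to separate the cluster's traits from all others on the
#' trait-by-module matrix (classes weighted inversely to frequency so
#' small clusters can win the root split). The module at the root is
#' recorded together with its split threshold and marked as selected only
#' if the threshold is positive and larger than the standard deviation of
#' that module's column across all traits; the module is then removed from
#' the matrix regardless of selection, and the procedure repeats for the
#' requested number of iterations (stopping early when no split can be
#' made or no module remains).
#'
#' @param mhat Trait-by-module matrix (raw projected values).
#' @param labels Cluster label vector over the rows of `mhat` (names
#'   optional; order must match).
#' @param cluster_id The cluster to characterize (must have at least 2
#'   members and 2 non-members).
#' @param iterations Number of root modules to extract (default 20).
#' @param seed Integer seed (the tree fit is deterministic; the seed is
#'   recorded for provenance).
#' @return A tibble of class `cluster_lv_report` with columns `iteration`,
#'   `lv`, `threshold`, `lv_sd`, `selected`; attributes record the cluster
#'   id and the number of iterations actually run.
#' @export
discriminative_lvs <- function(mhat, labels, cluster_id, iterations = 20,
                               seed = 1) {
  stopifnot(is.matrix(mhat), length(labels) == nrow(mhat))
  in_cluster <- labels == cluster_id
  if (sum(in_cluster) < 2L || sum(!in_cluster) < 2L) {
    stop("cluster ", sQuote(cluster_id), " needs at least 2 members and ",
         "2 non-members")
  }
  lv_sd_all <- apply(mhat, 2L, stats::sd)
  y <- factor(ifelse(in_cluster, "in", "out"), levels = c("out", "in"))
  w <- ifelse(in_cluster, 0.5 / sum(in_cluster), 0.5 / sum(!in_cluster))
  w <- w * length(y) # mean weight 1, inverse-frequency balanced
  x <- mhat
  rows <- list()
  set.seed(seed)
  for (it in seq_len(iterations)) {
    if (ncol(x) == 0L) break
    df <- data.frame(x, check.names = FALSE)
    df$.y <- y
    fit <- rpart::rpart(
      .y ~ ., data = df, weights = w, method = "class",
      control = rpart::rpart.control(maxdepth = 1L, cp = 0, minsplit = 2L,
                                     minbucket = 1L, xval = 0L,
                                     maxcompete = 0L, maxsurrogate = 0L,
                                     usesurrogate = 0L))
    if (is.null(fit$splits) || nrow(fit$splits) == 0L) break
    lv <- as.character(fit$frame$var[1L])
    srow <- which(rownames(fit$splits) == lv)[1L]
    threshold <- unname(fit$splits[srow, "index"])
    rows[[it]] <- tibble::tibble(
      iteration = it, lv = lv, threshold = threshold,
      lv_sd = unname(lv_sd_all[lv]),
      selected = threshold > 0 && threshold > lv_sd_all[lv])
    x <- x[, setdiff(colnames(x), lv), drop = FALSE]
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "cluster_id") <- cluster_id
  attr(out, "iterations_run") <- nrow(out)
  attr(out, "seed") <- seed
  class(out) <- c("cluster_lv_report", class(out))
  out
}
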