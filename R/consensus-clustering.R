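#' Combine trait rows by Stouffer's method
#'
#' Combines the z-score rows of traits mapped to the same group (e.g. the
#' same ontology term) with sample-size-based weights:
#' `sum(w_i M_ij) / sqrt(sum(w_i^2))` per gene `j`. Singleton groups pass
#' through unchanged.
#'
#' @param z_rows Trait-by-feature z-score matrix.
#' @param groups Named character vector mapping trait id to group id.
#' @param weights Named numeric vector of positive per-trait weights
#'   (typically `sqrt(GWAS sample size)`).
#' @return A group-by-feature matrix, groups in first-appearance order.
#' @export
stouffer_combine <- function(z_rows, groups, weights) {
  stopifnot(is.matrix(z_rows), !is.null(rownames(z_rows)))
  traits <- rownames(z_rows)
  if (!all(traits %in% names(groups))) {
    stop("missing group for trait(s): ",
         paste(sQuote(setdiff(traits, names(groups))), collapse = ", "))
  }
  if (!all(traits %in% names(weights))) {
    stop("missing weight for trait(s): ",
         paste(sQuote(setdiff(traits, names(weights))), collapse = ", "))
  }
  w <- weights[traits]
  if (any(!is.finite(w) | w <= 0)) stop("weights must be positive")
  grp <- as.character(groups[traits])
  uniq <- unique(grp)
  out <- matrix(NA_real_, length(uniq), ncol(z_rows),
                dimnames = list(uniq, colnames(z_rows)))
  for (g in uniq) {
    idx <- which(grp == g)
    out[g, ] <- colSums(z_rows[idx, , drop = FALSE] * w[idx]) /
      sqrt(sum(w[idx]^2))
  }
  out
}

#' Probit transform of association p-values
#'
#' Converts two-sided p-values to z-scores, `z = Phi^-1(1 - p/2)`, so that
#' stronger associations get larger values. P-values are clamped below at
#' `1e-300`.
#'
#' @param p Matrix (or vector) of p-values in `(0, 1]`.
#' @return Transformed values, same shape.
#' @export
probit_transform <- function(p) {
  if (any(p > 1, na.rm = TRUE)) stop("p-values above 1")
  if (any(p < 0, na.rm = TRUE)) stop("negative p-values")
  # upper-tail form of Phi^-1(1 - p/2), stable for tiny p
  stats::qnorm(pmax(p, 1e-300) / 2, lower.tail = FALSE)
}

#' Normalize trait rows to unit sum
#'
#' Divides each trait's (nonnegative) z-scores by their row sum,
#' `M_ij / sum_j M_ij`, damping highly polygenic traits whose associations
#' are large across the board.
#'
#' @param z Trait-by-feature matrix with nonnegative entries and positive
#'   row sums.
#' @return The row-normalized matrix (each row sums to 1).
#' @export
polygenicity_normalize <- function(z) {
  stopifnot(is.matrix(z))
  if (any(z < 0)) stop("entries must be nonnegative")
  rs <- rowSums(z)
  bad <- which(rs <= 0)
  if (length(bad) > 0L) {
    stop("zero row sum for trait(s): ",
         paste(sQuote(rownames(z)[bad]), collapse = ", "))
  }
  sweep(z, 1L, rs, "/")
}

#' Build the three data representations for the clustering ensemble
#'
#' Produces the raw matrix, its projection onto the top principal
#' components, and a UMAP embedding, all over the same traits. The
#' component count is capped at `min(n_components, n_traits - 1, n_features)`
#' (with a message when capping occurs); PCA is deterministic given the
#' data and UMAP is seeded and single-threaded.
#'
#' @param mhat Trait-by-module matrix (rows are traits).
#' @param seed Integer seed for the UMAP embedding.
#' @param n_components Target dimensionality (default 50).
#' @return A named list `raw`, `pca`, `umap` of trait-by-dimension
#'   matrices.
#' @export
make_representations <- function(mhat, seed = 1, n_components = 50) {
  stopifnot(is.matrix(mhat), nrow(mhat) >= 3L)
  ncomp <- min(n_components, nrow(mhat) - 1L, ncol(mhat))
  if (ncomp < n_components) {
    rlang::inform(paste0("make_representations: capping components at ",
                         ncomp))
  }
  pca <- stats::prcomp(mhat, center = TRUE, scale. = FALSE)
  pca_rep <- pca$x[, seq_len(min(ncomp, ncol(pca$x))), drop = FALSE]
  set.seed(seed)
  umap_rep <- uwot::umap(mhat, n_components = ncomp,
                         n_neighbors = min(15, nrow(mhat) - 1L),
                         init = "pca", n_threads = 1, n_sgd_threads = 0)
  rownames(umap_rep) <- rownames(mhat)
  colnames(umap_rep) <- paste0("UMAP", seq_len(ncol(umap_rep)))
  list(raw = mhat, pca = pca_rep, umap = umap_rep)
}

#' Generate a diverse ensemble of trait partitions
#'
#' Runs five clustering algorithm families over each data representation:
#' k-means, spectral clustering and Gaussian mixtures (for each `k` in
#' `k_range`, `n_seeds` seeded runs each), agglomerative hierarchical
#' clustering (for each `k`, the ward, complete, average and single
#' linkages), and a density-based scan over a `minPts` grid with, for each
#' `minPts`, epsilon values taken at quantiles of the mean
#' `minPts`-nearest-neighbour distance. Density-based noise points become
#' singleton clusters; partitions with a single cluster or all points
#' noise are dropped, and the surviving density-based partitions are
#' resampled with replacement to the mean partition count of the other
#' four families in that representation, so no family dominates.
#'
#' @param reps A representation list from [make_representations()] (or any
#'   named list of trait-by-dimension matrices over the same traits).
#' @param k_range Cluster counts; default `2:floor(sqrt(n_traits))`.
#' @param n_seeds Seeded runs per `k` for the stochastic algorithms.
#' @param linkages Hierarchical linkage criteria.
#' @param minpts `minPts` grid for the density-based member (values above
#'   `n_traits - 1` are skipped).
#' @param eps_quantiles Quantiles of the mean nearest-neighbour distance
#'   distribution at which epsilon is taken.
#' @param seed Integer base seed; every stochastic run derives its own
#'   recorded seed from it.
#' @return An object of class `trait_ensemble`: `labels` (trait-by-r
#'   integer matrix) and `meta` (one row per partition: algorithm,
#'   representation, params, seed).
#' @export
generate_ensemble <- function(reps, k_range = NULL, n_seeds = 5,
                              linkages = c("ward.D2", "complete",
                                           "average", "single"),
                              minpts = c(2, 3, 5, 8, 13, 21, 34, 55, 89,
                                         125),
                              eps_quantiles = seq(0.1, 0.9,
                                                  length.out = 5),
                              seed = 1) {
  stopifnot(is.list(reps), length(reps) >= 1L)
  n <- nrow(reps[[1L]])
  traits <- rownames(reps[[1L]])
  for (r in reps) stopifnot(nrow(r) == n)
  if (is.null(k_range)) k_range <- 2:max(2L, floor(sqrt(n)))
  labels <- list()
  meta <- list()
  counter <- 0L
  add <- function(lab, algorithm, representation, params, run_seed) {
    counter <<- counter + 1L
    labels[[counter]] <<- as.integer(lab)
    meta[[counter]] <<- tibble::tibble(algorithm = algorithm,
                                       representation = representation,
                                       params = params,
                                       seed = run_seed)
  }
  run_seed <- seed
  next_seed <- function() {
    run_seed <<- run_seed + 1L
    run_seed
  }
  for (rep_name in names(reps)) {
    x <- reps[[rep_name]]
    base_count <- counter
    algo_counts <- numeric(0)
    # k-means
    before <- counter
    for (k in k_range) for (s in seq_len(n_seeds)) {
      rs <- next_seed()
      set.seed(rs)
      km <- tryCatch(stats::kmeans(x, centers = k, nstart = 1L),
                     error = function(e) NULL)
      if (!is.null(km)) add(km$cluster, "kmeans", rep_name,
                            paste0("k=", k), rs)
    }
    algo_counts["kmeans"] <- counter - before
    # spectral
    before <- counter
    for (k in k_range) for (s in seq_len(n_seeds)) {
      rs <- next_seed()
      set.seed(rs)
      sp <- tryCatch(
        suppressWarnings(kernlab::specc(x, centers = k)@.Data),
        error = function(e) NULL)
      if (!is.null(sp) && length(unique(sp)) > 1L) {
        add(sp, "spectral", rep_name, paste0("k=", k), rs)
      }
    }
    algo_counts["spectral"] <- counter - before
    # Gaussian mixture
    before <- counter
    for (k in k_range) for (s in seq_len(n_seeds)) {
      rs <- next_seed()
      set.seed(rs)
      gm <- tryCatch(
        suppressWarnings(mclust::Mclust(x, G = k,
                                        modelNames = c("EII", "VII"),
                                        verbose = FALSE)),
        error = function(e) NULL)
      if (!is.null(gm) && length(unique(gm$classification)) > 1L) {
        add(gm$classification, "gmm", rep_name, paste0("k=", k), rs)
      }
    }
    algo_counts["gmm"] <- counter - before
    # hierarchical
    before <- counter
    d <- stats::dist(x)
    for (link in linkages) {
      hc <- stats::hclust(d, method = link)
      for (k in k_range) {
        add(stats::cutree(hc, k = k), "hierarchical", rep_name,
            paste0("k=", k, ",linkage=", link), NA_integer_)
      }
    }
    algo_counts["hierarchical"] <- counter - before
    # density-based
    dm <- as.matrix(d)
    db_labels <- list()
    db_params <- character(0)
    for (mp in minpts[minpts <= n - 1L]) {
      knn_mean <- apply(dm, 1L, function(row) {
        mean(sort(row[-which.min(row)])[seq_len(mp)])
      })
      eps_grid <- unique(stats::quantile(knn_mean, eps_quantiles,
                                         names = FALSE))
      for (eps in eps_grid[eps_grid > 0]) {
        lab <- dbscan_labels(dm, eps = eps, minpts = mp)
        n_core_clusters <- length(unique(lab$cluster[lab$cluster > 0L]))
        all_noise <- all(lab$cluster == 0L)
        if (all_noise || (n_core_clusters <= 1L && !any(lab$cluster == 0L))) {
          next  # invalid: all noise, or a single cluster
        }
        db_labels[[length(db_labels) + 1L]] <- expand_noise(lab$cluster)
        db_params <- c(db_params,
                       paste0("minPts=", mp, ",eps=", signif(eps, 6)))
      }
    }
    target <- round(mean(algo_counts))
    if (length(db_labels) == 0L) {
      rlang::inform(paste0("generate_ensemble: no valid density-based ",
                           "partition for representation ", rep_name))
    } else if (target > 0L) {
      rs <- next_seed()
      set.seed(rs)
      pick <- sample.int(length(db_labels), size = target, replace = TRUE)
      for (j in pick) {
        add(db_labels[[j]], "dbscan", rep_name, db_params[j], rs)
      }
    }
    stopifnot(counter > base_count)
  }
  lab_mat <- do.call(cbind, labels)
  rownames(lab_mat) <- traits
  structure(list(labels = lab_mat, meta = dplyr::bind_rows(meta)),
            class = "trait_ensemble")
}

#' @export
print.trait_ensemble <- function(x, ...) {
  cat("<trait_ensemble> ", ncol(x$labels), " partitions of ",
      nrow(x$labels), " traits\n", sep = "")
  print(table(x$meta$algorithm, x$meta$representation))
  invisible(x)
}

# Plain DBSCAN on a precomputed distance matrix. Noise points get label 0.
dbscan_labels <- function(dm, eps, minpts) {
  n <- nrow(dm)
  nb <- lapply(seq_len(n), function(i) which(dm[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= minpts
  cluster <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (cluster[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    cluster[i] <- cl
    while (length(queue) > 0L) {
      j <- queue[1L]
      queue <- queue[-1L]
      if (!core[j]) next
      for (q in nb[[j]]) {
        if (cluster[q] == 0L) {
          cluster[q] <- cl
          queue <- c(queue, q)
        }
      }
    }
  }
  list(cluster = cluster, core = core)
}

# Noise points become singleton clusters so pairwise disagreement is kept.
expand_noise <- function(cluster) {
  noise <- which(cluster == 0L)
  if (length(noise) > 0L) {
    cluster[noise] <- max(cluster) + seq_along(noise)
  }
  cluster
}

#' Evidence-accumulation distance between traits
#'
#' For each pair of traits, the fraction of ensemble partitions that place
#' them in different clusters: `D_ij = d_ij / r`. Entries are exact
#' rationals over `r`; the diagonal is zero and the matrix symmetric.
#'
#' @param ens A [generate_ensemble()] result.
#' @return An object of class `eac_distance` with the matrix `D` and the
#'   partition count `r`.
#' @export
eac_distance <- function(ens) {
  stopifnot(inherits(ens, "trait_ensemble"))
  lab <- ens$labels
  r <- ncol(lab)
  if (r < 1L) stop("empty ensemble")
  n <- nrow(lab)
  disagree <- matrix(0L, n, n)
  for (j in seq_len(r)) {
    disagree <- disagree + outer(lab[, j], lab[, j], "!=")
  }
  D <- disagree / r
  dimnames(D) <- list(rownames(lab), rownames(lab))
  structure(list(D = D, r = r), class = "eac_distance")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement under the permutation model; 1 for identical
#' partitions (up to label renaming), approximately 0 for independent
#' ones.
#'
#' @param p1,p2 Label vectors over the same items.
#' @return A scalar in `[-1, 1]`.
#' @export
ari <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("partitions must cover the same items")
  mclust::adjustedRandIndex(p1, p2)
}

#' Spectral consensus over the evidence-accumulation distance
#'
#' For each cluster count `k` and each kernel width `gamma`, transforms
#' the distance into a similarity `exp(-gamma * D^2)`, runs normalized
#' spectral clustering, and measures the candidate's agreement with the
#' ensemble as the median adjusted Rand index against every ensemble
#' partition. Per `k`, the `gamma` with the best agreement wins. The
#' default `gamma` grid is `{0.5, 1, 2, 5} / median(offdiag(D^2))`.
#'
#' @param dist An [eac_distance()] result.
#' @param ens The [generate_ensemble()] the distance came from.
#' @param k_range Cluster counts to derive (default
#'   `2:floor(sqrt(n_traits))`).
#' @param gamma_grid Optional explicit kernel widths.
#' @param seed Integer seed for the k-means step inside spectral
#'   clustering.
#' @return A tibble of class `consensus_solutions` with one row per `k`:
#'   `k`, `gamma`, `agreement`, and the winning `partition` (list column).
#'   The full k-by-gamma grid is kept in the `"grid"` attribute.
#' @export
consensus_partition <- function(dist, ens, k_range = NULL,
                                gamma_grid = NULL, seed = 1) {
  stopifnot(inherits(dist, "eac_distance"),
            inherits(ens, "trait_ensemble"))
  D <- dist$D
  n <- nrow(D)
  if (is.null(k_range)) k_range <- 2:max(2L, floor(sqrt(n)))
  off <- D[upper.tri(D)]^2
  if (is.null(gamma_grid)) {
    med <- stats::median(off)
    if (med <= 0) stop("degenerate distance matrix (all traits always ",
                       "co-clustered); cannot set a gamma grid")
    gamma_grid <- c(0.5, 1, 2, 5) / med
  }
  rows <- list()
  grid <- list()
  for (k in k_range) {
    best <- NULL
    for (g in gamma_grid) {
      S <- exp(-g * D^2)
      if (stats::sd(S[upper.tri(S)]) < 1e-12) {
        stop("degenerate similarity matrix (all off-diagonal entries ",
             "equal); try a different gamma")
      }
      part <- spectral_partition(S, k, seed = seed)
      agree <- stats::median(apply(ens$labels, 2L, ari, p2 = part))
      grid[[length(grid) + 1L]] <- tibble::tibble(k = k, gamma = g,
                                                  agreement = agree)
      cand <- list(k = k, gamma = g, agreement = agree, partition = part)
      if (is.null(best) || cand$agreement > best$agreement) best <- cand
    }
    rows[[as.character(k)]] <- tibble::tibble(
      k = best$k, gamma = best$gamma, agreement = best$agreement,
      partition = list(best$partition))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "grid") <- dplyr::bind_rows(grid)
  class(out) <- c("consensus_solutions", class(out))
  out
}

# Normalized spectral clustering (symmetric Laplacian, row-normalized
# eigenvector embedding, seeded k-means).
spectral_partition <- function(S, k, seed = 1) {
  d <- rowSums(S)
  d[d <= 0] <- 1e-12
  L <- S / sqrt(d) / rep(sqrt(d), each = nrow(S))
  e <- eigen(L, symmetric = TRUE)
  U <- e$vectors[, seq_len(k), drop = FALSE]
  norms <- sqrt(rowSums(U^2))
  norms[norms < 1e-12] <- 1
  U <- U / norms
  set.seed(seed)
  km <- stats::kmeans(U, centers = k, nstart = 10L, iter.max = 50L)
  stats::setNames(km$cluster, rownames(S))
}

#' Keep only high-agreement consensus solutions
#'
#' Retains the solutions whose ensemble agreement is strictly greater
#' than the 75th percentile of agreement values across all cluster counts.
#' If all agreements are equal nothing survives (with a warning).
#'
#' @param cons A [consensus_partition()] result (at least 4 solutions).
#' @return The filtered `consensus_solutions` tibble.
#' @export
filter_solutions <- function(cons) {
  stopifnot(inherits(cons, "consensus_solutions"))
  if (nrow(cons) < 4L) stop("need at least 4 solutions to filter")
  cut <- stats::quantile(cons$agreement, 0.75, names = FALSE)
  keep <- cons$agreement > cut
  if (!any(keep)) {
    warning("no solution exceeds the 75th percentile of agreement")
  }
  out <- cons[keep, ]
  class(out) <- c("consensus_solutions", class(out))
  out
}

#' Edges of the clustering tree across resolutions
#'
#' For each pair of consecutive resolutions (increasing `k`), counts the
#' traits shared between every cluster of the coarser partition and every
#' cluster of the finer one; edges with positive overlap describe how
#' traits flow between clusters as the resolution increases.
#'
#' @param cons A `consensus_solutions` tibble with at least 2 rows.
#' @return A tibble with columns `k_parent`, `cluster_parent`, `k_child`,
#'   `cluster_child`, `n_shared`.
#' @export
clustering_tree_edges <- function(cons) {
  stopifnot(inherits(cons, "consensus_solutions"))
  if (nrow(cons) < 2L) stop("need at least 2 resolutions")
  cons <- cons[order(cons$k), ]
  rows <- list()
  for (i in seq_len(nrow(cons) - 1L)) {
    p1 <- cons$partition[[i]]
    p2 <- cons$partition[[i + 1L]]
    tab <- table(parent = p1, child = p2)
    idx <- which(tab > 0, arr.ind = TRUE)
    rows[[i]] <- tibble::tibble(
      k_parent = cons$k[i],
      cluster_parent = as.integer(rownames(tab)[idx[, "parent"]]),
      k_child = cons$k[i + 1L],
      cluster_child = as.integer(colnames(tab)[idx[, "child"]]),
      n_shared = as.integer(tab[idx]))
  }
  dplyr::bind_rows(rows)
}
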