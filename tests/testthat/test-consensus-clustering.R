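test_that("Stouffer combining follows the weighted formula", {
  z <- matrix(c(1, 2, 3, 1, 2, 3, 5, 5, 5), 3, byrow = TRUE,
              dimnames = list(c("tr1", "tr2", "tr3"),
                              c("g1", "g2", "g3")))
  groups <- c(tr1 = "A", tr2 = "A", tr3 = "B")
  w <- c(tr1 = 1, tr2 = 1, tr3 = 2)
  out <- stouffer_combine(z, groups, w)
  # identical rows, equal weights: sqrt(2) times the row
  expect_equal(out["A", ], sqrt(2) * z["tr1", ], tolerance = 1e-12)
  # singleton group passes through
  expect_equal(out["B", ], z["tr3", ], tolerance = 1e-12)

  # three rows with weights (1, 2, 3) against direct evaluation
  set.seed(51)
  z3 <- matrix(rnorm(12), 3, 4,
               dimnames = list(paste0("t", 1:3), paste0("g", 1:4)))
  w3 <- c(t1 = 1, t2 = 2, t3 = 3)
  out3 <- stouffer_combine(z3, c(t1 = "G", t2 = "G", t3 = "G"), w3)
  expect_equal(out3["G", ],
               (1 * z3[1, ] + 2 * z3[2, ] + 3 * z3[3, ]) /
                 sqrt(1 + 4 + 9), tolerance = 1e-12)
  expect_error(stouffer_combine(z, groups, w[-1]), "weight")
})

test_that("the probit transform maps p-values to signed evidence", {
  expect_equal(probit_transform(1), 0)
  expect_equal(probit_transform(0.05), 1.959964, tolerance = 1e-5)
  set.seed(52)
  p <- sort(runif(20))
  z <- probit_transform(p)
  expect_true(all(diff(z) <= 0))  # smaller p, larger z
  expect_error(probit_transform(1.2), "above 1")
  # clamped extreme
  expect_lt(probit_transform(0), 40)
})

test_that("polygenicity normalization rescales rows to unit sum", {
  z <- rbind(a = c(1, 1, 2), b = c(10, 10, 20))
  out <- polygenicity_normalize(z)
  expect_equal(out["a", ], c(0.25, 0.25, 0.5), ignore_attr = TRUE)
  # scale invariance
  expect_equal(out["a", ], out["b", ])
  expect_equal(unname(rowSums(out)), c(1, 1), tolerance = 1e-12)
  z0 <- rbind(a = c(0, 0), b = c(1, 1))
  expect_error(polygenicity_normalize(z0), "a")
})

test_that("representations cover raw, orthogonal PCs and a seeded
           embedding", {
  set.seed(53)
  mhat <- matrix(rnorm(40 * 10), 40, 10,
                 dimnames = list(sprintf("t%02d", 1:40), NULL))
  reps <- suppressMessages(make_representations(mhat, seed = 9,
                                                n_components = 50))
  expect_identical(reps$raw, mhat)
  # capped at min(50, n - 1, p) = 10
  expect_equal(ncol(reps$pca), 10L)
  cp <- crossprod(reps$pca)
  expect_equal(cp - diag(diag(cp)), matrix(0, 10, 10),
               tolerance = 1e-8, ignore_attr = TRUE)
  reps2 <- suppressMessages(make_representations(mhat, seed = 9,
                                                 n_components = 50))
  expect_identical(reps$umap, reps2$umap)  # seeded determinism
})

test_that("the ensemble grid produces the expected partition counts", {
  set.seed(54)
  x <- matrix(rnorm(100 * 5), 100, 5,
              dimnames = list(sprintf("t%03d", 1:100), NULL))
  ens <- generate_ensemble(list(raw = x), seed = 4)
  km <- ens$meta$algorithm == "kmeans"
  # k in 2..floor(sqrt(100)) = 2..10, five seeds each
  expect_equal(sum(km), 45L)
  expect_equal(sum(ens$meta$algorithm == "hierarchical"), 9L * 4L)
  expect_true(all(apply(ens$labels, 2, function(l) length(l) == 100)))
  # stamped provenance
  expect_true(all(!is.na(ens$meta$seed[ens$meta$algorithm == "kmeans"])))
  # fixed seed: bit-identical rerun
  ens2 <- generate_ensemble(list(raw = x), seed = 4)
  expect_identical(ens$labels, ens2$labels)
  expect_identical(ens$meta, ens2$meta)
})

test_that("the internal density scan matches DBSCAN semantics on a toy
           layout", {
  # two tight pairs far apart plus one isolated point
  x <- rbind(c(0, 0), c(0, 0.1), c(10, 0), c(10, 0.1), c(50, 50))
  dm <- as.matrix(dist(x))
  lab <- modulewas:::dbscan_labels(dm, eps = 0.5, minpts = 2)
  expect_equal(lab$cluster[1:2], c(1L, 1L))
  expect_equal(lab$cluster[3:4], c(2L, 2L))
  expect_equal(lab$cluster[5], 0L)  # noise
  expanded <- modulewas:::expand_noise(lab$cluster)
  expect_equal(expanded[5], 3L)     # singleton cluster
})

test_that("the evidence-accumulation distance counts disagreements
           exactly", {
  lab1 <- c(a = 1L, b = 1L, c = 2L)
  ens1 <- as_trait_ensemble(cbind(lab1))
  D1 <- eac_distance(ens1)
  expect_equal(D1$D["a", "b"], 0)
  expect_equal(D1$D["a", "c"], 1)

  ens2 <- as_trait_ensemble(cbind(c(1L, 1L, 2L), c(1L, 2L, 2L)))
  expect_equal(eac_distance(ens2)$D[1, 2], 0.5)

  # random ensemble against a brute-force pair loop
  set.seed(55)
  lab <- matrix(sample(1:4, 20 * 7, replace = TRUE), 20, 7,
                dimnames = list(sprintf("t%02d", 1:20), NULL))
  D <- eac_distance(as_trait_ensemble(lab))$D
  for (i in c(1, 5, 12)) for (j in c(3, 9, 20)) {
    expect_equal(D[i, j], mean(lab[i, ] != lab[j, ]))
  }
  expect_true(isSymmetric(D))
  expect_equal(unname(diag(D)), rep(0, 20))
})

test_that("the adjusted Rand index matches the contingency closed form", {
  expect_equal(ari(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(ari(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)  # label permutation
  p1 <- c(1, 1, 2, 2); p2 <- c(1, 2, 2, 2)
  expect_equal(ari(p1, p2), ari_closed_form(p1, p2), tolerance = 1e-12)
  set.seed(56)
  q1 <- sample(1:3, 30, replace = TRUE)
  q2 <- sample(1:4, 30, replace = TRUE)
  expect_equal(ari(q1, q2), ari_closed_form(q1, q2), tolerance = 1e-12)
})

test_that("spectral consensus recovers perfect block structure and obeys
           the argmax contract", {
  blocks <- rep(1:3, each = 6)
  D <- outer(blocks, blocks, "!=") * 1
  dimnames(D) <- list(sprintf("t%02d", 1:18), sprintf("t%02d", 1:18))
  # ensemble of noisy copies of the block structure
  set.seed(57)
  lab <- vapply(1:12, function(i) {
    l <- blocks
    flip <- sample(18, 2)
    l[flip] <- sample(1:3, 2, replace = TRUE)
    l
  }, integer(18))
  rownames(lab) <- rownames(D)
  ens <- as_trait_ensemble(lab)
  dist <- structure(list(D = D, r = 12L), class = "eac_distance")
  cons <- consensus_partition(dist, ens, k_range = 2:4, seed = 3)
  k3 <- cons$partition[[match(3, cons$k)]]
  expect_equal(ari(k3, blocks), 1)

  # winner's agreement is the maximum over the gamma grid at each k
  grid <- attr(cons, "grid")
  for (k in cons$k) {
    expect_equal(cons$agreement[cons$k == k],
                 max(grid$agreement[grid$k == k]), tolerance = 1e-12)
  }

  # degenerate distance: all zeros
  D0 <- D * 0
  dist0 <- structure(list(D = D0, r = 12L), class = "eac_distance")
  expect_error(consensus_partition(dist0, ens, k_range = 2:3),
               "degenerate")
})

test_that("the agreement filter keeps strictly-above-quantile solutions", {
  mk <- function(agr) {
    out <- tibble::tibble(k = seq_along(agr) + 1L, gamma = 1,
                          agreement = agr,
                          partition = replicate(length(agr),
                                                1:5, simplify = FALSE))
    class(out) <- c("consensus_solutions", class(out))
    out
  }
  f16 <- filter_solutions(mk(seq(0.1, 1.6, by = 0.1)))
  expect_lte(nrow(f16), 4L)
  expect_equal(f16$agreement, c(1.3, 1.4, 1.5, 1.6))
  expect_warning(f0 <- filter_solutions(mk(rep(0.5, 8))), "no solution")
  expect_equal(nrow(f0), 0L)
})

test_that("clustering-tree edges conserve cluster sizes and match
           cross-tabulation", {
  p5 <- rep(1:2, each = 6)
  p10 <- c(rep(1, 3), rep(2, 3), rep(3, 6))  # nested refinement
  cons <- tibble::tibble(k = c(2L, 3L), gamma = 1,
                         agreement = c(0.9, 0.8),
                         partition = list(p5, p10))
  class(cons) <- c("consensus_solutions", class(cons))
  edges <- clustering_tree_edges(cons)
  # nested: each child cluster has exactly one incoming edge
  expect_equal(nrow(edges), 3L)
  expect_equal(sort(table(edges$cluster_child)), sort(table(1:3)),
               ignore_attr = TRUE)
  # conservation: outgoing shared counts sum to the parent cluster size
  for (cl in unique(p5)) {
    expect_equal(sum(edges$n_shared[edges$cluster_parent == cl]),
                 sum(p5 == cl))
  }
  # random pair against brute-force cross-tabulation
  set.seed(58)
  q1 <- sample(1:3, 15, replace = TRUE)
  q2 <- sample(1:4, 15, replace = TRUE)
  cons2 <- tibble::tibble(k = c(3L, 4L), gamma = 1,
                          agreement = c(0.5, 0.5),
                          partition = list(q1, q2))
  class(cons2) <- c("consensus_solutions", class(cons2))
  e2 <- clustering_tree_edges(cons2)
  for (r in seq_len(nrow(e2))) {
    expect_equal(e2$n_shared[r],
                 sum(q1 == e2$cluster_parent[r] &
                       q2 == e2$cluster_child[r]))
  }
})
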