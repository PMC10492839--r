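test_that("top-k restriction keeps the largest magnitudes with
           deterministic ties", {
  mt <- matrix(c(3, -2, 1), 1, 3,
               dimnames = list("trait1", c("gA", "gB", "gC")))
  expect_equal(topk_restrict(mt, Inf), mt)
  expect_equal(unname(topk_restrict(mt, 2)[1, ]), c(3, -2, 0))

  tie <- matrix(c(2, 2, 1), 1, 3,
                dimnames = list("trait1", c("gB", "gA", "gC")))
  out <- topk_restrict(tie, 1)
  expect_equal(unname(out[1, ]), c(0, 2, 0))  # lexicographic winner gA
  expect_error(topk_restrict(mt, 0), "positive")
})

test_that("raw reversal scores follow the sign convention", {
  mt <- matrix(2, 1, 1, dimnames = list("d1", "g1"))
  l <- matrix(-1, 1, 1, dimnames = list("c1", "g1"))
  sc <- score_drug_pairs(mt, l, k_grid = Inf)
  expect_equal(unname(sc$per_tissue_k$tissue1$kInf["c1", "d1"]), 2)

  # orthogonal profiles score zero
  mt2 <- matrix(c(1, 0), 1, 2, dimnames = list("d1", c("g1", "g2")))
  l2 <- matrix(c(0, 5), 1, 2, dimnames = list("c1", c("g1", "g2")))
  sc2 <- score_drug_pairs(mt2, l2, k_grid = Inf)
  expect_equal(unname(sc2$per_tissue_k$tissue1$kInf["c1", "d1"]), 0)
})

test_that("rank-averaged scores match a hand-enumerated oracle and the
           tissue maximum", {
  mt <- matrix(c(1, 0,
                 2, -1), 2, 2, byrow = TRUE,
               dimnames = list(c("dA", "dB"), c("g1", "g2")))
  l <- matrix(c(-1, 0,
                1, 1,
                0, -2), 3, 2, byrow = TRUE,
              dimnames = list(c("c1", "c2", "c3"), c("g1", "g2")))
  sc <- score_drug_pairs(mt, l, k_grid = c(Inf, 1))
  # k = all raw scores: -l %*% t(mt)
  raw_all <- -1 * l %*% t(mt)
  expect_equal(sc$per_tissue_k$tissue1$kInf, raw_all)
  # k = 1 restricts dA to g1 (|1| > |0|) and dB to g2 is wrong:
  # dB magnitudes are |2|, |-1| so g1 is kept
  mt_k1 <- matrix(c(1, 0, 2, 0), 2, 2, byrow = TRUE,
                  dimnames = dimnames(mt))
  expect_equal(sc$per_tissue_k$tissue1$k1, -1 * l %*% t(mt_k1))
  # hand-computed rank average per trait column
  expected <- (apply(raw_all, 2, rank) +
                 apply(-1 * l %*% t(mt_k1), 2, rank)) / 2
  expect_equal(sc$per_tissue$tissue1, expected)
  expect_equal(sc$final, expected)

  # two tissues: elementwise maximum of rank-averaged matrices
  sc2 <- score_drug_pairs(list(t1 = mt, t2 = -mt), l, k_grid = c(Inf, 1))
  expect_equal(sc2$final, pmax(sc2$per_tissue$t1, sc2$per_tissue$t2))
})

test_that("negating a compound negates its raw scores and monotone
           transforms keep ranks", {
  set.seed(41)
  mt <- matrix(rnorm(8), 2, 4,
               dimnames = list(c("d1", "d2"), paste0("g", 1:4)))
  l <- matrix(rnorm(12), 3, 4,
              dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
  sc <- score_drug_pairs(mt, l, k_grid = c(Inf, 2))
  l_neg <- l; l_neg["c2", ] <- -l["c2", ]
  sc_neg <- score_drug_pairs(mt, l_neg, k_grid = c(Inf, 2))
  for (k in c("kInf", "k2")) {
    expect_equal(sc_neg$per_tissue_k$tissue1[[k]]["c2", ],
                 -sc$per_tissue_k$tissue1[[k]]["c2", ])
  }
  # per-k ranks are invariant to strictly monotone transforms of raw
  # scores, so scaling the shared axis scales raw scores but not ranks
  sc_scaled <- score_drug_pairs(mt * 3, l, k_grid = c(Inf, 2))
  expect_equal(sc_scaled$final, sc$final)
})

test_that("module contributions are additive and sign-symmetric", {
  set.seed(42)
  mhat <- matrix(rnorm(20), 20, 1,
                 dimnames = list(sprintf("LV%02d", 1:20), "d1"))
  lhat <- matrix(rnorm(20), 1, 20,
                 dimnames = list("c1", sprintf("LV%02d", 1:20)))
  contrib <- lv_contributions(mhat, lhat, "c1", "d1")
  expect_equal(sum(contrib$contribution),
               as.numeric(-lhat %*% mhat), tolerance = 1e-10)
  expect_true(all(diff(contrib$contribution) <= 0))

  contrib_neg <- lv_contributions(mhat, -lhat, "c1", "d1")
  expect_equal(sort(contrib_neg$contribution),
               sort(-contrib$contribution), tolerance = 1e-12)

  # single-module toy: that module carries the whole score
  m1 <- mhat[1, , drop = FALSE]
  l1 <- lhat[, 1, drop = FALSE]
  c1 <- lv_contributions(m1, l1, "c1", "d1")
  expect_equal(c1$contribution, as.numeric(-l1 %*% m1))
  expect_error(lv_contributions(mhat, lhat, "cX", "d1"), "compound")
})

test_that("gold-standard evaluation matches exact cases and a pairwise
           oracle", {
  final <- matrix(c(5, 4, 3, 2, 1, 0), 3, 2,
                  dimnames = list(c("c1", "c2", "c3"), c("d1", "d2")))
  sc <- structure(list(final = final, per_tissue = list(),
                       per_tissue_k = list(), k_grid = Inf,
                       space = "gene"),
                  class = "drug_scores")
  gold_perfect <- tibble::tibble(
    compound = c("c1", "c2", "c3"), trait = "d1",
    indicated = c(TRUE, FALSE, FALSE))
  ev <- evaluate_drug_scores(sc, gold_perfect, n_permutations = 10)
  expect_equal(ev$summary$auroc, 1)
  expect_equal(ev$summary$average_precision, 1)

  # constant scores: midrank AUROC is exactly 0.5
  sc_const <- sc; sc_const$final[] <- 7
  ev_const <- evaluate_drug_scores(sc_const, gold_perfect,
                                   n_permutations = 10)
  expect_equal(ev_const$summary$auroc, 0.5)

  # 10-pair case against the O(n^2) concordance oracle
  set.seed(43)
  gold10 <- tibble::tibble(
    compound = rep(c("c1", "c2", "c3"), length.out = 10),
    trait = rep(c("d1", "d2"), 5),
    indicated = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE,
                  FALSE, FALSE))
  gold10 <- gold10[!duplicated(gold10[, 1:2]), ]
  s <- sc$final[cbind(gold10$compound, gold10$trait)]
  y <- gold10$indicated
  conc <- 0; total <- 0
  for (i in which(y)) for (j in which(!y)) {
    total <- total + 1
    conc <- conc + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  }
  ev10 <- evaluate_drug_scores(sc, gold10, n_permutations = 10)
  expect_equal(ev10$summary$auroc, conc / total)
  expect_error(evaluate_drug_scores(sc, dplyr::mutate(gold_perfect,
                                                      indicated = TRUE),
                                    n_permutations = 2),
               "both classes")
})

test_that("the evaluation agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(44)
  final <- matrix(rnorm(40), 10, 4,
                  dimnames = list(sprintf("c%02d", 1:10),
                                  sprintf("d%d", 1:4)))
  sc <- structure(list(final = final, per_tissue = list(),
                       per_tissue_k = list(), k_grid = Inf,
                       space = "lv"),
                  class = "drug_scores")
  gold <- tibble::tibble(
    compound = rep(rownames(final), 4),
    trait = rep(colnames(final), each = 10),
    indicated = sample(c(TRUE, FALSE), 40, replace = TRUE))
  ev <- evaluate_drug_scores(sc, gold, n_permutations = 5)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = gold$indicated,
    predictor = final[cbind(gold$compound, gold$trait)],
    quiet = TRUE, direction = "<")))
  expect_equal(ev$summary$auroc, ref, tolerance = 1e-10)
})
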