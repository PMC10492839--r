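#' Generate a block-correlated genotype reference panel
#'
#' Dosages are built from two latent Gaussian allele draws per SNP with a
#' shared per-block factor: within a block the latent variables correlate
#' at `within_block_r`, across blocks they are independent. Each latent
#' draw is thresholded at its per-SNP minor-allele frequency, so dosages
#' are 0/1/2 with binomial margins and block-structured LD.
#'
#' @param n_individuals Panel size.
#' @param block_sizes Integer vector of SNPs per LD block.
#' @param within_block_r Latent within-block correlation, scalar or one
#'   value per block (in `[0, 1)`).
#' @param maf_range Range of per-SNP minor-allele frequencies (drawn
#'   uniformly; must lie within `(0, 0.5]`).
#' @param seed Integer seed.
#' @return A [genotype_panel()] with per-SNP block labels.
#' @export
generate_panel <- function(n_individuals = 2000,
                           block_sizes = rep(5, 100),
                           within_block_r = 0.4,
                           maf_range = c(0.1, 0.4), seed = 1) {
  stopifnot(all(block_sizes >= 1L), n_individuals >= 10L)
  if (maf_range[1L] <= 0 || maf_range[2L] > 0.5) {
    stop("minor-allele frequencies must lie in (0, 0.5]")
  }
  n_blocks <- length(block_sizes)
  r <- rep_len(within_block_r, n_blocks)
  if (any(r < 0 | r >= 1)) stop("within_block_r must lie in [0, 1)")
  set.seed(seed)
  n_snps <- sum(block_sizes)
  blocks <- rep(seq_len(n_blocks), times = block_sizes)
  maf <- stats::runif(n_snps, maf_range[1L], maf_range[2L])
  X <- matrix(0L, n_individuals, n_snps)
  for (allele in 1:2) {
    f <- matrix(stats::rnorm(n_individuals * n_blocks), n_individuals)
    e <- matrix(stats::rnorm(n_individuals * n_snps), n_individuals)
    z <- sqrt(r)[blocks][col(e)] * f[, blocks] +
      sqrt(1 - r[blocks])[col(e)] * e
    X <- X + (stats::pnorm(z) < maf[col(z)])
  }
  colnames(X) <- sprintf("snp%04d", seq_len(n_snps))
  genotype_panel(X, blocks = blocks)
}

#' Generate per-gene per-tissue eQTL prediction models
#'
#' Each gene is assigned to one LD block and draws its model SNPs within
#' that block (per tissue, without replacement), with standard-normal
#' weights. Genes sharing a block therefore have correlated predicted
#' expression; genes in different blocks are essentially uncorrelated.
#'
#' @param panel A [generate_panel()] result (block labels required).
#' @param n_genes Number of genes.
#' @param n_tissues Number of tissues in the study.
#' @param tissues_per_gene `NULL` (every gene modelled in every tissue) or
#'   a length-2 range: each gene is modelled in a uniformly drawn number
#'   of tissues within the range, emulating the varying tissue
#'   availability of real eQTL model collections.
#' @param snps_per_model SNPs per (gene, tissue) model.
#' @param gene_blocks Optional explicit gene-to-block assignment (integer
#'   vector of length `n_genes`); default round-robin over the blocks.
#' @param seed Integer seed.
#' @return A tibble with columns `gene`, `tissue`, `snp_id`, `weight` and
#'   a `"gene_blocks"` attribute.
#' @export
generate_models <- function(panel, n_genes = 100, n_tissues = 2,
                            tissues_per_gene = NULL, snps_per_model = 3,
                            gene_blocks = NULL, seed = 1) {
  stopifnot(inherits(panel, "genotype_panel"), !is.null(panel$blocks))
  n_blocks <- max(panel$blocks)
  if (is.null(gene_blocks)) {
    gene_blocks <- rep_len(seq_len(n_blocks), n_genes)
  }
  stopifnot(length(gene_blocks) == n_genes,
            all(gene_blocks %in% seq_len(n_blocks)))
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  tissues <- sprintf("t%d", seq_len(n_tissues))
  rows <- list()
  for (g in seq_len(n_genes)) {
    block_snps <- panel$snp_ids[panel$blocks == gene_blocks[g]]
    if (length(block_snps) < snps_per_model) {
      stop("block ", gene_blocks[g], " has fewer than ", snps_per_model,
           " SNPs")
    }
    gene_tissues <- tissues
    if (!is.null(tissues_per_gene)) {
      n_t <- sample(tissues_per_gene[1L]:tissues_per_gene[2L], 1L)
      gene_tissues <- sort(sample(tissues, n_t))
    }
    for (tis in gene_tissues) {
      snps <- sample(block_snps, snps_per_model)
      rows[[length(rows) + 1L]] <-
        tibble::tibble(gene = genes[g], tissue = tis, snp_id = snps,
                       weight = stats::rnorm(snps_per_model))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "gene_blocks") <- stats::setNames(gene_blocks, genes)
  out
}

#' Generate a sparse nonnegative latent gene-module model
#'
#' Builds a PLIER-style loading matrix: a small nonnegative background on
#' every entry plus clearly elevated loadings on each module's designated
#' member genes, so member loadings exceed the background's upper
#' quantiles by construction.
#'
#' @param n_genes,n_lvs Dimensions (ignored where `gene_ids` /
#'   `member_sets` are given).
#' @param members_per_lv Members per module when `member_sets` is not
#'   supplied; modules take consecutive disjoint gene stretches (recycled
#'   if needed).
#' @param member_sets Optional named list: module id to character vector
#'   of member gene ids.
#' @param loading_scale Mean elevation of member loadings.
#' @param background_sd Scale of the nonnegative background loadings.
#' @param lambda2 Training ridge penalty stored in the model.
#' @param gene_ids Optional gene ids (default `g001`, ...).
#' @param with_B If `TRUE`, attach a module-by-sample metadata matrix with
#'   one labelled sample group per module.
#' @param seed Integer seed.
#' @return A [latent_model()].
#' @export
generate_latent_model <- function(n_genes = 100, n_lvs = 10,
                                  members_per_lv = 5, member_sets = NULL,
                                  loading_scale = 1, background_sd = 0.01,
                                  lambda2 = 1, gene_ids = NULL,
                                  with_B = FALSE, seed = 1) {
  set.seed(seed)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(n_genes))
  n_genes <- length(gene_ids)
  if (is.null(member_sets)) {
    member_sets <- lapply(seq_len(n_lvs), function(j) {
      idx <- ((j - 1L) * members_per_lv + seq_len(members_per_lv) - 1L) %%
        n_genes + 1L
      gene_ids[idx]
    })
    names(member_sets) <- sprintf("LV%02d", seq_len(n_lvs))
  }
  n_lvs <- length(member_sets)
  lv_ids <- names(member_sets)
  Z <- matrix(abs(stats::rnorm(n_genes * n_lvs, sd = background_sd)),
              n_genes, n_lvs, dimnames = list(gene_ids, lv_ids))
  for (lv in lv_ids) {
    mem <- member_sets[[lv]]
    Z[mem, lv] <- Z[mem, lv] +
      loading_scale * (0.5 + abs(stats::rnorm(length(mem), sd = 0.25)))
  }
  B <- NULL
  if (with_B) {
    B <- matrix(stats::rnorm(n_lvs * 2L * n_lvs, sd = 0.1), n_lvs,
                dimnames = list(lv_ids,
                                paste0("sample", seq_len(2L * n_lvs))))
    for (j in seq_len(n_lvs)) B[j, (2L * j - 1L):(2L * j)] <- 1
  }
  out <- latent_model(Z, lambda2 = lambda2, B = B)
  attr(out, "member_sets") <- member_sets
  out
}

#' Generate TWAS results with planted module-trait effects
#'
#' Simulates phenotypes over the panel individuals — null traits
#' independent of genotype, effect traits loading on the member genes of a
#' planted module with coefficients proportional to the loadings — then
#' runs the full association machinery: per-SNP GWAS summary statistics,
#' per-tissue summary z-scores, and the multi-tissue PC-reduced p-values.
#'
#' @param panel A [genotype_panel()].
#' @param models Prediction-model table.
#' @param latent_model A [latent_model()] whose member structure defines
#'   the planted effects.
#' @param n_null_traits Number of genotype-independent traits.
#' @param effects Data frame with columns `trait`, `lv`, `h2` (variance
#'   explained by the module signal); may be empty.
#' @param top_gene_fraction Member-set rule used to pick the planted
#'   genes.
#' @param condition_threshold PC condition-number threshold.
#' @param seed Integer seed.
#' @return An object of class `twas_result_set`: `pvals` (trait-by-gene),
#'   `z_tissues` (named list of trait-by-gene per-tissue z matrices),
#'   `gene_meta` (`gene`, `k`, `p`), `signatures` (trait-by-gene mean z
#'   across tissues), `phenotypes` (centered individuals-by-trait matrix),
#'   `sample_size`, and the GWAS SNP list.
#' @export
generate_twas <- function(panel, models, latent_model, n_null_traits = 5,
                          effects = NULL, top_gene_fraction = 0.01,
                          condition_threshold = 30, seed = 1) {
  set.seed(seed)
  n <- nrow(panel$X)
  genes <- sort(unique(models$gene))
  pes <- lapply(genes, function(g) {
    reduce_pcs(predict_expression(panel, models, g),
               threshold = condition_threshold)
  })
  names(pes) <- genes
  tissues <- sort(unique(models$tissue))
  # phenotypes
  trait_ids <- sprintf("trait%02d", seq_len(n_null_traits +
                                              NROW(effects)))
  Y <- matrix(stats::rnorm(n * length(trait_ids)), n,
              dimnames = list(NULL, trait_ids))
  planted <- character(0)
  if (NROW(effects) > 0L) {
    for (i in seq_len(nrow(effects))) {
      tr <- effects$trait[i]
      planted <- c(planted, tr)
      mem <- intersect(top_lv_genes(latent_model, effects$lv[i],
                                    top_gene_fraction), genes)
      cg <- latent_model$Z[mem, effects$lv[i]]
      signal <- rowSums(vapply(seq_along(mem), function(j) {
        cg[j] * rowMeans(pes[[mem[j]]]$T)
      }, numeric(n)))
      signal <- as.numeric(scale(signal))
      h2 <- effects$h2[i]
      Y[, tr] <- sqrt(h2) * signal + sqrt(1 - h2) * stats::rnorm(n)
    }
  }
  Y <- sweep(Y, 2L, colMeans(Y))
  # GWAS summary statistics per trait (marginal per-SNP regressions)
  Xc <- sweep(panel$X, 2L, colMeans(panel$X))
  sxx <- colSums(Xc^2)
  XtY <- crossprod(Xc, Y)
  beta <- XtY / sxx
  yty <- colSums(Y^2)
  se <- sqrt(sweep(-beta^2 * sxx, 2L, yty, "+") / (n - 2) / sxx)
  # per-tissue summary z-scores and multi-tissue p-values
  z_tissues <- lapply(tissues, function(tis) {
    matrix(NA_real_, length(trait_ids), length(genes),
           dimnames = list(trait_ids, genes))
  })
  names(z_tissues) <- tissues
  pvals <- matrix(NA_real_, length(trait_ids), length(genes),
                  dimnames = list(trait_ids, genes))
  has_model <- with(unique(models[, c("gene", "tissue")]),
                    split(tissue, gene))
  for (tr in trait_ids) {
    gwas <- tibble::tibble(snp_id = panel$snp_ids,
                           beta = beta[, tr], se = se[, tr])
    for (g in genes) {
      for (tis in intersect(tissues, has_model[[g]])) {
        z_tissues[[tis]][tr, g] <- spredixcan_z(gwas, models, panel, g,
                                                tis)
      }
      pvals[tr, g] <- smultixcan_p(Y[, tr], pes[[g]])$p_value
    }
  }
  z_arr <- simplify2array(z_tissues)
  signatures <- apply(z_arr, c(1L, 2L), mean, na.rm = TRUE)
  # genes without a model in a tissue carry no evidence there: zero
  # z-score (the neutral value of the downstream dot products)
  z_tissues <- lapply(z_tissues, function(z) {
    z[is.na(z)] <- 0
    z
  })
  gene_meta <- tibble::tibble(
    gene = genes,
    k = vapply(pes, function(x) x$k, integer(1)),
    p = vapply(pes, function(x) x$p, integer(1)))
  structure(list(pvals = pvals, z_tissues = z_tissues,
                 gene_meta = gene_meta, signatures = signatures,
                 phenotypes = Y,
                 sample_size = stats::setNames(rep(n, length(trait_ids)),
                                               trait_ids),
                 gwas_snps = panel$snp_ids, planted_traits = planted,
                 seed = seed),
            class = "twas_result_set")
}

#' @export
print.twas_result_set <- function(x, ...) {
  cat("<twas_result_set> ", nrow(x$pvals), " traits x ", ncol(x$pvals),
      " genes, ", length(x$z_tissues), " tissue(s)\n", sep = "")
  invisible(x)
}

#' Generate compound perturbation profiles with a planted reversal
#'
#' The planted compound's gene profile is the negated disease signature
#' plus Gaussian noise; all other compounds are pure noise on the
#' signature's scale.
#'
#' @param signature Named numeric vector: the disease's gene-level signed
#'   z-scores.
#' @param n_compounds Total number of compounds.
#' @param noise_sd Noise standard deviation added to the planted reversal.
#' @param planted_compound Id of the reversal compound.
#' @param seed Integer seed.
#' @return A compound-by-gene matrix; the planted compound id is kept in
#'   the `"planted_compound"` attribute.
#' @export
generate_drug_profiles <- function(signature, n_compounds = 30,
                                   noise_sd = 1,
                                   planted_compound = "drug01", seed = 1) {
  stopifnot(!is.null(names(signature)), n_compounds >= 2L)
  set.seed(seed)
  m <- length(signature)
  ids <- sprintf("drug%02d", seq_len(n_compounds))
  L <- matrix(stats::rnorm(n_compounds * m, sd = stats::sd(signature)),
              n_compounds, m, dimnames = list(ids, names(signature)))
  if (!planted_compound %in% ids) stop("planted compound id out of range")
  L[planted_compound, ] <- -signature +
    stats::rnorm(m, sd = noise_sd)
  attr(L, "planted_compound") <- planted_compound
  L
}

#' Generate trait profiles with planted cluster structure
#'
#' Traits live in module space: every entry is standard Gaussian noise,
#' and each cluster elevates its own disjoint set of discriminative
#' modules by `separation` units, so clusters are separated along their
#' module subspace while all other modules are uninformative. With
#' `separation = 0` the data have no structure (the null configuration).
#'
#' @param latent_model A [latent_model()] providing the module ids.
#' @param n_traits Number of traits.
#' @param n_clusters Number of planted clusters (near-equal sizes).
#' @param lvs_per_cluster Discriminative modules per cluster.
#' @param separation Mean shift on the discriminative modules.
#' @param seed Integer seed.
#' @return A list: `mhat` (trait-by-module matrix) and `truth` (planted
#'   `labels` and per-cluster `lv_sets`).
#' @export
generate_trait_clusters <- function(latent_model, n_traits = 50,
                                    n_clusters = 3, lvs_per_cluster = 3,
                                    separation = 4, seed = 1) {
  lv_ids <- colnames(latent_model$Z)
  if (n_clusters * lvs_per_cluster > length(lv_ids)) {
    stop("not enough modules for the requested cluster structure")
  }
  set.seed(seed)
  traits <- sprintf("trait%03d", seq_len(n_traits))
  labels <- stats::setNames(rep_len(seq_len(n_clusters), n_traits),
                            traits)
  labels <- labels[order(names(labels))]
  mhat <- matrix(stats::rnorm(n_traits * length(lv_ids)), n_traits,
                 dimnames = list(traits, lv_ids))
  lv_sets <- lapply(seq_len(n_clusters), function(cl) {
    lv_ids[(cl - 1L) * lvs_per_cluster + seq_len(lvs_per_cluster)]
  })
  names(lv_sets) <- as.character(seq_len(n_clusters))
  for (cl in seq_len(n_clusters)) {
    mhat[labels == cl, lv_sets[[as.character(cl)]]] <-
      mhat[labels == cl, lv_sets[[as.character(cl)]]] + separation
  }
  list(mhat = mhat, truth = list(labels = labels, lv_sets = lv_sets))
}

#' Simulate a complete named study scenario
#'
#' Three pre-registered desk-scale study designs exercise the pipeline end
#' to end with planted ground truth:
#'
#' * **A** (regression calibration and power): 2000 individuals; the
#'   tested module's 80 member genes sit in 20 LD blocks of 4 genes
#'   (within-block latent correlation 0.9) while the 220 background genes
#'   occupy their own blocks, mirroring the genome-wide background of a
#'   competitive test; 5 null traits plus one trait loading on the module
#'   (h2 = 0.05).
#' * **B** (drug reversal): 1000 individuals, 100 genes in independent
#'   blocks, 30 modules; one trait loads on a planted module (h2 = 0.3)
#'   and one of 30 compounds carries the negated disease signature plus
#'   noise; a labelled gold standard accompanies the scores.
#' * **C** (trait clusters): 50 traits in module space with 3 planted
#'   clusters of 3 discriminative modules each (separation 4), plus a
#'   structureless null copy (`mhat_null`) for the no-structure control.
#'
#' @param scenario `"A"`, `"B"` or `"C"`.
#' @param seed Integer seed; all components derive from it.
#' @return A named list with the generated objects, the planted `truth`,
#'   and the scenario `config`.
#' @export
simulate_scenario <- function(scenario = c("A", "B", "C"), seed = 1) {
  scenario <- match.arg(scenario)
  if (scenario == "A") {
    panel <- generate_panel(
      n_individuals = 2000,
      block_sizes = c(rep(5L, 20), rep(3L, 220)),
      within_block_r = 0.9, maf_range = c(0.1, 0.4), seed = seed)
    gene_blocks <- c(rep(1:20, each = 4L), 21:240)
    models <- generate_models(panel, n_genes = 300, n_tissues = 3,
                              tissues_per_gene = c(1, 3),
                              snps_per_model = 3,
                              gene_blocks = gene_blocks, seed = seed + 1L)
    member_sets <- c(
      list(LV01 = sprintf("g%03d", 1:80)),
      stats::setNames(lapply(1:11, function(j) {
        sprintf("g%03d", 80 + (j - 1L) * 20 + 1:20)
      }), sprintf("LV%02d", 2:12)))
    lm_ <- generate_latent_model(member_sets = member_sets,
                                 gene_ids = sprintf("g%03d", 1:300),
                                 lambda2 = 1, seed = seed + 2L)
    effects <- tibble::tibble(trait = "trait06", lv = "LV01", h2 = 0.05)
    twas <- generate_twas(panel, models, lm_, n_null_traits = 5,
                          effects = effects, top_gene_fraction = 0.265,
                          seed = seed + 3L)
    list(panel = panel, models = models, latent_model = lm_, twas = twas,
         truth = list(planted_lv = "LV01", planted_trait = "trait06"),
         config = list(top_gene_fraction = 0.265, planted_lv = "LV01"))
  } else if (scenario == "B") {
    panel <- generate_panel(
      n_individuals = 1000, block_sizes = rep(3L, 100),
      within_block_r = 0.5, maf_range = c(0.1, 0.4), seed = seed)
    models <- generate_models(panel, n_genes = 100, n_tissues = 3,
                              tissues_per_gene = c(1, 3),
                              snps_per_model = 3,
                              gene_blocks = 1:100, seed = seed + 1L)
    lm_ <- generate_latent_model(n_genes = 100, n_lvs = 30,
                                 members_per_lv = 3, lambda2 = 1,
                                 seed = seed + 2L)
    effects <- tibble::tibble(trait = "trait10", lv = "LV05", h2 = 0.3)
    twas <- generate_twas(panel, models, lm_, n_null_traits = 9,
                          effects = effects, top_gene_fraction = 0.03,
                          seed = seed + 3L)
    signature <- twas$signatures["trait10", ]
    drugs <- generate_drug_profiles(signature, n_compounds = 30,
                                    noise_sd = 1,
                                    planted_compound = "drug01",
                                    seed = seed + 4L)
    set.seed(seed + 5L)
    neg <- tibble::tibble(
      compound = sample(rownames(drugs), 40, replace = TRUE),
      trait = sample(rownames(twas$pvals), 40, replace = TRUE))
    neg <- neg[!(neg$compound == "drug01" & neg$trait == "trait10"), ]
    neg <- neg[!duplicated(neg), ]
    gold <- dplyr::bind_rows(
      tibble::tibble(compound = "drug01", trait = "trait10",
                     indicated = TRUE),
      tibble::tibble(compound = neg$compound, trait = neg$trait,
                     indicated = FALSE))
    list(panel = panel, models = models, latent_model = lm_, twas = twas,
         drugs = drugs, gold = gold,
         truth = list(planted_lv = "LV05", planted_trait = "trait10",
                      planted_compound = "drug01"),
         config = list(top_gene_fraction = 0.03, planted_lv = "LV05"))
  } else {
    lm_ <- generate_latent_model(n_genes = 100, n_lvs = 30,
                                 members_per_lv = 3, lambda2 = 1,
                                 seed = seed)
    clus <- generate_trait_clusters(lm_, n_traits = 50, n_clusters = 3,
                                    lvs_per_cluster = 3, separation = 4,
                                    seed = seed + 1L)
    null <- generate_trait_clusters(lm_, n_traits = 50, n_clusters = 3,
                                    lvs_per_cluster = 3, separation = 0,
                                    seed = seed + 2L)
    list(latent_model = lm_, mhat = clus$mhat, mhat_null = null$mhat,
         truth = clus$truth,
         config = list(n_clusters = 3, separation = 4))
  }
}
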