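#' Plot module-trait association results
#'
#' Effect size against one-sided evidence for every (module, trait) pair,
#' with the FDR threshold highlighted.
#'
#' @param object An `lv_assoc` tibble from [regress_all()].
#' @param alpha FDR threshold to highlight.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lv_assoc <- function(object, alpha = 0.05, ...) {
  df <- tibble::as_tibble(object)
  df$significant <- df$fdr < alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta,
                                   y = -log10(.data$pval),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey50", `TRUE` = "firebrick"),
      name = paste0("FDR < ", alpha)) +
    ggplot2::labs(x = "member effect (beta_s)",
                  y = "-log10 one-sided p",
                  title = "Module-trait associations") +
    ggplot2::theme_minimal()
}

#' Plot consensus-solution agreement across resolutions
#'
#' Ensemble agreement (median adjusted Rand index) of the winning
#' consensus partition at each cluster count, with the 75th-percentile
#' retention threshold.
#'
#' @param object A `consensus_solutions` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.consensus_solutions <- function(object, ...) {
  df <- tibble::as_tibble(object[, c("k", "agreement")])
  cut <- stats::quantile(df$agreement, 0.75, names = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$agreement)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = cut, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "number of clusters k",
                  y = "ensemble agreement (median ARI)",
                  title = "Consensus solutions by resolution") +
    ggplot2::theme_minimal()
}

#' Plot the ROC curve of a drug-repurposing evaluation
#'
#' @param object A `drug_evaluation` from [evaluate_drug_scores()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drug_evaluation <- function(object, ...) {
  p <- object$pairs[order(-object$pairs$score), ]
  tpr <- cumsum(p$indicated) / sum(p$indicated)
  fpr <- cumsum(!p$indicated) / sum(!p$indicated)
  df <- tibble::tibble(fpr = c(0, fpr), tpr = c(0, tpr))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUROC = %.3f)",
                                  object$summary$auroc)) +
    ggplot2::theme_minimal()
}

#' Plot a cluster's discriminative-module report
#'
#' Root-split thresholds by iteration, against each module's
#' across-trait standard deviation (the selection bar).
#'
#' @param object A `cluster_lv_report` from [discriminative_lvs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_lv_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$lv <- factor(df$lv, levels = df$lv[order(df$iteration)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lv, y = .data$threshold,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_point(ggplot2::aes(y = .data$lv_sd), shape = 4) +
    ggplot2::scale_fill_manual(
      values = c(`FALSE` = "grey70", `TRUE` = "seagreen"),
      name = "selected") +
    ggplot2::labs(x = "module (root-split order)",
                  y = "root threshold (x = module sd)",
                  title = paste0("Discriminative modules, cluster ",
                                 attr(object, "cluster_id"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
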