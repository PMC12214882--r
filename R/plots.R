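#' Volcano plot of channel enrichment results
#'
#' Log2 fold change (HRD vs HRP group-mean proportions) against
#' -log10(FDR-adjusted p), with the assay's selection thresholds drawn and
#' selected channels colored by enrichment direction (red HRD, blue HRP).
#'
#' @param results Enrichment tibble from [channel_enrichment()]; if it lacks
#'   a `selected` column, [select_channels()] is applied with `assay`.
#' @param assay `"WGS"` or `"WES"` (sets the fold-change threshold line).
#' @param label_top Number of most significant selected channels to label.
#' @return A ggplot object, faceted by channel class.
#' @export
plot_volcano <- function(results, assay = c("WGS", "WES"), label_top = 8) {
  assay <- match.arg(assay)
  if (!"selected" %in% names(results)) {
    results <- select_channels(results, assay)
  }
  thr <- switch(assay, WGS = 0.75, WES = 0.25)
  dat <- dplyr::mutate(results,
    neg_log10_q = -log10(pmax(.data$q_value, 1e-300)),
    status = dplyr::case_when(
      .data$selected & .data$direction == "HRD" ~ "HRD-enriched",
      .data$selected & .data$direction == "HRP" ~ "HRP-enriched",
      TRUE ~ "not selected"))
  lab <- dat |>
    dplyr::filter(.data$selected) |>
    dplyr::slice_max(.data$neg_log10_q, n = label_top, with_ties = FALSE)
  ggplot2::ggplot(dat, ggplot2::aes(.data$log2_fc, .data$neg_log10_q)) +
    ggplot2::geom_hline(yintercept = 3, linetype = "dashed",
                        color = "grey60") +
    ggplot2::geom_vline(xintercept = c(-thr, thr), linetype = "dashed",
                        color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(color = .data$status), size = 1.5) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$channel),
                       size = 2.5, vjust = -0.6, check_overlap = TRUE) +
    ggplot2::scale_color_manual(values = c(
      "HRD-enriched" = "#c0392b", "HRP-enriched" = "#2980b9",
      "not selected" = "grey70")) +
    ggplot2::facet_wrap(~class, scales = "free") +
    ggplot2::labs(x = "log2 fold change (HRD / HRP mean proportion)",
                  y = "-log10(FDR-adjusted p)", color = NULL) +
    ggplot2::theme_minimal()
}

#' PCA of the six features, colored by label
#'
#' Projects samples onto the first two principal components of the z-scored
#' six-feature matrix; with informative features, HRD and HRP samples
#' separate along these components.
#'
#' @param features Feature tibble from [derive_features()].
#' @param labels Tibble with `sample_id`, `label`.
#' @return A ggplot object.
#' @export
plot_feature_pca <- function(features, labels) {
  dat <- dplyr::inner_join(features, labels[, c("sample_id", "label")],
                           by = "sample_id")
  x <- scale(as.matrix(dat[, hrd_feature_names()]))
  x[, attr(x, "scaled:scale") == 0] <- 0
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  var_expl <- round(100 * pc$sdev[1:2]^2 / sum(pc$sdev^2), 1)
  scores <- tibble::tibble(pc1 = pc$x[, 1], pc2 = pc$x[, 2],
                           label = dat$label)
  ggplot2::ggplot(scores, ggplot2::aes(.data$pc1, .data$pc2,
                                       color = .data$label)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_color_manual(values = c(HRD = "#c0392b",
                                           HRP = "#2980b9")) +
    ggplot2::labs(x = paste0("PC1 (", var_expl[1], "%)"),
                  y = paste0("PC2 (", var_expl[2], "%)"), color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot classifier feature weights
#'
#' Bar plot of the fitted linear-SVM weights (and mean cross-validation
#' weights) per feature; positive weights mark HRD-predictive features,
#' negative weights HRP-predictive ones.
#'
#' @param object An `hrd_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hrd_model
#' @export
autoplot.hrd_model <- function(object, ...) {
  dat <- tidy(object) |>
    tidyr::pivot_longer(c("estimate", "cv_estimate"),
                        names_to = "which", values_to = "weight") |>
    dplyr::mutate(
      which = dplyr::recode(.data$which, estimate = "final model",
                            cv_estimate = "mean of CV folds"),
      term = factor(.data$term, levels = rev(object$feature_order)))
  ggplot2::ggplot(dat, ggplot2::aes(.data$weight, .data$term,
                                    fill = .data$weight > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, color = "grey40") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b",
                                          `FALSE` = "#2980b9")) +
    ggplot2::facet_wrap(~which) +
    ggplot2::labs(x = "SVM weight (z-scored features)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
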