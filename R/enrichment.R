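#' Mean per-group channel proportion profiles
#'
#' Converts each sample's catalog to within-class proportions and averages
#' them within the HRD and HRP groups.
#'
#' @param catalogs Long catalog tibble from [build_catalogs()].
#' @param labels Tibble with columns `sample_id`, `label` ("HRD"/"HRP").
#' @return Tibble with columns `class`, `channel`, `mean_prop_hrd`,
#'   `mean_prop_hrp`.
#' @export
group_mean_profiles <- function(catalogs, labels) {
  check_labels(catalogs, labels)
  catalog_proportions(catalogs) |>
    dplyr::inner_join(labels[, c("sample_id", "label")], by = "sample_id") |>
    dplyr::group_by(.data$class, .data$channel, .data$label) |>
    dplyr::summarise(mean_prop = mean(.data$proportion), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "label", values_from = "mean_prop",
                       names_glue = "mean_prop_{tolower(label)}") |>
    dplyr::select("class", "channel", "mean_prop_hrd", "mean_prop_hrp")
}

check_labels <- function(catalogs, labels) {
  stopifnot(all(c("sample_id", "label") %in% names(labels)))
  if (!all(labels$label %in% c("HRD", "HRP"))) {
    stop("labels must be 'HRD' or 'HRP'", call. = FALSE)
  }
  present <- unique(catalogs$sample_id)
  labelled <- labels$sample_id[labels$sample_id %in% present]
  groups <- unique(labels$label[labels$sample_id %in% present])
  if (length(setdiff(c("HRD", "HRP"), groups)) > 0) {
    stop("both an HRD and an HRP group with at least one cataloged sample ",
         "are required", call. = FALSE)
  }
  if (length(setdiff(present, labelled)) > 0) {
    stop("sample(s) without a label: ",
         paste(utils::head(setdiff(present, labelled), 3), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-channel HRD vs HRP enrichment tests
#'
#' For each of the 96 + 83 + 48 channels, pools event counts within the HRD
#' and HRP groups and tests the 2x2 table (events in the channel vs all other
#' events of that channel class) with the two-sided Fisher exact test.
#' Fold changes are computed on group-mean proportions:
#' `log2_fc = log2(mean_prop_hrd / mean_prop_hrp)`, with a pseudo-proportion
#' epsilon guarding zero means. P values are Benjamini-Hochberg adjusted,
#' by default jointly across all channels of all three classes.
#'
#' @inheritParams group_mean_profiles
#' @param epsilon Pseudo-proportion added to zero group means before the
#'   fold change; default (`NULL`) is half the smallest nonzero group mean of
#'   the channel's class. Channels empty in both groups get `log2_fc = 0`,
#'   `p_value = 1`.
#' @param fdr_family `"joint"` (one BH family over all 227 channels, the
#'   default) or `"per_class"`.
#' @return Tibble with one row per channel: `class`, `channel`,
#'   `mean_prop_hrd`, `mean_prop_hrp`, `log2_fc`, `p_value`, `q_value`,
#'   `direction` ("HRD" if `log2_fc` > 0 else "HRP").
#' @export
channel_enrichment <- function(catalogs, labels, epsilon = NULL,
                               fdr_family = c("joint", "per_class")) {
  fdr_family <- match.arg(fdr_family)
  means <- group_mean_profiles(catalogs, labels)

  pooled <- catalogs |>
    dplyr::inner_join(labels[, c("sample_id", "label")], by = "sample_id") |>
    dplyr::group_by(.data$class, .data$channel, .data$label) |>
    dplyr::summarise(events = sum(.data$count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "label", values_from = "events",
                       values_fill = 0L) |>
    dplyr::group_by(.data$class) |>
    dplyr::mutate(rest_hrd = sum(.data$HRD) - .data$HRD,
                  rest_hrp = sum(.data$HRP) - .data$HRP) |>
    dplyr::ungroup()

  res <- means |>
    dplyr::inner_join(pooled, by = c("class", "channel")) |>
    dplyr::group_by(.data$class) |>
    dplyr::mutate(eps = {
      nz <- c(.data$mean_prop_hrd[.data$mean_prop_hrd > 0],
              .data$mean_prop_hrp[.data$mean_prop_hrp > 0])
      if (!is.null(epsilon)) epsilon
      else if (length(nz) > 0) min(nz) / 2
      else 1  # class empty in both groups; fold changes are zeroed anyway
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      empty = .data$HRD + .data$HRP == 0,
      p_value = purrr::pmap_dbl(
        list(.data$HRD, .data$rest_hrd, .data$HRP, .data$rest_hrp,
             .data$empty),
        function(a, b, c, d, empty) {
          if (empty) return(1)
          stats::fisher.test(matrix(c(a, b, c, d), nrow = 2,
                                    byrow = TRUE))$p.value
        }),
      log2_fc = ifelse(
        .data$empty, 0,
        log2(pmax(.data$mean_prop_hrd, .data$eps) /
               pmax(.data$mean_prop_hrp, .data$eps)))
    )

  res <- if (fdr_family == "joint") {
    dplyr::mutate(res, q_value = stats::p.adjust(.data$p_value, "BH"))
  } else {
    res |>
      dplyr::group_by(.data$class) |>
      dplyr::mutate(q_value = stats::p.adjust(.data$p_value, "BH")) |>
      dplyr::ungroup()
  }
  res |>
    dplyr::mutate(direction = ifelse(.data$log2_fc > 0, "HRD", "HRP")) |>
    dplyr::select("class", "channel", "mean_prop_hrd", "mean_prop_hrp",
                  "log2_fc", "p_value", "q_value", "direction")
}

#' Select significantly enriched channels
#'
#' Volcano-style selection: a channel is selected when its absolute
#' log2 fold change exceeds the assay threshold (0.75 for WGS, 0.25 for WES)
#' and its -log10(BH-adjusted p value) exceeds 3.
#'
#' @param results Enrichment tibble from [channel_enrichment()].
#' @param assay `"WGS"` or `"WES"`.
#' @param log2fc_threshold,neg_log10_fdr Override the selection thresholds;
#'   defaults follow the assay.
#' @return The input tibble with a logical `selected` column.
#' @export
select_channels <- function(results, assay = c("WGS", "WES"),
                            log2fc_threshold = NULL, neg_log10_fdr = 3) {
  assay <- match.arg(assay)
  thr <- log2fc_threshold %||% switch(assay, WGS = 0.75, WES = 0.25)
  dplyr::mutate(results,
    selected = abs(.data$log2_fc) > thr &
      -log10(.data$q_value) > neg_log10_fdr)
}

#' Consensus channel sets across assays
#'
#' Intersects the selected channels of a WGS and a WES selection per
#' enrichment direction: only channels significantly enriched in both assays
#' are kept.
#'
#' @param wgs_selection,wes_selection Tibbles from [select_channels()].
#' @return List with character vectors `hrd_enriched` and `hrp_enriched`.
#' @export
intersect_assays <- function(wgs_selection, wes_selection) {
  pick <- function(sel, dir) {
    sel$channel[sel$selected & sel$direction == dir]
  }
  list(
    hrd_enriched = intersect(pick(wgs_selection, "HRD"),
                             pick(wes_selection, "HRD")),
    hrp_enriched = intersect(pick(wgs_selection, "HRP"),
                             pick(wes_selection, "HRP"))
  )
}
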