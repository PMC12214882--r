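#' Derive the six HRD features from channel catalogs
#'
#' Collapses each sample's SBS-96/ID-83/CN-48 catalog into the six genomic
#' features used by the classifier, in fixed order:
#' \enumerate{
#'   \item `n_ct_g` — proportion of substitutions that are C>T at NpCpG;
#'   \item `n_cg_t` — proportion of substitutions that are C>G at NpCpT;
#'   \item `del5_mh` — deletions >= 5 bp at microhomology (`5:Del:M:1..5`),
#'     an absolute count by default, or a proportion of all indels;
#'   \item `loh_1_40` — proportion of segments that are LOH of 1-40 Mb;
#'   \item `het3_9_10_40` — proportion of segments that are heterozygous,
#'     10-40 Mb, with total copy number >= 3;
#'   \item `het2_4_gt40` — proportion of segments that are heterozygous,
#'     > 40 Mb, with total copy number 2-4.
#' }
#' Samples with no events of a class get 0 for that class's features and are
#' flagged low-confidence with a warning.
#'
#' @param catalogs Long catalog tibble from [build_catalogs()].
#' @param assay `"WGS"` or `"WES"`; recorded on the output and checked
#'   against the model at prediction time.
#' @param del5mh_as_count If TRUE (default, matching the trained-model
#'   convention for both assays), `del5_mh` is the raw count; otherwise the
#'   proportion of all classified indels.
#' @return Tibble with columns `sample_id`, the six features in the order
#'   above, `assay`, and `low_confidence` (TRUE when any channel class had
#'   zero events).
#' @examples
#' muts <- tibble::tibble(sample_id = "s1", chromosome = "1",
#'                        position = c(1e6, 2e6), ref = "C", alt = c("T", "G"),
#'                        context5 = "A", context3 = c("G", "T"))
#' derive_features(build_catalogs(mutations = muts), assay = "WGS")
#' @export
derive_features <- function(catalogs, assay = c("WGS", "WES"),
                            del5mh_as_count = TRUE) {
  assay <- match.arg(assay)
  stopifnot(all(c("sample_id", "class", "channel", "count") %in%
                  names(catalogs)))
  map <- channel_feature_map()

  totals <- catalogs |>
    dplyr::group_by(.data$sample_id, .data$class) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")

  grouped <- catalogs |>
    dplyr::inner_join(map, by = c("class", "channel")) |>
    dplyr::group_by(.data$sample_id, .data$class, .data$feature) |>
    dplyr::summarise(events = sum(.data$count), .groups = "drop") |>
    dplyr::left_join(totals, by = c("sample_id", "class")) |>
    dplyr::mutate(value = dplyr::case_when(
      .data$feature == "del5_mh" & del5mh_as_count ~ as.numeric(.data$events),
      .data$total > 0 ~ .data$events / .data$total,
      TRUE ~ 0
    ))

  features <- grouped |>
    dplyr::select("sample_id", "feature", "value") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "value") |>
    dplyr::select("sample_id", dplyr::all_of(hrd_feature_names()))

  flags <- totals |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(low_confidence = any(.data$total == 0),
                     .groups = "drop")
  if (any(flags$low_confidence)) {
    warning(sum(flags$low_confidence), " sample(s) had zero events in at ",
            "least one channel class; their proportion features default to ",
            "0 and they are flagged low_confidence", call. = FALSE)
  }
  features |>
    dplyr::mutate(assay = assay) |>
    dplyr::left_join(flags, by = "sample_id") |>
    dplyr::arrange(match(.data$sample_id, unique(catalogs$sample_id)))
}

#' Write / read the six-feature table TSV
#'
#' Column order is the model contract: `sample`, the six features in
#' [hrd_feature_names()] order, `assay`.
#'
#' @param features Feature tibble from [derive_features()].
#' @param path File path.
#' @return `write_feature_tsv()` returns `path` invisibly;
#'   `read_feature_tsv()` returns the feature tibble.
#' @export
write_feature_tsv <- function(features, path) {
  out <- features[, c("sample_id", hrd_feature_names(), "assay")]
  names(out)[1] <- "sample"
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("sample", hrd_feature_names(), "assay")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("feature table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- raw[, required]
  names(out)[1] <- "sample_id"
  tibble::as_tibble(out)
}
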