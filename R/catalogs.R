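#' Build per-sample mutational channel catalogs
#'
#' Classifies somatic substitutions, indels and allele-specific copy-number
#' segments into the SBS-96, ID-83 and CN-48 channels and tallies them per
#' sample. Every sample present in any input appears once per channel;
#' channels with no events have count 0. Mitochondrial records are dropped
#' with a warning; sex chromosomes are processed like autosomes.
#'
#' @param mutations Tibble of substitutions with columns `sample_id`,
#'   `chromosome`, `position`, `ref`, `alt`, `context5`, `context3`, or NULL.
#' @param indels Tibble with columns `sample_id`, `chromosome`, `position`,
#'   `kind` ("insertion"/"deletion"), `sequence`, `flank5`, `flank3`, or NULL.
#' @param segments Tibble with columns `sample_id`, `chromosome`, `start`,
#'   `end`, `major_cn`, `minor_cn`, or NULL.
#' @param coord_convention Segment coordinate convention: `"inclusive"`
#'   (1-based inclusive, ASCAT-style; size = end - start + 1, the default) or
#'   `"half_open"` (size = end - start).
#' @return A long tibble with columns `sample_id`, `class` (SBS96/ID83/CN48),
#'   `channel` and `count`, 227 rows per sample in canonical channel order.
#'   Returns a zero-row tibble when all inputs are NULL or empty.
#' @examples
#' muts <- tibble::tibble(sample_id = "s1", chromosome = "1", position = 100,
#'                        ref = "C", alt = "T", context5 = "A", context3 = "G")
#' cat <- build_catalogs(mutations = muts)
#' cat[cat$count > 0, ]
#' @export
build_catalogs <- function(mutations = NULL, indels = NULL, segments = NULL,
                           coord_convention = c("inclusive", "half_open")) {
  coord_convention <- match.arg(coord_convention)
  mutations <- drop_mitochondrial(mutations, "mutations")
  indels <- drop_mitochondrial(indels, "indels")
  segments <- drop_mitochondrial(segments, "segments")

  samples <- unique(c(
    if (!is.null(mutations)) as.character(mutations$sample_id),
    if (!is.null(indels)) as.character(indels$sample_id),
    if (!is.null(segments)) as.character(segments$sample_id)
  ))
  if (length(samples) == 0) {
    return(tibble::tibble(sample_id = character(), class = character(),
                          channel = character(), count = integer()))
  }

  tally <- function(sample_id, channel, class) {
    tibble::tibble(sample_id = as.character(sample_id), channel = channel) |>
      dplyr::count(.data$sample_id, .data$channel, name = "count") |>
      dplyr::mutate(class = class)
  }

  observed <- list()
  if (!is.null(mutations) && nrow(mutations) > 0) {
    observed$sbs <- tally(
      mutations$sample_id,
      classify_sbs(mutations$ref, mutations$alt,
                   mutations$context5, mutations$context3),
      "SBS96")
  }
  if (!is.null(indels) && nrow(indels) > 0) {
    observed$id <- tally(
      indels$sample_id,
      classify_indel(indels$kind, indels$sequence,
                     indels$flank5, indels$flank3),
      "ID83")
  }
  if (!is.null(segments) && nrow(segments) > 0) {
    size <- segments$end - segments$start +
      if (coord_convention == "inclusive") 1L else 0L
    observed$cn <- tally(
      segments$sample_id,
      classify_cn_segment(segments$major_cn, segments$minor_cn, size),
      "CN48")
  }

  skeleton <- tidyr::expand_grid(
    sample_id = samples,
    dplyr::bind_rows(
      tibble::tibble(class = "SBS96", channel = sbs96_channels()),
      tibble::tibble(class = "ID83", channel = id83_channels()),
      tibble::tibble(class = "CN48", channel = cn48_channels())
    )
  )
  skeleton |>
    dplyr::left_join(dplyr::bind_rows(observed),
                     by = c("sample_id", "class", "channel")) |>
    dplyr::mutate(count = as.integer(tidyr::replace_na(.data$count, 0L)))
}

drop_mitochondrial <- function(tbl, what) {
  if (is.null(tbl) || nrow(tbl) == 0 || !"chromosome" %in% names(tbl)) {
    return(tbl)
  }
  mito <- normalize_chromosomes(tbl$chromosome) == "MT"
  if (any(mito)) {
    warning("dropping ", sum(mito), " mitochondrial ", what,
            " record(s); the channel schemas cover nuclear DNA only",
            call. = FALSE)
    tbl <- tbl[!mito, , drop = FALSE]
  }
  tbl
}

#' Convert catalog counts to within-class proportions
#'
#' Each sample's counts are divided by the sample's total event count for
#' that channel class. Samples with zero events of a class get proportion 0
#' for all its channels.
#'
#' @param catalogs Long catalog tibble from [build_catalogs()].
#' @return The input tibble with an added `proportion` column.
#' @export
catalog_proportions <- function(catalogs) {
  catalogs |>
    dplyr::group_by(.data$sample_id, .data$class) |>
    dplyr::mutate(
      proportion = if (sum(.data$count) > 0) {
        .data$count / sum(.data$count)
      } else {
        rep(0, dplyr::n())
      }) |>
    dplyr::ungroup()
}

#' Write / read channel catalogs as channels-by-samples TSV
#'
#' One row per channel in canonical schema order (96 SBS, then 83 ID, then
#' 48 CN), one column per sample, with leading `class` and `channel` columns.
#'
#' @param catalogs Long catalog tibble from [build_catalogs()].
#' @param path File path.
#' @return `write_catalog_tsv()` returns `path` invisibly;
#'   `read_catalog_tsv()` returns the long catalog tibble.
#' @export
write_catalog_tsv <- function(catalogs, path) {
  wide <- catalogs |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count")
  order_key <- c(paste0("SBS96:", sbs96_channels()),
                 paste0("ID83:", id83_channels()),
                 paste0("CN48:", cn48_channels()))
  wide <- wide[order(match(paste0(wide$class, ":", wide$channel), order_key)), ]
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @rdname write_catalog_tsv
#' @export
read_catalog_tsv <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  wide |>
    tidyr::pivot_longer(-c("class", "channel"),
                        names_to = "sample_id", values_to = "count") |>
    dplyr::mutate(count = as.integer(.data$count)) |>
    dplyr::select("sample_id", "class", "channel", "count") |>
    dplyr::arrange(match(.data$sample_id, unique(.data$sample_id)))
}
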