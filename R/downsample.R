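## WGS -> WES downsampling: restrict events to exome capture targets.
## Targets are 0-based half-open (BED convention); mutation positions are
## 1-based, so position p occupies target space [p-1, p).

#' Sort and merge target intervals
#'
#' Normalizes chromosome names, sorts, and merges overlapping or bookended
#' intervals so the target set is canonical and idempotent under re-merging.
#'
#' @param targets Tibble with columns `chromosome`, `start`, `end` (0-based
#'   half-open).
#' @return Merged tibble, sorted by chromosome and start.
#' @export
merge_intervals <- function(targets) {
  stopifnot(all(c("chromosome", "start", "end") %in% names(targets)))
  if (any(targets$end <= targets$start)) {
    stop("target interval ", which(targets$end <= targets$start)[1],
         " has end <= start", call. = FALSE)
  }
  targets |>
    dplyr::mutate(chromosome = normalize_chromosomes(.data$chromosome)) |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::group_modify(function(d, key) {
      ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L,
                                             end = d$end))
      tibble::tibble(start = IRanges::start(ir) - 1L,
                     end = IRanges::end(ir))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chromosome, .data$start)
}

overlaps_targets <- function(chromosome, first, last, targets) {
  targets <- merge_intervals(targets)
  chromosome <- normalize_chromosomes(chromosome)
  hit <- logical(length(chromosome))
  for (chr in unique(chromosome)) {
    sel <- chromosome == chr
    tchr <- targets[targets$chromosome == chr, ]
    if (nrow(tchr) == 0) next
    q <- IRanges::IRanges(start = first[sel], end = last[sel])
    s <- IRanges::IRanges(start = tchr$start + 1L, end = tchr$end)
    hit[sel] <- IRanges::countOverlaps(q, s) > 0
  }
  hit
}

#' Restrict mutation or indel records to exome targets
#'
#' Keeps a substitution iff its position falls in a target interval; keeps a
#' deletion iff any deleted base overlaps a target; insertions are kept iff
#' the insertion point does. Chromosome-name dialects ("chr1" vs "1") are
#' normalized on both sides.
#'
#' @param records Mutation or indel tibble (see [build_catalogs()] for the
#'   expected columns); `position` is 1-based.
#' @param targets Target interval tibble (0-based half-open), e.g. from
#'   [read_bed()].
#' @return The subset of `records` overlapping the targets, unchanged.
#' @export
restrict_mutations <- function(records, targets) {
  if (is.null(records) || nrow(records) == 0) return(records)
  width <- if ("kind" %in% names(records)) {
    ifelse(records$kind == "deletion", nchar(records$sequence), 1L)
  } else {
    1L
  }
  keep <- overlaps_targets(records$chromosome, records$position,
                           records$position + width - 1L, targets)
  records[keep, , drop = FALSE]
}

#' Restrict copy-number segments to exome targets
#'
#' Keeps a segment — with its original coordinates, size and copy numbers —
#' iff it overlaps at least one target base, emulating exome-derived
#' segmentation in which only segments spanning captured regions are
#' observable. Segment size bins therefore still reflect genomic extent.
#'
#' @param segments Segment tibble (1-based inclusive coordinates).
#' @param targets Target interval tibble (0-based half-open).
#' @return The subset of `segments` overlapping the targets, unchanged.
#' @export
restrict_segments <- function(segments, targets) {
  if (is.null(segments) || nrow(segments) == 0) return(segments)
  keep <- overlaps_targets(segments$chromosome, segments$start,
                           segments$end, targets)
  segments[keep, , drop = FALSE]
}

#' Downsample a whole cohort to exome resolution
#'
#' Applies [restrict_mutations()] to substitutions and indels and
#' [restrict_segments()] to copy-number segments, returning a cohort list of
#' the same shape with `assay` set to "WES".
#'
#' @param cohort List with elements `mutations`, `indels`, `segments` (any
#'   may be NULL) as produced by [simulate_cohort()].
#' @param targets Target interval tibble (0-based half-open).
#' @return The downsampled cohort list.
#' @export
downsample_cohort <- function(cohort, targets) {
  cohort$mutations <- restrict_mutations(cohort$mutations, targets)
  cohort$indels <- restrict_mutations(cohort$indels, targets)
  cohort$segments <- restrict_segments(cohort$segments, targets)
  cohort$assay <- "WES"
  cohort
}
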