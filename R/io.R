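## File dialects.
##
## Mutation TSV: sample, chrom, pos, ref, alt, flank5, flank3 (header
## required; ref/alt are VCF-style allele strings so indels are representable
## without a reference genome). Segment TSV: sample, chrom, start, end,
## major_cn, minor_cn (ASCAT-style, 1-based inclusive by default). BED:
## 0-based half-open, no header.

#' Read a somatic mutation table
#'
#' Reads the tab-separated mutation dialect (columns `sample`, `chrom`,
#' `pos`, `ref`, `alt`, `flank5`, `flank3`) and splits records into
#' substitutions and simple indels. VCF-style alleles are used: an indel
#' carries the shared anchor base (e.g. ref "ATT", alt "A" for a 2 bp
#' deletion). Complex indels (both inserted and deleted bases after trimming
#' the shared prefix) are not covered by the ID-83 schema and are dropped
#' with a warning. Multi-base substitutions (MNVs) are likewise dropped.
#'
#' @param path Path to the mutation TSV.
#' @return List with tibbles `mutations` (sample_id, chromosome, position,
#'   ref, alt, context5, context3) and `indels` (sample_id, chromosome,
#'   position, kind, sequence, flank5, flank3). Indel `position` is the first
#'   inserted/deleted base.
#' @export
read_mutation_tsv <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           sample = "c", chrom = "c", pos = "d",
                           ref = "c", alt = "c",
                           flank5 = "c", flank3 = "c"))
  required <- c("sample", "chrom", "pos", "ref", "alt", "flank5", "flank3")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("mutation table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  split_mutation_records(raw)
}

split_mutation_records <- function(raw) {
  nr <- nchar(raw$ref)
  na <- nchar(raw$alt)
  is_snv <- nr == 1 & na == 1
  is_del <- nr > 1 & na == 1 & substr(raw$ref, 1, 1) == raw$alt
  is_ins <- na > 1 & nr == 1 & substr(raw$alt, 1, 1) == raw$ref
  complex <- !(is_snv | is_del | is_ins)
  if (any(complex)) {
    warning("dropping ", sum(complex),
            " complex or multi-nucleotide record(s) not covered by the ",
            "SBS-96/ID-83 schemas", call. = FALSE)
  }

  mutations <- tibble::tibble(
    sample_id = raw$sample[is_snv],
    chromosome = normalize_chromosomes(raw$chrom[is_snv]),
    position = as.integer(raw$pos[is_snv]),
    ref = raw$ref[is_snv],
    alt = raw$alt[is_snv],
    context5 = substr(raw$flank5[is_snv], nchar(raw$flank5[is_snv]),
                      nchar(raw$flank5[is_snv])),
    context3 = substr(raw$flank3[is_snv], 1, 1)
  )

  del <- raw[is_del, , drop = FALSE]
  ins <- raw[is_ins, , drop = FALSE]
  indels <- dplyr::bind_rows(
    tibble::tibble(
      sample_id = del$sample,
      chromosome = normalize_chromosomes(del$chrom),
      position = as.integer(del$pos) + 1L,
      kind = "deletion",
      sequence = substr(del$ref, 2, nchar(del$ref)),
      ## the anchor base precedes the deleted bases: it belongs to the 5' flank
      flank5 = paste0(del$flank5, substr(del$ref, 1, 1)),
      flank3 = del$flank3
    ),
    tibble::tibble(
      sample_id = ins$sample,
      chromosome = normalize_chromosomes(ins$chrom),
      position = as.integer(ins$pos) + 1L,
      kind = "insertion",
      sequence = substr(ins$alt, 2, nchar(ins$alt)),
      flank5 = paste0(ins$flank5, substr(ins$alt, 1, 1)),
      flank3 = ins$flank3
    )
  )
  list(mutations = mutations, indels = indels)
}

#' Write mutation records back to the mutation TSV dialect
#'
#' Inverse of [read_mutation_tsv()]: re-encodes substitution and indel
#' tibbles as one VCF-style allele table.
#'
#' @param mutations,indels Tibbles as returned by [read_mutation_tsv()];
#'   either may be NULL.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mutation_tsv <- function(mutations = NULL, indels = NULL, path) {
  rows <- list()
  if (!is.null(mutations) && nrow(mutations) > 0) {
    rows$snv <- tibble::tibble(
      sample = mutations$sample_id, chrom = mutations$chromosome,
      pos = mutations$position, ref = mutations$ref, alt = mutations$alt,
      flank5 = mutations$context5, flank3 = mutations$context3)
  }
  if (!is.null(indels) && nrow(indels) > 0) {
    anchor <- substr(indels$flank5, nchar(indels$flank5),
                     nchar(indels$flank5))
    is_del <- indels$kind == "deletion"
    rows$indel <- tibble::tibble(
      sample = indels$sample_id, chrom = indels$chromosome,
      pos = indels$position - 1L,
      ref = ifelse(is_del, paste0(anchor, indels$sequence), anchor),
      alt = ifelse(is_del, anchor, paste0(anchor, indels$sequence)),
      flank5 = substr(indels$flank5, 1, nchar(indels$flank5) - 1L),
      flank3 = indels$flank3)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(sample = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character(), flank5 = character(),
                          flank3 = character())
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read an ASCAT-style allele-specific segment table
#'
#' Expects a header with columns `sample`, `chrom`, `start`, `end`,
#' `major_cn`, `minor_cn`. Coordinates are 1-based inclusive by default.
#'
#' @param path Path to the segment TSV.
#' @param coord_convention `"inclusive"` (default) or `"half_open"`;
#'   half-open inputs are converted to 1-based inclusive on read.
#' @return Tibble with columns `sample_id`, `chromosome`, `start`, `end`,
#'   `major_cn`, `minor_cn` (1-based inclusive).
#' @export
read_segment_tsv <- function(path,
                             coord_convention = c("inclusive", "half_open")) {
  coord_convention <- match.arg(coord_convention)
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("sample", "chrom", "start", "end", "major_cn", "minor_cn")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("segment table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    sample_id = as.character(raw$sample),
    chromosome = normalize_chromosomes(raw$chrom),
    start = as.integer(raw$start),
    end = as.integer(raw$end),
    major_cn = as.integer(raw$major_cn),
    minor_cn = as.integer(raw$minor_cn)
  )
  if (coord_convention == "half_open") {
    out$start <- out$start + 1L  # 0-based half-open -> 1-based inclusive
  }
  bad <- out$end < out$start
  if (any(bad)) {
    stop("segment ", which(bad)[1], " has end < start", call. = FALSE)
  }
  out
}

#' Write segments in the ASCAT-style TSV dialect
#'
#' @param segments Segment tibble (1-based inclusive).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_segment_tsv <- function(segments, path) {
  readr::write_tsv(tibble::tibble(
    sample = segments$sample_id, chrom = segments$chromosome,
    start = segments$start, end = segments$end,
    major_cn = segments$major_cn, minor_cn = segments$minor_cn), path)
  invisible(path)
}

#' Read exome target intervals from BED
#'
#' BED is 0-based half-open with no header; only the first three columns are
#' used. Chromosome names are normalized and intervals are sorted and merged
#' so the result is a canonical interval set.
#'
#' @param path Path to the BED file.
#' @return Tibble with columns `chromosome`, `start`, `end` (0-based
#'   half-open, sorted, non-overlapping).
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) == 0 || any(lengths(fields) < 3)) {
    stop("BED file ", path, " needs at least 3 tab-separated columns",
         call. = FALSE)
  }
  merge_intervals(tibble::tibble(
    chromosome = normalize_chromosomes(vapply(fields, `[[`, "", 1)),
    start = as.integer(vapply(fields, `[[`, "", 2)),
    end = as.integer(vapply(fields, `[[`, "", 3))
  ))
}

#' Write target intervals as BED
#'
#' @param targets Interval tibble (`chromosome`, `start`, `end`, 0-based
#'   half-open).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(targets, path) {
  readr::write_tsv(targets[, c("chromosome", "start", "end")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read somatic mutations from a VCF
#'
#' Thin VCF 4.x reader for single-sample or per-record sample annotation.
#' Flanking context is taken from a FASTA reference when provided; without a
#' reference the TSV dialect ([read_mutation_tsv()]), which carries flanks on
#' each record, must be used instead.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF.
#' @param fasta Optional path to the reference FASTA providing flanks.
#' @param sample_id Sample name to assign; defaults to the VCF file stem.
#' @param flank_width Flank width in bp to extract from the reference.
#' @return As [read_mutation_tsv()]: list of `mutations` and `indels`.
#' @export
read_vcf_mutations <- function(path, fasta = NULL, sample_id = NULL,
                               flank_width = 30L) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package; alternatively supply the ",
         "mutation TSV dialect which carries flanks on each record",
         call. = FALSE)
  }
  if (is.null(fasta)) {
    stop("a reference FASTA is required to derive flanking context from a ",
         "VCF; without one, use the mutation TSV dialect", call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  sample_id <- sample_id %||% sub("\\.vcf(\\.gz)?$", "", basename(path))

  seqs <- read_fasta_seqs(fasta)
  chrom <- normalize_chromosomes(fix$CHROM)
  pos <- as.integer(fix$POS)
  keep <- chrom %in% names(seqs)
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " VCF record(s) on contigs absent ",
            "from the reference FASTA", call. = FALSE)
  }
  ref_len <- nchar(fix$REF)
  f5 <- unname(substr(seqs[chrom], pmax(1L, pos - flank_width), pos - 1L))
  f3 <- unname(substr(seqs[chrom], pos + ref_len,
                      pos + ref_len + flank_width - 1L))
  split_mutation_records(tibble::tibble(
    sample = sample_id, chrom = chrom, pos = pos,
    ref = fix$REF, alt = fix$ALT, flank5 = f5, flank3 = f3)[keep, ])
}

read_fasta_seqs <- function(path) {
  lines <- readr::read_lines(path)
  headers <- grepl("^>", lines)
  id <- cumsum(headers)
  names <- sub("^>\\s*(\\S+).*$", "\\1", lines[headers])
  seqs <- vapply(split(lines[!headers], id[!headers]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  names(seqs) <- normalize_chromosomes(names)
  seqs
}
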