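#' Classify allele-specific copy-number segments into CN-48 channels
#'
#' Assigns each segment to one of the 48 canonical copy-number channels
#' defined by zygosity, total copy number (TCN) class and segment size.
#' Zygosity: homozygous deletion (TCN 0), LOH (minor copy number 0 with at
#' least one retained copy) or heterozygous (minor >= 1). TCN classes:
#' 1, 2, 3-4, 5-8, 9+ (LOH) and 2, 3-4, 5-8, 9+ (heterozygous). Size bins are
#' left-open/right-closed — (0,100kb], (100kb,1Mb], (1,10Mb], (10,40Mb],
#' (40Mb, Inf) — so a segment of exactly 40 Mb falls in 10-40Mb. Homozygous
#' deletions use the reduced bins (0,100kb], (100kb,1Mb], (1Mb, Inf).
#'
#' @param major_cn,minor_cn Major and minor allele copy numbers
#'   (non-negative integers, `major_cn >= minor_cn`).
#' @param size_bp Segment size in base pairs. For the default 1-based
#'   inclusive segment coordinates this is `end - start + 1`.
#' @return Character vector of CN-48 channel names, e.g. `"2:LOH:10-40Mb"`.
#' @examples
#' classify_cn_segment(2, 0, 20e6)  # "2:LOH:10-40Mb"
#' classify_cn_segment(1, 1, 50e6)  # "2:HET:>40Mb"
#' @export
classify_cn_segment <- function(major_cn, minor_cn, size_bp) {
  n <- length(major_cn)
  stopifnot(length(minor_cn) == n, length(size_bp) == n)
  if (any(major_cn < 0 | minor_cn < 0)) {
    stop("negative copy numbers in segment ",
         which(major_cn < 0 | minor_cn < 0)[1], call. = FALSE)
  }
  if (any(minor_cn > major_cn)) {
    stop("minor_cn exceeds major_cn in segment ",
         which(minor_cn > major_cn)[1],
         " (allele-specific calls must satisfy major >= minor)",
         call. = FALSE)
  }
  if (any(size_bp <= 0)) {
    stop("non-positive segment size in segment ", which(size_bp <= 0)[1],
         call. = FALSE)
  }
  tcn <- major_cn + minor_cn
  tcn_class <- dplyr::case_when(
    tcn == 0 ~ "0",
    tcn == 1 ~ "1",
    tcn == 2 ~ "2",
    tcn <= 4 ~ "3-4",
    tcn <= 8 ~ "5-8",
    TRUE ~ "9+"
  )
  zygosity <- dplyr::case_when(
    tcn == 0 ~ "HomDel",
    minor_cn == 0 ~ "LOH",
    TRUE ~ "HET"
  )
  size_bin <- ifelse(
    zygosity == "HomDel",
    as.character(cut(size_bp, c(0, 1e5, 1e6, Inf), CN_HOMDEL_BINS)),
    as.character(cut(size_bp, c(0, 1e5, 1e6, 1e7, 4e7, Inf), CN_SIZE_BINS))
  )
  paste0(tcn_class, ":", zygosity, ":", size_bin)
}
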