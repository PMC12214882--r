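## Canonical channel vocabularies.
##
## The three schemas are the field-standard classifications used by mutational
## signature analysis: 96 pyrimidine-centric trinucleotide substitution
## channels, 83 insertion/deletion channels stratified by length, repeat
## context and microhomology, and 48 allele-specific copy-number channels
## stratified by zygosity, total copy number (TCN) class and segment size.
## Channel ordering below is the package's canonical (bit-exact) output order.

SBS_SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

CN_SIZE_BINS <- c("0-100kb", "100kb-1Mb", "1-10Mb", "10-40Mb", ">40Mb")
CN_HOMDEL_BINS <- c("0-100kb", "100kb-1Mb", ">1Mb")
CN_TCN_LOH <- c("1", "2", "3-4", "5-8", "9+")
CN_TCN_HET <- c("2", "3-4", "5-8", "9+")

#' Canonical SBS-96 channel names
#'
#' Substitution-major ordering (C>A, C>G, C>T, T>A, T>C, T>G), then 5' base
#' A/C/G/T, then 3' base A/C/G/T, e.g. `"A[C>T]G"`.
#'
#' @return Character vector of 96 channel names in canonical order.
#' @export
sbs96_channels <- function() {
  unlist(lapply(SBS_SUBSTITUTIONS, function(s)
    unlist(lapply(BASES, function(b5) paste0(b5, "[", s, "]", BASES)))),
    use.names = FALSE)
}

#' Canonical ID-83 channel names
#'
#' The standard 83-channel indel classification: 1 bp deletions/insertions in
#' C or T homopolymer context (`1:Del:T:4`), longer events by adjacent
#' whole-motif repeat count (`3:Del:R:0`), and deletions at microhomology
#' (`5:Del:M:3`). The trailing integer counts additional adjacent copies
#' (repeat channels) or microhomology length in bp (M channels), capped at 5.
#'
#' @return Character vector of 83 channel names in canonical order.
#' @export
id83_channels <- function() {
  c(
    paste0("1:Del:C:", 0:5), paste0("1:Del:T:", 0:5),
    paste0("1:Ins:C:", 0:5), paste0("1:Ins:T:", 0:5),
    unlist(lapply(2:5, function(L) paste0(L, ":Del:R:", 0:5))),
    unlist(lapply(2:5, function(L) paste0(L, ":Ins:R:", 0:5))),
    "2:Del:M:1",
    paste0("3:Del:M:", 1:2),
    paste0("4:Del:M:", 1:3),
    paste0("5:Del:M:", 1:5)
  )
}

#' Canonical CN-48 channel names
#'
#' Allele-specific copy-number channels: homozygous deletions (TCN 0) with
#' three size bins, LOH (minor copy number 0, TCN classes 1/2/3-4/5-8/9+) and
#' heterozygous segments (TCN classes 2/3-4/5-8/9+), each with five size bins
#' (0-100kb, 100kb-1Mb, 1-10Mb, 10-40Mb, >40Mb), e.g. `"2:LOH:10-40Mb"`.
#'
#' @return Character vector of 48 channel names in canonical order.
#' @export
cn48_channels <- function() {
  c(
    paste0("0:HomDel:", CN_HOMDEL_BINS),
    unlist(lapply(CN_TCN_LOH, function(tc) paste0(tc, ":LOH:", CN_SIZE_BINS))),
    unlist(lapply(CN_TCN_HET, function(tc) paste0(tc, ":HET:", CN_SIZE_BINS)))
  )
}

#' Channel vocabulary for a channel class
#'
#' @param class One of `"SBS96"`, `"ID83"`, `"CN48"`.
#' @return Character vector of canonical channel names.
#' @export
channel_vocabulary <- function(class) {
  switch(match.arg(class, c("SBS96", "ID83", "CN48")),
    SBS96 = sbs96_channels(),
    ID83 = id83_channels(),
    CN48 = cn48_channels()
  )
}

#' The six HRD feature names, in model contract order
#'
#' Order is fixed: `n_ct_g`, `n_cg_t`, `del5_mh`, `loh_1_40`,
#' `het3_9_10_40`, `het2_4_gt40`. Trained models and feature tables depend on
#' this ordering.
#'
#' @return Character vector of six feature names.
#' @export
hrd_feature_names <- function() {
  c("n_ct_g", "n_cg_t", "del5_mh", "loh_1_40", "het3_9_10_40", "het2_4_gt40")
}

#' Channel-to-feature membership map
#'
#' Maps each mutational channel contributing to one of the six HRD features to
#' that feature. The map is a partial function: channels outside the six
#' groupings are absent. Feature groupings:
#' \describe{
#'   \item{n_ct_g}{C>T substitutions at NpCpG (`N[C>T]G`), enriched in HRP.}
#'   \item{n_cg_t}{C>G substitutions at NpCpT (`N[C>G]T`), enriched in HRD.}
#'   \item{del5_mh}{Deletions >= 5 bp at microhomology (`5:Del:M:1..5`).}
#'   \item{loh_1_40}{LOH segments of 1-40 Mb, all TCN classes.}
#'   \item{het3_9_10_40}{Heterozygous segments 10-40 Mb with TCN >= 3
#'     (classes 3-4, 5-8 and 9+).}
#'   \item{het2_4_gt40}{Heterozygous segments > 40 Mb with TCN 2-4
#'     (classes 2 and 3-4).}
#' }
#'
#' @return Tibble with columns `class`, `channel`, `feature`.
#' @export
channel_feature_map <- function() {
  dplyr::bind_rows(
    tibble::tibble(class = "SBS96",
                   channel = paste0(BASES, "[C>T]G"), feature = "n_ct_g"),
    tibble::tibble(class = "SBS96",
                   channel = paste0(BASES, "[C>G]T"), feature = "n_cg_t"),
    tibble::tibble(class = "ID83",
                   channel = paste0("5:Del:M:", 1:5), feature = "del5_mh"),
    tibble::tibble(class = "CN48",
                   channel = paste0(rep(CN_TCN_LOH, each = 2), ":LOH:",
                                    c("1-10Mb", "10-40Mb")),
                   feature = "loh_1_40"),
    tibble::tibble(class = "CN48",
                   channel = paste0(c("3-4", "5-8", "9+"), ":HET:10-40Mb"),
                   feature = "het3_9_10_40"),
    tibble::tibble(class = "CN48",
                   channel = paste0(c("2", "3-4"), ":HET:>40Mb"),
                   feature = "het2_4_gt40")
  )
}

#' Write the channel-to-feature map as TSV
#'
#' Ships the versioned channel membership map to disk for provenance
#' alongside analysis outputs.
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_channel_feature_map <- function(path) {
  map <- channel_feature_map()
  map$map_version <- as.character(utils::packageVersion("hrdsig"))
  readr::write_tsv(map, path)
  invisible(path)
}
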