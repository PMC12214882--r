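#' Classify single base substitutions into SBS-96 channels
#'
#' Assigns each substitution to one of the 96 pyrimidine-centric trinucleotide
#' channels. Substitutions recorded on the purine strand (reference A or G)
#' are reverse-complemented — mutated base, alternate base and both flanking
#' bases — before naming, so classification is strand-symmetric.
#'
#' @param ref,alt Reference and alternate bases (single characters, A/C/G/T).
#' @param context5,context3 Immediate 5' and 3' flanking bases.
#' @return Character vector of SBS-96 channel names, e.g. `"A[C>T]G"`.
#' @examples
#' classify_sbs("C", "T", "A", "G")  # "A[C>T]G"
#' classify_sbs("G", "A", "C", "T")  # same channel, purine strand
#' @export
classify_sbs <- function(ref, alt, context5, context3) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(context5) == n, length(context3) == n)
  bad <- !(ref %in% BASES) | !(alt %in% BASES) |
    !(context5 %in% BASES) | !(context3 %in% BASES)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("invalid base in substitution record ", i, ": ",
         context5[i], "[", ref[i], ">", alt[i], "]", context3[i],
         " (bases must be one of A/C/G/T)", call. = FALSE)
  }
  if (any(ref == alt)) {
    stop("ref and alt bases are identical in record ",
         which(ref == alt)[1], call. = FALSE)
  }
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, COMPLEMENT[ref], ref)
  a <- ifelse(pur, COMPLEMENT[alt], alt)
  c5 <- ifelse(pur, COMPLEMENT[context3], context5)
  c3 <- ifelse(pur, COMPLEMENT[context5], context3)
  paste0(c5, "[", r, ">", a, "]", c3)
}
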