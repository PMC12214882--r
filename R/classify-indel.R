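## ID-83 classification.
##
## 1 bp events are named by the pyrimidine of the affected base (T/C) and the
## number of additional adjacent copies of that base across both flanks.
## Longer events are named by event length (capped at 5) and the number of
## adjacent whole copies of the event motif in the flanks (repeat channels).
## Deletions >= 2 bp with no adjacent whole copy but partial junction homology
## are microhomology channels: MH length = max(longest prefix of the deleted
## sequence matching the start of the 3' flank, longest suffix matching the
## end of the 5' flank), capped at min(L - 1, 5). Repeat context takes
## precedence over microhomology.

run_length_at <- function(flank, base, from) {
  n <- nchar(flank)
  count <- 0L
  while (count < n) {
    pos <- if (from == "start") count + 1L else n - count
    if (substr(flank, pos, pos) != base) break
    count <- count + 1L
  }
  list(count = count, exhausted = count == n)
}

motif_copies_at <- function(flank, motif, from) {
  n <- nchar(flank)
  ml <- nchar(motif)
  copies <- 0L
  repeat {
    if ((copies + 1L) * ml > n) break
    window <- if (from == "start") {
      substr(flank, copies * ml + 1L, (copies + 1L) * ml)
    } else {
      substr(flank, n - (copies + 1L) * ml + 1L, n - copies * ml)
    }
    if (window != motif) break
    copies <- copies + 1L
  }
  ## exhausted: all full windows matched and the leftover partial window also
  ## matches, so a longer flank could reveal another copy
  leftover <- n - copies * ml
  partial_ok <- leftover > 0L && leftover < ml && {
    if (from == "start") {
      substr(flank, copies * ml + 1L, n) == substr(motif, 1L, leftover)
    } else {
      substr(flank, 1L, leftover) ==
        substr(motif, ml - leftover + 1L, ml)
    }
  }
  list(count = copies, exhausted = leftover == 0L || partial_ok)
}

prefix_match_len <- function(seq, flank3, cap) {
  k <- 0L
  n <- min(cap, nchar(flank3))
  while (k < n && substr(seq, k + 1L, k + 1L) == substr(flank3, k + 1L, k + 1L)) {
    k <- k + 1L
  }
  k
}

suffix_match_len <- function(seq, flank5, cap) {
  L <- nchar(seq)
  n5 <- nchar(flank5)
  k <- 0L
  n <- min(cap, n5)
  while (k < n && substr(seq, L - k, L - k) == substr(flank5, n5 - k, n5 - k)) {
    k <- k + 1L
  }
  k
}

classify_indel_one <- function(kind, sequence, flank5, flank3) {
  L <- nchar(sequence)
  tag <- if (kind == "deletion") "Del" else "Ins"
  if (L == 1L) {
    base <- sequence
    name_base <- if (base %in% c("C", "T")) base else unname(COMPLEMENT[base])
    r5 <- run_length_at(flank5, base, "end")
    r3 <- run_length_at(flank3, base, "start")
    n_adj <- r5$count + r3$count
    if (n_adj < 5L && (r5$exhausted || r3$exhausted)) {
      stop("flank too short to resolve homopolymer length for 1 bp ", kind,
           " of '", sequence, "'; provide longer flanking context",
           call. = FALSE)
    }
    return(paste0("1:", tag, ":", name_base, ":", min(n_adj, 5L)))
  }
  c5 <- motif_copies_at(flank5, sequence, "end")
  c3 <- motif_copies_at(flank3, sequence, "start")
  copies <- c5$count + c3$count
  if (copies < 5L && (c5$exhausted || c3$exhausted)) {
    stop("flank too short to resolve repeat count for ", L, " bp ", kind,
         " of '", sequence, "'; provide longer flanking context",
         call. = FALSE)
  }
  len_class <- min(L, 5L)
  if (kind == "insertion" || copies >= 1L) {
    return(paste0(len_class, ":", tag, ":R:", min(copies, 5L)))
  }
  cap <- min(L - 1L, 5L)
  mh <- max(prefix_match_len(sequence, flank3, cap),
            suffix_match_len(sequence, flank5, cap))
  if (mh >= 1L) {
    paste0(len_class, ":Del:M:", mh)
  } else {
    paste0(len_class, ":Del:R:0")
  }
}

#' Classify insertions and deletions into ID-83 channels
#'
#' Assigns each simple insertion or deletion to one of the 83 canonical indel
#' channels using the flanking sequence carried on the record, so no reference
#' genome is needed. Classification is strand-symmetric: a record and its
#' reverse complement map to the same channel.
#'
#' @param kind `"insertion"` or `"deletion"` (vectorized).
#' @param sequence Inserted or deleted bases (>= 1 bp).
#' @param flank5,flank3 Upstream/downstream flanking sequence; >= 25 bp is
#'   enough to resolve all repeat and microhomology categories. An error is
#'   raised if a flank is too short to settle the category.
#' @return Character vector of ID-83 channel names, e.g. `"5:Del:M:3"`.
#' @examples
#' classify_indel("deletion", "T", "GCAGCTAGCATGACGTACGATCGAC",
#'                "TTTTTAGCATGCATGACGTACGATC")  # "1:Del:T:5"
#' @export
classify_indel <- function(kind, sequence, flank5, flank3) {
  kind <- match.arg(kind, c("insertion", "deletion"), several.ok = TRUE)
  n <- length(sequence)
  kind <- rep_len(kind, n)
  stopifnot(length(flank5) == n, length(flank3) == n)
  ok_seq <- nchar(sequence) >= 1L &
    !grepl("[^ACGT]", sequence) & !grepl("[^ACGT]", flank5) &
    !grepl("[^ACGT]", flank3)
  if (any(!ok_seq)) {
    stop("record ", which(!ok_seq)[1],
         ": indel sequence and flanks must be non-empty A/C/G/T strings",
         call. = FALSE)
  }
  vapply(seq_len(n), function(i)
    classify_indel_one(kind[i], sequence[i], flank5[i], flank3[i]),
    character(1))
}
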