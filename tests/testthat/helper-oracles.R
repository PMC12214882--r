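## Independent oracles, deliberately written as plain character/loop code so
## they share no helpers with the package implementation.

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A")

oracle_revcomp <- function(x) {
  paste(rev(unname(ORACLE_COMP[strsplit(x, "")[[1]]])), collapse = "")
}

## Brute-force repeat / microhomology scanner for ID-83 classification.
oracle_classify_indel <- function(kind, sequence, flank5, flank3) {
  sv <- strsplit(sequence, "")[[1]]
  v5 <- strsplit(flank5, "")[[1]]
  v3 <- strsplit(flank3, "")[[1]]
  L <- length(sv)
  tag <- if (kind == "deletion") "Del" else "Ins"
  if (L == 1) {
    b <- sv[1]
    nb <- if (b %in% c("A", "G")) unname(ORACLE_COMP[b]) else b
    cnt <- 0
    i <- 1
    while (i <= length(v3) && v3[i] == b) { cnt <- cnt + 1; i <- i + 1 }
    j <- length(v5)
    while (j >= 1 && v5[j] == b) { cnt <- cnt + 1; j <- j - 1 }
    return(sprintf("1:%s:%s:%d", tag, nb, min(cnt, 5)))
  }
  copies <- 0
  i <- 1
  while (i + L - 1 <= length(v3) && all(v3[i:(i + L - 1)] == sv)) {
    copies <- copies + 1
    i <- i + L
  }
  j <- length(v5)
  while (j - L + 1 >= 1 && all(v5[(j - L + 1):j] == sv)) {
    copies <- copies + 1
    j <- j - L
  }
  lenc <- min(L, 5)
  if (kind == "insertion" || copies >= 1) {
    return(sprintf("%d:%s:R:%d", lenc, tag, min(copies, 5)))
  }
  mh3 <- 0
  while (mh3 < L - 1 && mh3 < length(v3) && v3[mh3 + 1] == sv[mh3 + 1]) {
    mh3 <- mh3 + 1
  }
  mh5 <- 0
  n5 <- length(v5)
  while (mh5 < L - 1 && mh5 < n5 && v5[n5 - mh5] == sv[L - mh5]) {
    mh5 <- mh5 + 1
  }
  mh <- min(max(mh3, mh5), 5)
  if (mh >= 1) sprintf("%d:Del:M:%d", lenc, mh)
  else sprintf("%d:Del:R:0", lenc)
}

## Random simple indels with 30 bp flanks; unconstrained, so all categories
## (and their boundaries) arise naturally.
oracle_random_indels <- function(n) {
  bases <- c("A", "C", "G", "T")
  rs <- function(k) paste(sample(bases, k, replace = TRUE), collapse = "")
  tibble::tibble(
    kind = sample(c("insertion", "deletion"), n, replace = TRUE),
    sequence = vapply(sample(1:7, n, replace = TRUE), rs, character(1)),
    flank5 = vapply(rep(30, n), rs, character(1)),
    flank3 = vapply(rep(30, n), rs, character(1))
  )
}

## Exact two-sided Fisher p for a 2x2 table by hypergeometric enumeration:
## sum of the probabilities of all tables (same margins) no more likely than
## the observed one.
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  lo <- max(0, k - n)
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## Hand-tabulated CN-48 rules, written as independent nested conditionals.
oracle_classify_cn <- function(major, minor, size) {
  tcn <- major + minor
  if (tcn == 0) {
    bin <- if (size <= 1e5) "0-100kb" else if (size <= 1e6) "100kb-1Mb"
      else ">1Mb"
    return(paste0("0:HomDel:", bin))
  }
  zyg <- if (minor == 0) "LOH" else "HET"
  cls <- if (tcn == 1) "1" else if (tcn == 2) "2" else if (tcn <= 4) "3-4"
    else if (tcn <= 8) "5-8" else "9+"
  bin <- if (size <= 1e5) "0-100kb" else if (size <= 1e6) "100kb-1Mb"
    else if (size <= 1e7) "1-10Mb" else if (size <= 4e7) "10-40Mb"
    else ">40Mb"
  paste0(cls, ":", zyg, ":", bin)
}

## AUC as explicit pairwise concordance over all positive-negative pairs.
oracle_auc <- function(truth, score) {
  pos <- score[as.logical(truth)]
  neg <- score[!as.logical(truth)]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

## Small labeled catalog pair used by several enrichment tests: two channels
## of one class carry all the signal.
two_channel_catalog <- function(hrd_counts, hrp_counts,
                                channels = c("A[C>A]A", "C[C>A]A")) {
  skel <- tidyr::expand_grid(
    sample_id = c("hrd1", "hrp1"),
    tibble::tibble(class = "SBS96", channel = sbs96_channels()))
  skel$count <- 0L
  for (i in seq_along(channels)) {
    skel$count[skel$sample_id == "hrd1" & skel$channel == channels[i]] <-
      hrd_counts[i]
    skel$count[skel$sample_id == "hrp1" & skel$channel == channels[i]] <-
      hrp_counts[i]
  }
  skel
}

two_channel_labels <- tibble::tibble(sample_id = c("hrd1", "hrp1"),
                                     label = c("HRD", "HRP"))
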