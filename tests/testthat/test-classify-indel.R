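rand_flank <- function(n = 30) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("homopolymer deletions and insertions count adjacent copies", {
  expect_equal(
    classify_indel("deletion", "T",
                   "GCAGCTAGCATGACGTACGATCGAC", "TTTTTAGCATGCATGACGTACGATC"),
    "1:Del:T:5")
  ## an isolated inserted C in a G run
  expect_equal(
    classify_indel("insertion", "C",
                   "GCAGCTAGCATGACGTACGATCGAT", "GGAGCTAGCATGACGTACGATCGAC"),
    "1:Ins:C:0")
  ## purine strand: deleted A == deleted T on the other strand
  expect_equal(
    classify_indel("deletion", "A",
                   "GCAGCTAGCATGACGTACGATCGAC", "AATGCTAGCATGACGTACGATCGAC"),
    "1:Del:T:2")
  ## copies on both flanks add up
  expect_equal(
    classify_indel("deletion", "T",
                   "GCAGCTAGCATGACGTACGATCGTT", "TTAGCTAGCATGACGTACGATCGAC"),
    "1:Del:T:4")
})

test_that("deletions at microhomology are measured from both junctions", {
  ## 5 bp deletion, 3' flank shares the 3 bp prefix ACG, 5' flank shares none
  expect_equal(
    classify_indel("deletion", "ACGTA",
                   "GCAGCTAGCATGACGTACGATCGAC", "ACGGGTAGCATGACGTACGATCGAC"),
    "5:Del:M:3")
  ## homology on the 5' side only: flank5 ends with the sequence suffix
  expect_equal(
    classify_indel("deletion", "ACGTA",
                   "GCAGCTAGCATGACGTACGATCCTA", "CCGGGTAGCATGACGTACGATCGAC"),
    "5:Del:M:2")
  ## a full adjacent copy takes repeat precedence over microhomology
  expect_equal(
    classify_indel("deletion", "ACGTA",
                   "GCAGCTAGCATGACGTACGATCGAC", "ACGTAGGCATGCATGACGTACGATC"),
    "5:Del:R:1")
  ## deletions of >= 6 bp with 5 bp homology fill the deepest MH category
  expect_equal(
    classify_indel("deletion", "ACGTAG",
                   "GCAGCTAGCATGACGTACGATCGAC", "ACGTACGCATGCATGACGTACGATC"),
    "5:Del:M:5")
  ## length-2 deletion with 1 bp homology
  expect_equal(
    classify_indel("deletion", "AT",
                   "GCAGCTAGCATGACGTACGATCGAC", "ACGGGTAGCATGACGTACGATCGAC"),
    "2:Del:M:1")
})

test_that("repeat-context events count whole adjacent motif copies", {
  expect_equal(
    classify_indel("deletion", "ACG",
                   "GCAGCTAGCATGACGTACGATCTTT", "ACGACGGTAGCATGACGTACGATCG"),
    "3:Del:R:2")
  expect_equal(
    classify_indel("insertion", "ACGTA",
                   "GCAGCTAGCATGACGTACGATCGAC", "CCGGGTAGCATGACGTACGATCGAC"),
    "5:Ins:R:0")
  ## no microhomology and no copies: R:0
  expect_equal(
    classify_indel("deletion", "ACGTA",
                   "GCAGCTAGCATGACGTACGATCGAC", "CCGGGTAGCATGACGTACGATCGAC"),
    "5:Del:R:0")
})

test_that("classification agrees with the brute-force scanner on random indels", {
  withr::local_seed(421)
  recs <- oracle_random_indels(2000)
  got <- classify_indel(recs$kind, recs$sequence, recs$flank5, recs$flank3)
  want <- mapply(oracle_classify_indel, recs$kind, recs$sequence,
                 recs$flank5, recs$flank3, USE.NAMES = FALSE)
  expect_identical(got, want)
  expect_true(all(got %in% id83_channels()))
})

test_that("unresolvable flanks raise an actionable error", {
  expect_error(classify_indel("deletion", "T", "GCA", "TTT"),
               "longer flanking context")
  expect_error(classify_indel("deletion", "ACG", "ACGACG", "TTTAAA"),
               "longer flanking context")
  expect_error(classify_indel("deletion", "", rand_flank(), rand_flank()),
               "non-empty")
  expect_error(classify_indel("deletion", "ANT", rand_flank(), rand_flank()),
               "A/C/G/T")
})
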