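test_that("substitutions are kept iff their position lies in a half-open target", {
  targets <- tibble::tibble(chromosome = "1", start = 100L, end = 200L)
  recs <- tibble::tibble(sample_id = "s", chromosome = "1",
                         position = c(100L, 101L, 150L, 200L, 201L),
                         ref = "C", alt = "T", context5 = "A", context3 = "G")
  kept <- restrict_mutations(recs, targets)
  ## BED [100,200) covers 1-based positions 101..200
  expect_equal(kept$position, c(101L, 150L, 200L))
})

test_that("deletions overlap by any deleted base; chromosome dialects are normalized", {
  targets <- tibble::tibble(chromosome = "chr1", start = 100L, end = 200L)
  dels <- tibble::tibble(sample_id = "s", chromosome = "1",
                         position = c(95L, 99L, 201L, 198L),
                         kind = "deletion",
                         sequence = c("AAAAAA", "AA", "AAA", "AAAAA"),
                         flank5 = strrep("C", 30), flank3 = strrep("G", 30))
  kept <- restrict_mutations(dels, targets)
  ## 95+6-1 = 100 < 101: out; 99..100: out; 201: out; 198..202: in
  expect_equal(kept$position, 198L)
})

test_that("segments keep original coordinates iff they touch a target", {
  targets <- tibble::tibble(chromosome = "1", start = c(1000L, 5000L),
                            end = c(2000L, 6000L))
  segs <- tibble::tibble(
    sample_id = "s", chromosome = c("1", "1", "2"),
    start = c(1L, 1999L, 1500L), end = c(900L, 50000000L, 1600L),
    major_cn = 2L, minor_cn = 1L)
  kept <- restrict_segments(segs, targets)
  ## only the long chr1 segment touches a target; coordinates are unchanged
  expect_equal(kept, segs[2, ])
  dropped <- dplyr::anti_join(segs, kept,
                              by = c("chromosome", "start", "end"))
  expect_equal(dplyr::bind_rows(kept, dropped) |>
                 dplyr::arrange(.data$chromosome, .data$start),
               dplyr::arrange(segs, .data$chromosome, .data$start))
})

test_that("restriction is idempotent and commutes with feature derivation", {
  cohort <- simulate_cohort(simulation_config(
    n_hrd = 4, n_hrp = 4, sbs_burden = 250, indel_burden = 50,
    n_segments = 35, seed = 17))
  targets <- toy_exome_targets(n_targets = 2000, width = 5000, seed = 3)
  wes <- downsample_cohort(cohort, targets)
  wes2 <- downsample_cohort(wes, targets)
  expect_identical(wes2$mutations, wes$mutations)
  expect_identical(wes2$indels, wes$indels)
  expect_identical(wes2$segments, wes$segments)

  direct <- suppressWarnings(derive_features(
    build_catalogs(wes$mutations, wes$indels, wes$segments), assay = "WES"))
  ## write the restricted records out and rerun the pipeline from files
  mpath <- withr::local_tempfile(fileext = ".tsv")
  spath <- withr::local_tempfile(fileext = ".tsv")
  write_mutation_tsv(wes$mutations, wes$indels, mpath)
  write_segment_tsv(wes$segments, spath)
  reread <- read_mutation_tsv(mpath)
  refeat <- suppressWarnings(derive_features(
    build_catalogs(reread$mutations, reread$indels, read_segment_tsv(spath)),
    assay = "WES"))
  expect_equal(refeat, direct)
})

test_that("the kept fraction of uniform substitutions tracks the target fraction", {
  targets <- toy_exome_targets(n_targets = 1500, width = 4000, seed = 5)
  target_bp <- sum(targets$end - targets$start)
  frac <- target_bp / (3 * 60e6)
  withr::local_seed(29)
  n <- 20000
  recs <- tibble::tibble(
    sample_id = "s", chromosome = sample(c("1", "2", "3"), n, replace = TRUE),
    position = sample.int(60e6, n, replace = TRUE),
    ref = "C", alt = "T", context5 = "A", context3 = "G")
  kept_frac <- nrow(restrict_mutations(recs, targets)) / n
  expect_lt(abs(kept_frac - frac), 4 * sqrt(frac * (1 - frac) / n))
})
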