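test_that("substitution features are within-class proportions", {
  cats <- catalog_from_counts(c("A[C>T]G" = 2, "C[C>G]T" = 2))
  f <- suppressWarnings(derive_features(cats, assay = "WGS"))
  expect_equal(f$n_ct_g, 0.5)
  expect_equal(f$n_cg_t, 0.5)
  expect_identical(names(f),
                   c("sample_id", hrd_feature_names(), "assay",
                     "low_confidence"))
})

test_that("del5_mh is a count by default and a proportion on request", {
  cats <- catalog_from_counts(c("5:Del:M:1" = 1, "5:Del:M:3" = 2,
                                "1:Del:T:0" = 7))
  expect_equal(suppressWarnings(derive_features(cats, "WES"))$del5_mh, 3)
  expect_equal(
    suppressWarnings(derive_features(cats, "WES",
                                     del5mh_as_count = FALSE))$del5_mh,
    0.3)
})

test_that("copy-number features group the schema channels without double counting", {
  cats <- catalog_from_counts(c("2:LOH:10-40Mb" = 1, "2:HET:>40Mb" = 1))
  f <- suppressWarnings(derive_features(cats, "WGS"))
  expect_equal(f$loh_1_40, 0.5)
  expect_equal(f$het2_4_gt40, 0.5)
  expect_equal(f$het3_9_10_40, 0)
  ## 9+ HET contributes to the mid-size amplification feature, 1:LOH to LOH
  cats2 <- catalog_from_counts(c("9+:HET:10-40Mb" = 1, "1:LOH:1-10Mb" = 2,
                                 "0:HomDel:>1Mb" = 1))
  f2 <- suppressWarnings(derive_features(cats2, "WGS"))
  expect_equal(f2$het3_9_10_40, 0.25)
  expect_equal(f2$loh_1_40, 0.5)
  ## the channel->feature map is a partial function
  map <- channel_feature_map()
  expect_equal(anyDuplicated(map$channel), 0)
  expect_lt(nrow(map), 96 + 83 + 48)
})

test_that("zero-event classes yield zero features and a low-confidence flag", {
  cats <- catalog_from_counts(c("A[C>T]G" = 4))
  expect_warning(f <- derive_features(cats, "WGS"), "low_confidence")
  expect_equal(f$loh_1_40, 0)
  expect_equal(f$del5_mh, 0)
  expect_true(f$low_confidence)
})

test_that("features are invariant to record order and file splitting", {
  cohort <- simulate_cohort(simulation_config(
    n_hrd = 3, n_hrp = 3, sbs_burden = 150, indel_burden = 40,
    n_segments = 25, seed = 5))
  f_ref <- cohort_features(cohort)
  withr::local_seed(1)
  shuffled <- build_catalogs(
    cohort$mutations[sample(nrow(cohort$mutations)), ],
    cohort$indels[sample(nrow(cohort$indels)), ],
    cohort$segments[sample(nrow(cohort$segments)), ])
  f_shuf <- derive_features(shuffled, assay = "WGS") |>
    dplyr::arrange(match(.data$sample_id, f_ref$sample_id))
  expect_equal(f_shuf, f_ref)
  ## splitting the cohort into two files and merging catalogs changes nothing
  half <- cohort$mutations$position %% 2 == 0
  split_cats <- dplyr::bind_rows(
    build_catalogs(cohort$mutations[half, ]),
    build_catalogs(cohort$mutations[!half, ])) |>
    dplyr::group_by(.data$sample_id, .data$class, .data$channel) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  full_cats <- build_catalogs(cohort$mutations) |>
    dplyr::arrange(.data$sample_id, .data$class, .data$channel)
  expect_equal(dplyr::arrange(split_cats, .data$sample_id, .data$class,
                              .data$channel),
               full_cats)
})

test_that("feature tables round-trip through TSV in contract column order", {
  cohort <- simulate_cohort(simulation_config(
    n_hrd = 2, n_hrp = 2, sbs_burden = 100, indel_burden = 25,
    n_segments = 20, seed = 8))
  f <- cohort_features(cohort)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tsv(f, path)
  hdr <- names(readr::read_tsv(path, show_col_types = FALSE, n_max = 0))
  expect_identical(hdr, c("sample", hrd_feature_names(), "assay"))
  back <- read_feature_tsv(path)
  expect_equal(back[, c("sample_id", hrd_feature_names(), "assay")],
               f[, c("sample_id", hrd_feature_names(), "assay")])
})
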