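test_that("group mean profiles average per-sample proportions", {
  cats <- dplyr::bind_rows(
    catalog_from_counts(c("A[C>A]A" = 2, "C[C>A]A" = 8), "h1"),   # 0.2
    catalog_from_counts(c("A[C>A]A" = 4, "C[C>A]A" = 6), "h2"),   # 0.4
    catalog_from_counts(c("A[C>A]A" = 1, "C[C>A]A" = 9), "p1"))
  labels <- tibble::tibble(sample_id = c("h1", "h2", "p1"),
                           label = c("HRD", "HRD", "HRP"))
  prof <- group_mean_profiles(cats, labels)
  target <- prof[prof$channel == "A[C>A]A", ]
  expect_equal(target$mean_prop_hrd, 0.3)
  expect_equal(target$mean_prop_hrp, 0.1)  # single-sample group = that sample
  ## permutation invariance
  prof2 <- group_mean_profiles(cats[sample(nrow(cats)), ], labels)
  expect_equal(dplyr::arrange(prof2, .data$class, .data$channel),
               dplyr::arrange(prof, .data$class, .data$channel))
})

test_that("identical groups give p = 1 and zero fold change", {
  cats <- two_channel_catalog(c(10, 90), c(10, 90))
  res <- channel_enrichment(cats, two_channel_labels)
  ch <- res[res$channel == "A[C>A]A", ]
  expect_equal(ch$p_value, 1)
  expect_equal(ch$log2_fc, 0)
  ## channels empty in both groups are inert
  empty <- res[res$channel == "T[T>G]T", ]
  expect_equal(empty$p_value, 1)
  expect_equal(empty$log2_fc, 0)
})

test_that("Fisher p values match exact hypergeometric enumeration", {
  ## spec-style 2x2: channel 8/2 in HRD vs 1/5 in HRP
  cats <- two_channel_catalog(c(8, 2), c(1, 5))
  res <- channel_enrichment(cats, two_channel_labels)
  p <- res$p_value[res$channel == "A[C>A]A"]
  expect_equal(p, oracle_fisher_two_sided(8, 2, 1, 5), tolerance = 1e-12)
  expect_equal(p, 0.03497, tolerance = 1e-3)
  ## a modest grid of tables, exact agreement
  for (tbl in list(c(3, 7, 6, 2), c(0, 10, 5, 5), c(12, 1, 2, 9),
                   c(5, 5, 5, 5), c(1, 0, 0, 1))) {
    got <- stats::fisher.test(matrix(tbl, 2, byrow = TRUE))$p.value
    expect_equal(got, do.call(oracle_fisher_two_sided, as.list(tbl)),
                 tolerance = 1e-12)
  }
})

test_that("fold changes use group-mean proportions with epsilon guarding zeros", {
  cats <- two_channel_catalog(c(2, 98), c(1, 99))
  res <- channel_enrichment(cats, two_channel_labels)
  expect_equal(res$log2_fc[res$channel == "A[C>A]A"], 1)  # 0.02 vs 0.01
  ## one-sided zero mean uses the configurable pseudo-proportion
  cats0 <- two_channel_catalog(c(4, 96), c(0, 100))
  res0 <- channel_enrichment(cats0, two_channel_labels, epsilon = 0.01)
  expect_equal(res0$log2_fc[res0$channel == "A[C>A]A"], 2)  # 0.04 vs eps
  expect_equal(res0$direction[res0$channel == "A[C>A]A"], "HRD")
})

test_that("BH adjustment is monotone with q >= p", {
  cohort <- simulate_cohort(simulation_config(
    n_hrd = 8, n_hrp = 8, sbs_burden = 400, indel_burden = 60,
    n_segments = 40, seed = 13), level = "catalog")
  res <- channel_enrichment(cohort$catalogs, cohort$labels)
  expect_true(all(res$q_value >= res$p_value - 1e-15))
  ord <- order(res$p_value)
  expect_true(all(diff(res$q_value[ord]) >= -1e-15))
  expect_equal(res$q_value, stats::p.adjust(res$p_value, "BH"))
})

test_that("selection applies the assay fold-change and FDR thresholds strictly", {
  mk <- function(lfc, q) tibble::tibble(
    class = "SBS96", channel = paste0("ch", seq_along(lfc)),
    mean_prop_hrd = 0.1, mean_prop_hrp = 0.1, log2_fc = lfc,
    p_value = q, q_value = q,
    direction = ifelse(lfc > 0, "HRD", "HRP"))
  wgs <- select_channels(mk(c(0.8, 0.5, 0.75, 0.76), c(1e-4, 1e-6, 1e-9, 1e-3)),
                         "WGS")
  expect_equal(wgs$selected, c(TRUE, FALSE, FALSE, FALSE))
  wes <- select_channels(mk(c(-0.3, -0.2, 0.26), c(1e-4, 1e-9, 1.0001e-3)),
                         "WES")
  expect_equal(wes$selected, c(TRUE, FALSE, FALSE))
  expect_equal(wes$direction[1], "HRP")
  expect_error(select_channels(mk(1, 0.1), "panel"))
})

test_that("assay intersection keeps channels enriched in both, per direction", {
  mk <- function(chs, dirs, sel) tibble::tibble(
    channel = chs, direction = dirs, selected = sel)
  wgs <- mk(c("a", "b", "c"), c("HRD", "HRD", "HRP"), c(TRUE, TRUE, TRUE))
  wes <- mk(c("b", "c", "d"), c("HRD", "HRP", "HRP"), c(TRUE, TRUE, TRUE))
  out <- intersect_assays(wgs, wes)
  expect_equal(out$hrd_enriched, "b")
  expect_equal(out$hrp_enriched, "c")
  expect_equal(intersect_assays(wgs, mk("z", "HRD", TRUE))$hrd_enriched,
               character(0))
  expect_equal(intersect_assays(wgs, wgs)$hrd_enriched, c("a", "b"))
})
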