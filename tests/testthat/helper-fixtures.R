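## Build a full 227-channel catalog for one sample from named channel counts.
catalog_from_counts <- function(counts, sample_id = "s1") {
  skel <- tibble::tibble(
    sample_id = sample_id,
    class = rep(c("SBS96", "ID83", "CN48"), c(96, 83, 48)),
    channel = c(sbs96_channels(), id83_channels(), cn48_channels()),
    count = 0L)
  skel$count[match(names(counts), skel$channel)] <- as.integer(counts)
  skel
}

## Deterministic small train/test pair at catalog level for model tests.
small_cohort_pair <- function(seed = 7, n_train = 15, n_test = 8) {
  train <- simulate_cohort(simulation_config(
    n_hrd = n_train, n_hrp = n_train, sbs_burden = 400, indel_burden = 60,
    n_segments = 40, seed = seed), level = "catalog")
  test <- simulate_cohort(simulation_config(
    n_hrd = n_test, n_hrp = n_test, sbs_burden = 400, indel_burden = 60,
    n_segments = 40, seed = seed + 1000), level = "catalog")
  list(train = train, test = test)
}
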