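## Synthetic labeled cohorts.
##
## Samples are drawn on a toy genome of 3 chromosomes x 60 Mb. Each sample
## gets class-specific channel probabilities: a baseline (uniform, with CpG
## transition mass elevated) tilted multiplicatively by the HRD/HRP effect
## sizes, then jittered with Dirichlet noise; event counts are multinomial
## at a Poisson-distributed per-sample burden. Concrete records (positions,
## flanks consistent with the assigned channel, random strand) are emitted so
## the channel classifiers are exercised end to end.

TOY_CHROMS <- c("1", "2", "3")
TOY_CHROM_LENGTH <- 60e6
SIM_FLANK <- 30L

#' Simulation configuration for synthetic HRD/HRP cohorts
#'
#' Defaults define the package's reference study conditions. Effect sizes
#' are multiplicative enrichments (>= 1) applied to the feature-defining
#' channel groups, in the directions observed in HRD vs HRP tumors:
#' `ct_g_hrp` (NpCpG C>T, elevated in HRP), `cg_t_hrd` (NpCpT C>G, HRD),
#' `del5mh_hrd` (microhomology deletions >= 5 bp, HRD), `loh_hrd`
#' (LOH 1-40 Mb, HRD), `het_mid_hrd` (HET TCN 3-9, 10-40 Mb, HRD) and
#' `het_large_hrp` (HET TCN 2-4, > 40 Mb, HRP). Default magnitudes put the
#' class-mean log2 fold changes near the WGS volcano-selection threshold so
#' selection behavior is meaningfully exercised.
#'
#' @param n_hrd,n_hrp Samples per class.
#' @param assay `"WGS"` or `"WES"`; presets the per-sample burdens
#'   (WGS: 2500 substitutions, 150 indels, 60 segments; WES: 80/10/40).
#' @param sbs_burden,indel_burden,n_segments Mean per-sample event counts
#'   (Poisson); override the assay preset.
#' @param effects Named list of multiplicative enrichments (see above); all
#'   must be >= 1. Setting all to 1 gives exchangeable null classes.
#' @param dirichlet_concentration Concentration of the per-sample Dirichlet
#'   jitter around the class channel probabilities; larger is less noisy.
#' @param seed Integer seed; fixed seed makes the cohort byte-reproducible.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_hrd = 100, n_hrp = 100,
                              assay = c("WGS", "WES"),
                              sbs_burden = NULL, indel_burden = NULL,
                              n_segments = NULL,
                              effects = list(), dirichlet_concentration = 500,
                              seed = 1) {
  assay <- match.arg(assay)
  presets <- switch(assay,
    WGS = list(sbs = 2500, indel = 150, seg = 60),
    WES = list(sbs = 80, indel = 10, seg = 40))
  eff <- list(ct_g_hrp = 2, cg_t_hrd = 2, del5mh_hrd = 3, loh_hrd = 2.5,
              het_mid_hrd = 2.5, het_large_hrp = 2.5)
  unknown <- setdiff(names(effects), names(eff))
  if (length(unknown) > 0) {
    stop("unknown effect(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  eff[names(effects)] <- effects
  if (any(unlist(eff) < 1)) {
    stop("effect sizes are multiplicative enrichments and must be >= 1",
         call. = FALSE)
  }
  cfg <- list(
    n_hrd = n_hrd, n_hrp = n_hrp, assay = assay,
    sbs_burden = sbs_burden %||% presets$sbs,
    indel_burden = indel_burden %||% presets$indel,
    n_segments = n_segments %||% presets$seg,
    effects = eff,
    dirichlet_concentration = dirichlet_concentration,
    seed = as.integer(seed)
  )
  if (any(c(cfg$sbs_burden, cfg$indel_burden, cfg$n_segments) <= 0)) {
    stop("burdens must be positive", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

## Class-conditional channel probabilities per channel class.
sim_channel_probs <- function(config) {
  map <- channel_feature_map()
  grp <- function(feature) map$channel[map$feature == feature]
  tilt <- function(base, channels, factor) {
    base[names(base) %in% channels] <- base[names(base) %in% channels] * factor
    base / sum(base)
  }
  sbs <- stats::setNames(rep(1, 96), sbs96_channels())
  sbs[grp("n_ct_g")] <- 5  # CpG transitions are common in all tumors
  id <- stats::setNames(rep(1, 83), id83_channels())
  cn <- stats::setNames(rep(1, 48), cn48_channels())
  e <- config$effects
  list(
    sbs = list(HRD = tilt(sbs, grp("n_cg_t"), e$cg_t_hrd),
               HRP = tilt(sbs, grp("n_ct_g"), e$ct_g_hrp)),
    id = list(HRD = tilt(id, grp("del5_mh"), e$del5mh_hrd),
              HRP = id / sum(id)),
    cn = list(HRD = tilt(tilt(cn, grp("loh_1_40"), e$loh_hrd),
                         grp("het3_9_10_40"), e$het_mid_hrd),
              HRP = tilt(cn, grp("het2_4_gt40"), e$het_large_hrp))
  )
}

dirichlet_jitter <- function(p, concentration) {
  g <- rgamma(length(p), shape = concentration * p)
  if (sum(g) == 0) return(p)
  stats::setNames(g / sum(g), names(p))
}

#' Simulate a labeled HRD/HRP cohort
#'
#' Draws per-sample channel counts from the class-conditional probabilities
#' of `config` and (by default) emits concrete mutation, indel and segment
#' records whose positions and flanking sequences realize the assigned
#' channels, so the channel classifiers must round-trip them.
#'
#' @param config A [simulation_config()].
#' @param level `"records"` (default) emits concrete records;
#'   `"catalog"` returns the channel counts directly as a catalog tibble,
#'   which is distributionally identical and much faster for replicate
#'   studies.
#' @return A list of class `hrd_cohort`: `mutations`, `indels`, `segments`
#'   (NULL at catalog level), `catalogs` (catalog level only), `labels`
#'   (sample_id, label), `assay`, `config`, `level`.
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_hrd = 3, n_hrp = 3,
#'                                             sbs_burden = 50,
#'                                             indel_burden = 10,
#'                                             n_segments = 10, seed = 7))
#' table(cohort$labels$label)
#' @export
simulate_cohort <- function(config, level = c("records", "catalog")) {
  level <- match.arg(level)
  stopifnot(inherits(config, "sim_config"))
  probs <- sim_channel_probs(config)
  labels <- tibble::tibble(
    sample_id = c(sprintf("HRD_%03d", seq_len(config$n_hrd)),
                  sprintf("HRP_%03d", seq_len(config$n_hrp))),
    label = rep(c("HRD", "HRP"), c(config$n_hrd, config$n_hrp))
  )

  withr::with_seed(config$seed, {
    draws <- purrr::map2(labels$sample_id, labels$label, function(sid, lab) {
      draw_one <- function(p, burden) {
        pj <- dirichlet_jitter(p, config$dirichlet_concentration)
        n <- rpois(1, burden)
        counts <- if (n > 0) drop(rmultinom(1, n, pj)) else rep(0L, length(p))
        stats::setNames(as.integer(counts), names(p))
      }
      list(sample_id = sid,
           sbs = draw_one(probs$sbs[[lab]], config$sbs_burden),
           id = draw_one(probs$id[[lab]], config$indel_burden),
           cn = draw_one(probs$cn[[lab]], config$n_segments))
    })

    if (level == "catalog") {
      catalogs <- purrr::map_dfr(draws, function(d) {
        tibble::tibble(
          sample_id = d$sample_id,
          class = rep(c("SBS96", "ID83", "CN48"), c(96, 83, 48)),
          channel = c(names(d$sbs), names(d$id), names(d$cn)),
          count = unname(c(d$sbs, d$id, d$cn)))
      })
      return(structure(list(mutations = NULL, indels = NULL, segments = NULL,
                            catalogs = catalogs, labels = labels,
                            assay = config$assay, config = config,
                            level = level),
                       class = "hrd_cohort"))
    }

    mutations <- purrr::map_dfr(draws, function(d)
      emit_sbs_records(d$sample_id, d$sbs))
    indels <- purrr::map_dfr(draws, function(d)
      emit_indel_records(d$sample_id, d$id))
    segments <- purrr::map_dfr(draws, function(d)
      emit_segment_records(d$sample_id, d$cn))
    structure(list(mutations = mutations, indels = indels,
                   segments = segments, catalogs = NULL, labels = labels,
                   assay = config$assay, config = config, level = level),
              class = "hrd_cohort")
  })
}

rand_bases <- function(n, exclude = NULL) {
  pool <- setdiff(BASES, exclude)
  sample(pool, n, replace = TRUE)
}

rand_seq <- function(len, exclude_last = NULL, exclude_first = NULL) {
  b <- rand_bases(len)
  if (!is.null(exclude_first) && b[1] %in% exclude_first) {
    b[1] <- sample(setdiff(BASES, exclude_first), 1)
  }
  if (!is.null(exclude_last) && b[len] %in% exclude_last) {
    b[len] <- sample(setdiff(BASES, exclude_last), 1)
  }
  paste(b, collapse = "")
}

emit_sbs_records <- function(sample_id, counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) {
    return(tibble::tibble(sample_id = character(), chromosome = character(),
                          position = integer(), ref = character(),
                          alt = character(), context5 = character(),
                          context3 = character()))
  }
  channel <- rep(names(counts), counts)
  n <- length(channel)
  c5 <- substr(channel, 1, 1)
  ref <- substr(channel, 3, 3)
  alt <- substr(channel, 5, 5)
  c3 <- substr(channel, 7, 7)
  flip <- runif(n) < 0.5  # emit half the records on the purine strand
  tibble::tibble(
    sample_id = sample_id,
    chromosome = sample(TOY_CHROMS, n, replace = TRUE),
    position = sample.int(TOY_CHROM_LENGTH - 100L, n) + 50L,
    ref = ifelse(flip, COMPLEMENT[ref], ref),
    alt = ifelse(flip, COMPLEMENT[alt], alt),
    context5 = ifelse(flip, COMPLEMENT[c3], c5),
    context3 = ifelse(flip, COMPLEMENT[c5], c3)
  )
}

## Construct one indel record realizing an ID-83 channel. Junction bases are
## constrained so the intended repeat count / microhomology length is exact.
make_indel_record <- function(channel) {
  parts <- strsplit(channel, ":", fixed = TRUE)[[1]]
  len_class <- as.integer(parts[1])
  kind <- if (parts[2] == "Del") "deletion" else "insertion"
  sub <- parts[3]
  num <- as.integer(parts[4])
  fl <- SIM_FLANK

  if (sub %in% c("C", "T")) {
    seq <- sub
    f5 <- paste0(rand_seq(fl - 1L), rand_bases(1, exclude = sub))
    f3 <- paste0(strrep(sub, num), rand_bases(1, exclude = sub),
                 rand_seq(fl - num - 1L))
  } else if (sub == "R") {
    L <- len_class
    motif <- paste(rand_bases(L), collapse = "")
    first <- substr(motif, 1, 1)
    last <- substr(motif, L, L)
    f3 <- paste0(strrep(motif, num), rand_bases(1, exclude = first),
                 rand_seq(fl - num * L - 1L))
    f5 <- paste0(rand_seq(fl - 1L), rand_bases(1, exclude = last))
    seq <- motif
  } else {  # microhomology deletion
    L <- if (len_class == 5L && num == 5L) 6L else max(len_class, num + 1L)
    seq <- paste(rand_bases(L), collapse = "")
    after_mh <- substr(seq, num + 1L, num + 1L)
    f3 <- paste0(substr(seq, 1L, num), rand_bases(1, exclude = after_mh),
                 rand_seq(fl - num - 1L))
    f5 <- paste0(rand_seq(fl - 1L),
                 rand_bases(1, exclude = substr(seq, L, L)))
  }

  if (runif(1) < 0.5) {  # emit on the opposite strand
    tmp <- revcomp(f5)
    f5 <- revcomp(f3)
    f3 <- tmp
    seq <- revcomp(seq)
  }
  list(kind = kind, sequence = seq, flank5 = f5, flank3 = f3)
}

emit_indel_records <- function(sample_id, counts) {
  counts <- counts[counts > 0]
  channel <- rep(names(counts), counts)
  n <- length(channel)
  if (n == 0) {
    return(tibble::tibble(sample_id = character(), chromosome = character(),
                          position = integer(), kind = character(),
                          sequence = character(), flank5 = character(),
                          flank3 = character()))
  }
  recs <- lapply(channel, make_indel_record)
  tibble::tibble(
    sample_id = sample_id,
    chromosome = sample(TOY_CHROMS, n, replace = TRUE),
    position = sample.int(TOY_CHROM_LENGTH - 200L, n) + 100L,
    kind = vapply(recs, `[[`, character(1), "kind"),
    sequence = vapply(recs, `[[`, character(1), "sequence"),
    flank5 = vapply(recs, `[[`, character(1), "flank5"),
    flank3 = vapply(recs, `[[`, character(1), "flank3")
  )
}

SIM_SIZE_RANGES <- list(
  "0-100kb" = c(1e3, 1e5), "100kb-1Mb" = c(1e5 + 1, 1e6),
  "1-10Mb" = c(1e6 + 1, 1e7), "10-40Mb" = c(1e7 + 1, 4e7),
  ">40Mb" = c(4e7 + 1, 5.5e7), ">1Mb" = c(1e6 + 1, 3e7)
)

make_segment <- function(channel) {
  parts <- strsplit(channel, ":", fixed = TRUE)[[1]]
  tcn <- switch(parts[1], "0" = 0L, "1" = 1L, "2" = 2L,
                "3-4" = sample(3:4, 1), "5-8" = sample(5:8, 1),
                "9+" = sample(9:12, 1))
  if (parts[2] == "HET") {
    minor <- sample.int(tcn %/% 2L, 1)
    major <- tcn - minor
  } else {
    minor <- 0L
    major <- tcn
  }
  rng <- SIM_SIZE_RANGES[[parts[3]]]
  size <- sample.int(rng[2] - rng[1] + 1L, 1) + rng[1] - 1L
  start <- sample.int(TOY_CHROM_LENGTH - size, 1)
  c(major = major, minor = minor, start = start, end = start + size - 1L)
}

emit_segment_records <- function(sample_id, counts) {
  counts <- counts[counts > 0]
  channel <- rep(names(counts), counts)
  n <- length(channel)
  if (n == 0) {
    return(tibble::tibble(sample_id = character(), chromosome = character(),
                          start = integer(), end = integer(),
                          major_cn = integer(), minor_cn = integer()))
  }
  segs <- vapply(channel, make_segment, numeric(4))
  tibble::tibble(
    sample_id = sample_id,
    chromosome = sample(TOY_CHROMS, n, replace = TRUE),
    start = as.integer(segs["start", ]),
    end = as.integer(segs["end", ]),
    major_cn = as.integer(segs["major", ]),
    minor_cn = as.integer(segs["minor", ])
  )
}

#' Catalogs and features for a simulated cohort
#'
#' Convenience pipeline: classifies a cohort's records into channel catalogs
#' (or uses the catalog-level counts directly) and derives the six features.
#'
#' @param cohort An `hrd_cohort` from [simulate_cohort()].
#' @param del5mh_as_count Passed to [derive_features()].
#' @return `cohort_catalogs()`: the long catalog tibble;
#'   `cohort_features()`: the feature tibble.
#' @export
cohort_catalogs <- function(cohort) {
  stopifnot(inherits(cohort, "hrd_cohort"))
  if (cohort$level == "catalog") return(cohort$catalogs)
  build_catalogs(cohort$mutations, cohort$indels, cohort$segments)
}

#' @rdname cohort_catalogs
#' @export
cohort_features <- function(cohort, del5mh_as_count = TRUE) {
  derive_features(cohort_catalogs(cohort), assay = cohort$assay,
                  del5mh_as_count = del5mh_as_count)
}

#' Synthetic exome target intervals on the toy genome
#'
#' Uniformly placed fixed-width targets covering roughly
#' `n_targets * width / 180 Mb` of the toy genome (about 1% at the
#' defaults), mimicking an exome capture design for downsampling tests.
#'
#' @param n_targets Number of targets.
#' @param width Target width in bp.
#' @param seed Integer seed.
#' @return Merged target tibble (`chromosome`, `start`, `end`, 0-based
#'   half-open).
#' @export
toy_exome_targets <- function(n_targets = 900, width = 2000, seed = 1) {
  withr::with_seed(seed, {
    start <- sample.int(TOY_CHROM_LENGTH - width - 1L, n_targets,
                        replace = TRUE)
    merge_intervals(tibble::tibble(
      chromosome = sample(TOY_CHROMS, n_targets, replace = TRUE),
      start = start, end = start + width
    ))
  })
}

#' @export
print.hrd_cohort <- function(x, ...) {
  cat("Synthetic cohort (", x$assay, ", ", x$level, " level): ",
      sum(x$labels$label == "HRD"), " HRD / ",
      sum(x$labels$label == "HRP"), " HRP samples\n", sep = "")
  if (x$level == "records") {
    cat("  ", nrow(x$mutations), " substitutions, ", nrow(x$indels),
        " indels, ", nrow(x$segments), " CN segments\n", sep = "")
  }
  invisible(x)
}
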