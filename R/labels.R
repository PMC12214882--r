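#' Assign ground-truth HRD/HRP labels from genomic annotations
#'
#' Applies the training-label rule: a sample is HRD if its genomic scar
#' (HRD) score meets the cancer-type threshold — at least 42 for breast, at
#' least 63 for ovarian — or if it harbors a germline/somatic/epigenetic
#' alteration in BRCA1 or BRCA2. All other samples are HRP.
#'
#' @param annotations Tibble with columns `sample_id`, and at least one of
#'   `hrd_score` (integer, NA allowed) and `brca_defect` (logical);
#'   `cancer_type` ("breast"/"ovarian") is required wherever a non-missing
#'   `hrd_score` is the only evidence.
#' @return The input tibble with an added `label` column ("HRD"/"HRP").
#' @examples
#' ann <- tibble::tibble(sample_id = c("a", "b", "c"),
#'                       hrd_score = c(42L, 41L, 50L),
#'                       brca_defect = c(FALSE, FALSE, TRUE),
#'                       cancer_type = "breast")
#' annotate_ground_truth(ann)$label  # "HRD" "HRP" "HRD"
#' @export
annotate_ground_truth <- function(annotations) {
  stopifnot("sample_id" %in% names(annotations))
  n <- nrow(annotations)
  score <- annotations[["hrd_score"]] %||% rep(NA_integer_, n)
  brca <- annotations[["brca_defect"]] %||% rep(FALSE, n)
  brca[is.na(brca)] <- FALSE
  ctype <- annotations[["cancer_type"]] %||% rep(NA_character_, n)

  if (all(is.na(score)) && !any(brca)) {
    if (!("hrd_score" %in% names(annotations)) &&
        !("brca_defect" %in% names(annotations))) {
      stop("annotations need at least one of hrd_score or brca_defect",
           call. = FALSE)
    }
  }
  needs_type <- !is.na(score) & !brca & is.na(ctype)
  if (any(needs_type)) {
    stop("cancer_type is required to interpret hrd_score for sample(s) ",
         paste(utils::head(annotations$sample_id[needs_type], 3),
               collapse = ", "),
         " (thresholds differ: 42 breast, 63 ovarian)", call. = FALSE)
  }
  bad_type <- !is.na(ctype) & !(ctype %in% c("breast", "ovarian"))
  if (any(bad_type)) {
    stop("unknown cancer_type '", ctype[bad_type][1],
         "'; expected 'breast' or 'ovarian'", call. = FALSE)
  }
  threshold <- ifelse(ctype == "ovarian", 63L, 42L)
  score_hrd <- !is.na(score) & !is.na(ctype) & score >= threshold
  annotations$label <- ifelse(score_hrd | brca, "HRD", "HRP")
  annotations
}
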