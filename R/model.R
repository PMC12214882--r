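#' Fit the linear-SVM HRD classifier
#'
#' Trains a linear-kernel, L2-regularized support vector machine on the six
#' genomic features. Features are z-scored on the training set; the
#' regularization constant C is chosen from `c_grid` by stratified 10-fold
#' cross-validation maximizing mean held-out AUC; the final SVM is refit on
#' all training data at the chosen C; and a Platt sigmoid mapping decision
#' values to HRD probabilities is fit on the pooled cross-validated decision
#' values. The whole procedure is deterministic given `seed`.
#'
#' @param features Feature tibble from [derive_features()] (columns
#'   `sample_id`, the six features, `assay`).
#' @param labels Tibble with columns `sample_id` and `label` ("HRD"/"HRP").
#' @param cancer_type `"breast"` or `"ovarian"`, recorded on the model.
#' @param c_grid Candidate C values.
#' @param n_folds Cross-validation folds (default 10); reduced with a warning
#'   when a class has fewer samples than folds.
#' @param seed Integer seed controlling fold assignment.
#' @param threshold Probability threshold stored as the model's operating
#'   point (HRD iff probability >= threshold; default 0.50).
#' @return An object of class `hrd_model`; see [tidy.hrd_model()] and
#'   [glance.hrd_model()] for broom-style summaries.
#' @export
hrd_fit <- function(features, labels, cancer_type = c("breast", "ovarian"),
                    c_grid = c(0.01, 0.1, 1, 10, 100), n_folds = 10,
                    seed = 1, threshold = 0.5) {
  cancer_type <- match.arg(cancer_type)
  dat <- dplyr::inner_join(features, labels[, c("sample_id", "label")],
                           by = "sample_id")
  if (nrow(dat) < nrow(features)) {
    warning(nrow(features) - nrow(dat), " sample(s) without a label were ",
            "dropped from training", call. = FALSE)
  }
  if (!all(dat$label %in% c("HRD", "HRP"))) {
    stop("labels must be 'HRD' or 'HRP'", call. = FALSE)
  }
  y <- factor(dat$label, levels = c("HRP", "HRD"))
  counts <- table(y)
  if (any(counts < 2)) {
    stop("need at least 2 samples per class to train; got ",
         counts[["HRD"]], " HRD and ", counts[["HRP"]], " HRP",
         call. = FALSE)
  }
  assay <- unique(dat[["assay"]] %||% "WGS")
  if (length(assay) != 1) {
    stop("features mix assays (", paste(assay, collapse = ", "),
         "); train one model per assay", call. = FALSE)
  }

  x <- as.matrix(dat[, hrd_feature_names()])
  rownames(x) <- dat$sample_id
  mu <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("feature(s) ",
            paste(hrd_feature_names()[sds == 0], collapse = ", "),
            " are constant in training data; their scale is left at 1",
            call. = FALSE)
    sds[sds == 0] <- 1
  }
  z <- scale(x, center = mu, scale = sds)

  k <- min(n_folds, min(counts))
  if (k < n_folds) {
    warning("reducing folds from ", n_folds, " to ", k,
            " (smallest class has ", min(counts), " samples)", call. = FALSE)
  }
  folds <- withr::with_seed(seed, make_stratified_folds(y, k))

  cv <- lapply(c_grid, function(C) {
    fold_fit <- lapply(seq_len(k), function(f) {
      tr <- folds != f
      m <- fit_linear_svm(z[tr, , drop = FALSE], y[tr], C)
      dv <- drop(z[!tr, , drop = FALSE] %*% m$w) + m$b
      list(auc = auc_rank(y[!tr] == "HRD", dv), dv = dv,
           idx = which(!tr), w = m$w)
    })
    aucs <- vapply(fold_fit, `[[`, numeric(1), "auc")
    list(C = C, mean_auc = mean(aucs, na.rm = TRUE), folds = fold_fit)
  })
  mean_aucs <- vapply(cv, `[[`, numeric(1), "mean_auc")
  best <- which(mean_aucs == max(mean_aucs))[1]  # ties -> smallest C
  best_cv <- cv[[best]]

  cv_weights <- rowMeans(vapply(best_cv$folds, `[[`, numeric(ncol(z)), "w"))
  oof_dv <- numeric(nrow(z))
  for (ff in best_cv$folds) oof_dv[ff$idx] <- ff$dv
  calibration <- fit_platt_sigmoid(oof_dv, y == "HRD")

  final <- fit_linear_svm(z, y, c_grid[best])
  train_dv <- drop(z %*% final$w) + final$b
  train_prob <- plogis(calibration[1] * train_dv + calibration[2])

  structure(list(
    cancer_type = cancer_type,
    assay = assay,
    feature_order = hrd_feature_names(),
    scaler_means = unname(mu),
    scaler_sds = unname(sds),
    svm_weights = unname(final$w),
    svm_bias = final$b,
    calibration_params = unname(calibration),
    regularization_c = c_grid[best],
    threshold = threshold,
    training_seed = as.integer(seed),
    cv_weights = unname(cv_weights),
    cv_auc = best_cv$mean_auc,
    cv_grid = tibble::tibble(c = c_grid, mean_auc = mean_aucs),
    train_auc = auc_rank(y == "HRD", train_prob),
    n_train = nrow(z),
    n_hrd = unname(counts[["HRD"]]),
    n_hrp = unname(counts[["HRP"]]),
    version = as.character(utils::packageVersion("hrdsig"))
  ), class = "hrd_model")
}

make_stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in levels(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

fit_linear_svm <- function(z, y, C) {
  m <- e1071::svm(z, y, kernel = "linear", cost = C, scale = FALSE)
  w <- drop(t(m$coefs) %*% m$SV)
  b <- -m$rho
  ## orient so positive decision values mean HRD
  dv <- drop(z %*% w) + b
  pred <- predict(m, z)
  s <- if (mean(dv[pred == "HRD"]) >= mean(dv[pred == "HRP"])) 1 else -1
  list(w = s * w, b = s * b)
}

## Platt scaling with regularized targets, fitted by BFGS on the
## cross-entropy; robust when the classes are linearly separable.
fit_platt_sigmoid <- function(dv, y) {
  n1 <- sum(y)
  n0 <- sum(!y)
  t <- ifelse(y, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  nll <- function(par) {
    p <- plogis(par[1] * dv + par[2])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(t * log(p) + (1 - t) * log(1 - p))
  }
  fit <- stats::optim(c(1, 0), nll, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12))
  fit$par
}

#' AUC by the rank statistic
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney
#' U statistic, with ties handled by midranks. Equals the proportion of
#' positive/negative pairs ranked concordantly (ties counting one half).
#'
#' @param truth Logical (or 0/1) vector; TRUE marks HRD.
#' @param score Numeric scores (probabilities or decision values).
#' @return AUC in 0-1, or NA when `truth` has one class.
#' @export
auc_rank <- function(truth, score) {
  truth <- as.logical(truth)
  n1 <- sum(truth)
  n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Predict HRD probabilities for new samples
#'
#' Applies the stored scaler, linear decision function and Platt sigmoid to
#' a feature table and thresholds the calibrated probability into HRD/HRP
#' status.
#'
#' @param object An `hrd_model`.
#' @param features Feature tibble from [derive_features()].
#' @param threshold Probability threshold; defaults to the model's stored
#'   operating point (0.50). A sample is HRD iff probability >= threshold.
#' @param override_assay Set TRUE to score features whose `assay` differs
#'   from the model's (normally an error).
#' @param ... Unused.
#' @return Tibble with columns `sample_id`, `decision_value`, `probability`,
#'   `label`, `threshold`.
#' @export
predict.hrd_model <- function(object, features, threshold = NULL,
                              override_assay = FALSE, ...) {
  threshold <- threshold %||% object$threshold
  missing <- setdiff(object$feature_order, names(features))
  if (length(missing) > 0) {
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  f_assay <- unique(features[["assay"]] %||% object$assay)
  if (!override_assay && !identical(sort(f_assay), object$assay)) {
    stop("features carry assay ", paste(f_assay, collapse = "/"),
         " but the model was trained on ", object$assay,
         "; pass override_assay = TRUE to score anyway", call. = FALSE)
  }
  x <- as.matrix(features[, object$feature_order])
  z <- sweep(sweep(x, 2, object$scaler_means), 2, object$scaler_sds, "/")
  dv <- drop(z %*% object$svm_weights) + object$svm_bias
  p <- plogis(object$calibration_params[1] * dv +
                object$calibration_params[2])
  tibble::tibble(
    sample_id = as.character(features[["sample_id"]] %||%
                               seq_len(nrow(features))),
    decision_value = dv,
    probability = p,
    label = hrd_classify(p, threshold),
    threshold = threshold
  )
}

#' Threshold HRD probabilities into status calls
#'
#' @param probability Numeric vector of probabilities in 0-1.
#' @param threshold Decision threshold; a sample is HRD iff
#'   `probability >= threshold` (default 0.50).
#' @return Character vector of "HRD"/"HRP".
#' @export
hrd_classify <- function(probability, threshold = 0.5) {
  stopifnot(all(probability >= 0 & probability <= 1))
  ifelse(probability >= threshold, "HRD", "HRP")
}

#' Evaluate predictions against ground truth
#'
#' Computes ranking and thresholded classification metrics: AUC (rank
#' statistic over probabilities), and sensitivity, precision and F1 with HRD
#' as the positive class, from the confusion matrix at the given threshold
#' (or from supplied predicted labels).
#'
#' @param truth Character vector of true labels ("HRD"/"HRP").
#' @param probability Numeric probabilities aligned with `truth`.
#' @param predicted Optional predicted labels; derived from `probability`
#'   and `threshold` when NULL.
#' @param threshold Probability threshold used when `predicted` is NULL.
#' @return One-row tibble: `auc`, `sensitivity`, `precision`, `f1`, `tp`,
#'   `fp`, `fn`, `tn`, `n`. AUC is NA (with a message) when `truth` has a
#'   single class.
#' @export
hrd_evaluate <- function(truth, probability, predicted = NULL,
                         threshold = 0.5) {
  stopifnot(all(truth %in% c("HRD", "HRP")),
            length(probability) == length(truth))
  predicted <- predicted %||% hrd_classify(probability, threshold)
  auc <- auc_rank(truth == "HRD", probability)
  if (is.na(auc)) {
    message("truth contains a single class; AUC is undefined and reported ",
            "as NA")
  }
  tp <- sum(predicted == "HRD" & truth == "HRD")
  fp <- sum(predicted == "HRD" & truth == "HRP")
  fn <- sum(predicted == "HRP" & truth == "HRD")
  tn <- sum(predicted == "HRP" & truth == "HRP")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(sens) && !is.na(prec) && sens + prec > 0) {
    2 * prec * sens / (prec + sens)
  } else {
    NA_real_
  }
  tibble::tibble(auc = auc, sensitivity = sens, precision = prec, f1 = f1,
                 tp = tp, fp = fp, fn = fn, tn = tn, n = length(truth))
}

#' @export
print.hrd_model <- function(x, ...) {
  cat("Linear-SVM HRD classifier (", x$cancer_type, ", ", x$assay, ")\n",
      sep = "")
  cat("  trained on ", x$n_train, " samples (", x$n_hrd, " HRD / ",
      x$n_hrp, " HRP), C = ", x$regularization_c, "\n", sep = "")
  cat("  CV AUC ", round(x$cv_auc, 3), ", training AUC ",
      round(x$train_auc, 3), ", threshold ", x$threshold, "\n", sep = "")
  w <- round(x$svm_weights, 3)
  names(w) <- x$feature_order
  print(w)
  invisible(x)
}

#' Tidy the fitted classifier weights
#'
#' @param x An `hrd_model`.
#' @param ... Unused.
#' @return Tibble with one row per feature: `term`, `estimate` (final SVM
#'   weight on z-scored features), `cv_estimate` (mean weight across the
#'   cross-validation folds).
#' @method tidy hrd_model
#' @export
tidy.hrd_model <- function(x, ...) {
  tibble::tibble(term = x$feature_order, estimate = x$svm_weights,
                 cv_estimate = x$cv_weights)
}

#' One-row model summary
#'
#' @param x An `hrd_model`.
#' @param ... Unused.
#' @return One-row tibble with cohort sizes, chosen C, CV/training AUC and
#'   the operating threshold.
#' @method glance hrd_model
#' @export
glance.hrd_model <- function(x, ...) {
  tibble::tibble(cancer_type = x$cancer_type, assay = x$assay,
                 n_train = x$n_train, n_hrd = x$n_hrd, n_hrp = x$n_hrp,
                 regularization_c = x$regularization_c, cv_auc = x$cv_auc,
                 train_auc = x$train_auc, threshold = x$threshold)
}

#' Serialize / restore a trained model as versioned JSON
#'
#' All model fields are written with 17 significant digits so the numeric
#' state round-trips exactly.
#'
#' @param model An `hrd_model`.
#' @param path JSON file path.
#' @return `write_hrd_model()` returns `path` invisibly; `read_hrd_model()`
#'   returns the restored `hrd_model`.
#' @export
write_hrd_model <- function(model, path) {
  payload <- unclass(model)
  payload$cv_grid <- as.list(payload$cv_grid)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_hrd_model
#' @export
read_hrd_model <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  payload$cv_grid <- tibble::as_tibble(payload$cv_grid)
  payload$training_seed <- as.integer(payload$training_seed)
  structure(payload, class = "hrd_model")
}
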