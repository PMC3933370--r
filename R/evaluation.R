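#' Confusion counts from true and predicted labels
#'
#' The abnormal class is the positive class.
#'
#' @param truth,predicted Vectors of `"normal"`/`"abnormal"` (or +/-1).
#' @return A list with integer fields `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  t_pos <- encode_labels(truth) > 0
  p_pos <- encode_labels(predicted) > 0
  list(TP = sum(t_pos & p_pos), TN = sum(!t_pos & !p_pos),
       FP = sum(!t_pos & p_pos), FN = sum(t_pos & !p_pos))
}

#' Classification accuracy, sensitivity and specificity
#'
#' `CA = (TP + TN) / (TP + TN + FP + FN) * 100`,
#' `SEN = TP / (TP + FN) * 100` (abnormal recall),
#' `SPE = TN / (TN + FP) * 100` (normal recall). A metric whose
#' denominator is zero is undefined and reported as `NA`, never as 0.
#'
#' @param counts A list with fields `TP`, `TN`, `FP`, `FN`, e.g. from
#'   [confusion_counts()].
#' @return Named list with percentages `CA`, `SEN`, `SPE`.
#' @export
compute_metrics <- function(counts) {
  with(counts, {
    n <- TP + TN + FP + FN
    list(
      CA = if (n > 0) (TP + TN) / n * 100 else NA_real_,
      SEN = if (TP + FN > 0) TP / (TP + FN) * 100 else NA_real_,
      SPE = if (TN + FP > 0) TN / (TN + FP) * 100 else NA_real_
    )
  })
}

# Deterministic stratified / grouped fold assignment.
assign_folds <- function(labels, n_folds, split_mode, seed, subject = NULL) {
  n <- length(labels)
  fold <- integer(n)
  if (split_mode == "cycle_stratified") {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      if (length(idx) < n_folds) {
        stop(sprintf("class '%s' has %d cycles, fewer than n_folds = %d",
                     cls, length(idx), n_folds), call. = FALSE)
      }
      perm <- with_seed(seed + match(cls, sort(unique(labels))), sample(idx))
      fold[perm] <- rep_len(seq_len(n_folds), length(perm))
    }
  } else {
    if (is.null(subject)) stop("subject_grouped split requires a subject vector", call. = FALSE)
    subj <- unique(subject)
    if (length(subj) < n_folds) {
      stop(sprintf("%d subjects, fewer than n_folds = %d", length(subj), n_folds),
           call. = FALSE)
    }
    perm <- with_seed(seed, sample(subj))
    sf <- rep_len(seq_len(n_folds), length(perm))
    fold <- sf[match(subject, perm)]
  }
  fold
}

#' k-fold cross-validation of a feature table
#'
#' Splits the per-cycle feature table into `n_folds` folds (default 5),
#' trains on `n_folds - 1` of them and tests on the held-out fold,
#' rotating the test fold so every cycle is tested exactly once. Folds are
#' class-stratified by default; a subject-grouped mode keeps all cycles of
#' a subject in one fold, which avoids subject leakage and is the
#' recommended protocol when subject identity is known. Feature
#' standardization and all model fitting happen inside each training fold.
#' Per-fold accuracy/sensitivity/specificity are averaged arithmetically
#' across folds; pooled-count metrics are also reported for transparency.
#'
#' @param features Feature data frame from [extract_features()] (columns
#'   `chi`, `xi`, `zeta`, `alpha` as available, plus `label`).
#' @param feature_set `"set1"`, `"set2"` or `"set3"` (default): which
#'   nested feature set feeds the classifier.
#' @param classifier `"elm"` (default) or `"svm"`.
#' @param n_folds Number of folds (default 5).
#' @param split_mode `"cycle_stratified"` (default) or `"subject_grouped"`.
#' @param seed Integer seed controlling fold assignment and ELM
#'   initialization (default 1).
#' @param subject Optional subject id per row (required for
#'   `subject_grouped`).
#' @param ... Passed to [elm_train()] (`n_hidden`) or [svm_train()]
#'   (`C`, `gamma`).
#' @return An object of class `evaluation_report`: list with `per_fold`
#'   (data frame of counts and metrics), `mean_CA`, `mean_SEN`,
#'   `mean_SPE`, `pooled` (metrics on summed counts), `fold` (assignment
#'   per row), and provenance tags.
#' @export
cross_validate <- function(features, feature_set = c("set3", "set1", "set2"),
                           classifier = c("elm", "svm"), n_folds = 5L,
                           split_mode = c("cycle_stratified", "subject_grouped"),
                           seed = 1L, subject = NULL, ...) {
  feature_set <- match.arg(feature_set)
  classifier <- match.arg(classifier)
  split_mode <- match.arg(split_mode)
  cols <- feature_set_columns(feature_set)
  missing_cols <- setdiff(cols, names(features))
  if (length(missing_cols)) {
    stop(sprintf("feature table lacks columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  keep <- stats::complete.cases(features[cols])
  if (!all(keep)) {
    message(sprintf("dropping %d cycles with missing feature values", sum(!keep)))
    features <- features[keep, , drop = FALSE]
    if (!is.null(subject)) subject <- subject[keep]
  }
  x <- as_feature_matrix(features[cols])
  labels <- as.character(features$label)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present in the feature table", call. = FALSE)
  }

  fold <- assign_folds(labels, n_folds, split_mode, seed, subject)
  per_fold <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    tr <- fold != k
    te <- !tr
    if (classifier == "elm") {
      model <- elm_train(x[tr, , drop = FALSE], labels[tr],
                         rng_seed = seed * 100L + k, ...)
      pred <- elm_predict(model, x[te, , drop = FALSE])$label
    } else {
      model <- svm_train(x[tr, , drop = FALSE], labels[tr], ...)
      pred <- svm_predict(model, x[te, , drop = FALSE])$label
    }
    cc <- confusion_counts(labels[te], pred)
    m <- compute_metrics(cc)
    per_fold[[k]] <- data.frame(fold = k, TP = cc$TP, TN = cc$TN,
                                FP = cc$FP, FN = cc$FN,
                                CA = m$CA, SEN = m$SEN, SPE = m$SPE)
  }
  per_fold <- do.call(rbind, per_fold)
  pooled_counts <- list(TP = sum(per_fold$TP), TN = sum(per_fold$TN),
                        FP = sum(per_fold$FP), FN = sum(per_fold$FN))
  structure(list(per_fold = per_fold,
                 mean_CA = mean(per_fold$CA, na.rm = TRUE),
                 mean_SEN = mean(per_fold$SEN, na.rm = TRUE),
                 mean_SPE = mean(per_fold$SPE, na.rm = TRUE),
                 pooled = compute_metrics(pooled_counts),
                 pooled_counts = pooled_counts,
                 fold = fold, feature_set = feature_set,
                 classifier = classifier, seed = as.integer(seed),
                 split_mode = split_mode),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s / %s, %d folds (%s, seed %d)\n",
              x$classifier, x$feature_set, nrow(x$per_fold), x$split_mode,
              x$seed))
  print(x$per_fold, row.names = FALSE)
  cat(sprintf("mean: CA %.2f%%  SEN %.2f%%  SPE %.2f%%\n",
              x$mean_CA, x$mean_SEN, x$mean_SPE))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  payload <- list(classifier = report$classifier,
                  feature_set = report$feature_set,
                  split_mode = report$split_mode, seed = report$seed,
                  per_fold = report$per_fold,
                  mean = list(CA = report$mean_CA, SEN = report$mean_SEN,
                              SPE = report$mean_SPE),
                  pooled = report$pooled,
                  pooled_counts = report$pooled_counts)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}
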