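# Feature-ranking harness: patient-level 80/20 split, per-feature binary
# classification (linear SVM or KNN), ranking by test accuracy.

#' Patient-level split specification
#'
#' The train/test split is always by patient, never by scan: all B-scans of
#' one subject land on the same side, so no test patient's anatomy leaks
#' into training.
#'
#' @param train_fraction Proportion of patients used for training
#'   (default 0.80).
#' @param seed Integer RNG seed for the shuffle (`NULL` = current stream).
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.8, seed = NULL) {
  if (!is.numeric(train_fraction) || length(train_fraction) != 1L ||
      train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must lie strictly between 0 and 1")
  structure(list(train_fraction = train_fraction, seed = seed),
            class = "split_spec")
}

#' Split patients into training and testing sets
#'
#' Shuffles the unique patient ids under the spec's seed and assigns the
#' first `round(train_fraction * n)` to training (clamped so both sides are
#' non-empty). With 148 patients and the default 0.80 fraction this gives
#' the canonical 118 training / 30 testing subjects.
#'
#' @param patients Character/factor vector of patient ids, or a manifest
#'   data.frame with a `patient_id` column (duplicates collapse).
#' @param spec A [split_spec()].
#' @return List with character vectors `train_ids` and `test_ids`
#'   (disjoint, jointly exhaustive).
#' @export
split_patients <- function(patients, spec = split_spec()) {
  if (is.data.frame(patients)) patients <- patients$patient_id
  ids <- unique(as.character(patients))
  n <- length(ids)
  if (n < 2L) stopf("need at least 2 patients to split")
  n_train <- min(max(1L, round(spec$train_fraction * n)), n - 1L)
  shuffled <- local_seed(spec$seed, sample(ids))
  list(train_ids = sort(shuffled[seq_len(n_train)]),
       test_ids = sort(shuffled[(n_train + 1L):n]))
}

labels12_to_pm1 <- function(labels) ifelse(check_labels(labels) == 1L, 1L, -1L)
pm1_to_labels12 <- function(y) ifelse(y > 0, 1L, 2L)

#' Train and evaluate a per-scan classifier on one feature
#'
#' Fits a binary classifier on the training scans only and evaluates it on
#' the test scans. `kind = "svm"` fits a linear-margin SVM
#' (`e1071::svm`, linear kernel); test scans are labeled by the sign of the
#' decision function `w'x + b` (+1 = cystic). `kind = "knn"` uses a
#' k-nearest-neighbour vote (`class::knn`, Euclidean metric, default
#' `k = 5`). When both classes occur in the test split, a continuous score
#' (SVM decision value / KNN positive-vote fraction) also yields an ROC and
#' AUC.
#'
#' @param features_train,features_test Numeric matrices, one row per scan.
#' @param labels_train,labels_test States over \{1, 2\} (1 = cystic), or
#'   \{+1, -1\} which are mapped (+1 = cystic).
#' @param kind `"svm"` or `"knn"`.
#' @param k Neighbourhood size for `"knn"`.
#' @return An `eval_report` (see [confusion_metrics()]) with extra fields
#'   `scores`, `auc` and `roc` when computable.
#' @export
train_eval_classifier <- function(features_train, labels_train,
                                  features_test, labels_test,
                                  kind = c("svm", "knn"), k = 5L) {
  kind <- match.arg(kind)
  features_train <- as.matrix(features_train)
  features_test <- as.matrix(features_test)
  norm12 <- function(l) if (all(l %in% c(-1, 1))) pm1_to_labels12(l) else check_labels(l)
  ltr <- norm12(labels_train); lte <- norm12(labels_test)
  if (nrow(features_train) != length(ltr) || nrow(features_test) != length(lte))
    stopf("features and labels must have matching lengths")
  if (length(unique(ltr)) < 2L)
    stopf("degenerate training set: only one class present")

  if (kind == "svm") {
    y <- factor(labels12_to_pm1(ltr), levels = c(-1L, 1L))
    fit <- e1071::svm(features_train, y, kernel = "linear", scale = FALSE)
    dvm <- attr(stats::predict(fit, features_test, decision.values = TRUE),
                "decision.values")
    dv <- dvm[, 1L]
    # e1071's decision value is positive toward the class named first in the
    # column label; orient so positive always means cystic (+1).
    if (startsWith(colnames(dvm)[1L], "-1")) dv <- -dv
    pred <- pm1_to_labels12(sign(dv) + 0.5 * (dv == 0))
    scores <- dv
  } else {
    votes <- class::knn(features_train, features_test,
                        cl = factor(ltr, levels = c(1L, 2L)),
                        k = min(k, nrow(features_train)), prob = TRUE)
    prob_win <- attr(votes, "prob")
    pred <- as.integer(as.character(votes))
    scores <- ifelse(pred == 1L, prob_win, 1 - prob_win)
  }

  rep <- confusion_metrics(pred, lte)
  rep$scores <- as.numeric(scores)
  if (length(unique(lte)) == 2L) {
    ra <- roc_auc(rep$scores, lte)
    rep$auc <- ra$auc
    rep$roc <- ra$roc
  }
  rep
}

#' Rank feature-extraction methods by test accuracy
#'
#' The selection harness: one patient-level split, then for every method an
#' identical extract-train-evaluate pass, producing a per-method evaluation
#' report and an ordering by test accuracy (descending, ties broken
#' alphabetically by method name).
#'
#' @param manifest A labeled manifest (see [read_manifest()]) whose `path`
#'   column points to loadable images.
#' @param methods Character vector of feature methods
#'   (see [feature_methods()]).
#' @param kind Classifier kind, `"svm"` or `"knn"`.
#' @param split A [split_spec()].
#' @param configs Optional named list of per-method config lists passed to
#'   [extract_feature()].
#' @param crop Optional [crop_spec()] applied to every image before
#'   extraction.
#' @return An object of class `feature_ranking`: list with `reports` (named
#'   list of eval reports), `accuracies` (named numeric), `ordering`
#'   (method names, best first) and `split`.
#' @export
rank_features <- function(manifest, methods, kind = c("svm", "knn"),
                          split = split_spec(), configs = list(),
                          crop = NULL) {
  kind <- match.arg(kind)
  if (length(methods) < 1L) stopf("need at least one method")
  if (is.null(manifest$label) || any(is.na(manifest$label)))
    stopf("rank_features requires a fully labeled manifest")
  sp <- split_patients(manifest, split)
  in_train <- manifest$patient_id %in% sp$train_ids

  images <- lapply(manifest$path, load_image)
  if (!is.null(crop)) images <- lapply(images, crop_margins, spec = crop)

  reports <- list()
  for (m in methods) {
    feats <- t(vapply(images, function(img)
      extract_feature(img, m, configs[[m]] %||% list())$values,
      numeric(extract_feature(images[[1L]], m, configs[[m]] %||% list())$K)))
    # Derive a per-method classifier seed from the split seed so the whole
    # harness (including KNN tie-breaking) is reproducible.
    mseed <- if (is.null(split$seed)) NULL
             else split$seed + match(m, methods)
    reports[[m]] <- local_seed(mseed, train_eval_classifier(
      feats[in_train, , drop = FALSE], manifest$label[in_train],
      feats[!in_train, , drop = FALSE], manifest$label[!in_train],
      kind = kind))
  }
  acc <- vapply(reports, `[[`, numeric(1), "accuracy")
  ordering <- names(acc)[order(-acc, names(acc))]  # ties break alphabetically
  structure(list(reports = reports, accuracies = acc,
                 ordering = ordering, split = sp, kind = kind),
            class = "feature_ranking")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.feature_ranking <- function(x, ...) {
  cat("<feature_ranking> (test accuracy, best first)\n")
  for (m in x$ordering)
    cat(sprintf("  %-10s %.3f\n", m, x$accuracies[[m]]))
  invisible(x)
}
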