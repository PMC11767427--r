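#' Stratified train/test split for the control vs osteopenia classifier
#'
#' Restricts the cohort to two stages and splits each class separately:
#' `round(fraction * n_class)` samples per class go to training, the rest
#' to test, so class proportions are preserved to within one sample. The
#' split is deterministic under `seed`.
#'
#' @param x staged `ow_cohort`.
#' @param classes the two stages to classify (default control vs
#'   osteopenia).
#' @param fraction training fraction (default 0.70).
#' @param seed RNG seed.
#' @return list with character vectors `train_ids` and `test_ids`.
#' @export
split_train_test <- function(x, classes = c("control", "osteopenia"),
                             fraction = 0.70, seed = 1L) {
  stopifnot(inherits(x, "ow_cohort"), length(classes) == 2)
  st <- cohort_stage(x)
  ids <- rownames(x$abundance)
  train <- character(0)
  test <- character(0)
  set.seed(seed)
  for (cl in classes) {
    cl_ids <- ids[st == cl]
    if (length(cl_ids) < 4) {
      stop("class '", cl, "' has fewer than 4 samples")
    }
    n_tr <- round(fraction * length(cl_ids))
    pick <- sample(cl_ids, n_tr)
    train <- c(train, pick)
    test <- c(test, setdiff(cl_ids, pick))
  }
  list(train_ids = train, test_ids = test)
}

#' Train, select important metabolites, retrain, and evaluate on held-out data
#'
#' A 500-tree random forest is fit on the training samples over the
#' candidate features (typically the differential metabolites between the
#' control and osteopenia groups). Gini impurity importances are
#' normalized to percent shares; features with a share at or above
#' `threshold` are retained (falling back to the top 3 with a warning when
#' none qualifies), a second forest is fit on the retained features only,
#' and out-of-sample class probabilities on the test set yield the ROC
#' curve with a DeLong 95% confidence interval on the AUC. Feature
#' selection sees training data only; test labels are touched exclusively
#' in the final evaluation.
#'
#' @param x staged `ow_cohort`.
#' @param features candidate metabolite ids (>= 2).
#' @param split [split_train_test()] result; computed from `seed` when
#'   NULL.
#' @param threshold importance-share selection cut as a fraction (default
#'   0.05, i.e. 5%).
#' @param seed RNG seed for the split and both forests.
#' @param n_trees trees per forest (default 500).
#' @param classes the two stages being classified.
#' @return `ow_biomarker_panel`: `selected`, `importance` (percent shares
#'   over all candidates), `train_ids`, `test_ids`, `roc`
#'   (threshold/FPR/TPR table), `auc`, `auc_ci`, `test_scores`,
#'   `test_labels` (1 = second class).
#' @export
train_select_retrain <- function(x, features, split = NULL,
                                 threshold = 0.05, seed = 1L,
                                 n_trees = 500,
                                 classes = c("control", "osteopenia")) {
  stopifnot(inherits(x, "ow_cohort"))
  features <- intersect(features, colnames(x$abundance))
  if (length(features) < 2) stop("need >= 2 candidate features")
  if (is.null(split)) split <- split_train_test(x, classes, seed = seed)
  st <- stats::setNames(cohort_stage(x), rownames(x$abundance))
  y_train <- factor(as.character(st[split$train_ids]), levels = classes)
  y_test <- factor(as.character(st[split$test_ids]), levels = classes)
  x_train <- x$abundance[split$train_ids, features, drop = FALSE]
  x_test <- x$abundance[split$test_ids, features, drop = FALSE]

  set.seed(seed)
  rf1 <- randomForest::randomForest(x_train, y_train, ntree = n_trees)
  imp <- randomForest::importance(rf1)[, "MeanDecreaseGini"]
  share <- 100 * imp / sum(imp)
  selected <- names(share)[share >= 100 * threshold]
  if (length(selected) == 0) {
    warning("no feature reaches the importance threshold; keeping top 3")
    selected <- names(sort(share, decreasing = TRUE))[
      seq_len(min(3, length(share)))
    ]
  }
  set.seed(seed + 1L)
  rf2 <- randomForest::randomForest(
    x_train[, selected, drop = FALSE], y_train, ntree = n_trees
  )
  prob <- stats::predict(
    rf2, x_test[, selected, drop = FALSE], type = "prob"
  )[, classes[2]]
  roc_obj <- pROC::roc(
    response = y_test, predictor = prob,
    levels = classes, direction = "<", quiet = TRUE
  )
  # pROC warns that the DeLong CI degenerates at AUC exactly 1; that is
  # expected behaviour, not a user-actionable condition
  ci <- suppressWarnings(
    as.numeric(pROC::ci.auc(roc_obj, method = "delong"))
  )
  structure(
    list(
      selected = selected,
      importance = share,
      threshold = threshold,
      train_ids = split$train_ids, test_ids = split$test_ids,
      roc = data.frame(
        threshold = roc_obj$thresholds,
        fpr = 1 - roc_obj$specificities,
        tpr = roc_obj$sensitivities
      ),
      auc = as.numeric(pROC::auc(roc_obj)),
      auc_ci = c(lower = ci[1], upper = ci[3]),
      test_scores = stats::setNames(prob, split$test_ids),
      test_labels = stats::setNames(
        as.integer(y_test == classes[2]), split$test_ids
      )
    ),
    class = "ow_biomarker_panel"
  )
}

#' Baseline classifier on bone-turnover markers
#'
#' Fits the same random forest on the three classical bone-turnover
#' markers (osteocalcin, PINP, beta-CTX, taken from the cohort metadata)
#' using an identical train/test split, providing the comparator scores
#' for [compare_auc()].
#'
#' @param x staged `ow_cohort` whose metadata carries the marker columns.
#' @param split [split_train_test()] result (share it with the metabolite
#'   panel for a paired comparison).
#' @param btm_columns metadata column names of the markers.
#' @param seed,n_trees,classes as in [train_select_retrain()].
#' @return list with `test_scores`, `test_labels`, `auc`.
#' @export
btm_baseline <- function(x, split,
                         btm_columns = c("osteocalcin", "PINP", "bCTX"),
                         seed = 1L, n_trees = 500,
                         classes = c("control", "osteopenia")) {
  stopifnot(inherits(x, "ow_cohort"))
  miss <- setdiff(btm_columns, names(x$metadata))
  if (length(miss) > 0) stop("metadata lacks BTM column(s): ", miss[1])
  st <- stats::setNames(cohort_stage(x), rownames(x$abundance))
  md <- x$metadata[match(rownames(x$abundance), x$metadata$sample_id), ]
  feat <- as.matrix(md[, btm_columns, drop = FALSE])
  rownames(feat) <- rownames(x$abundance)
  y_train <- factor(as.character(st[split$train_ids]), levels = classes)
  y_test <- factor(as.character(st[split$test_ids]), levels = classes)
  set.seed(seed + 2L)
  rf <- randomForest::randomForest(
    feat[split$train_ids, , drop = FALSE], y_train, ntree = n_trees
  )
  prob <- stats::predict(
    rf, feat[split$test_ids, , drop = FALSE], type = "prob"
  )[, classes[2]]
  roc_obj <- pROC::roc(
    response = y_test, predictor = prob,
    levels = classes, direction = "<", quiet = TRUE
  )
  list(
    test_scores = stats::setNames(prob, split$test_ids),
    test_labels = stats::setNames(
      as.integer(y_test == classes[2]), split$test_ids
    ),
    auc = as.numeric(pROC::auc(roc_obj))
  )
}

#' Paired comparison of two AUCs on the same test samples
#'
#' DeLong's test for two correlated ROC curves: both score vectors must be
#' computed on the identical test samples. Returns the AUC difference
#' (model A minus model B), the z statistic and the two-sided p-value.
#' Swapping the models negates the difference and leaves the p-value
#' unchanged.
#'
#' @param labels 0/1 outcome vector (or named vector; names must match the
#'   score names when present).
#' @param scores_a,scores_b numeric score vectors on the same samples.
#' @return list with `delta_auc`, `auc_a`, `auc_b`, `z`, `p_value`,
#'   `method`.
#' @export
compare_auc <- function(labels, scores_a, scores_b) {
  if (length(scores_a) != length(labels) ||
      length(scores_b) != length(labels)) {
    stop("scores and labels must cover the same test samples")
  }
  if (!is.null(names(scores_a)) && !is.null(names(scores_b)) &&
      !identical(sort(names(scores_a)), sort(names(scores_b)))) {
    stop("the two models were scored on different test samples")
  }
  if (!is.null(names(scores_a)) && !is.null(names(scores_b))) {
    scores_b <- scores_b[names(scores_a)]
    if (!is.null(names(labels))) labels <- labels[names(scores_a)]
  }
  labels <- as.integer(labels)
  ra <- pROC::roc(labels, as.numeric(scores_a),
    levels = c(0, 1), direction = "<", quiet = TRUE
  )
  rb <- pROC::roc(labels, as.numeric(scores_b),
    levels = c(0, 1), direction = "<", quiet = TRUE
  )
  auc_a <- as.numeric(pROC::auc(ra))
  auc_b <- as.numeric(pROC::auc(rb))
  if (isTRUE(all.equal(as.numeric(scores_a), as.numeric(scores_b)))) {
    return(list(
      delta_auc = 0, auc_a = auc_a, auc_b = auc_b,
      z = 0, p_value = 1, method = "delong"
    ))
  }
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  list(
    delta_auc = auc_a - auc_b, auc_a = auc_a, auc_b = auc_b,
    z = unname(tst$statistic), p_value = tst$p.value,
    method = "delong"
  )
}
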