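# Frame-level posture classification: standing (1) vs lying (0) from the
# nine-feature vector. The shipped default is the RBF-kernel SVM with
# C = 1, gamma = 0.1; decision tree, random forest and gradient boosting
# are available behind the same interface for comparison.

#' Classifier specification
#'
#' Family plus hyperparameters for the posture classifier. Defaults per
#' family: SVM `C = 1`, RBF kernel, `gamma = 0.1`; decision tree
#' `max_depth = 5`, `min_samples_split = 2`; random forest
#' `n_estimators = 100`, `max_features = "sqrt"`, `max_depth = 10`;
#' gradient boosting (`"xgboost"`) `n_estimators = 200`,
#' `learning_rate = 0.0045`, `max_depth = 4`.
#'
#' @param family One of `"svm"`, `"decision_tree"`, `"random_forest"`,
#'   `"xgboost"`.
#' @param ... Hyperparameter overrides for the chosen family.
#' @param rng_seed Seed for any stochastic part of training (bootstrap,
#'   feature subsampling); fitting is deterministic given the seed.
#' @return A `classifier_spec` object.
#' @export
#' @examples
#' classifier_spec("svm")
#' classifier_spec("random_forest", n_estimators = 50)
classifier_spec <- function(family = c("svm", "decision_tree",
                                       "random_forest", "xgboost"),
                            ..., rng_seed = 1L) {
  family <- match.arg(family)
  defaults <- switch(family,
    svm = list(C = 1.0, kernel = "rbf", gamma = 0.1),
    decision_tree = list(max_depth = 5L, min_samples_split = 2L),
    random_forest = list(n_estimators = 100L, max_features = "sqrt",
                         max_depth = 10L, min_samples_split = 2L),
    xgboost = list(n_estimators = 200L, learning_rate = 0.0045,
                   max_depth = 4L, lambda = 1))
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown hyperparameter(s) for ", family, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  hp <- utils::modifyList(defaults, over)
  if (family == "svm") {
    if (hp$C <= 0 || hp$gamma <= 0) stop("C and gamma must be > 0", call. = FALSE)
    if (!identical(hp$kernel, "rbf"))
      stop("only the RBF kernel is implemented", call. = FALSE)
  }
  for (k in intersect(c("max_depth", "min_samples_split", "n_estimators"),
                      names(hp)))
    if (hp[[k]] < 1) stop(k, " must be a positive integer", call. = FALSE)
  structure(list(family = family, hyperparameters = hp,
                 rng_seed = as.integer(rng_seed)),
            class = "classifier_spec")
}

.feature_matrix <- function(table) {
  if (is.matrix(table)) {
    if (ncol(table) != 9L) stop("feature matrix must have 9 columns",
                                call. = FALSE)
    colnames(table) <- feature_names()
    return(table)
  }
  miss <- setdiff(feature_names(), names(table))
  if (length(miss))
    stop("feature table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  as.matrix(table[, feature_names()])
}

#' Train a posture classifier
#'
#' Fits the chosen family on a labeled feature table. The normalization
#' transform (see [fit_normalizer()]) is fitted on the training features
#' and stored in the model, so inference inputs are transformed
#' identically. Training is deterministic under `spec$rng_seed`.
#'
#' @param table Feature table with the nine feature columns (see
#'   [feature_names()]); any `NA` must have been resolved upstream
#'   ([resolve_missing()]).
#' @param labels Integer posture labels, 0 = lying, 1 = standing. Defaults
#'   to `table$label`.
#' @param spec A [classifier_spec()].
#' @param preprocess A [preprocess_config()]; only its `angle_norm` field
#'   is used here.
#' @return A fitted `posture_model`.
#' @export
train_posture_classifier <- function(table, labels = table$label,
                                     spec = classifier_spec("svm"),
                                     preprocess = preprocess_config()) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (is.null(labels)) stop("labels are required (0 lying, 1 standing)",
                            call. = FALSE)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be binary: 0 (lying) or 1 (standing)", call. = FALSE)
  X_raw <- .feature_matrix(table)
  if (nrow(X_raw) != length(labels))
    stop("feature rows and labels differ in length", call. = FALSE)
  if (anyNA(X_raw))
    stop("features contain NA; resolve missing values before training",
         call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("training data must contain both classes", call. = FALSE)

  norm_tab <- as.data.frame(X_raw)
  normalizer <- fit_normalizer(norm_tab, preprocess)
  X <- as.matrix(apply_normalizer(normalizer, norm_tab))

  hp <- spec$hyperparameters
  set.seed(spec$rng_seed)
  fit <- switch(spec$family,
    svm = .svm_fit(X, labels, C = hp$C, gamma = hp$gamma),
    decision_tree = .tree_fit(X, labels, max_depth = hp$max_depth,
                              min_samples_split = hp$min_samples_split),
    random_forest = {
      mtry <- if (identical(hp$max_features, "sqrt"))
        max(1L, floor(sqrt(ncol(X)))) else as.integer(hp$max_features)
      .forest_fit(X, labels, n_estimators = hp$n_estimators,
                  max_depth = hp$max_depth,
                  min_samples_split = hp$min_samples_split, mtry = mtry)
    },
    xgboost = .gboost_fit(X, labels, n_estimators = hp$n_estimators,
                          learning_rate = hp$learning_rate,
                          max_depth = hp$max_depth, lambda = hp$lambda))
  structure(list(spec = spec, normalizer = normalizer, fit = fit,
                 metadata = list(n_train = nrow(X),
                                 n_lying = sum(labels == 0L),
                                 n_standing = sum(labels == 1L),
                                 seed = spec$rng_seed,
                                 trained_at = format(Sys.time(), tz = "UTC")),
                 format_version = 1L),
            class = "posture_model")
}

#' @export
print.posture_model <- function(x, ...) {
  cat(sprintf("<posture_model> family %s, trained on %d frames (%d lying / %d standing)\n",
              x$spec$family, x$metadata$n_train, x$metadata$n_lying,
              x$metadata$n_standing))
  invisible(x)
}

#' Predict posture labels
#'
#' One label per row: 1 standing, 0 lying. With `type = "score"` a real
#' decision score is returned instead (higher = more standing-like): the
#' SVM margin, a leaf/ensemble probability, or boosted log-odds depending
#' on the family.
#'
#' @param object A fitted `posture_model`.
#' @param newdata Feature table or 9-column matrix; no `NA` allowed.
#' @param type `"label"` or `"score"`.
#' @param ... Ignored.
#' @return Integer labels or numeric scores, one per row.
#' @export
predict.posture_model <- function(object, newdata,
                                  type = c("label", "score"), ...) {
  type <- match.arg(type)
  X_raw <- .feature_matrix(newdata)
  if (nrow(X_raw) == 0L)
    return(if (type == "label") integer(0) else numeric(0))
  if (anyNA(X_raw))
    stop("features contain NA; resolve missing values before prediction",
         call. = FALSE)
  X <- as.matrix(apply_normalizer(object$normalizer, as.data.frame(X_raw)))
  score <- switch(object$spec$family,
    svm = .svm_decision(object$fit, X),
    decision_tree = .tree_predict(object$fit, X) - 0.5,
    random_forest = .forest_predict(object$fit, X) - 0.5,
    xgboost = .gboost_decision(object$fit, X))
  if (type == "score") score else as.integer(score > 0)
}

#' Stratified train/test split
#'
#' Splits row indices into train and test, preserving class proportions,
#' deterministically under `seed`.
#'
#' @param labels Binary label vector.
#' @param test_frac Fraction held out (default 0.3).
#' @param seed RNG seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, test_frac = 0.3, seed = 1L) {
  stopifnot(test_frac > 0, test_frac < 1)
  set.seed(seed)
  test <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_test <- max(1L, round(length(idx) * test_frac))
    test <- c(test, sample(idx, n_test))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

## ---- evaluation -----------------------------------------------------------

#' Evaluate predictions against labels
#'
#' Builds the confusion table for the chosen positive class and derives
#' accuracy, precision, recall, F1 (harmonic mean of precision and recall)
#' and specificity from the counts. When decision scores are supplied, the
#' ROC is traced over all score thresholds and AUC computed by the
#' trapezoidal rule (ties handled by threshold grouping). With only one
#' class present AUC is `NA` with a warning; other metrics still come out.
#'
#' @param actual Integer ground-truth labels.
#' @param predicted Integer predicted labels.
#' @param scores Optional numeric decision scores, oriented so that larger
#'   means more confidently *positive*.
#' @param positive Which label value counts as positive (default 0, the
#'   lying class -- the fall-relevant posture).
#' @return An `eval_report` with counts `tp`, `tn`, `fp`, `fn` and metrics
#'   `accuracy`, `precision`, `recall`, `f1`, `specificity`, `auc`.
#' @export
eval_report <- function(actual, predicted, scores = NULL, positive = 0L) {
  if (length(actual) != length(predicted))
    stop("actual and predicted differ in length", call. = FALSE)
  pos <- actual == positive
  ppos <- predicted == positive
  tp <- sum(pos & ppos); tn <- sum(!pos & !ppos)
  fp <- sum(!pos & ppos); fn <- sum(pos & !ppos)
  auc <- NA_real_
  if (!is.null(scores)) {
    if (length(scores) != length(actual))
      stop("scores and actual differ in length", call. = FALSE)
    if (length(unique(pos)) < 2L) {
      warning("AUC undefined: evaluation set contains a single class",
              call. = FALSE)
    } else {
      auc <- .roc_auc(scores, pos)
    }
  }
  report_from_counts(tp, tn, fp, fn, auc = auc)
}

#' Build an evaluation report from confusion counts
#'
#' @param tp,tn,fp,fn Non-negative confusion counts.
#' @param auc Optional AUC to attach.
#' @return An `eval_report`.
#' @export
report_from_counts <- function(tp, tn, fp, fn, auc = NA_real_) {
  total <- tp + tn + fp + fn
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  structure(list(
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = if (total > 0) (tp + tn) / total else NA_real_,
    precision = prec, recall = rec, f1 = f1,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    auc = auc), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> TP=%d TN=%d FP=%d FN=%d\n", x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("  accuracy %.4f  precision %.4f  recall %.4f  f1 %.4f  specificity %.4f",
              x$accuracy, x$precision, x$recall, x$f1, x$specificity))
  if (!is.na(x$auc)) cat(sprintf("  auc %.4f", x$auc))
  cat("\n")
  invisible(x)
}

# AUC by trapezoidal integration of the ROC over distinct-score thresholds.
.roc_auc <- function(scores, is_pos) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- is_pos[ord]
  np <- sum(p); nn <- sum(!p)
  # cumulative counts at each distinct threshold (ties grouped)
  last_of_group <- c(diff(s) != 0, TRUE)
  tpr <- c(0, cumsum(p)[last_of_group] / np)
  fpr <- c(0, cumsum(!p)[last_of_group] / nn)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Full train/evaluate harness
#'
#' Stratified 70/30 split, training on the larger part, evaluation on the
#' holdout; the report is computed with [eval_report()].
#'
#' @param table Labeled feature table (must carry a `label` column).
#' @param spec A [classifier_spec()].
#' @param preprocess A [preprocess_config()].
#' @param test_frac Holdout fraction.
#' @param seed Split seed.
#' @return List with `model`, `report`, and the `split` indices.
#' @export
train_and_evaluate <- function(table, spec = classifier_spec("svm"),
                               preprocess = preprocess_config(),
                               test_frac = 0.3, seed = 1L) {
  if (is.null(table$label)) stop("table must have a 'label' column",
                                 call. = FALSE)
  split <- stratified_split(table$label, test_frac, seed)
  model <- train_posture_classifier(table[split$train, , drop = FALSE],
                                    spec = spec, preprocess = preprocess)
  test <- table[split$test, , drop = FALSE]
  pred <- predict(model, test)
  sc <- predict(model, test, type = "score")
  # scores are standing-oriented; report's positive class is lying (0)
  report <- eval_report(test$label, pred, scores = -sc, positive = 0L)
  list(model = model, report = report, split = split)
}

## ---- model persistence ----------------------------------------------------

#' Save / load a fitted posture model
#'
#' The model artifact is a single JSON file carrying a format-version
#' field, the classifier spec, the fitted normalization statistics, and the
#' family-specific decision state (support vectors and coefficients, or
#' flattened tree arrays). Numbers are written at full precision, so a
#' loaded model predicts identically to the saved one.
#'
#' @param model A fitted `posture_model`.
#' @param path File path for the artifact.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "posture_model"))
  if (!dir.exists(dirname(path)))
    stop("cannot write model to '", path, "': directory does not exist",
         call. = FALSE)
  payload <- list(format_version = model$format_version,
                  spec = unclass(model$spec),
                  normalizer = unclass(model$normalizer),
                  metadata = model$metadata,
                  fit = model$fit)
  ok <- tryCatch({
    writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                null = "null", matrix = "rowmajor"),
               path)
    TRUE
  }, error = function(e)
    stop("cannot write model to '", path, "': ", conditionMessage(e),
         call. = FALSE))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  payload <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                                         simplifyMatrix = TRUE),
                      error = function(e)
                        stop("corrupt model file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(payload$format_version))
    stop("corrupt model file '", path, "': no format_version", call. = FALSE)
  if (payload$format_version != 1L)
    stop("model format version ", payload$format_version,
         " not supported (this build reads version 1)", call. = FALSE)
  spec <- structure(payload$spec, class = "classifier_spec")
  normalizer <- payload$normalizer
  if (!is.null(normalizer$stats))
    normalizer$stats <- lapply(normalizer$stats, function(v)
      stats::setNames(as.numeric(v), feature_names()))
  normalizer <- structure(normalizer, class = "feature_normalizer")
  fit <- .rehydrate_fit(spec$family, payload$fit)
  structure(list(spec = spec, normalizer = normalizer, fit = fit,
                 metadata = payload$metadata,
                 format_version = payload$format_version),
            class = "posture_model")
}

.rehydrate_tree <- function(tr) {
  list(feature = as.integer(unlist(tr$feature)),
       threshold = as.numeric(unlist(tr$threshold)),
       left = as.integer(unlist(tr$left)),
       right = as.integer(unlist(tr$right)),
       prob1 = as.numeric(unlist(tr$prob1)))
}

.rehydrate_fit <- function(family, fit) {
  switch(family,
    svm = {
      sv_x <- fit$sv_x
      if (is.list(sv_x)) sv_x <- do.call(rbind, lapply(sv_x, as.numeric))
      list(sv_x = matrix(as.numeric(sv_x), ncol = 9L),
           sv_coef = as.numeric(unlist(fit$sv_coef)),
           b = as.numeric(fit$b), gamma = as.numeric(fit$gamma),
           C = as.numeric(fit$C), n_sv = as.integer(fit$n_sv),
           converged = isTRUE(fit$converged))
    },
    decision_tree = .rehydrate_tree(fit),
    random_forest = list(trees = lapply(fit$trees, .rehydrate_tree)),
    xgboost = list(f0 = as.numeric(fit$f0),
                   learning_rate = as.numeric(fit$learning_rate),
                   trees = lapply(fit$trees, .rehydrate_tree)))
}
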