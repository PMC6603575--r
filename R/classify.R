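# Classification of windowed activity features: random forest, SVM and
# class-weighted SVM, with stratified k-fold cross-validation and macro
# F-score reporting.

#' Class weights for imbalanced training
#'
#' Inverse-frequency class weights: each class is weighted by the majority
#' class count divided by its own count, so the majority class has weight 1
#' and under-represented classes are up-weighted proportionally. Used as
#' per-class misclassification penalties by the weighted SVM.
#'
#' @param counts Named (or ordered) vector of positive per-class window
#'   counts.
#' @return A tibble with columns `class`, `count`, `weight`.
#' @examples
#' class_weights(c(on_bed = 200, off_bed = 300, lying = 2000))
#' @export
class_weights <- function(counts) {
  if (length(counts) < 1L || any(!is.finite(counts)) || any(counts < 1)) {
    abort_bad_input("`counts` must all be positive")
  }
  cls <- names(counts) %||% paste0("class", seq_along(counts))
  tibble::tibble(class = cls, count = as.numeric(counts),
                 weight = max(counts) / as.numeric(counts))
}

#' Confusion matrix in the canonical class order
#'
#' @param actual,predicted Vectors of class labels.
#' @param classes Ordered class labels (default [activity_levels()]).
#' @return A `confusion_matrix`: integer matrix, rows = actual,
#'   columns = predicted.
#' @export
confusion_matrix <- function(actual, predicted, classes = activity_levels()) {
  m <- table(factor(actual, levels = classes),
             factor(predicted, levels = classes))
  m <- unclass(as.matrix(m))
  dimnames(m) <- list(actual = classes, predicted = classes)
  structure(m, class = c("confusion_matrix", "matrix"))
}

as_confusion_matrix <- function(m, classes = activity_levels()) {
  m <- as.matrix(m)
  if (!all(dim(m) == length(classes)) || any(m < 0)) {
    abort_bad_input("confusion matrix must be square and non-negative")
  }
  dimnames(m) <- list(actual = classes, predicted = classes)
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Per-class and overall F-scores of a confusion matrix
#'
#' For each class, `TP` is the diagonal cell, `FN` the rest of its row, `FP`
#' the rest of its column, and the F-score is `2*TP / (2*TP + FP + FN) * 100`
#' (per cent). The overall score is the unweighted (macro) mean of the
#' per-class scores. A class with `2*TP + FP + FN = 0` has an undefined
#' F-score; it is reported as 0 with a warning.
#'
#' @param cm A `confusion_matrix` or plain 3x3 count matrix (rows = actual).
#' @return A `performance_report`: list with `per_class_f` (named numeric,
#'   per cent), `overall_f`, and the matrix. [tidy()] and [glance()] give
#'   tibble views.
#' @examples
#' m <- rbind(c(180, 2, 34), c(0, 1737, 1), c(33, 1, 262))
#' f_scores(m)
#' @export
f_scores <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) cm <- as_confusion_matrix(cm)
  if (sum(cm) == 0) abort_bad_input("confusion matrix is all zero")
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  denom <- 2 * tp + fp + fn
  f <- ifelse(denom > 0, 2 * tp / denom * 100, 0)
  if (any(denom == 0)) {
    warning("class with no instances or predictions; F-score set to 0",
            call. = FALSE)
  }
  names(f) <- rownames(cm)
  structure(list(per_class_f = f, overall_f = mean(f), cm = cm),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("<performance_report>\n")
  for (cl in names(x$per_class_f)) {
    cat(sprintf("  %-8s F = %5.1f %%\n", cl, x$per_class_f[[cl]]))
  }
  cat(sprintf("  overall  F = %5.1f %% (macro average)\n", x$overall_f))
  invisible(x)
}

#' @rdname f_scores
#' @param x A `performance_report`.
#' @param ... Unused.
#' @method tidy performance_report
#' @export
tidy.performance_report <- function(x, ...) {
  tibble::tibble(class = names(x$per_class_f),
                 f_score = unname(x$per_class_f))
}

#' @rdname f_scores
#' @method glance performance_report
#' @export
glance.performance_report <- function(x, ...) {
  tibble::tibble(overall_f = x$overall_f, n = sum(x$cm))
}

#' Model specification
#'
#' Declares the learning algorithm and its hyperparameters. `"rf"` is a
#' random forest (default 100 trees); `"svm"` an RBF-kernel support vector
#' machine (cost 1, `gamma = 1 / (n_features * var(x))`, the scaled-feature
#' convention); `"wsvm"` the same SVM with per-class misclassification
#' penalties from [class_weights()]. Features are z-scored (fit on the
#' training data only) for the SVM variants; the forest consumes raw
#' features.
#'
#' @param algorithm `"rf"`, `"svm"` or `"wsvm"`.
#' @param seed Integer seed fixed into every fit for reproducibility.
#' @param ntree Trees for the forest.
#' @param cost SVM cost parameter.
#' @param gamma Optional SVM kernel width; default leaves it to the
#'   `1 / (n_features * var)` rule.
#' @return A `model_spec` object.
#' @export
model_spec <- function(algorithm = c("rf", "svm", "wsvm"), seed = 1L,
                       ntree = 100L, cost = 1, gamma = NULL) {
  algorithm <- match.arg(algorithm)
  structure(list(algorithm = algorithm, seed = as.integer(seed),
                 ntree = as.integer(ntree), cost = cost, gamma = gamma),
            class = "model_spec")
}

#' Train an activity classifier
#'
#' Fits the classifier declared by a [model_spec()] to a feature table.
#' The weighted SVM derives its per-class penalties from the training-set
#' class counts via [class_weights()]. The feature pipeline is identical
#' for all algorithms; only the SVM variants standardise features
#' (z-score parameters estimated on the training data).
#'
#' @param data Feature tibble from [extract_features()] (feature columns
#'   plus `label`), or a plain data frame of features if `labels` is given.
#' @param spec A [model_spec()].
#' @param labels Optional label vector when `data` carries no `label`
#'   column.
#' @return A `bedegress_model` handle usable with [predict()].
#' @export
train_classifier <- function(data, spec = model_spec("rf"), labels = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(labels)) data <- dplyr::mutate(tibble::as_tibble(data),
                                              label = labels)
  fm <- feature_matrix(data)
  y <- droplevels(fm$label)
  if (any(is.na(fm$label))) abort_bad_input("unrecognised class labels")
  if (nlevels(y) < 2L) abort_bad_input("need at least two classes to train")
  x <- fm$x
  if (any(!is.finite(x))) abort_bad_input("feature matrix must be finite")
  scaling <- NULL
  if (spec$algorithm %in% c("svm", "wsvm")) {
    mu <- colMeans(x)
    sg <- apply(x, 2, sd)
    sg[sg == 0] <- 1
    scaling <- list(center = mu, scale = sg)
    x <- scale(x, center = mu, scale = sg)
  }
  set.seed(spec$seed)
  fit <- switch(
    spec$algorithm,
    rf = randomForest::randomForest(x = x, y = y, ntree = spec$ntree),
    svm = e1071::svm(x = x, y = y, kernel = "radial", cost = spec$cost,
                     gamma = spec$gamma %||% (1 / ncol(x)), scale = FALSE),
    wsvm = {
      cw <- class_weights(table(y))
      w <- stats::setNames(cw$weight, cw$class)
      e1071::svm(x = x, y = y, kernel = "radial", cost = spec$cost,
                 gamma = spec$gamma %||% (1 / ncol(x)), scale = FALSE,
                 class.weights = w)
    }
  )
  structure(list(fit = fit, spec = spec, scaling = scaling,
                 features = colnames(fm$x), classes = levels(y)),
            class = "bedegress_model")
}

#' @export
print.bedegress_model <- function(x, ...) {
  cat(sprintf("<bedegress_model> %s, %d features, classes: %s\n",
              x$spec$algorithm, length(x$features),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Predict activity classes
#'
#' @param object A `bedegress_model` from [train_classifier()].
#' @param newdata Feature tibble (extra `label` / `modality` columns are
#'   ignored).
#' @param ... Unused.
#' @return Factor of predicted class labels.
#' @export
predict.bedegress_model <- function(object, newdata, ...) {
  x <- as.matrix(tibble::as_tibble(newdata)[object$features])
  storage.mode(x) <- "double"
  if (!is.null(object$scaling)) {
    x <- scale(x, center = object$scaling$center,
               scale = object$scaling$scale)
  }
  predict(object$fit, x)
}

stratified_folds <- function(y, k, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Splits the windows into `k` stratified folds (every class represented in
#' every fold), trains on `k - 1` folds, predicts the held-out fold, and
#' sums the per-fold confusion matrices, so each window is predicted exactly
#' once and the summed matrix total equals the sample count. The report is
#' computed from the summed matrix with [f_scores()].
#'
#' @param data Feature tibble with a `label` column.
#' @param spec A [model_spec()].
#' @param k Number of folds (default 5, i.e. 80% train / 20% test per fold).
#' @param seed Integer seed controlling the fold assignment.
#' @return A `cv_result`: list with `confusion` (summed matrix), `report`
#'   (a `performance_report`), `k`, `seed`, `spec`, `n`. [tidy()] returns
#'   per-class F-scores, [glance()] the one-row summary.
#' @export
cross_validate <- function(data, spec = model_spec("rf"), k = 5L, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  data <- tibble::as_tibble(data)
  if (!"label" %in% names(data)) abort_bad_input("`data` needs a label column")
  y <- factor(data$label, levels = activity_levels())
  y <- droplevels(y)
  if (nrow(data) < k) abort_bad_input("fewer samples than folds")
  if (any(table(y) < k)) {
    abort_bad_input(sprintf("every class needs at least k = %d windows", k))
  }
  fold <- stratified_folds(y, k, seed)
  cm <- matrix(0L, length(activity_levels()), length(activity_levels()))
  for (f in seq_len(k)) {
    train <- data[fold != f, , drop = FALSE]
    test <- data[fold == f, , drop = FALSE]
    fit <- train_classifier(train, spec)
    pred <- predict(fit, test)
    cm <- cm + unclass(confusion_matrix(test$label, pred))
  }
  cm <- as_confusion_matrix(cm)
  structure(list(confusion = cm, report = f_scores(cm), k = k,
                 seed = as.integer(seed), spec = spec, n = nrow(data)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d-fold, n = %d windows\n",
              x$spec$algorithm, x$k, x$n))
  print(x$report)
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `cv_result`.
#' @param ... Unused.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) {
  dplyr::mutate(tidy(x$report), algorithm = x$spec$algorithm, .before = 1)
}

#' @rdname cross_validate
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(algorithm = x$spec$algorithm, overall_f = x$report$overall_f,
                 n = x$n, k = x$k, seed = x$seed)
}
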