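#' Train a morphological phenotype classifier
#'
#' Trains a classifier of the four morphological phenotypes (AE, BB, FP,
#' LA) from shape-feature vectors, with calibrated per-class probability
#' scores. Two families are provided: a support vector machine with
#' pairwise-coupling probability calibration, and a random forest whose
#' vote frequencies serve as probabilities. Features are standardized
#' internally (parameters stored in the model); classes are weighted by
#' inverse frequency. A stratified held-out split reports accuracy before
#' the final model is refit on all data.
#'
#' @param features numeric matrix or data.frame of shape measures, one row
#'   per cell image.
#' @param labels character vector of phenotype labels (the four trainable
#'   classes only; at least 2 examples of each).
#' @param family `"svm"` or `"random_forest"`.
#' @param config list of optional hyperparameters: `holdout_fraction`
#'   (default 0.2), `cost`/`gamma` for the SVM, `ntree` (default 500) for
#'   the forest.
#' @param seed integer seed (split, SVM calibration folds, forest).
#' @return an object of class `phenotype_classifier` with elements
#'   `family`, `fit`, `scaler`, `classes`, `feature_names`,
#'   `heldout_accuracy`, `n_per_class`, `seed`.
#' @export
#' @examples
#' \donttest{
#' set.seed(1)
#' fx <- generate_archetype_set(40, seed = 2)
#' mdl <- train_classifier(fx$features, fx$labels, family = "svm", seed = 1)
#' mdl$heldout_accuracy
#' }
train_classifier <- function(features, labels,
                             family = c("svm", "random_forest"),
                             config = list(), seed = 1) {
  family <- match.arg(family)
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  bad_rows <- which(!complete.cases(features) |
                      apply(features, 1, function(r) any(!is.finite(r))))
  if (length(bad_rows)) {
    stop("non-finite feature values in row(s): ",
         paste(head(bad_rows, 10), collapse = ", "))
  }
  classes <- phenotype_levels()
  extra <- setdiff(unique(labels), classes)
  if (length(extra)) {
    stop("labels must be among the trainable classes (",
         paste(classes, collapse = ", "), "); found: ",
         paste(extra, collapse = ", "))
  }
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2L)) {
    stop("every class needs >= 2 examples; missing or sparse: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  holdout_fraction <- config$holdout_fraction %||% 0.2

  scaler <- standardize_features(features)
  x <- scaler$scaled
  y <- factor(labels, levels = classes)
  w <- as.numeric(1 / counts); names(w) <- classes
  w <- w * length(classes) / sum(w)

  # stratified held-out split
  idx_test <- with_seed(derive_seed(seed, 1), unlist(lapply(classes, function(cl) {
    i <- which(y == cl)
    sample(i, max(1L, round(length(i) * holdout_fraction)))
  })))
  fit_one <- function(rows, s) {
    with_seed(s, switch(family,
      svm = e1071::svm(x[rows, , drop = FALSE], y[rows], probability = TRUE,
                       kernel = "radial",
                       cost = config$cost %||% 1,
                       gamma = config$gamma %||% (1 / ncol(x)),
                       class.weights = w),
      random_forest = randomForest::randomForest(
        x[rows, , drop = FALSE], y[rows],
        ntree = config$ntree %||% 500L, classwt = w)
    ))
  }
  fit_ho <- fit_one(setdiff(seq_along(y), idx_test), derive_seed(seed, 2))
  pred_ho <- classifier_scores(family, fit_ho, x[idx_test, , drop = FALSE])
  acc <- mean(classes[max.col(pred_ho, ties.method = "first")] ==
                as.character(y[idx_test]))

  fit_all <- fit_one(seq_along(y), derive_seed(seed, 3))
  structure(list(family = family, fit = fit_all, scaler = scaler,
                 classes = classes, feature_names = scaler$kept,
                 heldout_accuracy = acc,
                 n_per_class = as.integer(counts), seed = seed,
                 config = config),
            class = "phenotype_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

classifier_scores <- function(family, fit, x_scaled) {
  if (family == "svm") {
    pr <- attr(predict(fit, x_scaled, probability = TRUE), "probabilities")
  } else {
    pr <- predict(fit, x_scaled, type = "prob")
  }
  pr <- pr[, phenotype_levels(), drop = FALSE]
  pr / rowSums(pr)
}

#' @export
print.phenotype_classifier <- function(x, ...) {
  cat("Phenotype classifier (", x$family, "), ",
      sum(x$n_per_class), " training images; held-out accuracy ",
      round(x$heldout_accuracy, 3), "\n", sep = "")
  invisible(x)
}

#' @export
#' @rdname train_classifier
#' @param object a `phenotype_classifier`.
#' @param newdata shape-feature matrix/data.frame (raw scale; standardized
#'   with the model's stored parameters).
#' @param ... unused.
predict.phenotype_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  miss <- setdiff(object$feature_names, colnames(newdata))
  if (length(miss)) {
    stop("feature list mismatch; missing measure(s): ",
         paste(miss, collapse = ", "))
  }
  xs <- predict(object$scaler, newdata)
  classifier_scores(object$family, object$fit, xs)
}

#' Assign a phenotype call from calibrated scores
#'
#' Applies the definite/intermediate rule: the cell is assigned to the
#' class with the maximum calibrated probability score if that score
#' strictly exceeds the threshold (default 0.6); otherwise the cell is in
#' the intermediate state (`INT`). A tie at exactly the threshold is INT.
#'
#' @param model a [train_classifier()] model.
#' @param shape a single [compute_shape_vector()] result or a feature
#'   matrix/data.frame (one row per cell).
#' @param threshold definite-call cutoff on the maximum score.
#' @return a data.frame of class `phenotype_call` with columns `score_AE`,
#'   `score_BB`, `score_FP`, `score_LA`, `label`. Scores sum to 1 per row.
#' @export
assign_phenotype <- function(model, shape, threshold = 0.6) {
  stopifnot(inherits(model, "phenotype_classifier"))
  if (inherits(shape, "shape_vector")) {
    shape <- matrix(unclass(shape), nrow = 1L,
                    dimnames = list(NULL, names(shape)))
  }
  scores <- predict(model, shape)
  call_from_scores(scores, threshold)
}

#' @rdname assign_phenotype
#' @param scores numeric matrix (or vector) of 4 class probabilities in the
#'   order AE, BB, FP, LA; rows are renormalized to sum to 1.
#' @export
call_from_scores <- function(scores, threshold = 0.6) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  stopifnot(ncol(scores) == 4L)
  colnames(scores) <- phenotype_levels()
  scores <- scores / rowSums(scores)
  imax <- max.col(scores, ties.method = "first")
  smax <- scores[cbind(seq_len(nrow(scores)), imax)]
  label <- ifelse(smax > threshold, phenotype_levels()[imax], "INT")
  out <- as.data.frame(scores)
  names(out) <- paste0("score_", phenotype_levels())
  out$label <- label
  class(out) <- c("phenotype_call", "data.frame")
  out
}

#' Agreement between two classifiers
#'
#' Fraction of cells receiving identical labels (including `INT`) from two
#' models under the same definite-call threshold.
#'
#' @param model_a,model_b [train_classifier()] models sharing a feature
#'   list.
#' @param features shape-feature matrix.
#' @param threshold definite-call cutoff.
#' @return agreement fraction in `[0, 1]`.
#' @export
compare_classifiers <- function(model_a, model_b, features, threshold = 0.6) {
  if (!setequal(model_a$feature_names, model_b$feature_names)) {
    stop("models were trained on different feature lists")
  }
  la <- assign_phenotype(model_a, features, threshold)$label
  lb <- assign_phenotype(model_b, features, threshold)$label
  mean(la == lb)
}
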