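#' Standardize a shape-feature table
#'
#' Centres and scales each measure to mean 0 and variance 1 over the
#' table, storing the parameters so unseen data can be mapped into the same
#' standardized shape space. Constant measures cannot be standardized and
#' are dropped with a warning (recorded in the returned object).
#'
#' @param features numeric matrix or data.frame, one row per observation,
#'   one column per measure (>= 2 rows).
#' @return an object of class `feature_scaler` with elements `center`,
#'   `scale`, `kept`, `dropped` and `scaled` (the standardized training
#'   table).
#' @export
#' @examples
#' fs <- standardize_features(matrix(rnorm(40), 10, 4,
#'   dimnames = list(NULL, c("a", "b", "c", "d"))))
#' colMeans(fs$scaled)
standardize_features <- function(features) {
  features <- as.matrix(features)
  if (!is.numeric(features)) stop("features must be numeric")
  if (nrow(features) < 2L) stop("need at least 2 rows to standardize")
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  ctr <- colMeans(features)
  scl <- apply(features, 2, sd)
  dropped <- colnames(features)[!is.finite(scl) | scl == 0]
  if (length(dropped)) {
    warning("dropping constant measure(s): ", paste(dropped, collapse = ", "))
  }
  kept <- setdiff(colnames(features), dropped)
  obj <- structure(list(center = ctr[kept], scale = scl[kept], kept = kept,
                        dropped = dropped),
                   class = "feature_scaler")
  obj$scaled <- predict(obj, features)
  obj
}

#' @export
#' @rdname standardize_features
#' @param object a `feature_scaler`.
#' @param newdata matrix or data.frame with (at least) the kept measures.
#' @param ... unused.
predict.feature_scaler <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)) && ncol(newdata) == length(object$kept)) {
    colnames(newdata) <- object$kept
  }
  miss <- setdiff(object$kept, colnames(newdata))
  if (length(miss)) stop("newdata lacks measure(s): ", paste(miss, collapse = ", "))
  x <- newdata[, object$kept, drop = FALSE]
  scale(x, center = object$center, scale = object$scale)[, , drop = FALSE]
}

#' @export
print.feature_scaler <- function(x, ...) {
  cat("Feature scaler:", length(x$kept), "measure(s) kept")
  if (length(x$dropped)) cat(";", length(x$dropped), "constant dropped")
  cat("\n")
  invisible(x)
}
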