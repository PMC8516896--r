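#' Fit a 3-D t-SNE embedding of the shape space
#'
#' Exact (dense) t-SNE of standardized shape features into three
#' dimensions, used to visualise the geometric shape space and
#' morphodynamic trajectories in it. The training map is frozen in the
#' returned model so unseen cells can later be placed into the same
#' coordinates with [project_embedding()].
#'
#' @param features standardized feature matrix (>= 50 rows), e.g. the
#'   `scaled` element of [standardize_features()].
#' @param config list of hyperparameters: `perplexity` (default 30),
#'   `n_iter` (default 400), `learning_rate` (default 200),
#'   `exaggeration` (default 12, applied for the first quarter of the
#'   iterations), `knn` (out-of-sample initialisation neighbours,
#'   default 10).
#' @param seed integer seed for the random initialisation.
#' @param labels optional class labels; if given, the mean silhouette
#'   width of the classes in the embedded coordinates is reported.
#' @return an object of class `shape_embedding` with elements `Y` (n x 3
#'   embedded coordinates), `X` (training features), `config`,
#'   `silhouette` (or `NA`) and `betas` (per-point kernel precisions).
#' @export
fit_embedding <- function(features, config = list(), seed = 1,
                          labels = NULL) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (n < 50L) stop("need at least 50 points to fit an embedding")
  perplexity <- config$perplexity %||% 30
  if (n - 1 < 3 * perplexity) {
    stop("perplexity ", perplexity, " requires more than ",
         3 * perplexity + 1, " points (have ", n, ")")
  }
  n_iter <- config$n_iter %||% 400L
  eta <- config$learning_rate %||% 200
  exaggeration <- config$exaggeration %||% 12
  d2 <- sq_dist(x, x)
  aff <- gaussian_affinities(d2, perplexity)
  p <- aff$p
  p <- (p + t(p)) / (2 * n)
  p <- pmax(p, 1e-12)

  y <- with_seed(seed, matrix(rnorm(n * 3L, sd = 1e-4), n, 3L))
  inc <- matrix(0, n, 3L)
  gains <- matrix(1, n, 3L)
  stop_exag <- max(1L, round(n_iter / 4))
  momentum <- 0.5
  for (it in seq_len(n_iter)) {
    pe <- if (it <= stop_exag) p * exaggeration else p
    num <- 1 / (1 + sq_dist(y, y))
    diag(num) <- 0
    q <- pmax(num / sum(num), 1e-12)
    l <- (pe - q) * num
    grad <- 4 * (diag(rowSums(l)) %*% y - l %*% y)
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - eta * gains * grad
    y <- y + inc
    y <- sweep(y, 2, colMeans(y))
    if (it == 250L) momentum <- 0.8
  }
  sil <- NA_real_
  if (!is.null(labels)) {
    sil <- mean(cluster::silhouette(as.integer(factor(labels)),
                                    dist(y))[, "sil_width"])
  }
  structure(list(Y = y, X = x, config = list(perplexity = perplexity,
                                             knn = config$knn %||% 10L),
                 silhouette = sil, betas = aff$beta, seed = seed),
            class = "shape_embedding")
}

#' @export
print.shape_embedding <- function(x, ...) {
  cat("3-D shape-space embedding of ", nrow(x$Y), " points (perplexity ",
      x$config$perplexity, ")", sep = "")
  if (is.finite(x$silhouette)) cat("; class silhouette", round(x$silhouette, 3))
  cat("\n")
  invisible(x)
}

#' Project unseen cells into a frozen embedding
#'
#' Places each new point into the trained 3-D map without moving the
#' training coordinates: the point's Gaussian affinities to the training
#' set are computed at the model's perplexity, and its embedded position
#' minimises its own Kullback-Leibler divergence contribution against the
#' frozen map (quasi-Newton descent from the median embedded coordinate of
#' its `knn` nearest training neighbours). `method = "knn"` skips the
#' descent and returns the neighbour median — a fast fallback.
#'
#' @param model a [fit_embedding()] model.
#' @param features standardized feature matrix of new points (same columns
#'   as the training features).
#' @param method `"kl"` (default) or `"knn"`.
#' @return numeric matrix (rows = new points, 3 columns).
#' @export
project_embedding <- function(model, features, method = c("kl", "knn")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "shape_embedding"))
  xnew <- as.matrix(features)
  if (is.null(dim(xnew))) xnew <- matrix(xnew, nrow = 1L)
  if (ncol(xnew) != ncol(model$X)) {
    stop("feature dimension mismatch: model has ", ncol(model$X),
         ", new data has ", ncol(xnew))
  }
  k <- model$config$knn
  yt <- model$Y
  out <- matrix(0, nrow(xnew), 3L)
  for (i in seq_len(nrow(xnew))) {
    d2 <- sq_dist(xnew[i, , drop = FALSE], model$X)[1L, ]
    nn <- order(d2)[seq_len(min(k, length(d2)))]
    y0 <- apply(yt[nn, , drop = FALSE], 2, median)
    if (method == "knn") {
      out[i, ] <- y0
      next
    }
    p <- gaussian_row(d2, model$config$perplexity)
    kl <- function(y) {
      w <- 1 / (1 + colSums((t(yt) - y)^2))
      q <- pmax(w / sum(w), 1e-12)
      sum(p * (log(p) - log(q)))
    }
    kl_grad <- function(y) {
      dy <- sweep(yt, 2, y, "-")
      w <- 1 / (1 + rowSums(dy^2))
      q <- pmax(w / sum(w), 1e-12)
      -2 * colSums((p - q) * w * dy)
    }
    out[i, ] <- optim(y0, kl, kl_grad, method = "BFGS",
                      control = list(maxit = 100))$par
  }
  out
}

# squared Euclidean distances between rows of a and rows of b
sq_dist <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  d2
}

# Per-row Gaussian affinities at fixed perplexity (binary search on the
# kernel precision beta), excluding self-affinities on the diagonal.
gaussian_affinities <- function(d2, perplexity) {
  n <- nrow(d2)
  p <- matrix(0, n, n)
  betas <- numeric(n)
  target <- log(perplexity)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    res <- beta_search(di, target)
    row <- numeric(n)
    row[-i] <- res$p
    p[i, ] <- row
    betas[i] <- res$beta
  }
  list(p = p, beta = betas)
}

gaussian_row <- function(d2_row, perplexity) {
  pmax(beta_search(d2_row, log(perplexity))$p, 1e-12)
}

beta_search <- function(di, target, tol = 1e-5, max_iter = 50L) {
  beta <- 1
  lo <- -Inf; hi <- Inf
  for (it in seq_len(max_iter)) {
    w <- exp(-di * beta)
    sw <- sum(w)
    if (sw <= 0) {
      h <- 0
    } else {
      sdw <- sum(di * w)
      h <- log(sw) + beta * sdw / sw # Shannon entropy of the row
    }
    diff <- h - target
    if (abs(diff) < tol) break
    if (diff > 0) {
      lo <- beta
      beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
    } else {
      hi <- beta
      beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
    }
  }
  w <- exp(-di * beta)
  list(p = w / sum(w), beta = beta)
}
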