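#' Mean-square displacement of tracked series
#'
#' Computes the time-averaged mean-square displacement (MSD) over all
#' overlapping frame pairs within each track, then averages across tracks;
#' the per-lag standard error is taken across tracks (not across pairs),
#' respecting within-track correlation. Works for 2-D centroid tracks
#' (MSD in square micrometres) and for scalar standardized shape measures
#' (dimensionless MSD) alike.
#'
#' @param series one track or a list of tracks; each track is a numeric
#'   vector (scalar series), a 2-column matrix of points, or a
#'   [cell_track()] (centroid is used).
#' @param dt sampling interval in hours (taken from tracks if supplied).
#' @param max_lag largest lag in hours; default one quarter of the median
#'   track span (a standard bias control for time-averaged MSD). Values at
#'   or beyond the longest track span are truncated with a warning.
#' @return an object of class `msd_curve`: data.frame with columns
#'   `lag_h`, `msd`, `sem`, `n_pairs`.
#' @export
#' @examples
#' walks <- replicate(20, cumsum(rnorm(100)), simplify = FALSE)
#' compute_msd(walks, dt = 0.25)
compute_msd <- function(series, dt = NULL, max_lag = NULL) {
  tracks <- normalize_series(series)
  if (is.null(dt)) {
    dt <- attr(tracks, "dt")
    if (is.null(dt)) stop("dt must be supplied for raw series")
  }
  lens <- vapply(tracks, nrow, integer(1))
  if (max(lens) < 3L) stop("need at least 3 samples in some track")
  spans <- (lens - 1L) * dt
  k_default <- max(1L, floor(median(spans) / 4 / dt))
  if (is.null(max_lag)) {
    k_max <- k_default
  } else {
    k_max <- floor(max_lag / dt + 1e-9)
    if (max_lag >= max(spans)) {
      k_max <- max(lens) - 1L
      warning("max_lag reaches beyond the longest track; truncating to ",
              k_max * dt, " h")
    }
  }
  k_max <- max(k_max, 1L)
  per_track <- lapply(tracks, function(m) {
    n <- nrow(m)
    ks <- seq_len(min(k_max, n - 1L))
    msd_k <- vapply(ks, function(k) {
      d <- m[(k + 1):n, , drop = FALSE] - m[1:(n - k), , drop = FALSE]
      mean(rowSums(d^2))
    }, numeric(1))
    list(ks = ks, msd = msd_k, n_pairs = n - ks)
  })
  lags <- 0:k_max
  msd <- sem <- numeric(k_max + 1L)
  n_pairs <- integer(k_max + 1L)
  n_pairs[1] <- sum(lens)
  for (k in seq_len(k_max)) {
    vals <- unlist(lapply(per_track, function(pt)
      if (k <= length(pt$ks)) pt$msd[k] else NULL))
    msd[k + 1L] <- mean(vals)
    sem[k + 1L] <- if (length(vals) > 1L) sd(vals) / sqrt(length(vals)) else NA_real_
    n_pairs[k + 1L] <- sum(unlist(lapply(per_track, function(pt)
      if (k <= length(pt$ks)) pt$n_pairs[k] else NULL)))
  }
  msd_curve(lags * dt, msd, sem, n_pairs)
}

msd_curve <- function(lag_h, msd, sem, n_pairs) {
  stopifnot(all(diff(lag_h) > 0), all(msd >= -1e-12))
  structure(data.frame(lag_h = lag_h, msd = msd, sem = sem,
                       n_pairs = n_pairs),
            class = c("msd_curve", "data.frame"))
}

normalize_series <- function(series) {
  as_points <- function(s) {
    if (inherits(s, "cell_track")) {
      return(structure(cbind(s$data$x_um, s$data$y_um), dt = s$dt))
    }
    if (is.numeric(s) && is.null(dim(s))) return(matrix(s, ncol = 1L))
    m <- as.matrix(s)
    stopifnot(is.numeric(m))
    m
  }
  if (inherits(series, "cell_track") || is.numeric(series)) {
    one <- as_points(series)
    out <- list(one)
    attr(out, "dt") <- attr(one, "dt")
    return(out)
  }
  if (is.matrix(series) || is.data.frame(series)) {
    return(list(as_points(series)))
  }
  out <- lapply(series, as_points)
  dts <- unique(unlist(lapply(out, attr, "dt")))
  if (length(dts) == 1L) attr(out, "dt") <- dts
  out
}

#' @export
print.msd_curve <- function(x, ...) {
  cat("MSD curve:", nrow(x), "lags up to", max(x$lag_h), "h\n")
  print.data.frame(head(as.data.frame(x), 8), row.names = FALSE)
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, log = "xy", ...) {
  keep <- x$lag_h > 0 & x$msd > 0
  plot(x$lag_h[keep], x$msd[keep], log = log, xlab = "lag (h)",
       ylab = "MSD", pch = 16, ...)
  invisible(x)
}

#' Fit an anomalous-diffusion exponent to an MSD curve
#'
#' Ordinary least squares of `log(msd)` on `log(lag)` over the requested
#' lag range: the slope is the anomalous exponent alpha (alpha < 1
#' subdiffusive, about 1 diffusive, about 2 ballistic), reported with its
#' 95 percent confidence interval and the 95 percent prediction band in
#' the fitted space. A linear-axis fit (`space = "linear"`, slope and
#' band of msd vs lag) is available for figure parity.
#'
#' @param curve an [compute_msd()] result.
#' @param lag_range numeric length-2, hours; default all positive lags.
#' @param space `"loglog"` (default; fits alpha) or `"linear"`.
#' @return an object of class `power_law_fit` with elements `exponent`,
#'   `amplitude`, `ci95`, `prediction_band`, `space` and the underlying
#'   `lm` fit.
#' @export
fit_power_law_exponent <- function(curve, lag_range = NULL,
                                   space = c("loglog", "linear")) {
  space <- match.arg(space)
  stopifnot(inherits(curve, "msd_curve"))
  d <- as.data.frame(curve)
  keep <- d$lag_h > 0
  if (!is.null(lag_range)) {
    keep <- keep & d$lag_h >= lag_range[1] & d$lag_h <= lag_range[2]
  }
  if (space == "loglog") {
    bad <- keep & d$msd <= 0
    if (any(bad)) {
      warning("excluding ", sum(bad), " non-positive MSD value(s) from log fit")
      keep <- keep & d$msd > 0
    }
  }
  d <- d[keep, , drop = FALSE]
  if (nrow(d) < 4L) stop("need at least 4 usable lags in range")
  if (space == "loglog") {
    fit <- lm(log(msd) ~ log(lag_h), data = d)
  } else {
    fit <- lm(msd ~ lag_h, data = d)
  }
  # the band is evaluated at the fitted lags by design
  band <- suppressWarnings(predict(fit, interval = "prediction", level = 0.95))
  ci <- confint(fit, level = 0.95)
  structure(list(
    exponent = unname(coef(fit)[2L]),
    amplitude = if (space == "loglog") exp(unname(coef(fit)[1L]))
                else unname(coef(fit)[1L]),
    ci95 = unname(ci[2L, ]),
    prediction_band = data.frame(lag_h = d$lag_h, fit = band[, "fit"],
                                 lwr = band[, "lwr"], upr = band[, "upr"]),
    space = space, fit = fit
  ), class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("Power-law fit (", x$space, "): exponent = ",
      round(x$exponent, 3), " [", round(x$ci95[1], 3), ", ",
      round(x$ci95[2], 3), "]\n", sep = "")
  invisible(x)
}
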