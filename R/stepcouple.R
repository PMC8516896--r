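#' Categorize migration steps by coarse-class transitions
#'
#' Each consecutive frame pair of a labelled track yields one step record:
#' the 2-D centroid displacement magnitude over one sampling interval,
#' together with the coarse classes at the start and end frame
#' (mesenchymal `ME` = FP + LA, amoeboidal `AM` = AE + BB, plus `INT`) and
#' the resulting ordered category (e.g. `"AM-ME"` for a step that starts
#' in the amoeboidal and ends in the mesenchymal class). Frame pairs with
#' a missing label are skipped and counted.
#'
#' @param tracks a [cell_track()] or list thereof, with phenotype labels
#'   and centroids.
#' @param coarse_map named mapping from phenotype to coarse class; default
#'   [coarse_map_default()].
#' @return data.frame of class `step_records` with columns `cell_id`,
#'   `time_h`, `magnitude_um`, `start_class`, `end_class`, `category`;
#'   attribute `n_skipped` counts label-less frame pairs.
#' @export
categorize_steps <- function(tracks, coarse_map = coarse_map_default()) {
  tracks <- as_track_list(tracks)
  n_skipped <- 0L
  out <- lapply(tracks, function(tr) {
    d <- tr$data
    n <- nrow(d)
    if (n < 2L) return(NULL)
    from <- d$phenotype[-n]; to <- d$phenotype[-1L]
    ok <- !is.na(from) & !is.na(to)
    n_skipped <<- n_skipped + sum(!ok)
    if (!any(ok)) return(NULL)
    mag <- sqrt(diff(d$x_um)^2 + diff(d$y_um)^2)
    sc <- coarse_class(from[ok], coarse_map)
    ec <- coarse_class(to[ok], coarse_map)
    data.frame(cell_id = tr$cell_id, time_h = d$time_h[-n][ok],
               magnitude_um = mag[ok], start_class = sc, end_class = ec,
               category = paste(sc, ec, sep = "-"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(cell_id = character(), time_h = numeric(),
                      magnitude_um = numeric(), start_class = character(),
                      end_class = character(), category = character())
  }
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("step_records", "data.frame")
  out
}

#' Fit a log-normal step-size distribution
#'
#' Maximum-likelihood log-normal fit of step magnitudes, reported as the
#' distribution's mean `m` and variance `sigma2` on the natural
#' (micrometre) scale — `m = exp(mu + s2/2)`,
#' `sigma2 = (exp(s2) - 1) exp(2 mu + s2)` where `mu`, `s2` are the
#' log-scale MLEs (also returned). 95 percent confidence intervals come
#' from a nonparametric bootstrap. A model-comparison diagnostic reports
#' the log-likelihood advantage of the log-normal over a Gaussian fit of
#' the same data (positive = log-normal preferred). Zero magnitudes are
#' excluded (log undefined) and counted.
#'
#' @param magnitudes positive step magnitudes in micrometres (n >= 30
#'   after zero-removal).
#' @param n_boot bootstrap resamples for the CIs (default 1000).
#' @param seed integer seed.
#' @return an object of class `lognormal_fit`: list with `m`, `sigma2`,
#'   `mu_log`, `s2_log`, `ci_m`, `ci_sigma2`, `n`, `n_zero`,
#'   `loglik_lognormal`, `loglik_gaussian`, `delta_loglik`.
#' @export
fit_lognormal <- function(magnitudes, n_boot = 1000L, seed = 1) {
  x <- magnitudes[!is.na(magnitudes)]
  n_zero <- sum(x <= 0)
  x <- x[x > 0]
  if (length(x) < 30L) {
    stop("need at least 30 positive magnitudes (have ", length(x), ")")
  }
  if (var(log(x)) == 0) stop("zero variance: all magnitudes equal")
  nat <- lnorm_natural(x)
  boot <- with_seed(derive_seed(seed, 23), {
    vapply(seq_len(n_boot), function(b) {
      xb <- x[sample.int(length(x), replace = TRUE)]
      unlist(lnorm_natural(xb)[c("m", "sigma2")])
    }, numeric(2))
  })
  ci_m <- quantile(boot[1, ], c(0.025, 0.975), names = FALSE)
  ci_s <- quantile(boot[2, ], c(0.025, 0.975), names = FALSE)
  # Gaussian comparison on the same data
  mu_g <- mean(x)
  sd_g <- sqrt(mean((x - mu_g)^2))
  ll_ln <- sum(dlnorm(x, nat$mu_log, sqrt(nat$s2_log), log = TRUE))
  ll_g <- sum(dnorm(x, mu_g, sd_g, log = TRUE))
  structure(list(m = nat$m, sigma2 = nat$sigma2,
                 mu_log = nat$mu_log, s2_log = nat$s2_log,
                 ci_m = ci_m, ci_sigma2 = ci_s,
                 n = length(x), n_zero = n_zero,
                 loglik_lognormal = ll_ln, loglik_gaussian = ll_g,
                 delta_loglik = ll_ln - ll_g),
            class = "lognormal_fit")
}

lnorm_natural <- function(x) {
  lx <- log(x)
  mu <- mean(lx)
  s2 <- mean((lx - mu)^2) # MLE variance
  list(mu_log = mu, s2_log = s2,
       m = exp(mu + s2 / 2),
       sigma2 = (exp(s2) - 1) * exp(2 * mu + s2))
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat("Log-normal fit (n = ", x$n, "): m = ", signif(x$m, 4),
      " um [", signif(x$ci_m[1], 4), ", ", signif(x$ci_m[2], 4),
      "], sigma2 = ", signif(x$sigma2, 4), " um^2 [",
      signif(x$ci_sigma2[1], 4), ", ", signif(x$ci_sigma2[2], 4), "]\n",
      sep = "")
  cat("  log-likelihood vs Gaussian: ", signif(x$delta_loglik, 4),
      if (x$delta_loglik > 0) " (log-normal preferred)\n" else
        " (Gaussian preferred)\n", sep = "")
  invisible(x)
}

#' Class-conditional mean-square displacement
#'
#' MSD computed only over frame pairs lying entirely inside maximal runs
#' of one coarse class — the motility of cells while they dwell in that
#' class, with no contribution from class-switching steps. Each maximal
#' dwell segment is treated as a track of its own and fed to
#' [compute_msd()].
#'
#' @param tracks labelled tracks.
#' @param class coarse class: `"AM"`, `"ME"` or `"INT"`.
#' @param max_lag largest lag in hours (passed to [compute_msd()]).
#' @param coarse_map phenotype-to-class mapping.
#' @return an [compute_msd()] curve; zero-row curve (with a warning) if no
#'   dwell segment is long enough.
#' @export
conditional_msd <- function(tracks, class = c("AM", "ME", "INT"),
                            max_lag = NULL,
                            coarse_map = coarse_map_default()) {
  class <- match.arg(class)
  tracks <- as_track_list(tracks)
  dt <- track_dt(tracks)
  segs <- list()
  for (tr in tracks) {
    cc <- coarse_class(tr$data$phenotype, coarse_map)
    cc[is.na(cc)] <- "NA"
    r <- rle(cc)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$values)) {
      if (r$values[i] == class && r$lengths[i] >= 2L) {
        segs[[length(segs) + 1L]] <-
          cbind(tr$data$x_um[starts[i]:ends[i]],
                tr$data$y_um[starts[i]:ends[i]])
      }
    }
  }
  if (!length(segs) || max(vapply(segs, nrow, integer(1))) < 3L) {
    warning("no ", class, " dwell segment long enough for an MSD")
    return(msd_curve(numeric(0), numeric(0), numeric(0), integer(0)))
  }
  if (is.null(max_lag)) {
    # default lag range: lags supported by a non-negligible share of dwell
    # segments (90th percentile of segment spans), within the parent
    # tracks' quarter-span rule
    track_span <- median(vapply(tracks, function(tr)
      (n_frames(tr) - 1L) * tr$dt, numeric(1)))
    seg_q90 <- quantile(vapply(segs, nrow, integer(1)) - 1L, 0.9,
                        names = FALSE) * dt
    max_lag <- max(dt, min(track_span / 4, seg_q90))
  }
  suppressWarnings(compute_msd(segs, dt = dt, max_lag = max_lag))
}

#' Occurrence-weighted average of conditional MSD curves
#'
#' Per-lag convex combination of class-conditional MSD curves, weighted by
#' the occurrence fraction of each class. This is the motility predicted
#' if class-switching steps carried no special displacement; comparing it
#' with the full-trajectory MSD quantifies how much switch-coupled steps
#' add.
#'
#' @param curves named list of [compute_msd()] curves.
#' @param fractions numeric weights (same order/names), summing to 1.
#' @return an `msd_curve` on the intersected lag grid (with a warning if
#'   the input grids differ).
#' @export
weighted_average_msd <- function(curves, fractions) {
  stopifnot(length(curves) == length(fractions))
  if (abs(sum(fractions) - 1) > 1e-6) stop("fractions must sum to 1")
  grids <- lapply(curves, function(cv) round(cv$lag_h, 9))
  common <- Reduce(intersect, grids)
  if (!all(vapply(grids, function(g) length(g) == length(common),
                  logical(1)))) {
    warning("lag grids differ; intersecting")
  }
  if (!length(common)) stop("curves share no lags")
  common <- sort(common)
  msd <- rep(0, length(common))
  npairs <- rep(0L, length(common))
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    ix <- match(common, round(cv$lag_h, 9))
    msd <- msd + fractions[i] * cv$msd[ix]
    npairs <- npairs + cv$n_pairs[ix]
  }
  msd_curve(common, msd, rep(NA_real_, length(common)), npairs)
}

#' Effective diffusivity from a linear MSD fit
#'
#' Least-squares slope `b` of MSD against lag over the requested range;
#' the per-spatial-dimension effective diffusivity is `D = b / (2 d)`
#' with `d = spatial_dims` (so a 2-D MSD slope of 24 um^2/h corresponds
#' to D = 6 um^2/h per dimension).
#'
#' @param curve an [compute_msd()] curve (in square micrometres).
#' @param spatial_dims number of spatial dimensions contributing to the
#'   MSD (default 2, projected centroid motion).
#' @param lag_range numeric length-2 range of lags (hours) to fit;
#'   default all positive lags.
#' @return an object of class `diffusivity_estimate`: list with
#'   `D_per_dim` (um^2/h), `ci95`, `slope`, `lag_range`, `n_lags`.
#' @export
effective_diffusivity <- function(curve, spatial_dims = 2,
                                  lag_range = NULL) {
  stopifnot(inherits(curve, "msd_curve"), spatial_dims >= 1)
  d <- as.data.frame(curve)
  keep <- d$lag_h > 0
  if (!is.null(lag_range)) {
    keep <- keep & d$lag_h >= lag_range[1] & d$lag_h <= lag_range[2]
  }
  d <- d[keep, , drop = FALSE]
  if (nrow(d) < 2L) stop("need at least 2 lags in range")
  fit <- lm(msd ~ lag_h, data = d)
  b <- unname(coef(fit)[2L])
  ci <- if (nrow(d) >= 3L) {
    unname(suppressWarnings(confint(fit))[2L, ]) # exact lines fit perfectly
  } else c(NA_real_, NA_real_)
  dd <- b / (2 * spatial_dims)
  if (dd < 0) {
    warning("negative MSD slope; reporting D = 0")
    dd <- 0
  }
  structure(list(D_per_dim = dd, ci95 = ci / (2 * spatial_dims), slope = b,
                 lag_range = range(d$lag_h), n_lags = nrow(d)),
            class = "diffusivity_estimate")
}

#' @export
print.diffusivity_estimate <- function(x, ...) {
  cat("Effective diffusivity: ", signif(x$D_per_dim, 4), " um^2/h per dimension",
      if (all(is.finite(x$ci95))) paste0(" [", signif(x$ci95[1], 4), ", ",
                                         signif(x$ci95[2], 4), "]"),
      " (lags ", x$lag_range[1], "-", x$lag_range[2], " h)\n", sep = "")
  invisible(x)
}
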