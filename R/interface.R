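#' Kernel estimate of event density along the interface axis
#'
#' One-dimensional Gaussian kernel estimate of the density of
#' phenotype-transition (or dwell) events along the x-axis perpendicular
#' to an ECM interface, normalised per unit time: the integral of the
#' returned curve over x equals events per hour. Together with the cell
#' density `M(x)` it defines the spatial transition frequency
#' `R(i -> j, x) = P(i -> j, x) / M(x)`, the likelihood of a cell at x to
#' undergo the event per hour.
#'
#' @param positions event x-coordinates in micrometres.
#' @param total_time total observation time in hours (> 0).
#' @param bandwidth Gaussian kernel standard deviation in micrometres.
#' @param grid evaluation grid (micrometres); default spans the positions
#'   with 3 bandwidths of padding at spacing `bandwidth / 5`.
#' @param weights optional per-event weights (default 1).
#' @return an object of class `kernel_estimate`: data.frame with columns
#'   `x_um`, `value`, `valid`; attributes `bandwidth`, `total` (integral)
#'   and `kind`.
#' @export
event_density <- function(positions, total_time, bandwidth = 10,
                          grid = NULL, weights = NULL) {
  stopifnot(total_time > 0, bandwidth > 0)
  kde_1d(positions, bandwidth, grid, weights,
         norm = 1 / total_time, kind = "P")
}

#' @rdname event_density
#' @param frame_positions x-coordinates of every (cell, frame) observation
#'   in micrometres.
#' @param n_frames number of frames observed, so the estimate integrates
#'   to the mean number of cells per frame.
#' @export
cell_density <- function(frame_positions, n_frames, bandwidth = 10,
                         grid = NULL) {
  stopifnot(n_frames > 0, bandwidth > 0)
  kde_1d(frame_positions, bandwidth, grid, NULL,
         norm = 1 / n_frames, kind = "M")
}

kde_1d 	<- function(positions, bandwidth, grid, weights, norm, kind) {
  positions <- positions[!is.na(positions)]
  if (is.null(weights)) weights <- rep(1, length(positions))
  stopifnot(length(weights) == length(positions))
  if (is.null(grid)) {
    if (length(positions)) {
      grid <- seq(min(positions) - 3 * bandwidth,
                  max(positions) + 3 * bandwidth, by = bandwidth / 5)
    } else {
      grid <- seq(-3 * bandwidth, 3 * bandwidth, by = bandwidth / 5)
    }
  }
  val <- if (length(positions)) {
    vapply(grid, function(g)
      sum(weights * dnorm(g - positions, 0, bandwidth)), numeric(1)) * norm
  } else {
    rep(0, length(grid))
  }
  out <- data.frame(x_um = grid, value = val, valid = TRUE)
  attr(out, "bandwidth") <- bandwidth
  attr(out, "total") <- sum(weights) * norm
  attr(out, "kind") <- kind
  class(out) <- c("kernel_estimate", "data.frame")
  out
}

#' @export
print.kernel_estimate <- function(x, ...) {
  cat("Kernel estimate (", attr(x, "kind") %||% "?", "): ",
      nrow(x), " grid points, bandwidth ", attr(x, "bandwidth"),
      " um, integral ", signif(attr(x, "total"), 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.kernel_estimate <- function(x, ...) {
  plot(x$x_um, x$value, type = "l", xlab = "x (um)",
       ylab = attr(x, "kind") %||% "density", ...)
  if (any(!x$valid)) points(x$x_um[!x$valid], x$value[!x$valid], col = 2)
  invisible(x)
}

#' Spatial transition frequency R(i -> j, x)
#'
#' Pointwise ratio of the event-density estimate `P` and the cell-density
#' estimate `M` on their shared grid: `R = P / M` wherever the cell
#' density is at least `density_floor` (relative to its maximum); grid
#' points with too little cell mass are flagged invalid and no division
#' is performed there. The identity `R * M = P` holds exactly on valid
#' points.
#'
#' @param P an [event_density()] estimate.
#' @param M a [cell_density()] estimate on the same grid and bandwidth.
#' @param density_floor minimum cell density, as a fraction of `max(M)`
#'   (default 0.05).
#' @return a `kernel_estimate` of kind `"R"` (per hour), with `valid`
#'   flagging the supported grid points.
#' @export
spatial_frequency <- function(P, M, density_floor = 0.05) {
  stopifnot(inherits(P, "kernel_estimate"), inherits(M, "kernel_estimate"))
  if (nrow(P) != nrow(M) || any(abs(P$x_um - M$x_um) > 1e-9)) {
    stop("P and M must share one evaluation grid")
  }
  if (!isTRUE(all.equal(attr(P, "bandwidth"), attr(M, "bandwidth")))) {
    stop("P and M must share one bandwidth")
  }
  floor_abs <- density_floor * max(M$value)
  valid <- M$value >= floor_abs & floor_abs > 0
  val <- rep(NA_real_, nrow(P))
  val[valid] <- P$value[valid] / M$value[valid]
  out <- data.frame(x_um = P$x_um, value = val, valid = valid)
  attr(out, "bandwidth") <- attr(P, "bandwidth")
  attr(out, "total") <- NA_real_
  attr(out, "kind") <- "R"
  class(out) <- c("kernel_estimate", "data.frame")
  out
}

#' Transition and dwell events of labelled tracks
#'
#' Extracts one event per consecutive frame pair: a transition event
#' `i -> j` when the label changes, a dwell event `i -> i` when it stays.
#' The event x-coordinate is the midpoint of the two frames (unbiased for
#' symmetric motion). Dwell and transition events share units, so both
#' can be fed to [event_density()].
#'
#' @param tracks labelled tracks.
#' @return data.frame with columns `cell_id`, `time_h`, `x_um`, `from`,
#'   `to`, `dwell` (logical).
#' @export
transition_events <- function(tracks) {
  tracks <- as_track_list(tracks)
  out <- lapply(tracks, function(tr) {
    d <- tr$data
    n <- nrow(d)
    if (n < 2L) return(NULL)
    from <- d$phenotype[-n]; to <- d$phenotype[-1L]
    ok <- !is.na(from) & !is.na(to)
    if (!any(ok)) return(NULL)
    data.frame(cell_id = tr$cell_id, time_h = d$time_h[-n][ok],
               x_um = ((d$x_um[-n] + d$x_um[-1L]) / 2)[ok],
               from = from[ok], to = to[ok],
               dwell = (from == to)[ok], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) data.frame(cell_id = character(), time_h = numeric(),
                               x_um = numeric(), from = character(),
                               to = character(), dwell = logical()) else out
}

#' Spatial frequency profile of one event type
#'
#' Convenience wrapper: builds `P` for the chosen event `(from, to)` (a
#' dwell event when `from == to`), `M` from all frames, and returns the
#' trio on one grid.
#'
#' @param tracks labelled tracks with positions.
#' @param from,to states defining the event.
#' @param bandwidth kernel bandwidth in micrometres.
#' @param grid optional evaluation grid.
#' @param density_floor relative cell-density floor for the ratio.
#' @return list with elements `P`, `M`, `R` (kernel estimates).
#' @export
event_frequency_profile <- function(tracks, from, to, bandwidth = 10,
                                    grid = NULL, density_floor = 0.05) {
  tracks <- as_track_list(tracks)
  ev <- transition_events(tracks)
  total_time <- sum(vapply(tracks, function(tr)
    (n_frames(tr) - 1L) * tr$dt, numeric(1)))
  frames_x <- unlist(lapply(tracks, function(tr) tr$data$x_um))
  n_frames_total <- sum(vapply(tracks, n_frames, integer(1)))
  if (is.null(grid)) {
    grid <- seq(min(frames_x) - 3 * bandwidth,
                max(frames_x) + 3 * bandwidth, by = bandwidth / 5)
  }
  sel <- ev$from == from & ev$to == to
  p <- event_density(ev$x_um[sel], total_time, bandwidth, grid)
  m <- cell_density(frames_x, n_frames_total, bandwidth, grid)
  list(P = p, M = m, R = spatial_frequency(p, m, density_floor))
}

#' Per-layer summary statistics across an ECM interface
#'
#' Splits observations at `x = interface_x` and reuses the mesoscale
#' estimators on each side: occurrence fractions and dwell times use the
#' side of each frame (tracks are cut into maximal single-side runs);
#' transition rates assign each frame pair to the side of its midpoint.
#'
#' @param tracks labelled tracks with positions.
#' @param interface_x interface position in micrometres.
#' @param states dwell-state set.
#' @param n_boot bootstrap iterations for fraction/dwell CIs.
#' @param seed integer seed.
#' @return list with elements `left` and `right`, each a list with
#'   `fractions`, `dwell`, `rates`, `n_frames` (empty sides are reported
#'   with `n_frames = 0`).
#' @export
layer_statistics <- function(tracks, interface_x = 0,
                             states = phenotype_states(), n_boot = 200L,
                             seed = 1) {
  tracks <- as_track_list(tracks)
  dt <- track_dt(tracks)
  side_of <- function(x) ifelse(x < interface_x, "left", "right")
  sub_tracks <- function(side) {
    out <- list()
    for (tr in tracks) {
      s <- side_of(tr$data$x_um)
      r <- rle(s)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (i in seq_along(r$values)) {
        if (r$values[i] != side) next
        ix <- starts[i]:ends[i]
        out[[length(out) + 1L]] <- cell_track(
          paste0(tr$cell_id, "_", side, "_", i),
          tr$data$time_h[ix], tr$data$x_um[ix], tr$data$y_um[ix],
          phenotype = tr$data$phenotype[ix], dt = tr$dt,
          condition = tr$condition)
      }
    }
    out
  }
  side_rates <- function(side) {
    k <- length(states)
    n_trans <- matrix(0, k, k, dimnames = list(states, states))
    time_h <- setNames(numeric(k), states)
    for (tr in tracks) {
      d <- tr$data
      n <- nrow(d)
      s_frame <- side_of(d$x_um)
      tb <- table(factor(d$phenotype[s_frame == side & !is.na(d$phenotype)],
                         levels = states))
      time_h <- time_h + as.numeric(tb) * dt
      if (n < 2L) next
      mid_side <- side_of((d$x_um[-n] + d$x_um[-1L]) / 2)
      from <- d$phenotype[-n]; to <- d$phenotype[-1L]
      ok <- mid_side == side & !is.na(from) & !is.na(to) & from != to
      if (any(ok)) {
        tt <- table(factor(from[ok], levels = states),
                    factor(to[ok], levels = states))
        n_trans <- n_trans + unclass(as.matrix(tt))
      }
    }
    q <- n_trans / ifelse(time_h > 0, time_h, NA_real_)
    q[is.na(q)] <- 0
    diag(q) <- 0
    out <- rate_matrix(q, states)
    attr(out, "counts") <- n_trans
    attr(out, "occupancy_h") <- time_h
    out
  }
  one_side <- function(side) {
    st <- sub_tracks(side)
    nf <- if (length(st)) sum(vapply(st, n_frames, integer(1))) else 0L
    if (nf == 0L) {
      return(list(fractions = NULL, dwell = NULL, rates = NULL,
                  n_frames = 0L))
    }
    nb <- if (length(st) >= 2L) n_boot else 0L
    list(fractions = occurrence_fractions(st, states, n_boot = nb,
                                          seed = derive_seed(seed, 31)),
         dwell = dwell_times(st, states, n_boot = nb,
                             seed = derive_seed(seed, 32)),
         rates = side_rates(side),
         n_frames = nf)
  }
  list(left = one_side("left"), right = one_side("right"))
}
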