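#' Segment a single cell from a grayscale frame
#'
#' Simple global-threshold segmentation: Otsu binarisation, hole filling,
#' morphological opening (radius 1 px) and retention of the largest
#' 8-connected component.
#'
#' @param image 2-D numeric matrix of intensities (any range, non-constant).
#' @param pixel_size micrometres per pixel.
#' @param method thresholding method; only `"otsu"` is provided.
#' @return a [binary_mask()].
#' @export
segment_frame <- function(image, pixel_size = 1, method = "otsu") {
  image <- as.matrix(image)
  rng <- range(image, finite = TRUE)
  if (!all(is.finite(rng)) || rng[1] == rng[2]) {
    stop("image is constant; nothing to segment")
  }
  method <- match.arg(method, "otsu")
  norm <- (image - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bin <- norm > thr
  bin <- EBImage::fillHull(EBImage::Image(bin * 1)) > 0.5
  kern <- EBImage::makeBrush(3, shape = "diamond")
  bin <- EBImage::opening(EBImage::Image(bin * 1), kern) > 0.5
  lab <- label_components(as.matrix(bin))
  if (max(lab) == 0L) stop("segmentation produced an empty mask")
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  binary_mask(lab == keep, pixel_size = pixel_size, check = FALSE)
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-centroid frame-to-frame linking of labelled masks. Pairs
#' of detections are linked in order of increasing distance; a link longer
#' than `max_jump` (or a missed detection) terminates the track and any
#' unmatched detection starts a new one.
#'
#' @param frames list of integer label matrices (0 = background), one per
#'   frame, as produced by e.g. [label_components()].
#' @param dt frame interval in hours.
#' @param pixel_size micrometres per pixel.
#' @param max_jump maximum linking distance in micrometres.
#' @return a list of [cell_track()].
#' @export
link_tracks <- function(frames, dt = 0.25, pixel_size = 1, max_jump = 20) {
  stopifnot(length(frames) >= 2L, dt > 0, max_jump > 0)
  cents <- lapply(frames, function(lab) {
    lab <- as.matrix(lab)
    labs <- sort(unique(lab[lab > 0]))
    if (!length(labs)) return(matrix(numeric(0), 0, 2))
    t(vapply(labs, function(l) {
      idx <- which(lab == l, arr.ind = TRUE)
      c((mean(idx[, 2]) - 0.5) * pixel_size, (mean(idx[, 1]) - 0.5) * pixel_size)
    }, numeric(2)))
  })
  open_tracks <- list()   # active: list(xs, ys, t0_frame)
  done_tracks <- list()
  prev <- cents[[1]]
  for (i in seq_len(nrow(prev))) {
    open_tracks[[i]] <- list(x = prev[i, 1], y = prev[i, 2], t0 = 1L)
  }
  for (f in 2:length(frames)) {
    cur <- cents[[f]]
    n_open <- length(open_tracks)
    n_cur <- nrow(cur)
    assigned_open <- rep(FALSE, n_open)
    assigned_cur <- rep(FALSE, n_cur)
    if (n_open > 0L && n_cur > 0L) {
      last_xy <- t(vapply(open_tracks, function(tr)
        c(tail(tr$x, 1), tail(tr$y, 1)), numeric(2)))
      d <- sqrt(outer(last_xy[, 1], cur[, 1], "-")^2 +
                  outer(last_xy[, 2], cur[, 2], "-")^2)
      ord <- order(d)
      for (k in ord) {
        if (d[k] > max_jump) break
        oi <- (k - 1L) %% n_open + 1L
        ci <- (k - 1L) %/% n_open + 1L
        if (assigned_open[oi] || assigned_cur[ci]) next
        assigned_open[oi] <- TRUE
        assigned_cur[ci] <- TRUE
        open_tracks[[oi]]$x <- c(open_tracks[[oi]]$x, cur[ci, 1])
        open_tracks[[oi]]$y <- c(open_tracks[[oi]]$y, cur[ci, 2])
      }
    }
    # close unmatched tracks, open new ones for unmatched detections
    if (n_open > 0L) {
      done_tracks <- c(done_tracks, open_tracks[!assigned_open])
      open_tracks <- open_tracks[assigned_open]
    }
    if (n_cur > 0L) {
      for (ci in which(!assigned_cur)) {
        open_tracks[[length(open_tracks) + 1L]] <-
          list(x = cur[ci, 1], y = cur[ci, 2], t0 = f)
      }
    }
  }
  done_tracks <- c(done_tracks, open_tracks)
  tracks <- lapply(seq_along(done_tracks), function(i) {
    tr <- done_tracks[[i]]
    nf <- length(tr$x)
    t0 <- (tr$t0 - 1L) * dt
    cell_track(paste0("track_", i), time_h = t0 + (seq_len(nf) - 1L) * dt,
               x_um = tr$x, y_um = tr$y, dt = dt)
  })
  tracks[order(vapply(tracks, function(t) t$data$time_h[1], numeric(1)))]
}
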