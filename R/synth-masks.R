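#' Parameters of a synthetic cell-shape archetype
#'
#' Describes one of the four morphological archetypes as a star-convex
#' body with phenotype-specific protrusions: small blebbing (`BB`) is a
#' round body with small hemispherical bumps, actin-enriched leading edge
#' (`AE`) a round body with a few sharp spikes, filopodial (`FP`) an
#' elongated body with long thin spikes near its poles, and lamellipodial
#' (`LA`) a polarised body with one fan-shaped lobe.
#'
#' @param phenotype one of `"AE"`, `"BB"`, `"FP"`, `"LA"`.
#' @param body_radius cell-body radius in micrometres (> 0).
#' @param protrusion_count number of protrusions (>= 0).
#' @param protrusion_length protrusion length in micrometres (>= 0).
#' @param protrusion_width protrusion width in micrometres (> 0).
#' @param elongation body aspect ratio (>= 1; 1 = round).
#' @param noise_amplitude boundary-noise amplitude relative to
#'   `body_radius`, in `[0, 1)`.
#' @return an object of class `archetype_params`.
#' @export
#' @examples
#' archetype_params("FP", body_radius = 8, protrusion_count = 4,
#'                  protrusion_length = 16, elongation = 3)
archetype_params <- function(phenotype, body_radius = 10,
                             protrusion_count = 4, protrusion_length = 5,
                             protrusion_width = 3, elongation = 1,
                             noise_amplitude = 0.05) {
  phenotype <- match.arg(phenotype, phenotype_levels())
  stopifnot(body_radius > 0, protrusion_count >= 0, protrusion_length >= 0,
            protrusion_width > 0, elongation >= 1,
            noise_amplitude >= 0, noise_amplitude < 1)
  structure(list(phenotype = phenotype, body_radius = body_radius,
                 protrusion_count = as.integer(protrusion_count),
                 protrusion_length = protrusion_length,
                 protrusion_width = protrusion_width,
                 elongation = elongation,
                 noise_amplitude = noise_amplitude),
            class = "archetype_params")
}

#' Default archetype library
#'
#' One [archetype_params()] per trainable phenotype, tuned so the four
#' archetypes are well separated in shape space (e.g. the filopodial
#' archetype's aspect ratio exceeds twice the blebbing archetype's by
#' construction).
#'
#' @return named list of `archetype_params`, names `AE`, `BB`, `FP`, `LA`.
#' @export
archetype_library_default <- function() {
  list(
    AE = archetype_params("AE", body_radius = 10, protrusion_count = 3,
                          protrusion_length = 7, protrusion_width = 2.5,
                          elongation = 1.1, noise_amplitude = 0.06),
    BB = archetype_params("BB", body_radius = 10, protrusion_count = 8,
                          protrusion_length = 2.5, protrusion_width = 5,
                          elongation = 1, noise_amplitude = 0.05),
    FP = archetype_params("FP", body_radius = 8, protrusion_count = 4,
                          protrusion_length = 16, protrusion_width = 2.5,
                          elongation = 3, noise_amplitude = 0.06),
    LA = archetype_params("LA", body_radius = 10, protrusion_count = 1,
                          protrusion_length = 10, protrusion_width = 14,
                          elongation = 1.4, noise_amplitude = 0.06)
  )
}

#' Render a synthetic archetype mask
#'
#' Rasterises the star-convex archetype boundary onto a pixel grid with a
#' 20 percent margin. The boundary radius is the body ellipse plus
#' phenotype-specific protrusion bumps plus a low-order random Fourier
#' perturbation of relative amplitude `noise_amplitude`. Identical
#' parameters and seed give a bit-identical mask.
#'
#' @param params an [archetype_params()].
#' @param pixel_size micrometres per pixel.
#' @param seed integer seed for boundary noise and protrusion placement.
#' @return a [binary_mask()] containing a single 8-connected component.
#' @export
#' @examples
#' m <- generate_archetype_mask(archetype_library_default()$BB, seed = 1)
generate_archetype_mask <- function(params, pixel_size = 1, seed = 1) {
  stopifnot(inherits(params, "archetype_params"), pixel_size > 0)
  geom <- with_seed(seed, archetype_geometry(params))
  rasterize_archetype(geom, pixel_size, fail_param = "protrusion_width")
}

# Draws the random realisation of an archetype: a polar body boundary
# (ellipse + low-order Fourier noise + wide polar protrusions for blebs
# and the fan lobe) plus capsule spikes (constant-width segments) for the
# sharp filopodial / actin-spike protrusions.
archetype_geometry <- function(params) {
  p <- params
  a <- p$body_radius * p$elongation
  b <- p$body_radius
  k <- p$protrusion_count
  polar_centers <- polar_widths <- numeric(0)
  capsules <- NULL
  if (k > 0L) {
    phase <- runif(1, 0, 2 * pi)
    if (p$phenotype %in% c("BB", "LA")) {
      polar_centers <- switch(p$phenotype,
        BB = phase + 2 * pi * (seq_len(k) - 1) / k +
          rnorm(k, 0, 0.15 / max(k, 1)),
        LA = phase + rnorm(k, 0, 0.1))
      polar_widths <- rep(p$protrusion_width / (2 * b), k)
    } else {
      # AE: spikes spread around the body; FP: spikes near the poles
      centers <- switch(p$phenotype,
        AE = phase + 2 * pi * (seq_len(k) - 1) / k + rnorm(k, 0, 0.2),
        FP = rep(c(0, pi), length.out = k) + rnorm(k, 0, 0.25))
      r_base <- a * b / sqrt((b * cos(centers))^2 + (a * sin(centers))^2)
      len <- p$protrusion_length * exp(rnorm(k, 0, 0.1))
      capsules <- data.frame(
        x0 = 0.6 * r_base * cos(centers), y0 = 0.6 * r_base * sin(centers),
        x1 = (r_base + len) * cos(centers), y1 = (r_base + len) * sin(centers),
        half_width = rep(p$protrusion_width / 2, k))
    }
  }
  n_modes <- 6L
  amp <- p$noise_amplitude * b
  coefs <- if (amp > 0) rnorm(n_modes, 0, amp / sqrt(n_modes)) else
    numeric(n_modes)
  phis <- runif(n_modes, 0, 2 * pi)
  boundary <- function(theta) {
    r <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
    if (length(polar_centers)) {
      for (i in seq_along(polar_centers)) {
        d <- atan2(sin(theta - polar_centers[i]), cos(theta - polar_centers[i]))
        if (p$phenotype == "LA") {
          w <- polar_widths[i]
          lobe <- ifelse(abs(d) < w, cos(pi * d / (2 * w)), 0)
          r <- r + p$protrusion_length * pmax(lobe, 0)^0.5
        } else {
          r <- r + p$protrusion_length * exp(-0.5 * (d / polar_widths[i])^2)
        }
      }
    }
    for (m in seq_len(n_modes)) {
      r <- r + coefs[m] * cos((m + 1) * theta + phis[m])
    }
    pmax(r, 0.3 * b)
  }
  reach <- max(boundary(seq(0, 2 * pi, length.out = 721L)))
  if (!is.null(capsules)) {
    reach <- max(reach, sqrt(capsules$x1^2 + capsules$y1^2) +
                   capsules$half_width)
  }
  list(boundary = boundary, capsules = capsules, reach = reach)
}

rasterize_archetype <- function(geom, pixel_size, fail_param = NULL) {
  half <- ceiling(1.2 * geom$reach / pixel_size) # 20 percent margin
  n <- 2L * half + 1L
  ctr <- half + 1L
  x <- (matrix(rep(seq_len(n), each = n), n, n) - ctr) * pixel_size
  y <- (matrix(rep(seq_len(n), times = n), n, n) - ctr) * pixel_size
  d <- sqrt(x^2 + y^2)
  th <- atan2(y, x)
  g <- d <= matrix(geom$boundary(as.vector(th)), n, n)
  caps <- geom$capsules
  if (!is.null(caps)) {
    for (i in seq_len(nrow(caps))) {
      ex <- caps$x1[i] - caps$x0[i]
      ey <- caps$y1[i] - caps$y0[i]
      len2 <- ex^2 + ey^2
      t <- pmin(pmax(((x - caps$x0[i]) * ex + (y - caps$y0[i]) * ey) / len2,
                     0), 1)
      dx <- x - (caps$x0[i] + t * ex)
      dy <- y - (caps$y0[i] + t * ey)
      g <- g | (dx^2 + dy^2 <= caps$half_width[i]^2)
    }
  }
  ncomp <- max(label_components(g))
  if (ncomp != 1L) {
    stop("rasterised archetype mask is not a single connected component (",
         ncomp, " components); increase ",
         if (is.null(fail_param)) "protrusion_width" else fail_param,
         " relative to pixel_size")
  }
  binary_mask(g, pixel_size = pixel_size)
}

#' Generate a labelled archetype training set
#'
#' Renders `n_per_class` masks per trainable phenotype from an archetype
#' library, with mild multiplicative jitter of body radius and protrusion
#' length plus independent boundary noise, and computes their shape
#' vectors. This is the standard internal fixture for classifier training
#' and embedding tests.
#'
#' @param n_per_class masks per phenotype.
#' @param library archetype library; default [archetype_library_default()].
#' @param pixel_size micrometres per pixel.
#' @param jitter log-normal standard deviation of the per-mask size jitter.
#' @param seed integer master seed.
#' @param return_masks also return the rendered masks.
#' @return list with `features` (matrix, one row per mask, 21 columns),
#'   `labels` (character) and optionally `masks`.
#' @export
generate_archetype_set <- function(n_per_class = 100,
                                   library = archetype_library_default(),
                                   pixel_size = 1, jitter = 0.08, seed = 1,
                                   return_masks = FALSE) {
  classes <- names(library)
  rows <- vector("list", n_per_class * length(classes))
  labels <- character(length(rows))
  masks <- if (return_masks) vector("list", length(rows)) else NULL
  i <- 0L
  for (ci in seq_along(classes)) {
    base <- library[[ci]]
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      s <- derive_seed(seed, (ci - 1L) * n_per_class + j)
      jit <- with_seed(derive_seed(s, 999), exp(rnorm(2, 0, jitter)))
      pj <- base
      pj$body_radius <- base$body_radius * jit[1]
      pj$protrusion_length <- base$protrusion_length * jit[2]
      m <- generate_archetype_mask(pj, pixel_size = pixel_size, seed = s)
      rows[[i]] <- compute_shape_vector(m)
      labels[i] <- classes[ci]
      if (return_masks) masks[[i]] <- m
    }
  }
  features <- do.call(rbind, lapply(rows, unclass))
  rownames(features) <- NULL
  out <- list(features = features, labels = labels)
  if (return_masks) out$masks <- masks
  out
}

#' Render a phenotype-switching track as a mask movie
#'
#' Produces one mask per frame, drawn from the frame phenotype's archetype
#' and placed at the frame's centroid on a canvas sized to contain every
#' frame (20 percent margin). Intermediate (`INT`) frames are rendered as
#' the previous definite phenotype's archetype with protrusion length
#' halved.
#'
#' @param track a [cell_track()] with phenotype labels.
#' @param archetype_library named list of [archetype_params()] covering all
#'   non-INT labels in the track.
#' @param pixel_size micrometres per pixel.
#' @param seed integer seed (per-frame boundary noise).
#' @param max_canvas_px refuse to allocate a canvas larger than this on a
#'   side, reporting the required size.
#' @return list of [binary_mask()], one per frame, sharing one canvas.
#' @export
render_track_movie <- function(track, archetype_library = archetype_library_default(),
                               pixel_size = 1, seed = 1,
                               max_canvas_px = 2000L) {
  stopifnot(inherits(track, "cell_track"))
  ph <- track$data$phenotype
  if (any(is.na(ph))) stop("track must have phenotype labels on every frame")
  defs <- unique(ph[ph != "INT"])
  missing_arch <- setdiff(defs, names(archetype_library))
  if (length(missing_arch)) {
    stop("archetype_library lacks phenotype(s): ",
         paste(missing_arch, collapse = ", "))
  }
  # INT frames: previous definite label (or next, for a leading INT run)
  eff <- ph
  last_def <- NA_character_
  for (i in seq_along(eff)) {
    if (eff[i] != "INT") last_def <- eff[i] else if (!is.na(last_def)) eff[i] <- last_def
  }
  nxt <- NA_character_
  for (i in rev(seq_along(eff))) {
    if (ph[i] != "INT") nxt <- ph[i] else if (eff[i] == "INT" && !is.na(nxt)) eff[i] <- nxt
  }
  if (any(eff == "INT")) stop("track has no definite phenotype frame")

  rmax <- max(vapply(archetype_library, function(p)
    p$body_radius * p$elongation + p$protrusion_length +
      p$noise_amplitude * p$body_radius, numeric(1)))
  x <- track$data$x_um; y <- track$data$y_um
  pad <- 1.2 * rmax
  x0 <- min(x) - pad; y0 <- min(y) - pad
  ncol_px <- ceiling((max(x) + pad - x0) / pixel_size) + 1L
  nrow_px <- ceiling((max(y) + pad - y0) / pixel_size) + 1L
  if (max(ncol_px, nrow_px) > max_canvas_px) {
    stop("track movie needs a ", nrow_px, "x", ncol_px,
         " px canvas, above the limit of ", max_canvas_px,
         " px; reduce extent or increase pixel_size")
  }
  lapply(seq_along(eff), function(i) {
    pars <- archetype_library[[eff[i]]]
    if (ph[i] == "INT") pars$protrusion_length <- pars$protrusion_length * 0.5
    cell <- generate_archetype_mask(pars, pixel_size = pixel_size,
                                    seed = derive_seed(seed, i))
    place_on_canvas(cell$grid, nrow_px, ncol_px,
                    row = round((y[i] - y0) / pixel_size) + 1L,
                    col = round((x[i] - x0) / pixel_size) + 1L,
                    pixel_size = pixel_size)
  })
}

place_on_canvas <- function(g, nrow_px, ncol_px, row, col, pixel_size) {
  canvas <- matrix(FALSE, nrow_px, ncol_px)
  hr <- (nrow(g) - 1L) %/% 2L
  hc <- (ncol(g) - 1L) %/% 2L
  r0 <- row - hr; c0 <- col - hc
  rr <- seq_len(nrow(g)) + r0 - 1L
  cc <- seq_len(ncol(g)) + c0 - 1L
  keep_r <- rr >= 1L & rr <= nrow_px
  keep_c <- cc >= 1L & cc <= ncol_px
  canvas[rr[keep_r], cc[keep_c]] <- g[keep_r, keep_c]
  binary_mask(canvas, pixel_size = pixel_size, check = FALSE)
}
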