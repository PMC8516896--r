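#' Primitive calibration masks
#'
#' Simple digital shapes with known continuum geometry, used to calibrate
#' and sanity-check the shape measures: a disk (form factor at its 4*pi
#' minimum), an axis-aligned rectangle (extent and solidity exactly 1), a
#' semicircular band of centreline radius R (skeleton length close to pi*R
#' and curl close to 2/pi), and a plus-sign polyomino (concave, for
#' convex-hull checks).
#'
#' @param radius disk radius in pixels.
#' @param pixel_size micrometres per pixel.
#' @param margin background margin in pixels around the shape.
#' @return a [binary_mask()].
#' @export
#' @examples
#' compute_shape_vector(square_mask(30))[c("extent", "solidity")]
disk_mask <- function(radius, pixel_size = 1, margin = 3) {
  n <- 2 * (radius + margin) + 1
  ctr <- (n + 1) / 2
  xy <- seq_len(n) - ctr
  d2 <- outer(xy^2, xy^2, "+")
  binary_mask(d2 <= radius^2, pixel_size = pixel_size)
}

#' @rdname disk_mask
#' @param width,height rectangle sides in pixels (`height` defaults to
#'   `width`, giving a square).
#' @export
square_mask <- function(width, height = width, pixel_size = 1, margin = 3) {
  g <- matrix(FALSE, height + 2 * margin, width + 2 * margin)
  g[margin + seq_len(height), margin + seq_len(width)] <- TRUE
  binary_mask(g, pixel_size = pixel_size)
}

#' @rdname disk_mask
#' @param band_width radial thickness of the band in pixels.
#' @param angle_range angular extent in radians (default a half circle).
#' @export
band_mask <- function(radius, band_width = 5, angle_range = c(0, pi),
                      pixel_size = 1, margin = 3) {
  rmax <- radius + band_width / 2
  n <- 2 * ceiling(rmax + margin) + 1
  ctr <- (n + 1) / 2
  x <- matrix(rep(seq_len(n) - ctr, each = n), n, n)
  y <- matrix(rep(-(seq_len(n) - ctr), times = n), n, n) # y upward for angles
  r <- sqrt(x^2 + y^2)
  th <- atan2(y, x)
  th[th < 0] <- th[th < 0] + 2 * pi
  g <- r >= radius - band_width / 2 & r <= radius + band_width / 2 &
    th >= angle_range[1] & th <= angle_range[2]
  binary_mask(g, pixel_size = pixel_size)
}

#' @rdname disk_mask
#' @param arm_width,arm_length width and full length of each arm in pixels.
#' @export
plus_mask <- function(arm_width = 3, arm_length = 9, pixel_size = 1,
                      margin = 3) {
  n <- arm_length + 2 * margin
  g <- matrix(FALSE, n, n)
  lo <- margin + floor((arm_length - arm_width) / 2) + 1
  hi <- lo + arm_width - 1
  g[lo:hi, margin + seq_len(arm_length)] <- TRUE
  g[margin + seq_len(arm_length), lo:hi] <- TRUE
  binary_mask(g, pixel_size = pixel_size)
}
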