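#' Binary cell mask
#'
#' One segmented cell per frame: a logical pixel grid plus the physical
#' pixel size. Rows index y (downward), columns index x (rightward); pixel
#' centres sit at `(col - 0.5, row - 0.5) * pixel_size` micrometres.
#'
#' @param grid logical (or 0/1) matrix, `TRUE` = foreground.
#' @param pixel_size pixel edge length in micrometres (> 0).
#' @param check if `TRUE` (default) require exactly one 8-connected
#'   foreground component; masks touching the image border are flagged with
#'   a warning.
#' @return an object of class `binary_mask`.
#' @export
#' @examples
#' m <- binary_mask(matrix(c(0,1,1,0,1,1,0,0,0), 3, 3) > 0, pixel_size = 1)
binary_mask <- function(grid, pixel_size = 1, check = TRUE) {
  grid <- as.matrix(grid)
  if (is.numeric(grid)) grid <- grid > 0
  stopifnot(is.logical(grid), pixel_size > 0)
  if (!any(grid)) stop("mask has no foreground pixels")
  if (check) {
    ncomp <- max(label_components(grid))
    if (ncomp != 1L) {
      stop("mask must have exactly one 8-connected component (found ",
           ncomp, ")")
    }
    if (any(grid[1, ]) || any(grid[nrow(grid), ]) ||
        any(grid[, 1]) || any(grid[, ncol(grid)])) {
      warning("mask touches the image border; measures may be truncated")
    }
  }
  structure(list(grid = grid, pixel_size = pixel_size), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("Binary mask ", nrow(x$grid), "x", ncol(x$grid), " px (",
      x$pixel_size, " um/px), ", sum(x$grid), " foreground px\n", sep = "")
  invisible(x)
}

# 8-connected labelling via EBImage; returns an integer matrix of labels.
label_components <- function(grid) {
  lab <- EBImage::bwlabel(EBImage::Image(grid * 1))
  storage.mode(lab) <- "integer"
  as.matrix(lab)
}

#' Read and write mask stacks as multi-page TIFF
#'
#' Masks are stored 8-bit, one page per frame, foreground 255.
#'
#' @param masks a `binary_mask` or list of them (a movie).
#' @param path file path.
#' @return `read_mask_tiff()` returns a list of `binary_mask`.
#' @export
write_mask_tiff <- function(masks, path) {
  if (inherits(masks, "binary_mask")) masks <- list(masks)
  pages <- lapply(masks, function(m) m$grid * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @param pixel_size micrometres per pixel to attach on read.
#' @param check passed to [binary_mask()].
#' @export
read_mask_tiff <- function(path, pixel_size = 1, check = TRUE) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    binary_mask(p > 0.5, pixel_size = pixel_size, check = check)
  })
}
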