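#' Single-cell track container
#'
#' A `cell_track` is a uniformly sampled time series for one cell: centroid
#' position in micrometres, optional phenotype dwell-state label per frame,
#' and free-form condition metadata (collagen concentration, gelation
#' temperature, alignment, drug label, ...). Tracks are the common currency
#' of the dynamics modules.
#'
#' @param cell_id scalar identifier.
#' @param time_h numeric vector of frame times in hours, strictly
#'   increasing with constant spacing `dt`.
#' @param x_um,y_um numeric centroid coordinates in micrometres.
#' @param phenotype optional character vector of dwell-state labels
#'   (see [phenotype_states()]); `NA` allowed.
#' @param dt sampling interval in hours; default 0.25 h (4 frames per hour).
#'   Validated against `time_h` to within 1e-9.
#' @param condition optional named list or string of metadata.
#' @return an object of class `cell_track`: a list with elements `cell_id`,
#'   `dt`, `condition` and `data` (a data.frame with columns `time_h`,
#'   `x_um`, `y_um`, `phenotype`).
#' @export
#' @examples
#' tr <- cell_track("c1", time_h = seq(0, 1, by = 0.25),
#'                  x_um = c(0, 1, 2, 2, 3), y_um = c(0, 0, 1, 1, 2),
#'                  phenotype = c("BB", "BB", "INT", "LA", "LA"))
#' n_frames(tr)
cell_track <- function(cell_id, time_h, x_um, y_um, phenotype = NULL,
                       dt = NULL, condition = NULL) {
  n <- length(time_h)
  stopifnot(n >= 1L, length(x_um) == n, length(y_um) == n)
  if (is.null(phenotype)) phenotype <- rep(NA_character_, n)
  stopifnot(length(phenotype) == n)
  if (n >= 2L) {
    gaps <- diff(time_h)
    if (any(gaps <= 0)) stop("time_h must be strictly increasing")
    if (is.null(dt)) dt <- gaps[1L]
    if (any(abs(gaps - dt) > 1e-9)) {
      stop("frame spacing of cell ", cell_id,
           " is not uniform at dt = ", dt, " h")
    }
  } else if (is.null(dt)) dt <- 0.25
  structure(list(
    cell_id = cell_id, dt = dt, condition = condition,
    data = data.frame(time_h = time_h, x_um = x_um, y_um = y_um,
                      phenotype = as.character(phenotype),
                      stringsAsFactors = FALSE)
  ), class = "cell_track")
}

#' @rdname cell_track
#' @param track a `cell_track`.
#' @export
n_frames <- function(track) nrow(track$data)

#' @export
print.cell_track <- function(x, ...) {
  cat("Cell track ", format(x$cell_id), ": ", n_frames(x), " frames, dt = ",
      x$dt, " h (", round(diff(range(x$data$time_h)), 3), " h)\n", sep = "")
  ph <- x$data$phenotype
  if (any(!is.na(ph))) {
    tab <- table(factor(ph, levels = phenotype_states()))
    cat("  occupancy:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

as_track_list <- function(tracks) {
  if (inherits(tracks, "cell_track")) return(list(tracks))
  if (!is.list(tracks) || !all(vapply(tracks, inherits, TRUE, "cell_track"))) {
    stop("expected a cell_track or a list of cell_track objects")
  }
  tracks
}

track_dt <- function(tracks) {
  dts <- vapply(as_track_list(tracks), `[[`, numeric(1), "dt")
  if (diff(range(dts)) > 1e-9) stop("tracks have differing dt")
  dts[1L]
}

#' Convert tracks to and from a flat table
#'
#' `tracks_to_table()` flattens a list of [cell_track()] objects to one
#' data.frame with columns `cell_id`, `frame`, `time_h`, `x_um`, `y_um`,
#' `phenotype`, `condition`; `table_to_tracks()` inverts it (rows may be in
#' any order; they are sorted by time within cell).
#'
#' @param tracks a `cell_track` or list thereof.
#' @return a data.frame, or a list of `cell_track`.
#' @export
tracks_to_table <- function(tracks) {
  tracks <- as_track_list(tracks)
  do.call(rbind, lapply(tracks, function(tr) {
    cond <- tr$condition
    cond_chr <- if (is.null(cond)) "" else
      paste(names(cond), unlist(cond), sep = "=", collapse = ";")
    if (is.null(names(cond)) && length(cond) == 1L) cond_chr <- as.character(cond)
    data.frame(cell_id = tr$cell_id, frame = seq_len(n_frames(tr)),
               tr$data[, c("time_h", "x_um", "y_um", "phenotype")],
               condition = cond_chr, stringsAsFactors = FALSE)
  }))
}

#' @rdname tracks_to_table
#' @param table a data.frame as produced by `tracks_to_table()`.
#' @param dt expected sampling interval in hours, validated per cell;
#'   `NULL` to accept each cell's own spacing.
#' @export
table_to_tracks <- function(table, dt = NULL) {
  required <- c("cell_id", "time_h", "x_um", "y_um")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols)) {
    stop("track table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"phenotype" %in% names(table)) table$phenotype <- NA_character_
  split_rows <- split(table, table$cell_id)
  tracks <- lapply(split_rows, function(df) {
    df <- df[order(df$time_h), , drop = FALSE]
    cond <- if ("condition" %in% names(df) && nzchar(df$condition[1L]))
      df$condition[1L] else NULL
    cell_track(df$cell_id[1L], df$time_h, df$x_um, df$y_um,
               phenotype = df$phenotype, dt = dt, condition = cond)
  })
  unname(tracks)
}
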