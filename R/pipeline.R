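#' Analysis run configuration
#'
#' Central container for every tunable parameter of the pipeline, with
#' the standard defaults: sampling at 4 frames per hour (`dt = 0.25`),
#' definite-call threshold 0.6, 1000 bootstrap iterations, 10 um kernel
#' bandwidth. A resolved copy of the configuration is written alongside
#' every pipeline run.
#'
#' @param dt sampling interval, hours.
#' @param pixel_size micrometres per pixel.
#' @param threshold definite/intermediate probability cutoff.
#' @param n_boot bootstrap iterations.
#' @param bandwidth kernel bandwidth, micrometres.
#' @param int_handling `"explicit"` or `"bridged"` (see
#'   [transition_matrix()]).
#' @param classifier_family `"svm"` or `"random_forest"`.
#' @param measures feature list (default the 21-measure panel).
#' @param seed master seed.
#' @param interface_x optional interface position (micrometres); enables
#'   the spatial stage of [run_pipeline()].
#' @param ... further named entries kept verbatim.
#' @return a list of class `run_config`.
#' @export
run_config <- function(dt = 0.25, pixel_size = 1, threshold = 0.6,
                       n_boot = 1000L, bandwidth = 10,
                       int_handling = "explicit",
                       classifier_family = "svm",
                       measures = shape_measure_names(), seed = 1,
                       interface_x = NULL, ...) {
  stopifnot(dt > 0, pixel_size > 0, threshold > 0, threshold < 1,
            n_boot >= 0, bandwidth > 0)
  structure(list(dt = dt, pixel_size = pixel_size, threshold = threshold,
                 n_boot = as.integer(n_boot), bandwidth = bandwidth,
                 int_handling = int_handling,
                 classifier_family = classifier_family,
                 measures = measures, seed = seed,
                 interface_x = interface_x, ...),
            class = "run_config")
}

#' Read and write track tables
#'
#' Tracks travel as CSV with columns `cell_id`, `frame`, `time_h`,
#' `x_um`, `y_um` and optional `phenotype`, `condition` (units encoded in
#' the column names). On read, rows are grouped by cell and time-sorted;
#' the frame spacing of every cell is validated against `config$dt`, and
#' a skipped frame is reported with the offending cell id.
#'
#' @param path CSV file path.
#' @param config a [run_config()]; its `dt` validates the table.
#' @return `read_track_table()` returns a list of [cell_track()];
#'   `write_track_table()` returns the path invisibly.
#' @export
read_track_table <- function(path, config = run_config()) {
  tab <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  tryCatch(table_to_tracks(tab, dt = config$dt),
           error = function(e) stop("reading ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
}

#' @rdname read_track_table
#' @param tracks a list of [cell_track()].
#' @export
write_track_table <- function(tracks, path) {
  write.csv(tracks_to_table(tracks), path, row.names = FALSE)
  invisible(path)
}

#' Run the full track-level analysis pipeline
#'
#' From labelled tracks (or unlabelled tracks plus a classifier and
#' per-frame shape features) to the complete results bundle: occurrence
#' fractions, dwell times, transition-rate matrix, probability fluxes,
#' step records and per-category log-normal fits, conditional and
#' weighted-average MSDs with effective diffusivities, and (when
#' `config$interface_x` is set) per-layer statistics. Results are
#' returned as a list and, if `out_dir` is given, written as CSV/JSON
#' together with the resolved configuration and its hash.
#'
#' @param tracks labelled tracks (list of [cell_track()]).
#' @param config a [run_config()].
#' @param model optional [train_classifier()] model; required only when
#'   tracks lack phenotype labels (then `features` must give per-frame
#'   shape vectors).
#' @param features optional list (per track) of per-frame feature
#'   matrices used with `model` to label frames.
#' @param out_dir optional output directory.
#' @return a list of class `morphodyn_results`.
#' @export
run_pipeline <- function(tracks, config = run_config(), model = NULL,
                         features = NULL, out_dir = NULL) {
  tracks <- as_track_list(tracks)
  log_lines <- character()
  say <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  unlabelled <- vapply(tracks, function(tr) all(is.na(tr$data$phenotype)),
                       logical(1))
  if (any(unlabelled)) {
    if (is.null(model) || is.null(features)) {
      stop("tracks lack phenotype labels: train a classifier and pass it ",
           "together with per-frame features, or supply labelled tracks")
    }
    for (i in which(unlabelled)) {
      calls <- assign_phenotype(model, features[[i]], config$threshold)
      tracks[[i]]$data$phenotype <- calls$label
    }
    say("classified ", sum(unlabelled), " track(s)")
  }
  say("tracks: ", length(tracks), "; frames: ",
      sum(vapply(tracks, n_frames, integer(1))))

  res <- list(config = config)
  res$fractions <- occurrence_fractions(tracks, n_boot = config$n_boot,
                                        seed = derive_seed(config$seed, 1))
  res$dwell <- dwell_times(tracks, n_boot = config$n_boot,
                           seed = derive_seed(config$seed, 2))
  res$rates <- transition_matrix(tracks,
                                 int_handling = config$int_handling,
                                 n_boot = config$n_boot,
                                 seed = derive_seed(config$seed, 3))
  frac_for_flux <- setNames(res$fractions$fraction, res$fractions$state)
  states_r <- rownames(res$rates)
  res$flux <- probability_flux(frac_for_flux[states_r], res$rates)
  say("rates estimated over ", sum(attr(res$rates, "occupancy_h")),
      " state-hours")

  res$steps <- categorize_steps(tracks)
  res$step_fits <- lapply(split(res$steps$magnitude_um, res$steps$category),
                          function(m) {
    if (sum(m > 0) >= 30L) fit_lognormal(m, n_boot = min(config$n_boot, 500L),
                                         seed = derive_seed(config$seed, 4))
    else paste0("insufficient steps (n = ", length(m), ")")
  })
  say("steps: ", nrow(res$steps), " in ",
      length(unique(res$steps$category)), " categories")

  res$msd_full <- compute_msd(tracks)
  res$msd_conditional <- list(
    AM = conditional_msd(tracks, "AM"),
    ME = conditional_msd(tracks, "ME"),
    INT = conditional_msd(tracks, "INT"))
  cls_frac <- class_fractions(tracks)
  # classes whose dwell segments support at least 3 positive lags enter the
  # weighted average (short-lived classes cannot contribute long lags)
  usable <- vapply(res$msd_conditional, nrow, integer(1)) >= 4L
  if (sum(usable) >= 2L && sum(cls_frac[usable]) > 0) {
    w <- cls_frac[usable] / sum(cls_frac[usable])
    res$msd_weighted <- suppressWarnings(
      weighted_average_msd(res$msd_conditional[usable], w))
    dfit <- function(cv) {
      if (sum(cv$lag_h > 0) >= 2L) effective_diffusivity(cv) else NULL
    }
    res$diffusivity <- list(
      full = dfit(res$msd_full),
      weighted = dfit(res$msd_weighted),
      AM = dfit(res$msd_conditional$AM),
      ME = dfit(res$msd_conditional$ME))
  }
  if (!is.null(config$interface_x)) {
    res$layers <- layer_statistics(tracks, config$interface_x,
                                   n_boot = min(config$n_boot, 200L),
                                   seed = derive_seed(config$seed, 5))
    say("layer statistics at x = ", config$interface_x)
  }
  res$log <- log_lines
  class(res) <- "morphodyn_results"
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

class_fractions <- function(tracks) {
  cc <- coarse_class(unlist(lapply(as_track_list(tracks),
                                   function(tr) tr$data$phenotype)))
  cc <- cc[!is.na(cc)]
  tb <- table(factor(cc, levels = c("AM", "ME", "INT")))
  as.numeric(tb) / sum(tb)
}

#' @export
print.morphodyn_results <- function(x, ...) {
  cat("morphodyn results bundle\n")
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}

write_results <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- res$config
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  cfg_hash <- unname(tools::md5sum(cfg_path))
  stamp <- function(df) {
    attr(df, "config_hash") <- cfg_hash
    df
  }
  write.csv(stamp(res$fractions), file.path(out_dir, "fractions.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(res$dwell), file.path(out_dir, "dwell.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(res$steps), file.path(out_dir, "steps.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(res$msd_full), file.path(out_dir, "msd_full.csv"),
            row.names = FALSE)
  dynamics <- list(
    config_hash = cfg_hash,
    rates = unclass(res$rates),
    rate_counts = attr(res$rates, "counts"),
    occupancy_h = as.list(attr(res$rates, "occupancy_h")),
    flux = res$flux$J,
    detailed_balance_score = res$flux$score,
    step_fits = lapply(res$step_fits, function(f)
      if (inherits(f, "lognormal_fit")) unclass(f)[c("m", "sigma2", "n")]
      else f),
    diffusivity = lapply(res$diffusivity, function(d)
      if (inherits(d, "diffusivity_estimate")) d$D_per_dim else NULL),
    log = res$log
  )
  jsonlite::write_json(dynamics, file.path(out_dir, "dynamics.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(out_dir)
}
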