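#' Log-normal step-size model coupled to coarse-class dynamics
#'
#' Cell displacements over one sampling interval are modelled as isotropic
#' 2-D steps whose magnitude (in micrometres) is log-normal, with parameters
#' that depend on the step category: the ordered pair of coarse classes
#' (`AM`, `ME`, `INT`) at the start and end frame of the step
#' (e.g. an `"AM-ME"` step starts in the amoeboidal class and ends in the
#' mesenchymal class).
#'
#' @param log_mean named numeric vector: mean of `log(step magnitude in um)`
#'   per category. Names must be of the form `"AM-ME"`.
#' @param log_variance named numeric vector of the same length: variance of
#'   the log step magnitude per category (> 0).
#' @return an object of class `step_model`.
#' @details The defaults are calibrated so that cells dwelling in the
#'   amoeboidal class diffuse with an effective diffusivity of about
#'   6 um^2/h per spatial dimension and mesenchymal dwellers about
#'   19 um^2/h (sampling interval 0.25 h), steps concurrent with a class
#'   switch are larger than dwell steps, and the natural-scale variance of
#'   ME-to-AM steps is roughly twice that of AM-to-ME steps.
#' @export
#' @examples
#' sm <- step_model_default()
#' step_categories()
step_model <- function(log_mean, log_variance) {
  cats <- step_categories()
  stopifnot(is.numeric(log_mean), is.numeric(log_variance))
  if (!all(cats %in% names(log_mean)) || !all(cats %in% names(log_variance))) {
    stop("log_mean and log_variance must be named for all 9 categories: ",
         paste(cats, collapse = ", "))
  }
  log_mean <- log_mean[cats]
  log_variance <- log_variance[cats]
  if (any(!is.finite(log_mean)) || any(!is.finite(log_variance)) ||
      any(log_variance <= 0)) {
    stop("log_variance must be finite and > 0")
  }
  structure(list(log_mean = log_mean, log_variance = log_variance),
            class = "step_model")
}

#' @rdname step_model
#' @export
step_categories <- function() {
  cls <- c("AM", "ME", "INT")
  as.vector(t(outer(cls, cls, function(a, b) paste(a, b, sep = "-"))))
}

#' @rdname step_model
#' @export
step_model_default <- function() {
  # E[X^2] = exp(2 mu + 2 sigma^2) equals 4 * D_eff * dt at dt = 0.25 h
  lv <- c("AM-AM" = 0.5, "AM-ME" = 0.5, "AM-INT" = 0.5,
          "ME-AM" = 0.78, "ME-ME" = 0.5, "ME-INT" = 0.5,
          "INT-AM" = 0.5, "INT-ME" = 0.5, "INT-INT" = 0.5)
  lm_ <- c("AM-AM" = 0.396, "AM-ME" = 1.00, "AM-INT" = 0.65,
           "ME-AM" = 0.90, "ME-ME" = 0.972, "ME-INT" = 0.80,
           "INT-AM" = 0.55, "INT-ME" = 0.85, "INT-INT" = 0.651)
  step_model(lm_, lv)
}

#' @export
print.step_model <- function(x, ...) {
  cat("Log-normal step model (9 coarse-class categories)\n")
  print(round(rbind(log_mean = x$log_mean, log_variance = x$log_variance), 3))
  invisible(x)
}

# Draw one step magnitude (um) for a category.
draw_step_magnitude <- function(model, category) {
  m <- model$log_mean[[category]]
  v <- model$log_variance[[category]]
  exp(rnorm(1L, mean = m, sd = sqrt(v)))
}

step_category_of <- function(from, to, map = coarse_map_default()) {
  paste(coarse_class(from, map), coarse_class(to, map), sep = "-")
}
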