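#' Simulate a phenotype-switching motile track
#'
#' Simulates the generative model underlying the analysis: phenotype
#' dwell-state dynamics are a continuous-time Markov chain with generator
#' `Q`, observed at the sampling interval `dt`; the centroid performs a
#' 2-D random walk whose step magnitudes over each interval are log-normal
#' with parameters set by the step's coarse-class category (start class,
#' end class), and whose directions are isotropic.
#'
#' @param Q a [rate_matrix()] over phenotype dwell states.
#' @param steps a [step_model()].
#' @param duration track duration in hours (>= dt).
#' @param dt sampling interval in hours; default 0.25 (4 frames per hour).
#' @param seed integer seed.
#' @param initial_state starting state; default samples the stationary
#'   distribution of `Q` (uniform if `Q` has absorbing structure).
#' @param origin starting centroid `(x, y)` in micrometres.
#' @param cell_id identifier for the returned track.
#' @param condition metadata attached to the track.
#' @return a [cell_track()] with `floor(duration / dt) + 1` frames.
#' @export
#' @examples
#' tr <- simulate_phenotype_track(default_rate_matrix(), step_model_default(),
#'                                duration = 10, seed = 1)
simulate_phenotype_track <- function(Q, steps, duration, dt = 0.25, seed = 1,
                                     initial_state = NULL, origin = c(0, 0),
                                     cell_id = "sim_1", condition = NULL) {
  stopifnot(is_rate_matrix(Q), inherits(steps, "step_model"))
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  if (duration < dt) stop("duration must be at least dt")
  states <- rownames(Q)
  if (is.null(initial_state)) {
    initial_state <- with_seed(derive_seed(seed, 0), sample_stationary(Q))
  }
  stopifnot(initial_state %in% states)
  n_frames <- floor(duration / dt + 1e-9) + 1L
  labels <- with_seed(derive_seed(seed, 1),
                      ctmc_observe(Q, initial_state, dt, n_frames))
  xy <- with_seed(derive_seed(seed, 2), walk_from_labels(labels, steps, origin))
  cell_track(cell_id, time_h = (seq_len(n_frames) - 1L) * dt,
             x_um = xy[, 1], y_um = xy[, 2], phenotype = labels,
             dt = dt, condition = condition)
}

sample_stationary <- function(Q) {
  states <- rownames(Q)
  p <- tryCatch(stationary_distribution(Q), error = function(e) NULL)
  if (is.null(p) || any(!is.finite(p)) || any(p < 0)) {
    p <- rep(1 / length(states), length(states))
  }
  sample(states, 1L, prob = p)
}

# Exact Gillespie simulation of the chain, observed at frame times.
ctmc_observe <- function(Q, state, dt, n_frames) {
  states <- rownames(Q)
  t_end <- (n_frames - 1L) * dt
  jump_t <- 0
  path_t <- 0
  path_s <- state
  cur <- state
  while (jump_t < t_end) {
    i <- match(cur, states)
    lambda <- -Q[i, i]
    if (lambda <= 0) break # absorbing
    jump_t <- jump_t + rexp(1L, lambda)
    if (jump_t >= t_end) break
    pr <- unclass(Q)[i, ]
    pr[i] <- 0
    cur <- sample(states, 1L, prob = pr / lambda)
    path_t <- c(path_t, jump_t)
    path_s <- c(path_s, cur)
  }
  obs_t <- (seq_len(n_frames) - 1L) * dt
  path_s[findInterval(obs_t + 1e-12, path_t)]
}

walk_from_labels <- function(labels, steps, origin) {
  n <- length(labels)
  xy <- matrix(0, n, 2)
  xy[1, ] <- origin
  if (n >= 2L) {
    for (k in seq_len(n - 1L)) {
      cat_k <- step_category_of(labels[k], labels[k + 1L])
      mag <- draw_step_magnitude(steps, cat_k)
      ang <- runif(1L, 0, 2 * pi)
      xy[k + 1L, ] <- xy[k, ] + mag * c(cos(ang), sin(ang))
    }
  }
  xy
}

#' Simulate a two-layer ECM population
#'
#' Cells move in a plane split at `x = x_interface` into two layers with
#' different phenotype-switching generators (emulating collagen gelled at
#' two temperatures). At each frame the chain evolves over one interval
#' under the generator of the layer containing the cell's current
#' position, then the cell steps according to the step model.
#'
#' @param Q_left,Q_right generators for `x < x_interface` and
#'   `x >= x_interface`; must share one state set.
#' @param steps a [step_model()].
#' @param n_cells number of cells.
#' @param duration,dt hours.
#' @param x_interface interface position in micrometres (default 0).
#' @param seed integer master seed.
#' @param x_half_width initial positions are scattered uniformly over
#'   `x_interface + c(-1, 1) * x_half_width` micrometres.
#' @param y_width initial y positions uniform on `[0, y_width]`.
#' @return list of [cell_track()].
#' @export
simulate_two_layer_population <- function(Q_left, Q_right, steps,
                                          n_cells = 20, duration = 24,
                                          dt = 0.25, x_interface = 0,
                                          seed = 1, x_half_width = 150,
                                          y_width = 150) {
  stopifnot(is_rate_matrix(Q_left), is_rate_matrix(Q_right))
  if (!identical(rownames(Q_left), rownames(Q_right))) {
    stop("Q_left and Q_right must share the same state set")
  }
  states <- rownames(Q_left)
  n_frames <- floor(duration / dt + 1e-9) + 1L
  lapply(seq_len(n_cells), function(ci) {
    with_seed(derive_seed(seed, ci), {
      x <- numeric(n_frames); y <- numeric(n_frames)
      lab <- character(n_frames)
      x[1] <- runif(1, x_interface - x_half_width, x_interface + x_half_width)
      y[1] <- runif(1, 0, y_width)
      q0 <- if (x[1] < x_interface) Q_left else Q_right
      lab[1] <- sample_stationary(q0)
      for (k in seq_len(n_frames - 1L)) {
        q <- if (x[k] < x_interface) Q_left else Q_right
        lab[k + 1L] <- ctmc_observe(q, lab[k], dt, 2L)[2L]
        mag <- draw_step_magnitude(steps, step_category_of(lab[k], lab[k + 1L]))
        ang <- runif(1L, 0, 2 * pi)
        x[k + 1L] <- x[k] + mag * cos(ang)
        y[k + 1L] <- y[k] + mag * sin(ang)
      }
      cell_track(paste0("cell_", ci), time_h = (seq_len(n_frames) - 1L) * dt,
                 x_um = x, y_um = y, phenotype = lab, dt = dt,
                 condition = list(x_interface = x_interface))
    })
  })
}

#' Simulate a mean-reverting shape-measure series
#'
#' An Ornstein-Uhlenbeck process sampled at interval `dt`: a stationary,
#' mean-reverting stand-in for the fluctuation of one standardized shape
#' measure. Its mean-square displacement is `2 v (1 - exp(-lag / theta))`,
#' which plateaus at twice the stationary variance — the subdiffusive
#' signature used to contrast shape-space dynamics with centroid motion.
#'
#' @param n number of samples.
#' @param theta relaxation time in hours.
#' @param variance stationary variance.
#' @param dt sampling interval in hours.
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
simulate_ou_series <- function(n, theta = 1, variance = 1, dt = 0.25,
                               seed = 1) {
  stopifnot(n >= 1, theta > 0, variance > 0, dt > 0)
  with_seed(seed, {
    x <- numeric(n)
    x[1] <- rnorm(1, 0, sqrt(variance))
    a <- exp(-dt / theta)
    s <- sqrt(variance * (1 - a^2))
    for (k in seq_len(n - 1L)) x[k + 1L] <- a * x[k] + rnorm(1, 0, s)
    x
  })
}
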