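#' Occurrence fractions of phenotype dwell states
#'
#' Fraction of all observed frames spent in each dwell state, with
#' cell-level bootstrap confidence intervals (the resampling unit is the
#' whole track, respecting temporal correlation).
#'
#' @param tracks a [cell_track()] or list thereof, with phenotype labels.
#' @param states dwell-state set; default the five phenotype states.
#' @param n_boot bootstrap iterations (default 1000); 0 to skip.
#' @param seed integer seed for the bootstrap.
#' @return data.frame with columns `state`, `fraction`, `lower`, `upper`,
#'   `n_frames`. Fractions sum to 1.
#' @export
occurrence_fractions <- function(tracks, states = phenotype_states(),
                                 n_boot = 1000L, seed = 1) {
  tracks <- as_track_list(tracks)
  assert_states(states)
  labs <- lapply(tracks, function(tr) tr$data$phenotype)
  check_labels(labs, states)
  frac_of <- function(trs) {
    l <- unlist(lapply(trs, function(tr) tr$data$phenotype))
    l <- l[!is.na(l)]
    if (!length(l)) stop("no labelled frames")
    as.numeric(table(factor(l, levels = states))) / length(l)
  }
  point <- frac_of(tracks)
  ci <- matrix(NA_real_, length(states), 2L)
  if (n_boot > 0L && length(tracks) >= 2L) {
    bs <- bootstrap_ci(frac_of, tracks, n_boot = n_boot, seed = seed)
    ci <- cbind(bs$lower, bs$upper)
  }
  data.frame(state = states, fraction = point,
             lower = ci[, 1], upper = ci[, 2],
             n_frames = sum(lengths(labs)))
}

check_labels <- function(labs, states) {
  all_labs <- unique(unlist(labs))
  unknown <- setdiff(all_labs[!is.na(all_labs)], states)
  if (length(unknown)) {
    stop("unknown dwell-state label(s): ", paste(unknown, collapse = ", "))
  }
}

#' Dwell times of phenotype states
#'
#' A dwell episode is a maximal run of consecutive frames in one state;
#' its duration is the run length times the sampling interval. Episodes
#' touching a track boundary are censored (the full dwell was not
#' observed) and excluded from the mean under the default rule; censored
#' counts are reported. Confidence intervals are cell-level bootstrap.
#'
#' @inheritParams occurrence_fractions
#' @param censoring `"drop_boundary"` (default) excludes boundary-touching
#'   episodes from means; `"include"` keeps them (biased low).
#' @return an object of class `dwell_stats`: data.frame with columns
#'   `state`, `mean_dwell_h`, `lower`, `upper`, `n_completed`,
#'   `n_censored`. States never observed completing an episode have
#'   `NA` mean.
#' @export
dwell_times <- function(tracks, states = phenotype_states(),
                        censoring = c("drop_boundary", "include"),
                        n_boot = 1000L, seed = 1) {
  censoring <- match.arg(censoring)
  tracks <- as_track_list(tracks)
  assert_states(states)
  check_labels(lapply(tracks, function(tr) tr$data$phenotype), states)
  eps <- dwell_episodes(tracks)
  mean_of <- function(trs) {
    e <- dwell_episodes(trs)
    vapply(states, function(s) {
      keep <- e$state == s & (censoring == "include" | !e$censored)
      if (!any(keep)) NA_real_ else mean(e$duration_h[keep])
    }, numeric(1))
  }
  point <- mean_of(tracks)
  ci <- matrix(NA_real_, length(states), 2L)
  if (n_boot > 0L && length(tracks) >= 2L) {
    bs <- bootstrap_ci(mean_of, tracks, n_boot = n_boot, seed = seed)
    ci <- cbind(bs$lower, bs$upper)
  }
  out <- data.frame(
    state = states, mean_dwell_h = unname(point),
    lower = ci[, 1], upper = ci[, 2],
    n_completed = vapply(states, function(s)
      sum(eps$state == s & !eps$censored), integer(1)),
    n_censored = vapply(states, function(s)
      sum(eps$state == s & eps$censored), integer(1))
  )
  class(out) <- c("dwell_stats", "data.frame")
  out
}

dwell_episodes <- function(tracks) {
  out <- lapply(as_track_list(tracks), function(tr) {
    l <- tr$data$phenotype
    keep <- !is.na(l)
    l <- l[keep]
    if (!length(l)) return(NULL)
    r <- rle(l)
    nrun <- length(r$lengths)
    data.frame(state = r$values,
               duration_h = r$lengths * tr$dt,
               censored = seq_len(nrun) == 1L | seq_len(nrun) == nrun)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) data.frame(state = character(), duration_h = numeric(),
                               censored = logical()) else out
}

#' Estimate the phenotype transition-rate matrix from tracks
#'
#' The default estimator is the transition count over occupancy time:
#' `r[i, j] = N(i -> j) / T_i`, where `N(i -> j)` counts consecutive-frame
#' label changes from i to j and `T_i` is the total time spent in state i
#' (frames labelled i times `dt`), giving per-hour rates. With
#' `int_handling = "bridged"`, runs of the intermediate state no longer
#' than `bridge_max` frames sandwiched between definite states i and j are
#' collapsed into a direct i to j event, the INT time being split equally
#' between i and j, and a 4-state matrix is returned. An optional
#' matrix-logarithm correction (`method = "matrix_log"`) compensates the
#' under-counting of fast chains sampled at finite `dt` by estimating the
#' per-frame stochastic matrix and taking its principal logarithm over
#' `dt`.
#'
#' @inheritParams occurrence_fractions
#' @param int_handling `"explicit"` (INT is a state of the matrix) or
#'   `"bridged"`.
#' @param bridge_max maximal INT run length (frames) collapsed in bridged
#'   mode.
#' @param method `"count"` (default) or `"matrix_log"`.
#' @param n_boot bootstrap iterations for rate CIs (default 0 = none, as
#'   rate matrices are often post-processed; set e.g. 1000 for CIs).
#' @return a [rate_matrix()] with attributes `ci_lower`, `ci_upper`
#'   (matrices, if bootstrapped), `counts` (transition counts) and
#'   `occupancy_h` (per-state occupancy time in hours).
#' @export
transition_matrix <- function(tracks, states = phenotype_states(),
                              int_handling = c("explicit", "bridged"),
                              bridge_max = 2L,
                              method = c("count", "matrix_log"),
                              n_boot = 0L, seed = 1) {
  int_handling <- match.arg(int_handling)
  method <- match.arg(method)
  tracks <- as_track_list(tracks)
  if (int_handling == "bridged") {
    check_labels(lapply(tracks, function(tr) tr$data$phenotype), states)
    states <- setdiff(states, "INT")
  } else {
    check_labels(lapply(tracks, function(tr) tr$data$phenotype), states)
  }
  assert_states(states)
  dt <- track_dt(tracks)
  est <- function(trs) {
    cnt <- rate_counts(trs, states, int_handling, bridge_max, dt)
    q <- cnt$n_trans / ifelse(cnt$time_h > 0, cnt$time_h, NA_real_)
    q[is.na(q)] <- 0
    diag(q) <- 0
    if (method == "matrix_log") q <- matrix_log_rates(cnt, dt)
    q
  }
  q_hat <- est(tracks)
  out <- rate_matrix(q_hat, states)
  cnt <- rate_counts(tracks, states, int_handling, bridge_max, dt)
  attr(out, "counts") <- cnt$n_trans
  attr(out, "occupancy_h") <- cnt$time_h
  attr(out, "method") <- method
  attr(out, "int_handling") <- int_handling
  if (n_boot > 0L && length(tracks) >= 2L) {
    offdiag <- function(trs) {
      q <- est(trs)
      q[row(q) != col(q)]
    }
    bs <- bootstrap_ci(offdiag, tracks, n_boot = n_boot, seed = seed)
    lo <- hi <- matrix(NA_real_, length(states), length(states),
                       dimnames = list(states, states))
    lo[row(lo) != col(lo)] <- bs$lower
    hi[row(hi) != col(hi)] <- bs$upper
    attr(out, "ci_lower") <- lo
    attr(out, "ci_upper") <- hi
  }
  out
}

# Count i -> j consecutive-frame transitions and per-state occupancy time.
rate_counts <- function(tracks, states, int_handling, bridge_max, dt) {
  k <- length(states)
  n_trans <- matrix(0, k, k, dimnames = list(states, states))
  time_h <- setNames(numeric(k), states)
  for (tr in as_track_list(tracks)) {
    l <- tr$data$phenotype
    l <- l[!is.na(l)]
    if (!length(l)) next
    if (int_handling == "bridged") {
      br <- bridge_int_runs(l, bridge_max, tr$dt)
      l <- br$labels
      time_extra <- br$time_extra
      for (s in names(time_extra)) {
        if (s %in% states) time_h[s] <- time_h[s] + time_extra[[s]]
      }
      keep <- l != "INT"
      # INT runs longer than bridge_max break the sequence
      seq_id <- cumsum(!keep)
      segs <- split(l[keep], seq_id[keep])
    } else {
      segs <- list(l)
    }
    # occupancy: all retained frames
    retained <- unlist(segs)
    tb <- table(factor(retained, levels = states))
    time_h <- time_h + as.numeric(tb) * tr$dt
    for (seg in segs) {
      n <- length(seg)
      if (n < 2L) next
      from <- seg[-n]; to <- seg[-1L]
      chg <- from != to
      if (any(chg)) {
        tt <- table(factor(from[chg], levels = states),
                    factor(to[chg], levels = states))
        n_trans <- n_trans + unclass(as.matrix(tt))
      }
    }
  }
  list(n_trans = n_trans, time_h = time_h)
}

# Collapse short INT runs between definite states; returns relabelled
# sequence (short INT runs removed by absorbing half their time into each
# neighbour) plus the extra occupancy time credited to each state.
bridge_int_runs <- function(l, bridge_max, dt) {
  r <- rle(l)
  time_extra <- list()
  keep_runs <- rep(TRUE, length(r$lengths))
  for (i in seq_along(r$lengths)) {
    if (r$values[i] != "INT") next
    if (r$lengths[i] <= bridge_max && i > 1L && i < length(r$lengths) &&
        r$values[i - 1L] != "INT" && r$values[i + 1L] != "INT") {
      half <- r$lengths[i] * dt / 2
      a <- r$values[i - 1L]; b <- r$values[i + 1L]
      time_extra[[a]] <- (time_extra[[a]] %||% 0) + half
      time_extra[[b]] <- (time_extra[[b]] %||% 0) + half
      keep_runs[i] <- FALSE
    }
  }
  labels <- inverse.rle(list(lengths = r$lengths[keep_runs],
                             values = r$values[keep_runs]))
  list(labels = labels, time_extra = time_extra)
}

# Matrix-logarithm correction for discrete sampling: per-frame stochastic
# matrix -> principal logarithm / dt (negative off-diagonals clamped).
matrix_log_rates <- function(cnt, dt) {
  k <- nrow(cnt$n_trans)
  n_stay <- cnt$time_h / dt - rowSums(cnt$n_trans)
  pm <- cnt$n_trans
  diag(pm) <- diag(pm) + pmax(n_stay, 0)
  rs <- rowSums(pm)
  pm <- pm / ifelse(rs > 0, rs, 1)
  diag(pm)[rs == 0] <- 1
  eg <- eigen(pm)
  if (any(Re(eg$values) <= 0)) {
    warning("per-frame matrix has non-positive eigenvalues; ",
            "matrix-log correction unreliable, returning raw-count rates")
    q <- cnt$n_trans / ifelse(cnt$time_h > 0, cnt$time_h, NA_real_)
    q[is.na(q)] <- 0
    diag(q) <- 0
    return(q)
  }
  lg <- eg$vectors %*% diag(log(as.complex(eg$values))) %*% solve(eg$vectors)
  q <- Re(lg) / dt
  q[row(q) != col(q)][q[row(q) != col(q)] < 0] <- 0
  diag(q) <- 0
  q
}

#' Probability fluxes and the detailed-balance score
#'
#' Net stationary probability flux between each ordered pair of states,
#' `J[i, j] = p_i r[i, j] - p_j r[j, i]` (per hour), antisymmetric by
#' construction. The detailed-balance score is `max |J|` over pairs
#' divided by the largest one-way flux `max p_i r[i, j]`: 0 for an
#' equilibrium-like (detailed-balanced) phenotype landscape, up to 1 for
#' strongly driven cycles.
#'
#' @param fractions named numeric vector of state occupancy probabilities
#'   (or the data.frame from [occurrence_fractions()]).
#' @param rates a [rate_matrix()] over the same states.
#' @return an object of class `flux_table`: list with `J` (antisymmetric
#'   matrix), `score`, `one_way` (matrix of `p_i r[i, j]`).
#' @export
probability_flux <- function(fractions, rates) {
  stopifnot(is_rate_matrix(rates))
  if (is.data.frame(fractions)) {
    fractions <- setNames(fractions$fraction, fractions$state)
  }
  states <- rownames(rates)
  if (!all(states %in% names(fractions))) {
    stop("fractions must cover the states of the rate matrix")
  }
  p <- fractions[states]
  r <- unclass(rates)
  diag(r) <- 0
  one_way <- p * r # rows scaled by p_i
  j <- one_way - t(one_way)
  score <- if (max(one_way) > 0) max(abs(j)) / max(one_way) else 0
  structure(list(J = j, score = score, one_way = one_way),
            class = "flux_table")
}

#' @export
print.flux_table <- function(x, digits = 4, ...) {
  cat("Probability fluxes (per hour); detailed-balance score ",
      round(x$score, 3), "\n", sep = "")
  print(round(x$J, digits))
  invisible(x)
}

#' Cell-level bootstrap confidence interval
#'
#' Percentile bootstrap of any statistic of a track set: the resampling
#' unit is the whole cell track (with replacement, preserving the number
#' of cells), so within-track temporal correlation is respected.
#' Replicates on which the statistic fails are dropped with a warning.
#'
#' @param statistic function taking a list of tracks and returning a
#'   numeric scalar or vector.
#' @param tracks list of [cell_track()] (>= 2).
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return list with `lower`, `upper` (same shape as the statistic),
#'   `point`, `n_failed`.
#' @export
bootstrap_ci <- function(statistic, tracks, n_boot = 1000L, seed = 1,
                         level = 0.95) {
  tracks <- as_track_list(tracks)
  if (length(tracks) < 2L) stop("bootstrap needs at least 2 cells")
  point <- statistic(tracks)
  reps <- with_seed(derive_seed(seed, 17), {
    lapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(tracks), replace = TRUE)
      tryCatch(statistic(tracks[idx]), error = function(e) NULL)
    })
  })
  failed <- vapply(reps, is.null, logical(1))
  if (any(failed)) {
    warning(sum(failed), " bootstrap replicate(s) failed and were dropped")
  }
  reps <- do.call(rbind, lapply(reps[!failed], as.numeric))
  a <- (1 - level) / 2
  lower <- apply(reps, 2, quantile, probs = a, na.rm = TRUE)
  upper <- apply(reps, 2, quantile, probs = 1 - a, na.rm = TRUE)
  list(lower = lower, upper = upper, point = point,
       n_failed = sum(failed))
}
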