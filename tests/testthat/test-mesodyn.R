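make_track <- function(labels, dt = 0.25, id = "t1") {
  n <- length(labels)
  cell_track(id, time_h = (seq_len(n) - 1) * dt, x_um = seq_len(n),
             y_um = rep(0, n), phenotype = labels, dt = dt)
}

test_that("occurrence fractions count frames and conserve probability", {
  tr <- make_track(rep("FP", 20))
  f <- occurrence_fractions(tr, n_boot = 0)
  expect_equal(f$fraction[f$state == "FP"], 1)
  expect_equal(sum(f$fraction[f$state != "FP"]), 0)

  trs <- lapply(1:6, function(i)
    simulate_phenotype_track(default_rate_matrix(), step_model_default(),
                             duration = 15, seed = i,
                             cell_id = paste0("c", i)))
  f2 <- occurrence_fractions(trs, n_boot = 100, seed = 1)
  expect_equal(sum(f2$fraction), 1, tolerance = 1e-12)
  expect_true(all(f2$lower <= f2$fraction + 1e-12 &
                    f2$fraction <= f2$upper + 1e-12))
  expect_error(occurrence_fractions(make_track(c("ZZ", "ZZ"))), "unknown")
})

test_that("long-run fractions match the chain's stationary distribution", {
  q <- two_state_Q(0.5, 0.25)
  trs <- lapply(1:10, function(i)
    simulate_phenotype_track(q, uniform_step_model(), duration = 200,
                             seed = 40 + i, cell_id = paste0("c", i)))
  f <- occurrence_fractions(trs, states = c("BB", "FP"), n_boot = 500,
                            seed = 2)
  # pi = (1/3, 2/3), within 3 bootstrap standard errors
  se3 <- 3 * (f$upper - f$lower) / 3.92
  expect_lt(abs(f$fraction[1] - 1 / 3), se3[1])
  expect_lt(abs(f$fraction[2] - 2 / 3), se3[2])
})

test_that("dwell episodes follow the stated counting and censoring rules", {
  # interior run of 4 frames at dt = 0.25 -> one completed 1.0 h episode
  tr <- make_track(c("AE", "BB", "BB", "BB", "BB", "AE"))
  d <- dwell_times(tr, n_boot = 0)
  expect_equal(d$mean_dwell_h[d$state == "BB"], 1.0)
  expect_equal(d$n_completed[d$state == "BB"], 1L)
  # single-label track: censored on both ends, mean undefined
  mono <- dwell_times(make_track(rep("FP", 30)), n_boot = 0)
  expect_equal(mono$n_completed[mono$state == "FP"], 0L)
  expect_true(is.na(mono$mean_dwell_h[mono$state == "FP"]))
  expect_equal(mono$n_censored[mono$state == "FP"], 1L)
})

test_that("simulated dwell means match the generator after discretization correction", {
  q <- two_state_Q(0.4, 0.2)
  trs <- lapply(1:20, function(i)
    simulate_phenotype_track(q, uniform_step_model(), duration = 100,
                             dt = 0.25, seed = 60 + i,
                             cell_id = paste0("c", i)))
  d <- dwell_times(trs, states = c("BB", "FP"), n_boot = 0)
  eps <- morphodyn:::dwell_episodes(trs)
  for (s in c("BB", "FP")) {
    lam <- -unclass(q)[s, s]
    expected <- 0.25 / (1 - exp(-lam * 0.25)) # discretised exponential mean
    done <- eps$duration_h[eps$state == s & !eps$censored]
    se <- sd(done) / sqrt(length(done))
    expect_lt(abs(d$mean_dwell_h[d$state == s] - expected), 3 * se)
  }
})

test_that("the rate estimator is the transition count over occupancy time", {
  tr <- make_track(c("AE", "AE", "BB", "BB"))
  r <- transition_matrix(tr, states = c("AE", "BB"))
  expect_equal(r["AE", "BB"], 1 / (2 * 0.25)) # 1 event over 0.5 h in AE
  expect_equal(r["BB", "AE"], 0)
  r0 <- transition_matrix(make_track(rep("LA", 10)))
  expect_true(all(unclass(r0)[row(r0) != col(r0)] == 0))
  expect_error(transition_matrix(make_track(c("QQ", "QQ"))), "unknown")
})

test_that("bridged INT handling collapses short runs into direct events", {
  # BB -> (INT x2) -> LA: one direct BB -> LA event; INT time split equally
  tr <- make_track(c("BB", "BB", "INT", "INT", "LA", "LA"))
  rb <- transition_matrix(tr, int_handling = "bridged", bridge_max = 2L)
  expect_false("INT" %in% rownames(rb))
  cnt <- attr(rb, "counts")
  expect_equal(cnt["BB", "LA"], 1)
  occ <- attr(rb, "occupancy_h")
  expect_equal(unname(occ["BB"]), 2 * 0.25 + 0.25) # half of the 0.5 h INT run
  expect_equal(unname(occ["LA"]), 2 * 0.25 + 0.25)
  # a long INT run is not bridged: no BB -> LA event
  tr2 <- make_track(c("BB", "BB", "INT", "INT", "INT", "LA", "LA"))
  rb2 <- transition_matrix(tr2, int_handling = "bridged", bridge_max = 2L)
  expect_equal(attr(rb2, "counts")["BB", "LA"], 0)
})

test_that("row conservation holds exactly between counts and occupancy", {
  trs <- lapply(1:5, function(i)
    simulate_phenotype_track(default_rate_matrix(), step_model_default(),
                             duration = 25, seed = 80 + i,
                             cell_id = paste0("c", i)))
  r <- transition_matrix(trs)
  cnt <- attr(r, "counts")
  occ <- attr(r, "occupancy_h")
  labs <- lapply(trs, function(tr) tr$data$phenotype)
  for (s in rownames(r)) {
    frames_i <- sum(vapply(labs, function(l) sum(l == s), numeric(1)))
    # runs of s that end at a track boundary produce no outgoing event
    end_runs <- sum(vapply(labs, function(l) tail(l, 1) == s, logical(1)))
    stays <- sum(vapply(labs, function(l) {
      n <- length(l)
      sum(l[-n] == s & l[-1] == s)
    }, numeric(1)))
    expect_identical(sum(cnt[s, ]) + stays, frames_i - end_runs)
    expect_equal(unname(occ[s]), frames_i * 0.25)
  }
})

test_that("a 4-state chain's rates are recovered within 3 standard errors", {
  s4 <- phenotype_levels()
  q <- matrix(0, 4, 4, dimnames = list(s4, s4))
  q["AE", "BB"] <- 0.45; q["BB", "AE"] <- 0.55
  q["FP", "LA"] <- 0.50; q["LA", "FP"] <- 0.60
  q["AE", "FP"] <- 0.25; q["FP", "AE"] <- 0.20
  q["AE", "LA"] <- 0.30; q["LA", "AE"] <- 0.30
  q["BB", "LA"] <- 0.20; q["LA", "BB"] <- 0.15
  q["BB", "FP"] <- 0.02; q["FP", "BB"] <- 0.02
  q <- rate_matrix(q)
  trs <- lapply(1:25, function(i)
    simulate_phenotype_track(q, uniform_step_model(), duration = 80,
                             seed = 200 + i, cell_id = paste0("c", i)))
  r <- transition_matrix(trs, states = s4, method = "matrix_log")
  cnt <- attr(r, "counts")
  occ <- attr(r, "occupancy_h")
  expect_gte(sum(occ), 2000)
  for (i in s4) for (j in s4) {
    if (i == j) next
    se <- sqrt(max(cnt[i, j], 1)) / occ[i]
    expect_lt(abs(r[i, j] - q[i, j]), 3 * se + 1e-9)
  }
  # occurrence fractions match the stationary distribution within 3
  # bootstrap standard errors
  pi_true <- stationary_distribution(q)
  f <- occurrence_fractions(trs, states = s4, n_boot = 400, seed = 3)
  se3 <- 3 * (f$upper - f$lower) / 3.92
  expect_true(all(abs(f$fraction - pi_true) < se3))
  # mean dwell agrees with 1 / total exit rate after accounting for the
  # geometric run-length bias
  d <- dwell_times(trs, states = s4, n_boot = 400, seed = 4)
  for (s in s4) {
    lam <- -unclass(q)[s, s]
    target <- 0.25 / (1 - exp(-lam * 0.25))
    ds <- d[d$state == s, ]
    expect_lt(abs(ds$mean_dwell_h - target), 3 * (ds$upper - ds$lower) / 3.92)
  }
})

test_that("probability flux is antisymmetric, null at equilibrium, cyclic when driven", {
  # reversible chain built from a potential: r_ij = k_ij * p_j, k symmetric
  p <- c(A = 0.5, B = 0.3, C = 0.2)
  k <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
  r <- rate_matrix(k * rep(p, each = 3), names(p))
  fl <- probability_flux(p, r)
  expect_lt(max(abs(fl$J)), 1e-12)
  expect_equal(fl$J + t(fl$J), matrix(0, 3, 3, dimnames = dimnames(fl$J)))
  expect_lt(fl$score, 1e-10)

  # driven 3-cycle: uniform clockwise bias
  rc <- rate_matrix(matrix(c(0, 1, 0.2, 0.2, 0, 1, 1, 0.2, 0), 3, 3,
                           byrow = TRUE), c("A", "B", "C"))
  pc <- stationary_distribution(rc)
  flc <- probability_flux(pc, rc)
  expect_gt(flc$J["A", "B"], 0)
  expect_gt(flc$J["B", "C"], 0)
  expect_gt(flc$J["C", "A"], 0)
  expect_gt(flc$score, 0.1)
  expect_equal(flc$J["A", "B"] + flc$J["B", "A"], 0)
})

test_that("the cell-level bootstrap has the right width and determinism", {
  trs <- lapply(1:100, function(i) make_track(rep("AE", 5), id = i))
  # constant statistic -> zero-width interval
  b0 <- bootstrap_ci(function(x) 1.5, trs, n_boot = 100, seed = 1)
  expect_identical(unname(b0$lower), unname(b0$upper))
  # mean of N(0,1) per-cell values, n = 100 -> width near 2 * 1.96 / 10
  vals <- withr::with_seed(7, rnorm(100))
  stat <- function(tl) mean(vals[match(vapply(tl, `[[`, numeric(1), "cell_id"),
                                       seq_len(100))])
  b <- bootstrap_ci(stat, trs, n_boot = 1000, seed = 2)
  width <- unname(b$upper - b$lower)
  expect_lt(abs(width - 2 * 1.96 / 10) / (2 * 1.96 / 10), 0.2)
  b2 <- bootstrap_ci(stat, trs, n_boot = 1000, seed = 2)
  expect_identical(b$lower, b2$lower)
  # failing replicates are dropped with a warning
  flaky <- local({
    n <- 0
    function(tl) {
      n <<- n + 1
      if (n %% 7 == 0) stop("boom")
      length(tl)
    }
  })
  expect_warning(bootstrap_ci(flaky, trs, n_boot = 50, seed = 3), "dropped")
})

test_that("dwell means and rate matrix are self-consistent on simulated chains", {
  q <- two_state_Q(0.5, 0.25)
  trs <- lapply(1:15, function(i)
    simulate_phenotype_track(q, uniform_step_model(), duration = 150,
                             seed = 300 + i, cell_id = paste0("c", i)))
  r <- transition_matrix(trs, states = c("BB", "FP"))
  d <- dwell_times(trs, states = c("BB", "FP"), n_boot = 300, seed = 5)
  for (s in c("BB", "FP")) {
    lam_hat <- sum(r[s, colnames(r) != s])
    implied <- 0.25 / (1 - exp(-lam_hat * 0.25))
    ds <- d[d$state == s, ]
    expect_lt(abs(ds$mean_dwell_h - implied), 3 * (ds$upper - ds$lower) / 3.92)
  }
})
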