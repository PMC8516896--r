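trap_integral <- function(est) {
  x <- est$x_um
  sum(diff(x) * (head(est$value, -1) + tail(est$value, -1)) / 2)
}

test_that("event density has the closed-form kernel shape and normalization", {
  bw <- 10
  p <- event_density(rep(0, 10), total_time = 10, bandwidth = bw)
  # mass 1 event per hour, Gaussian of sd bw centred at 0
  expect_equal(p$value[which.min(abs(p$x_um))], dnorm(0, 0, bw),
               tolerance = 1e-6)
  expect_lt(abs(trap_integral(p) - 1), 0.01)
  # integral equals events / total_time on any input
  set.seed(5)
  p2 <- event_density(rnorm(137, 20, 30), total_time = 7, bandwidth = bw)
  expect_lt(abs(trap_integral(p2) - 137 / 7) / (137 / 7), 0.01)
  # two clusters produce modes at the cluster centres
  xs <- c(rnorm(200, -100, 3), rnorm(200, 100, 3))
  p3 <- event_density(xs, total_time = 1, bandwidth = 10,
                      grid = seq(-150, 150, by = 1))
  v <- p3$value
  local_max <- which(v > c(-Inf, head(v, -1)) & v > c(tail(v, -1), -Inf))
  modes <- p3$x_um[local_max]
  expect_lt(min(abs(modes + 100)), 2)
  expect_lt(min(abs(modes - 100)), 2)
  # no events: valid all-zero estimate
  p0 <- event_density(numeric(0), total_time = 5, bandwidth = bw)
  expect_true(all(p0$value == 0))
})

test_that("cell density integrates to mean cells per frame and is linear", {
  m <- cell_density(rep(50, 40), n_frames = 40, bandwidth = 8)
  expect_lt(abs(trap_integral(m) - 1), 0.01)
  expect_equal(m$x_um[which.max(m$value)], 50, tolerance = 2)
  # doubling every observation doubles M exactly
  set.seed(6)
  xs <- runif(500, 0, 200)
  g <- seq(-30, 230, by = 2)
  m1 <- cell_density(xs, n_frames = 10, bandwidth = 10, grid = g)
  m2 <- cell_density(c(xs, xs), n_frames = 10, bandwidth = 10, grid = g)
  expect_equal(m2$value, 2 * m1$value, tolerance = 1e-12)
  # uniform scatter is flat away from the edges
  set.seed(7)
  xs2 <- runif(1e4, 0, 400)
  mu <- cell_density(xs2, n_frames = 1, bandwidth = 10,
                     grid = seq(50, 350, by = 5))
  expect_lt(max(abs(mu$value / mean(mu$value) - 1)), 0.1)
})

test_that("halving the bandwidth leaves the integrals unchanged", {
  set.seed(8)
  xs <- rnorm(400, 0, 40)
  g <- seq(-200, 200, by = 1)
  for (bw in c(10, 5)) {
    p <- event_density(xs, total_time = 20, bandwidth = bw, grid = g)
    m <- cell_density(xs, n_frames = 50, bandwidth = bw, grid = g)
    expect_lt(abs(trap_integral(p) - 20) / 20, 0.01)
    expect_lt(abs(trap_integral(m) - 8) / 8, 0.01)
  }
})

test_that("R = P / M holds exactly on valid points and respects the floor", {
  set.seed(9)
  g <- seq(-100, 100, by = 2)
  p <- event_density(rnorm(60, 0, 20), total_time = 12, bandwidth = 10,
                     grid = g)
  m <- cell_density(rnorm(500, 10, 30), n_frames = 25, bandwidth = 10,
                    grid = g)
  r <- spatial_frequency(p, m, density_floor = 0.05)
  ok <- r$valid
  expect_true(any(ok))
  expect_equal(r$value[ok] * m$value[ok], p$value[ok], tolerance = 1e-14)
  expect_true(all(is.na(r$value[!ok])))
  # mismatched grids and bandwidths are refused
  p2 <- event_density(rnorm(60), total_time = 12, bandwidth = 10,
                      grid = g + 1)
  expect_error(spatial_frequency(p2, m), "grid")
  m2 <- cell_density(rnorm(500), n_frames = 25, bandwidth = 5, grid = g)
  expect_error(spatial_frequency(p, m2), "bandwidth")
  # floor guard: a zero-density M invalidates everything, no division
  m0 <- cell_density(numeric(0), n_frames = 10, bandwidth = 10, grid = g)
  r0 <- spatial_frequency(p, m0)
  expect_true(all(!r0$valid))
})

test_that("a permanently dwelling cell has R(i->i) = 1/dt independent of bandwidth", {
  n <- 41
  tr <- cell_track("d1", time_h = (seq_len(n) - 1) * 0.25,
                   x_um = rep(30, n), y_um = rep(0, n),
                   phenotype = rep("FP", n))
  for (bw in c(5, 15)) {
    prof <- event_frequency_profile(list(tr), "FP", "FP", bandwidth = bw)
    vals <- prof$R$value[prof$R$valid]
    expect_lt(max(abs(vals - 4)), 1e-9) # 1/dt = 4 per hour
  }
})

test_that("transition events carry midpoint coordinates and dwell flags", {
  tr <- cell_track("e1", time_h = c(0, 0.25, 0.5), x_um = c(0, 10, 40),
                   y_um = c(0, 0, 0), phenotype = c("BB", "BB", "LA"))
  ev <- transition_events(tr)
  expect_equal(ev$x_um, c(5, 25))
  expect_identical(ev$dwell, c(TRUE, FALSE))
  expect_identical(ev$from, c("BB", "BB"))
  expect_identical(ev$to, c("BB", "LA"))
})

test_that("layer statistics split sides correctly and handle empty sides", {
  q <- default_rate_matrix()
  pop <- simulate_two_layer_population(q, q, step_model_default(),
                                       n_cells = 10, duration = 10,
                                       seed = 21)
  ls <- layer_statistics(pop, interface_x = 0, n_boot = 50)
  expect_gt(ls$left$n_frames, 0L)
  expect_gt(ls$right$n_frames, 0L)
  expect_equal(sum(ls$left$fractions$fraction), 1, tolerance = 1e-12)
  total <- sum(vapply(pop, n_frames, integer(1)))
  expect_identical(ls$left$n_frames + ls$right$n_frames, total)

  # all cells strictly left: right side reported empty without error
  only_left <- lapply(pop, function(tr) {
    tr$data$x_um <- -abs(tr$data$x_um) - 1
    tr
  })
  ls2 <- layer_statistics(only_left, interface_x = 0, n_boot = 0)
  expect_identical(ls2$right$n_frames, 0L)
  expect_null(ls2$right$rates)
})

test_that("an FP-favouring right layer shifts occupancy and R(x) across the interface", {
  q_left <- default_rate_matrix()
  q_right <- default_rate_matrix()
  q_right["LA", "FP"] <- 1.2
  q_right["FP", "LA"] <- 0.2
  q_left["LA", "FP"] <- 0.25
  q_left["FP", "LA"] <- 0.8
  pop <- simulate_two_layer_population(q_left, q_right, step_model_default(),
                                       n_cells = 24, duration = 24,
                                       seed = 31)
  ls <- layer_statistics(pop, interface_x = 0, n_boot = 0)
  frac <- function(side) {
    f <- ls[[side]]$fractions
    f$fraction[f$state == "FP"]
  }
  expect_gt(frac("right"), frac("left"))
  # per-cell paired sign test (left cell vs right cell)
  fp_frac <- vapply(pop, function(tr)
    mean(tr$data$phenotype == "FP"), numeric(1))
  side <- vapply(pop, function(tr) mean(tr$data$x_um >= 0) > 0.5, logical(1))
  expect_gte(sum(side), 5L)
  expect_gte(sum(!side), 5L)
  expect_lt(stats::wilcox.test(fp_frac[side], fp_frac[!side],
                               alternative = "greater",
                               exact = FALSE)$p.value, 0.05)
})
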