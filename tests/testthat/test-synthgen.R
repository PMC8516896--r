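test_that("archetype masks are deterministic and match their gross geometry", {
  lib <- archetype_library_default()
  m1 <- generate_archetype_mask(lib$FP, seed = 7)
  m2 <- generate_archetype_mask(lib$FP, seed = 7)
  expect_identical(m1$grid, m2$grid)
  expect_false(identical(m1$grid,
                         generate_archetype_mask(lib$FP, seed = 8)$grid))

  # protrusion-free round body is a near-disk
  bb0 <- archetype_params("BB", body_radius = 10, protrusion_count = 0,
                          elongation = 1, noise_amplitude = 0)
  v0 <- compute_shape_vector(generate_archetype_mask(bb0, seed = 1))
  expect_gte(v0[["solidity"]], 0.98)
  expect_lte(v0[["aspect_ratio"]], 1.05)

  # elongated spiky FP vs compact BB: aspect-ratio ordering by construction
  v_fp <- compute_shape_vector(generate_archetype_mask(lib$FP, seed = 2))
  v_bb <- compute_shape_vector(generate_archetype_mask(lib$BB, seed = 2))
  expect_gt(v_fp[["aspect_ratio"]], 2 * v_bb[["aspect_ratio"]])
})

test_that("unresolvable protrusions raise a parameter-naming error", {
  thin <- archetype_params("FP", body_radius = 8, protrusion_count = 4,
                           protrusion_length = 25, protrusion_width = 0.4,
                           elongation = 3, noise_amplitude = 0)
  expect_error(generate_archetype_mask(thin, pixel_size = 1, seed = 1),
               "protrusion_width")
})

test_that("simulated tracks observe the phenotype chain at the frame rate", {
  q0 <- rate_matrix(matrix(0, 2, 2), c("AE", "BB"))
  tr <- simulate_phenotype_track(q0, step_model_default(), duration = 5,
                                 seed = 1, initial_state = "AE")
  expect_true(all(tr$data$phenotype == "AE"))

  tr10 <- simulate_phenotype_track(default_rate_matrix(),
                                   step_model_default(),
                                   duration = 10, dt = 0.25, seed = 2)
  expect_equal(n_frames(tr10), 41L)
  steps <- sqrt(diff(tr10$data$x_um)^2 + diff(tr10$data$y_um)^2)
  expect_true(all(steps > 0))
  # determinism
  tr10b <- simulate_phenotype_track(default_rate_matrix(),
                                    step_model_default(),
                                    duration = 10, dt = 0.25, seed = 2)
  expect_identical(tr10$data, tr10b$data)
  expect_error(simulate_phenotype_track(default_rate_matrix(),
                                        step_model_default(),
                                        duration = 1, dt = -0.1), "dt")
})

test_that("long-run occupancy matches the stationary distribution", {
  # pi_BB = r(FP->BB) / (r(BB->FP) + r(FP->BB)) = 1/3 for rates 0.5, 0.25
  q <- two_state_Q(0.5, 0.25)
  tr <- simulate_phenotype_track(q, uniform_step_model(), duration = 4000,
                                 dt = 0.25, seed = 3, initial_state = "BB")
  lab <- tr$data$phenotype
  occ <- mean(lab == "BB")
  # batch-mean standard error over 40 blocks of 100 h
  blocks <- split(lab == "BB", rep(seq_len(40), each = 400, length.out = length(lab)))
  se <- sd(vapply(blocks, mean, numeric(1))) / sqrt(40)
  expect_lt(abs(occ - 1 / 3), 3 * se)

  # occupancy converges as dt shrinks
  occ_fine <- mean(simulate_phenotype_track(
    q, uniform_step_model(), duration = 2000, dt = 0.05, seed = 4,
    initial_state = "BB")$data$phenotype == "BB")
  occ_coarse <- mean(simulate_phenotype_track(
    q, uniform_step_model(), duration = 2000, dt = 0.25, seed = 5,
    initial_state = "BB")$data$phenotype == "BB")
  expect_lt(abs(occ_fine - occ_coarse), 0.02)
})

test_that("continuous dwell durations are exponential with the generator's rate", {
  q <- two_state_Q(0.5, 0.25)
  # fine sampling approximates the continuous chain; >= 500 completed dwells
  tr <- simulate_phenotype_track(q, uniform_step_model(), duration = 3600,
                                 dt = 0.05, seed = 6, initial_state = "BB")
  eps <- morphodyn:::dwell_episodes(list(tr))
  done <- eps[!eps$censored & eps$state == "BB", "duration_h"]
  expect_gte(length(done), 500L)
  se <- sd(done) / sqrt(length(done))
  # discretised run-length expectation of an exponential dwell
  expected <- 0.05 / (1 - exp(-0.5 * 0.05))
  expect_lt(abs(mean(done) - expected), 3 * se)
})

test_that("step magnitudes follow the generating log-normal per category", {
  # frozen single-state chain: all steps are AM-AM
  q0 <- rate_matrix(matrix(0, 2, 2), c("AE", "BB"))
  sm <- uniform_step_model(mu = 0.4, s2 = 0.5)
  pass <- vapply(1:8, function(s) {
    tr <- simulate_phenotype_track(q0, sm, duration = 500, dt = 0.25,
                                   seed = s, initial_state = "BB")
    mags <- sqrt(diff(tr$data$x_um)^2 + diff(tr$data$y_um)^2)
    stats::ks.test(log(mags), "pnorm", 0.4, sqrt(0.5))$p.value > 0.01
  }, logical(1))
  expect_gte(mean(pass), 7 / 8)
})

test_that("two-layer populations follow the local generator on each side", {
  q <- two_state_Q(0.5, 0.25)
  pop <- simulate_two_layer_population(q, q, uniform_step_model(),
                                       n_cells = 16, duration = 40,
                                       seed = 11)
  expect_length(pop, 16L)
  expect_true(all(vapply(pop, n_frames, integer(1)) == 161L))
  expect_error(simulate_two_layer_population(q, default_rate_matrix(),
                                             uniform_step_model()),
               "state set")

  # cells that never cross the interface obey their side's generator
  # (matrix-log correction removes the finite-dt undercount)
  crossed <- vapply(pop, function(tr) any(tr$data$x_um >= 0) &&
                      any(tr$data$x_um < 0), logical(1))
  stay <- pop[!crossed]
  expect_gt(length(stay), 1L)
  r_hat <- transition_matrix(stay, states = c("BB", "FP"),
                             method = "matrix_log")
  counts <- attr(r_hat, "counts")
  occ <- attr(r_hat, "occupancy_h")
  for (i in rownames(q)) for (j in colnames(q)) {
    if (i == j || occ[i] == 0) next
    se <- sqrt(max(counts[i, j], 1)) / occ[i]
    expect_lt(abs(r_hat[i, j] - q[i, j]), 3 * se + 1e-9)
  }
})

test_that("rendered movies are deterministic and placed on one canvas", {
  tr <- cell_track("m1", time_h = seq(0, 1.75, by = 0.25),
                   x_um = seq(0, 35, by = 5), y_um = rep(0, 8),
                   phenotype = rep("AE", 8))
  mv1 <- render_track_movie(tr, seed = 5)
  mv2 <- render_track_movie(tr, seed = 5)
  expect_length(mv1, 8L)
  expect_identical(lapply(mv1, `[[`, "grid"), lapply(mv2, `[[`, "grid"))
  dims <- vapply(mv1, function(m) dim(m$grid), integer(2))
  expect_true(all(dims == dims[, 1]))
  # canvas overflow is refused with the required size
  far <- cell_track("m2", time_h = c(0, 0.25), x_um = c(0, 5000),
                    y_um = c(0, 0), phenotype = c("AE", "AE"))
  expect_error(render_track_movie(far), "canvas")
})
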