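test_that("steps are categorized by the coarse-class pair and conserved", {
  tr <- cell_track("s1", time_h = c(0, 0.25, 0.5),
                   x_um = c(0, 3, 3), y_um = c(0, 4, 8),
                   phenotype = c("FP", "LA", "BB"))
  st <- categorize_steps(tr)
  expect_equal(st$category, c("ME-ME", "ME-AM"))
  expect_equal(st$magnitude_um, c(5, 4))

  trs <- lapply(1:5, function(i)
    simulate_phenotype_track(default_rate_matrix(), step_model_default(),
                             duration = 10, seed = i,
                             cell_id = paste0("c", i)))
  st2 <- categorize_steps(trs)
  expect_identical(nrow(st2),
                   sum(vapply(trs, n_frames, integer(1))) - length(trs))
  expect_identical(attr(st2, "n_skipped"), 0L)
  # missing labels skip the adjacent pairs and are counted
  trs[[1]]$data$phenotype[3] <- NA
  st3 <- categorize_steps(trs)
  expect_identical(attr(st3, "n_skipped"), 2L)
  expect_identical(nrow(st3), nrow(st2) - 2L)
})

test_that("per-category step means match the generating log-normals", {
  sm <- step_model_default()
  trs <- lapply(1:20, function(i)
    simulate_phenotype_track(default_rate_matrix(), sm, duration = 40,
                             seed = 500 + i, cell_id = paste0("c", i)))
  st <- categorize_steps(trs)
  for (cat_k in c("AM-AM", "ME-ME")) {
    mags <- st$magnitude_um[st$category == cat_k]
    expect_gt(length(mags), 100L)
    mu <- sm$log_mean[[cat_k]]; s2 <- sm$log_variance[[cat_k]]
    m_true <- exp(mu + s2 / 2)
    se <- sd(mags) / sqrt(length(mags))
    expect_lt(abs(mean(mags) - m_true), 3 * se)
  }
})

test_that("the log-normal fit recovers closed-form natural-scale moments", {
  x <- withr::with_seed(9, exp(rnorm(1e4, 0, 0.5))) # mu = 0, s2 = 0.25
  fit <- fit_lognormal(x, n_boot = 400, seed = 1)
  m_true <- exp(0.125)
  v_true <- (exp(0.25) - 1) * exp(0.25)
  expect_true(fit$ci_m[1] <= m_true && m_true <= fit$ci_m[2])
  expect_true(fit$ci_sigma2[1] <= v_true && v_true <= fit$ci_sigma2[2])
  expect_gt(fit$delta_loglik, 0)
  # cross-check the log-scale MLE against an independent fitter
  ref <- MASS::fitdistr(x, "lognormal")
  expect_equal(fit$mu_log, unname(ref$estimate["meanlog"]), tolerance = 1e-6)
  expect_equal(sqrt(fit$s2_log), unname(ref$estimate["sdlog"]),
               tolerance = 1e-3)
})

test_that("the Gaussian-comparison diagnostic prefers the true model", {
  wins <- vapply(1:10, function(s) {
    x <- withr::with_seed(s, abs(rnorm(500, 5, 1))) # effectively Gaussian
    fit_lognormal(x, n_boot = 0, seed = s)$delta_loglik < 0
  }, logical(1))
  expect_gte(mean(wins), 0.9)
  expect_error(fit_lognormal(rep(2, 100)), "variance")
  expect_error(fit_lognormal(runif(10)), "30")
  # zero magnitudes are excluded and counted
  x <- c(rep(0, 5), withr::with_seed(1, exp(rnorm(100))))
  fit <- fit_lognormal(x, n_boot = 0)
  expect_identical(fit$n_zero, 5L)
  expect_identical(fit$n, 100L)
})

test_that("conditional MSD uses only within-class dwell segments", {
  # single-class track: conditional equals unconditional exactly
  tr <- simulate_phenotype_track(rate_matrix(matrix(0, 2, 2), c("FP", "LA")),
                                 uniform_step_model(), duration = 20,
                                 seed = 3, initial_state = "FP")
  full <- compute_msd(tr)
  cond <- conditional_msd(tr, "ME")
  expect_equal(cond$msd, full$msd)
  # alternating classes leave no usable segment
  alt <- cell_track("a", time_h = (0:9) * 0.25, x_um = rnorm(10),
                    y_um = rnorm(10),
                    phenotype = rep(c("BB", "FP"), 5))
  expect_warning(empty <- conditional_msd(alt, "AM"), "segment")
  expect_identical(nrow(empty), 0L)
})

test_that("class-dependent step scales appear in the conditional MSDs", {
  # ME steps three times the AM log-mean scale
  cats <- step_categories()
  lm_ <- setNames(rep(0.3, 9), cats)
  lm_[c("ME-ME")] <- 0.3 + log(3)
  sm <- step_model(lm_, setNames(rep(0.4, 9), cats))
  q <- two_state_Q(0.4, 0.4)
  ok <- vapply(1:5, function(s) {
    trs <- lapply(1:12, function(i)
      simulate_phenotype_track(q, sm, duration = 30, seed = s * 100 + i,
                               cell_id = paste0("c", i)))
    m_am <- conditional_msd(trs, "AM")
    m_me <- conditional_msd(trs, "ME")
    k <- min(4, nrow(m_am) - 1, nrow(m_me) - 1)
    all(m_me$msd[2:(k + 1)] > m_am$msd[2:(k + 1)])
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("the weighted-average MSD is a per-lag convex combination", {
  lags <- (0:8) * 0.25
  c1 <- morphodyn:::msd_curve(lags, lags * 2, rep(NA, 9), rep(10L, 9))
  c2 <- morphodyn:::msd_curve(lags, lags * 6, rep(NA, 9), rep(10L, 9))
  same <- weighted_average_msd(list(c1, c1), c(0.5, 0.5))
  expect_equal(same$msd, c1$msd)
  first <- weighted_average_msd(list(c1, c2), c(1, 0))
  expect_equal(first$msd, c1$msd)
  mix <- weighted_average_msd(list(c1, c2), c(0.25, 0.75))
  expect_equal(mix$msd, lags * 5)
  # differing grids intersect with a warning
  c3 <- morphodyn:::msd_curve(lags[1:5], lags[1:5] * 6, rep(NA, 5), rep(10L, 5))
  expect_warning(short <- weighted_average_msd(list(c1, c3), c(0.5, 0.5)),
                 "grids")
  expect_identical(nrow(short), 5L)
  expect_error(weighted_average_msd(list(c1, c2), c(0.7, 0.7)), "sum")
})

test_that("effective diffusivity follows the 2dD convention and recovers truth", {
  lags <- (0:10) * 0.25
  exact4 <- morphodyn:::msd_curve(lags, 4 * lags, rep(NA, 11), rep(10L, 11))
  expect_equal(effective_diffusivity(exact4)$D_per_dim, 1, tolerance = 1e-12)
  exact24 <- morphodyn:::msd_curve(lags, 24 * lags, rep(NA, 11), rep(10L, 11))
  expect_equal(effective_diffusivity(exact24)$D_per_dim, 6, tolerance = 1e-12)

  # parameter recovery: D = 5 um^2/h per dimension
  D <- 5; dt <- 0.25
  walks <- withr::with_seed(12, replicate(500, {
    cbind(cumsum(rnorm(80, sd = sqrt(2 * D * dt))),
          cumsum(rnorm(80, sd = sqrt(2 * D * dt))))
  }, simplify = FALSE))
  est <- effective_diffusivity(compute_msd(walks, dt = dt))
  expect_lt(abs(est$D_per_dim - D) / D, 0.05)
  # negative slope reports zero with a warning
  dec <- morphodyn:::msd_curve(lags, rev(seq_along(lags)) * 1.0,
                               rep(NA, 11), rep(10L, 11))
  expect_warning(z <- effective_diffusivity(dec), "negative|0")
  expect_identical(z$D_per_dim, 0)
})

test_that("switch-coupled large steps make the full MSD exceed the weighted average", {
  cats <- step_categories()
  lm_ <- setNames(rep(0.3, 9), cats)
  lm_[c("AM-ME", "ME-AM")] <- 1.6 # switching steps much larger
  sm <- step_model(lm_, setNames(rep(0.4, 9), cats))
  q <- two_state_Q(0.8, 0.8) # frequent switching
  ok <- vapply(1:5, function(s) {
    trs <- lapply(1:15, function(i)
      simulate_phenotype_track(q, sm, duration = 30, seed = s * 1000 + i,
                               cell_id = paste0("c", i)))
    full <- compute_msd(trs)
    am <- suppressWarnings(conditional_msd(trs, "AM", max_lag = max(full$lag_h)))
    me <- suppressWarnings(conditional_msd(trs, "ME", max_lag = max(full$lag_h)))
    cc <- morphodyn:::class_fractions(trs)[1:2]
    w <- suppressWarnings(weighted_average_msd(list(am, me), cc / sum(cc)))
    k <- nrow(w)
    all(full$msd[match(w$lag_h[2:k], full$lag_h)] > w$msd[2:k])
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})
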