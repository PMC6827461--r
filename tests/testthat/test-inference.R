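params <- test_optimized_params()

test_that("observed series validates its inputs", {
  s <- observed_series(c(1, 5, 9), c(0, 0.1, 0.2))
  expect_s3_class(s, "observed_series")
  expect_error(observed_series(c(5, 1), c(0, 0)), "increasing")
  expect_error(observed_series(c(1, 2), c(0, 1.5)), "\\[0, 1\\]")
  path <- withr::local_tempfile(fileext = ".csv")
  write_series(s, path)
  expect_equal(read_series(path), s, ignore_attr = TRUE)
})

test_that("cost is the sum of squared deviations from the simulated trajectory", {
  gens <- c(5, 12, 20)
  traj <- simulate_trajectory(params, 20, engine = "r")  # independent path
  obs <- observed_series(gens, traj$beta[gens + 1])
  expect_equal(cost(params, obs), 0, tolerance = 1e-24)

  # single point, hand arithmetic
  x <- 0.004
  obs1 <- observed_series(12, x)
  expect_equal(cost(params, obs1), (x - traj$beta[13])^2, tolerance = 1e-12)

  # perturbed observations: residuals add up across points
  noisy <- observed_series(gens, pmin(1, traj$beta[gens + 1] + 1e-3))
  expect_equal(cost(params, noisy), 3 * 1e-6, tolerance = 1e-12)

  # no mutation anywhere: all-zero observations fit exactly
  p0 <- model_params(params$gamma, 0, params$r, params$R_mut, params$S_base,
                     params$kappa_star, params$kappa_T)
  expect_equal(cost(p0, observed_series(gens, c(0, 0, 0))), 0)

  # extinction-inducing parameters score infinite cost
  doomed <- model_params(0, 0, 5, 5, 0.9, 1, 5, w0 = 4)
  expect_equal(cost(doomed, obs1), Inf)
})

test_that("starting parameters are drawn on the documented scales", {
  bounds <- parameter_bounds()
  set.seed(99)
  draws <- replicate(2000, {
    p <- sample_initial_parameters(bounds)
    c(p$gamma, p$mu, p$r, p$R_mut, p$S_base, p$kappa_star, p$kappa_T)
  })
  expect_true(all(draws[1, ] >= 1e-10 & draws[1, ] <= 1e-2))
  expect_true(all(draws[3, ] >= 1 & draws[3, ] <= 5))
  expect_true(all(draws[5, ] > 0.5 & draws[5, ] <= 1))
  expect_true(all(draws[6, ] < draws[7, ]))
  ks <- ks.test(log10(draws[1, ]), "punif", -10, -2)
  expect_gt(ks$p.value, 0.01)
  ks2 <- ks.test(log10(draws[2, ]), "punif", -10, -2)
  expect_gt(ks2$p.value, 0.01)

  set.seed(7)
  a <- sample_initial_parameters(bounds)
  set.seed(7)
  b <- sample_initial_parameters(bounds)
  expect_identical(a, b)
})

test_that("the multi-start best cost is non-increasing in the restart count", {
  p <- model_params(1e-3, 1e-3, 1.6, 2.4, 0.9, 5, 8, w0 = 4)
  gens <- c(4, 8, 12)
  traj <- simulate_trajectory(p, 12)
  obs <- observed_series(gens, traj$beta[gens + 1])
  f2 <- fit(obs, n_restarts = 2, seed = 5, maxit = 2000, w0 = 4L)
  f5 <- fit(obs, n_restarts = 5, seed = 5, maxit = 2000, w0 = 4L)
  expect_lte(f5$best_cost, f2$best_cost)
  # prefix property: the first two restarts are identical across the runs
  expect_equal(f5$restarts$cost[1:2], f2$restarts$cost[1:2])
  expect_equal(f5$best_cost, min(f5$restarts$cost[f5$restarts$converged]))
})

test_that("fit results serialize to JSON with the per-restart table", {
  p <- model_params(1e-3, 1e-3, 1.6, 2.4, 0.9, 5, 8, w0 = 4)
  obs <- observed_series(c(4, 8), simulate_trajectory(p, 8)$beta[c(5, 9)])
  f <- fit(obs, n_restarts = 2, seed = 11, maxit = 2000, w0 = 4L)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(f, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$best_cost, f$best_cost, tolerance = 1e-12)
  expect_equal(nrow(back$restarts), 2L)
  expect_equal(back$best_params$kappa_T, f$best_params$kappa_T)
})
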