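# Cross-validated model selection, forward simulation error, and
# explained variance by dimension.

test_that("variance explained grows with D and plateaus at the truth", {
  # ground truth with 3 informative dimensions
  set.seed(30)
  A <- diag(c(0.95, 0.8, 0.6))
  p <- toy_params(K = 1, D = 3, N = 15, A = A,
                  C = matrix(rnorm(45, sd = 0.6), 15, 3), q = 0.3, r = 0.1)
  sim <- simulate_session(p, NULL, n_frames = 1500, seed = 30)
  cv <- cross_validate_rslds(sim$recording, NULL, K_grid = 1, D_grid = c(1, 3),
                             n_folds = 3, seed = 1,
                             config = list(max_iter = 10))
  g <- cv$grid[order(cv$grid$D), ]
  expect_true(all(diff(g$ve_mean) > 0))
  expect_gt(max(g$ve_mean), 0.9)
  expect_equal(unname(cv$chosen["D"]), 3)
  expect_error(cross_validate_rslds(sim$recording, NULL, integer(0), 1:2),
               "empty")
})

test_that("forward simulation error is exact for the generator on its own output", {
  sc <- ground_truth_scenario("line_attractor", duration = 60,
                              emission_noise_sd = 0, process_noise_sd = 0,
                              seed = 31)
  ss <- synthetic_session(sc)
  pseudo_fit <- list(params = ss$params, posterior_latents = ss$latents,
                     most_likely_states = ss$states,
                     inputs = ss$inputs$values, sampling_rate = 15)
  fse <- forward_simulation_error(pseudo_fit, horizon_frames = 15)
  expect_equal(max(fse$mse), 0, tolerance = 1e-16)
  expect_equal(fse$performance, 1)
  expect_true(all(fse$normalized >= 0 & fse$normalized <= 1))

  # on a fitted noisy session the normalization stays bounded
  fit <- short_line_fit()
  fse2 <- forward_simulation_error(fit)
  expect_true(all(fse2$normalized >= 0 & fse2$normalized <= 1))
  expect_true(fse2$performance >= 0 && fse2$performance <= 1)
  expect_error(forward_simulation_error(fit, horizon_frames = 1e7), "exceeds")
})

test_that("time-shuffled latents forward-simulate near the normalization floor", {
  fit <- short_line_fit()
  shuf <- fit
  set.seed(1)
  perm <- sample(ncol(fit$posterior_latents))
  shuf$posterior_latents <- fit$posterior_latents[, perm]
  shuf$most_likely_states <- fit$most_likely_states[perm]
  fse_obs <- forward_simulation_error(fit)
  fse_shuf <- forward_simulation_error(shuf)
  expect_lt(mean(fse_obs$mse), mean(fse_shuf$mse))
})

test_that("explained variance by dimension follows the emission geometry", {
  # orthogonal C with isotropic independent latents: fractions track the
  # squared column norms (singular values squared)
  set.seed(40)
  T_ <- 4000
  X <- matrix(rnorm(2 * T_), 2, T_)
  Cm <- cbind(c(2, 0, 0), c(0, 1, 0))
  p <- toy_params(K = 1, D = 2, N = 3, C = Cm, q = 0.1, r = 0.05)
  fit <- list(params = p, posterior_latents = X)
  ve <- explained_variance_by_dimension(fit)
  expect_equal(ve[1] / ve[2], 4, tolerance = 0.15)
  expect_true(all(ve >= 0 & ve <= 1))

  # a zero dimension explains nothing
  X0 <- rbind(X[1, ], 0)
  ve0 <- explained_variance_by_dimension(list(params = p, posterior_latents = X0))
  expect_equal(unname(ve0[2]), 0)

  # orthogonalized attribution sums to at most one even with correlated latents
  Xc <- rbind(X[1, ], X[1, ] * 0.9 + 0.1 * X[2, ])
  vec <- explained_variance_by_dimension(list(params = p, posterior_latents = Xc))
  expect_lte(sum(vec), 1 + 1e-8)
})
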