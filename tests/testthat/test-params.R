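# Elementary model operations against closed forms and hand arithmetic.

test_that("transition probabilities follow the softmax link", {
  p <- toy_params(K = 3, D = 2, N = 3)
  # symmetric logits give the uniform distribution
  expect_equal(transition_probabilities(p, c(0, 0)), rep(1 / 3, 3))
  expect_equal(sum(transition_probabilities(p, rnorm(2))), 1, tolerance = 1e-12)

  # strong offset drives a near-one-hot limit
  p1 <- toy_params(K = 3, D = 2, N = 3, r_tr = c(10, 0, 0))
  pr <- transition_probabilities(p1, c(0, 0))
  expect_equal(pr, exp(c(10, 0, 0)) / sum(exp(c(10, 0, 0))), tolerance = 1e-12)
  expect_gt(pr[1], 0.9999)

  # K = 2 closed form for logits (1, 0)
  p2 <- toy_params(K = 2, D = 1, N = 2, r_tr = c(1, 0))
  expect_equal(transition_probabilities(p2, 0),
               c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)

  expect_error(transition_probabilities(p, c(0, 0, 0)), "length")
})

test_that("one-step latent mean matches hand arithmetic", {
  p <- toy_params(K = 1, D = 2, N = 2, A = diag(2))
  expect_equal(latent_mean_step(p, 1, c(0.3, -0.2)), c(0.3, -0.2))

  p2 <- toy_params(K = 1, D = 2, N = 2, A = matrix(c(0.5, 0, 0, 0.2), 2, 2))
  p2$b[[1]] <- c(0.1, 0)
  expect_equal(latent_mean_step(p2, 1, c(1, 1)), c(0.6, 0.2))

  p3 <- toy_params(K = 1, D = 2, m = 1, N = 2, A = diag(0, 2))
  p3$V[[1]] <- matrix(c(1, 0), 2, 1)
  expect_equal(latent_mean_step(p3, 1, c(5, 5), u_prev = 2), c(2, 0))
  expect_error(latent_mean_step(p3, 2, c(0, 0), 0), "out of range")
})

test_that("emission mean is C x + d", {
  p <- toy_params(K = 1, D = 2, N = 2, C = diag(2))
  expect_equal(emission_mean(p, c(1.5, -2)), c(1.5, -2))
  p$d_bias <- c(0.4, 0.7)
  expect_equal(emission_mean(p, c(0, 0)), c(0.4, 0.7))
  p2 <- toy_params(K = 1, D = 2, N = 2, C = matrix(c(1, 2, 3, 4), 2, 2))
  expect_equal(emission_mean(p2, c(1, 1)), c(4, 6))
})

test_that("joint log-probability equals the product of hand-computed densities", {
  # single all-zero frame: only normalizing constants remain
  p <- toy_params(K = 1, D = 1, N = 1, C = matrix(1), q = 0.2, r = 0.3)
  lp1 <- joint_log_probability(p, z = 1, x = matrix(0), y = matrix(0), x1_sd = 10)
  expect_equal(lp1, dnorm(0, 0, 10, log = TRUE) + dnorm(0, 0, 0.3, log = TRUE))

  # doubling the observation noise SD changes the emission term by a
  # known amount: + log(2) per frame minus 3/8 of the scaled residual
  y0 <- matrix(0.5)
  lp_r <- joint_log_probability(p, 1, matrix(0), y0)
  p2 <- p; p2$obs_noise <- diag(0.6^2, 1)
  lp_2r <- joint_log_probability(p2, 1, matrix(0), y0)
  expect_equal(lp_r - lp_2r,
               log(2) - 0.5 * 0.5^2 * (1 / 0.3^2 - 1 / 0.6^2), tolerance = 1e-12)

  # T = 2, K = 1: transition + dynamics + emissions by hand
  x <- matrix(c(0.2, 0.5), 1, 2)
  y <- matrix(c(0.1, 0.6), 1, 2)
  lp <- joint_log_probability(p, c(1, 1), x, y)
  by_hand <- dnorm(0.2, 0, 10, log = TRUE) +
    dnorm(0.5, 0.5 * 0.2, 0.2, log = TRUE) +
    dnorm(0.1, 0.2, 0.3, log = TRUE) + dnorm(0.6, 0.5, 0.3, log = TRUE)
  expect_equal(lp, by_hand, tolerance = 1e-12)
})

test_that("parameter validation rejects malformed sets", {
  expect_error(toy_params(K = 1, D = 2, N = 1), "at least as many neurons")
  expect_error(rslds_params(A = list(diag(2)), V = list(matrix(0, 2, 0)),
                            b = list(numeric(2)),
                            C = matrix(c(1, 1, 2, 2), 2, 2), d_bias = numeric(2),
                            obs_noise = diag(2), process_noise = diag(2),
                            R_tr = matrix(0, 1, 2), W_tr = matrix(0, 1, 0),
                            r_tr = 0), "rank deficient")
})
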