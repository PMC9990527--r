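# Time constants, line-attractor score, state selection, and the
# integration dimension.

test_that("time constants follow tau = 1/|log|lambda||", {
  f <- 15
  spec <- time_constants(diag(c(exp(-1), 0.99, 0.5)), f)
  expect_equal(spec$tau_frames[spec$modulus == exp(-1)], 1, tolerance = 1e-12)
  expect_equal(spec$tau_frames[spec$modulus == 0.99], 1 / abs(log(0.99)),
               tolerance = 1e-12)
  expect_equal(spec$tau_frames[1], 1 / abs(log(0.99)), tolerance = 1e-12) # sorted

  # the synthetic ground-truth eigenvalue maps back to 100 s
  lam <- exp(-1 / (100 * f))
  s2 <- time_constants(diag(c(lam, 0.5)), f)
  expect_equal(s2$tau_seconds[1], 100, tolerance = 1e-10)

  # zero eigenvalue convention and unit-circle sentinel
  s3 <- time_constants(matrix(0, 2, 2), f)
  expect_true(all(s3$tau_frames == 0))
  s4 <- time_constants(diag(c(1, 0.5)), f)
  expect_true(s4$at_unit_circle[1])
  expect_equal(s4$tau_frames[1], 1e12)
  expect_warning(time_constants(diag(c(1.2, 0.1)), f), "unstable")

  # complex pairs share a modulus and a time constant
  rot <- 0.98 * matrix(c(cos(0.3), sin(0.3), -sin(0.3), cos(0.3)), 2, 2)
  s5 <- time_constants(rot, f)
  expect_equal(s5$tau_frames[1], s5$tau_frames[2], tolerance = 1e-12)
})

test_that("time constants are invariant to latent re-parameterization", {
  set.seed(50)
  A <- diag(c(0.995, 0.8, 0.4)) + matrix(rnorm(9, sd = 0.003), 3)
  M <- matrix(rnorm(9), 3); M <- M + diag(3) * 3
  spec1 <- time_constants(A, 15)
  spec2 <- time_constants(M %*% A %*% solve(M), 15)
  expect_equal(spec1$tau_frames, spec2$tau_frames, tolerance = 1e-6)
})

test_that("line-attractor score is the log2 time-constant ratio", {
  expect_equal(line_attractor_score(c(5, 5, 1)), 0)
  expect_equal(line_attractor_score(c(10, 5, 1)), 1)
  # scale invariance
  expect_equal(line_attractor_score(c(300, 10, 2)),
               line_attractor_score(c(3000, 100, 20)))
  expect_warning(s <- line_attractor_score(c(3, 0)), "zero")
  expect_true(is.infinite(s))
  expect_error(line_attractor_score(5), "at least two")
})

test_that("analysis-state selection follows behavior enrichment", {
  states <- c(rep(1L, 50), rep(2L, 50))
  ann <- c(rep("background", 50), rep("attack", 50))
  sel <- select_analysis_state(states, ann, "attack")
  expect_equal(sel$state, 2L)
  expect_equal(sel$enrichment$fraction[2], 1)

  # uniform spread ties with a warning toward the lower index
  states2 <- rep(c(1L, 2L), 50)
  ann2 <- rep("attack", 100)
  expect_warning(sel2 <- select_analysis_state(states2, ann2, "attack"), "tie")
  expect_equal(sel2$state, 1L)
  expect_error(select_analysis_state(states, ann, "intromission"), "no frames")

  # synthetic session: the chosen state carries the slow mode
  runs <- acceptance_line_runs()
  r <- runs[[1]]
  expect_gt(r$spectrum$tau_seconds[1], 20)
})

test_that("integration dimension tracks the slowest eigenvector", {
  p <- toy_params(K = 1, D = 3, N = 4, A = diag(c(0.5, 0.99, 0.2)),
                  C = matrix(rnorm(12), 4, 3))
  fit <- list(params = p, posterior_latents = matrix(abs(rnorm(30)), 3, 10),
              sampling_rate = 15)
  integ <- identify_integration_dimension(fit, 1)
  expect_equal(integ$index, 2L)
  expect_equal(abs(integ$direction), c(0, 1, 0), tolerance = 1e-12)

  # similarity invariance: a rotated copy has the same tau, rotated axis
  set.seed(51)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  p2 <- p; p2$A[[1]] <- Q %*% p$A[[1]] %*% t(Q)
  fit2 <- list(params = p2,
               posterior_latents = Q %*% fit$posterior_latents,
               sampling_rate = 15)
  integ2 <- identify_integration_dimension(fit2, 1)
  expect_equal(integ2$tau_frames, integ$tau_frames, tolerance = 1e-9)
  expect_equal(abs(sum(integ2$direction * (Q %*% integ$direction))), 1,
               tolerance = 1e-9)

  # recovery on a fitted line-attractor session: within 10 degrees of truth
  runs <- acceptance_line_runs()
  r <- runs[[1]]
  integ3 <- identify_integration_dimension(r$fit, r$enriched$state)
  # compare through the emission map (latent bases differ between truth and fit)
  axis_true <- attr(r$session$params, "ground_truth")$slow_axis
  dir_y_true <- r$session$params$C %*% axis_true
  dir_y_fit <- r$fit$params$C %*% integ3$direction
  ang <- acos(min(1, abs(sum(dir_y_true * dir_y_fit)) /
                    sqrt(sum(dir_y_true^2) * sum(dir_y_fit^2)))) * 180 / pi
  expect_lt(ang, 10)
})
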