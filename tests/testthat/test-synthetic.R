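# Synthetic-session generator: spectrum placement, determinism, emission
# consistency, behavior/latent coupling, and pose synthesis.

test_that("ground-truth spectra match the scenario targets", {
  f <- 15
  sc <- ground_truth_scenario("line_attractor", target_slow_tau = 100,
                              sampling_rate = f, seed = 2)
  p <- make_ground_truth_params(sc)
  lam <- sort(Mod(eigen(p$A[[sc$K]])$values), decreasing = TRUE)
  expect_equal(lam[1], exp(-1 / (100 * f)), tolerance = 1e-10)
  # every other eigenvalue, in every state, has tau < 2 s
  for (k in seq_len(sc$K)) {
    mods <- sort(Mod(eigen(p$A[[k]])$values), decreasing = TRUE)
    others <- if (k == sc$K) mods[-1] else mods
    expect_true(all(others < exp(-1 / (2 * f))))
  }
  # pure integrator limit
  sci <- ground_truth_scenario("line_attractor", target_slow_tau = Inf, seed = 2)
  pi_ <- make_ground_truth_params(sci)
  expect_equal(max(Mod(eigen(pi_$A[[sci$K]])$values)), 1, tolerance = 1e-12)

  # rotational pair at the requested angle and modulus
  scr <- ground_truth_scenario("rotational", rotation_period = 10,
                               rotation_modulus = 0.995, sampling_rate = f,
                               seed = 2)
  pr <- make_ground_truth_params(scr)
  eg <- eigen(pr$A[[scr$K]])$values
  cx <- eg[order(-abs(Im(eg)))][1:2]
  expect_equal(sort(Mod(cx)), rep(0.995, 2), tolerance = 1e-10)
  expect_equal(max(abs(Arg(cx))), 2 * pi / (10 * f), tolerance = 1e-10)

  expect_error(make_ground_truth_params(
    ground_truth_scenario("rotational", D = 2, N = 4, seed = 1)), NA)
  expect_error(ground_truth_scenario("line_attractor", target_slow_tau = -5),
               "positive")
})

test_that("simulation follows the stated dynamics and is seed-deterministic", {
  # K=1, A=0, b=0, no noise: pinned at the origin
  p0 <- toy_params(K = 1, D = 2, N = 3, A = diag(0, 2), q = 0, r = 0)
  sim0 <- simulate_session(p0, NULL, n_frames = 20, seed = 1)
  expect_true(all(sim0$latents[, -1] == 0))

  # K=1, A = 0.5 I, b = (1, 0): converges to the fixed point (2, 0)
  p1 <- toy_params(K = 1, D = 2, N = 3, A = diag(0.5, 2), q = 0, r = 0)
  p1$b[[1]] <- c(1, 0)
  sim1 <- simulate_session(p1, NULL, n_frames = 80, seed = 1)
  expect_equal(sim1$latents[, 80], c(2, 0), tolerance = 1e-8)

  # AR(1) theory: empirical lag-1 autocorrelation matches the eigenvalue
  p2 <- toy_params(K = 1, D = 1, N = 3, A = matrix(0.95), q = 0.2, r = 0.01)
  sim2 <- simulate_session(p2, NULL, n_frames = 9000, seed = 4)
  x <- drop(sim2$latents)
  ac <- cor(x[-1], x[-length(x)])
  expect_equal(ac, 0.95, tolerance = 0.02)

  # determinism: identical seeds give identical sessions
  sc <- ground_truth_scenario("line_attractor", duration = 60, seed = 9)
  s1 <- synthetic_session(sc); s2 <- synthetic_session(sc)
  expect_identical(s1$recording$activity, s2$recording$activity)
  expect_identical(s1$annotations$behavior, s2$annotations$behavior)
  expect_identical(s1$pose$distance, s2$pose$distance)

  # explosion guard names the offending state's spectral radius
  px <- toy_params(K = 1, D = 1, N = 2, A = matrix(2), q = 0, r = 0.01)
  px$b[[1]] <- 1
  expect_error(simulate_session(px, NULL, 200, seed = 1), "spectral radius")
})

test_that("emissions are consistent with the stated observation model", {
  sc <- ground_truth_scenario("line_attractor", duration = 120, seed = 5)
  ss <- synthetic_session(sc)
  resid <- ss$recording$activity -
    (ss$params$C %*% ss$latents + ss$params$d_bias)
  expect_equal(mean(resid), 0, tolerance = 5e-3)
  expect_equal(sd(resid), sc$emission_noise_sd, tolerance = 2e-2)
})

test_that("behavior labels are gated by the slow dimension", {
  sc <- ground_truth_scenario("line_attractor", duration = 120, seed = 5)

  # constant slow dimension: no attack is ever emitted
  lat0 <- matrix(0, sc$D, 1800)
  ann0 <- synthesize_behavior_annotations(lat0, rep(1L, 1800), sc)
  expect_false("attack" %in% ann0$behavior)

  # monotone ramp crossing both thresholds: labels appear in escalation order
  p <- make_ground_truth_params(sc)
  gt <- attr(p, "ground_truth")
  ramp <- outer(gt$slow_axis, seq(0, 3, length.out = 1800))
  annr <- synthesize_behavior_annotations(ramp, rep(1L, 1800), sc, params = p)
  lab <- annr$behavior
  first <- vapply(c("sniff", "dominance_mount", "attack"),
                  function(b) match(b, lab), 0L)
  expect_true(all(diff(first) > 0))
  # every attack frame sits at/above the upper threshold by construction
  sn <- drop(t(gt$slow_axis) %*% ramp)
  sn <- (sn - min(sn)) / diff(range(sn))
  expect_true(all(sn[annr$behavior == "attack"] >= sc$behavior_thresholds[2]))

  # stochastic ordering in a full session: CDF means escalate
  ss <- short_line_session()
  gt2 <- attr(ss$params, "ground_truth")
  s <- drop(t(gt2$slow_axis) %*% ss$latents)
  mu <- vapply(c("sniff", "dominance_mount", "attack"),
               function(b) mean(s[ss$annotations$behavior == b]), 0)
  expect_true(all(diff(mu) > 0))
})

test_that("pose features depend on the behavior label as constructed", {
  ss <- short_line_session()
  lab <- ss$annotations$behavior
  expect_lt(mean(ss$pose$distance[lab == "attack"]),
            mean(ss$pose$distance[lab == "background"]))
  expect_true(all(ss$pose$distance > 0))
  expect_true(all(ss$pose$facing_angle >= 0 & ss$pose$facing_angle <= pi))
  expect_true(all(is.finite(as.matrix(ss$pose[, -1]))))

  # zero noise: features are a deterministic function of the labels
  sc0 <- ground_truth_scenario("line_attractor", duration = 60,
                               pose_noise_sd = 0, seed = 3)
  ss0 <- synthetic_session(sc0)
  dist_by_label <- tapply(ss0$pose$distance, ss0$annotations$behavior,
                          function(x) diff(range(x)))
  expect_true(all(dist_by_label == 0))
})
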