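# Tuning rasters, regressor bank, neuron assignment, keypoint pose
# features, rotation angles, sequentiality.

test_that("behavior-averaged activity matches direct arithmetic", {
  ann <- data.frame(frame = 0:2,
                    behavior = c("sniff", "sniff", "attack"),
                    intruder_sex = "male")
  attr(ann, "sampling_rate") <- 15
  Y <- matrix(c(1, 2, 3,
                4, 5, 6), 2, 3, byrow = TRUE)
  tm <- suppressMessages(behavior_mean_activity(Y, ann))
  expect_equal(unname(tm[, "sniff|male"]), c(1.5, 4.5))
  expect_equal(unname(tm[, "attack|male"]), c(3, 6))
  expect_true("attack|female" %in% attr(tm, "missing"))

  # invariance to frame order within behaviors
  perm <- c(2, 1, 3)
  tm2 <- suppressMessages(behavior_mean_activity(Y[, perm], ann))
  expect_equal(tm, tm2)
})

test_that("the default regressor bank has 40 distinct nonzero regressors", {
  bank <- build_regressor_bank()
  expect_length(bank, 40)
  expect_false(any(duplicated(lapply(bank, unname))))
  expect_true(all(vapply(bank, sum, 0) > 0))
  # union regressors are the elementwise OR of their members
  b <- bank
  expect_equal(unname(b[["sniff|any"]]),
               unname(pmin(b[["sniff|male"]] + b[["sniff|female"]], 1)))
  expect_equal(unname(b[["male_directed_all"]]),
               unname(pmin(Reduce(`+`, b[paste0(behavior_vocabulary, "|male")]), 1)))
})

test_that("neurons are assigned to their best regressor with the 50% rule", {
  bank <- build_regressor_bank()
  combos <- attr(bank, "combos")
  tuning <- matrix(0, 3, length(combos), dimnames = list(NULL, combos))
  # neuron 1: exactly an attack|male profile
  tuning[1, ] <- bank[["attack|male"]]
  # neuron 2: affinely rescaled escalation-union profile (no complement
  # regressor exists in the bank, so the fit is unambiguous)
  tuning[2, ] <- 3 * bank[["dominance_mount+attack|male"]] + 7
  # neuron 3: flat
  tuning[3, ] <- 5
  asg <- assign_neurons(tuning, bank)
  expect_equal(asg$regressor[1], "attack|male")
  expect_equal(asg$r_squared[1], 1)
  expect_equal(asg$regressor[2], "dominance_mount+attack|male")
  expect_equal(asg$r_squared[2], 1, tolerance = 1e-12)
  expect_true(asg$omitted[3])
  expect_false(any(asg$omitted[1:2]))
})

test_that("pose features from keypoints follow the stated geometry", {
  # resident at origin facing +x (nose at (1,0)); intruder on the +x axis
  mk <- function(int_x, int_y, n = 3) {
    data.frame(resident_nose_x = rep(1, n), resident_nose_y = 0,
               resident_head_x = 0, resident_head_y = 0,
               resident_hip_x = 0, resident_hip_y = 0,
               intruder_head_x = int_x, intruder_head_y = int_y,
               intruder_hip_x = int_x, intruder_hip_y = int_y)
  }
  # intruder straight ahead: facing angle 0
  pf <- pose_features_from_keypoints(mk(5, 0), sampling_rate = 10)
  expect_equal(pf$facing_angle, rep(0, 3), tolerance = 1e-9)
  # intruder perpendicular to the nose axis (above the resident centroid
  # at (1/3, 0)): facing angle pi/2
  pf2 <- pose_features_from_keypoints(mk(1 / 3, 5), sampling_rate = 10)
  expect_equal(pf2$facing_angle, rep(pi / 2, 3), tolerance = 1e-6)
  # stationary animals: zero speed
  expect_true(all(pf$speed == 0))
  # distance between centroids (resident centroid at (1/3, 0))
  expect_equal(pf$distance, rep(5 - 1 / 3, 3), tolerance = 1e-9)
})

test_that("rotation angle is referenced to sniff onset and tracks orbits", {
  # synthetic circular orbit, quarter period = 90 degrees
  T_ <- 400
  period <- 200
  ang <- 2 * pi * (0:(T_ - 1)) / period
  X <- rbind(cos(ang), sin(ang))
  lab <- rep("background", T_)
  lab[11:360] <- "sniff"
  ann <- data.frame(frame = 0:(T_ - 1), behavior = lab, intruder_sex = "female")
  attr(ann, "sampling_rate") <- 15
  eps <- data.frame(start_frame = 10, end_frame = 360)
  ra <- rotation_angle(X, ann, eps)
  s <- ra$series
  expect_equal(s$theta_deg[1], 0)
  q <- period / 4
  expect_equal(s$theta_deg[s$frame == 10 + q], 90, tolerance = 1)
  # +360 degrees per completed orbit
  expect_equal(s$theta_deg[s$frame == 10 + period], 360, tolerance = 1)
})

test_that("sequentiality index separates sequences from shared time courses", {
  set.seed(80)
  N <- 20; L <- 100
  mk_episode <- function(seqential) {
    M <- matrix(0, N, L)
    for (i in seq_len(N)) {
      center <- if (seqential) round(i * L / N) else 50
      M[i, ] <- exp(-(seq_len(L) - center)^2 / 18) + rnorm(L, 0, 0.02)
    }
    M
  }
  to_rec <- function(eps) recording(do.call(cbind, eps), 15)
  episodes <- data.frame(start_frame = (0:3) * L, end_frame = (1:4) * L)

  seq_rec <- to_rec(replicate(4, mk_episode(TRUE), simplify = FALSE))
  res_seq <- sequentiality_index(seq_rec, episodes, n_shuffles = 30, seed = 1)
  expect_gt(res_seq$index, 0.7)
  expect_true(res_seq$exceeds_null)
  expect_gt(res_seq$index, max(res_seq$shuffle_indices))

  ident_rec <- to_rec(replicate(4, mk_episode(FALSE), simplify = FALSE))
  res_id <- sequentiality_index(ident_rec, episodes, n_shuffles = 30, seed = 1)
  expect_lt(res_id$index, res_seq$index)
  expect_lt(res_id$index, 0.6)
})

test_that("episodes are sniff-anchored merged social spans", {
  lab <- rep("background", 1000)
  lab[101:130] <- "sniff"; lab[151:200] <- "mount_usv"   # one episode
  lab[700:720] <- "mount_usv"                            # no sniff: dropped
  ann <- data.frame(frame = 0:999, behavior = lab, intruder_sex = "female")
  attr(ann, "sampling_rate") <- 15
  eps <- episodes_from_annotations(ann)
  expect_equal(nrow(eps), 1)
  expect_equal(eps$start_frame, 100)
  expect_equal(eps$end_frame, 200)
})
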