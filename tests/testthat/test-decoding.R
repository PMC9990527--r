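# Bout merging, the threshold decoder, shuffle nulls, threshold
# transfer, behavior CDFs, and the pose GLM.

make_bout_labels <- function(spans, T_) {
  lab <- rep("background", T_)
  for (s in spans) lab[(s$start + 1):s$end] <- s$behavior
  ann <- data.frame(frame = 0:(T_ - 1), behavior = lab, intruder_sex = "male")
  attr(ann, "sampling_rate") <- 15
  class(ann) <- c("behavior_annotation", "data.frame")
  ann
}

test_that("bout merging respects the five-second rule", {
  # two attack bouts 3 s apart merge into one trial
  ann <- make_bout_labels(list(list(start = 0, end = 30, behavior = "attack"),
                               list(start = 75, end = 105, behavior = "attack")),
                          300)
  b <- merge_bouts(ann, gap_seconds = 5)
  expect_equal(nrow(b), 1)
  expect_equal(b$start_frame, 0); expect_equal(b$end_frame, 105)

  # a 6 s gap stays two trials
  ann2 <- make_bout_labels(list(list(start = 0, end = 30, behavior = "attack"),
                                list(start = 120, end = 150, behavior = "attack")),
                           300)
  b2 <- merge_bouts(ann2, gap_seconds = 5)
  expect_equal(nrow(b2), 2)
  expect_equal(length(unique(b2$trial_id)), 2)

  # empty annotations give an empty table
  b3 <- merge_bouts(make_bout_labels(list(), 100))
  expect_equal(nrow(b3), 0)
})

test_that("threshold decoder separates disjoint classes perfectly", {
  T_ <- 600
  spans <- list(list(start = 0, end = 50, behavior = "sniff"),
                list(start = 150, end = 200, behavior = "sniff"),
                list(start = 300, end = 350, behavior = "attack"),
                list(start = 450, end = 500, behavior = "attack"))
  ann <- make_bout_labels(spans, T_)
  sig <- numeric(T_)
  sig[ann$behavior == "sniff"] <- runif(sum(ann$behavior == "sniff"), 0, 0.3)
  sig[ann$behavior == "attack"] <- runif(sum(ann$behavior == "attack"), 0.6, 1)
  b <- merge_bouts(ann)
  dec <- fit_threshold_decoder(sig, b, c("sniff", "attack"))
  expect_equal(dec$f1, 1)
  expect_true(dec$positive_high)

  # symmetric under swapping the pair (orientation flips)
  dec2 <- fit_threshold_decoder(sig, b, c("attack", "sniff"))
  expect_equal(dec2$f1, 1)
  expect_false(dec2$positive_high)

  # results invariant to affine rescaling of the raw signal
  dec3 <- fit_threshold_decoder(5 * sig - 2, b, c("sniff", "attack"))
  expect_equal(dec3$f1, dec$f1)

  # single-class input is refused
  expect_error(fit_threshold_decoder(sig, b, c("sniff", "intromission")),
               "present")
})

test_that("identical class distributions decode at chance", {
  set.seed(70)
  f1s <- replicate(20, {
    T_ <- 900
    spans <- lapply(0:8, function(i)
      list(start = i * 100, end = i * 100 + 40,
           behavior = if (i %% 2 == 0) "sniff" else "attack"))
    ann <- make_bout_labels(spans, T_)
    sig <- rnorm(T_)          # label-independent
    b <- merge_bouts(ann, gap_seconds = 2)
    fit_threshold_decoder(sig, b, c("sniff", "attack"))$f1
  })
  expect_lt(mean(f1s), 0.62)
  expect_gt(mean(f1s), 0.38)
})

test_that("shuffle null calibrates and detects coupled signals", {
  set.seed(71)
  T_ <- 900
  spans <- lapply(0:8, function(i)
    list(start = i * 100, end = i * 100 + 40,
         behavior = if (i %% 2 == 0) "sniff" else "attack"))
  ann <- make_bout_labels(spans, T_)
  b <- merge_bouts(ann, gap_seconds = 2)

  # coupled signal: observed F1 exceeds the null's 97.5th percentile
  sig <- numeric(T_)
  sig[ann$behavior == "attack"] <- 0.8 + rnorm(sum(ann$behavior == "attack"), 0, 0.05)
  sig[ann$behavior != "attack"] <- 0.2 + rnorm(sum(ann$behavior != "attack"), 0, 0.05)
  nul <- shuffle_null(sig, b, c("sniff", "attack"), n_shuffles = 99, seed = 1)
  expect_true(nul$significant)
  expect_equal(length(nul$f1), 99)

  # label-independent signal: observed F1 falls inside the null spread
  sig0 <- rnorm(T_)
  nul0 <- shuffle_null(sig0, b, c("sniff", "attack"), n_shuffles = 99, seed = 2)
  expect_lt(nul0$observed_f1, max(nul0$f1) + 1e-9)
  expect_error(shuffle_null(sig0, b, c("sniff", "attack"), n_shuffles = 0),
               "at least 1")
})

test_that("cross-animal threshold transfer behaves as constructed", {
  set.seed(72)
  mk <- function(flip = FALSE, T_ = 900) {
    spans <- lapply(0:8, function(i)
      list(start = i * 100, end = i * 100 + 40,
           behavior = if (i %% 2 == 0) "sniff" else "attack"))
    ann <- make_bout_labels(spans, T_)
    sig <- numeric(T_)
    hi <- ann$behavior == "attack"
    sig[hi] <- 0.8 + rnorm(sum(hi), 0, 0.05)
    sig[!hi] <- 0.2 + rnorm(sum(!hi), 0, 0.05)
    if (flip) sig <- 1 - sig
    list(signal = sig, bouts = merge_bouts(ann, gap_seconds = 2))
  }
  # identical construction: transfer F1 approximately equals self F1
  ses <- list(mk(), mk(), mk(), mk())
  tr <- cross_animal_threshold_transfer(ses, c("sniff", "attack"))
  expect_true(all(tr$mean_transfer > 0.9))
  expect_equal(dim(tr$f1_matrix), c(4, 4))

  # an anti-correlated target collapses the transferred performance
  ses2 <- list(mk(), mk(flip = TRUE))
  tr2 <- cross_animal_threshold_transfer(ses2, c("sniff", "attack"))
  expect_lt(tr2$f1_matrix[1, 2], 0.4)
})

test_that("behavior CDFs order escalating behaviors on synthetic sessions", {
  ss <- short_line_session()
  gt <- attr(ss$params, "ground_truth")
  sig <- drop(t(gt$slow_axis) %*% ss$latents)
  cdf <- behavior_cdf(sig, ss$annotations,
                      c("sniff", "dominance_mount", "attack"))
  expect_true(all(diff(cdf$means$mean) > 0))
  expect_equal(cdf$means$behavior[1], "sniff")
  # CDFs are proper distribution functions
  for (f in cdf$cdfs) {
    expect_equal(f(-0.1), 0); expect_equal(f(1.1), 1)
  }
  # constant signal: degenerate and equal across behaviors
  cdf0 <- behavior_cdf(rep(0.5, nrow(ss$annotations)), ss$annotations,
                       c("sniff", "attack"))
  expect_equal(cdf0$means$mean, c(0, 0))
})

test_that("pose GLM recovers exact linear structure and rejects noise", {
  ss <- short_line_session()
  pose <- ss$pose
  # signal that is an exact linear function of the features
  sig <- 2 * pose$distance - 0.5 * pose$speed + 3
  rep1 <- pose_glm(sig, pose)
  expect_gt(rep1$r_squared, 0.999)
  # independent signal: cross-validated R^2 near zero (can be negative)
  set.seed(73)
  rep0 <- pose_glm(rnorm(nrow(pose)), pose)
  expect_lt(rep0$r_squared, 0.05)
})

test_that("IBI pseudo-bouts cover the gaps inside merged trials", {
  ann <- make_bout_labels(list(list(start = 0, end = 30, behavior = "attack"),
                               list(start = 60, end = 90, behavior = "attack"),
                               list(start = 300, end = 330, behavior = "attack")),
                          600)
  ib <- ibi_bouts(ann, "attack", gap_seconds = 5)
  expect_equal(nrow(ib), 1)
  expect_equal(ib$start_frame, 30); expect_equal(ib$end_frame, 60)
  expect_equal(ib$behavior, "ibi_attack")
})
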