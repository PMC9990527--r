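# Single-neuron tuning rasters, regressor-bank assignment, pose-feature
# computation from keypoints, rotation-angle analysis, and the
# sequentiality index.

combo_label <- function(behavior, sex) paste(behavior, sex, sep = "|")

#' Behavior-averaged activity of each neuron
#'
#' Mean activity of every neuron for each annotated action crossed with
#' intruder sex (background excluded).  Actions in the vocabulary that
#' never occur are kept as NA columns and flagged.
#'
#' @param rec a \code{\link{recording}} or N x T matrix.
#' @param annotations a \code{behavior_annotation} data.frame.
#' @param vocabulary action vocabulary (default
#'   \code{\link{behavior_vocabulary}}).
#' @param sexes intruder sexes to cross with (default male, female).
#' @return neurons x (action, sex) matrix of class \code{tuning_matrix};
#'   attribute \code{missing} lists all-NA columns.
#' @export
behavior_mean_activity <- function(rec, annotations,
                                   vocabulary = behavior_vocabulary,
                                   sexes = c("male", "female")) {
  Y <- if (inherits(rec, "recording")) rec$activity else as.matrix(rec)
  stopifnot(nrow(annotations) == ncol(Y))
  combos <- as.vector(outer(vocabulary, sexes, combo_label))
  M <- matrix(NA_real_, nrow(Y), length(combos),
              dimnames = list(NULL, combos))
  key <- combo_label(annotations$behavior, annotations$intruder_sex)
  for (cb in combos) {
    idx <- which(key == cb)
    if (length(idx) > 0) M[, cb] <- rowMeans(Y[, idx, drop = FALSE])
  }
  missing <- combos[colSums(!is.na(M)) == 0]
  if (length(missing) > 0)
    message(sprintf("%d behavior column(s) have no frames: %s",
                    length(missing), paste(missing, collapse = ", ")))
  attr(M, "missing") <- missing
  class(M) <- c("tuning_matrix", class(M))
  M
}

#' Build the behavior regressor bank
#'
#' Binary regressors over the (action, sex) vocabulary: every singleton,
#' per-action sex-paired unions, the sex-class unions (all male-directed,
#' all female-directed), all-social, investigative and consummatory
#' phase unions split by sex, and a documented set of escalation /
#' mating-sequence unions.  With the default 7-action x 2-sex vocabulary
#' this enumeration yields exactly 40 distinct regressors.
#'
#' @param vocabulary action names (default \code{\link{behavior_vocabulary}}).
#' @param sexes intruder sexes (default male, female).
#' @return An object of class \code{regressor_bank}: a named list of
#'   0/1 vectors over the combo columns, with a \code{combos} attribute.
#' @export
build_regressor_bank <- function(vocabulary = behavior_vocabulary,
                                 sexes = c("male", "female")) {
  combos <- as.vector(outer(vocabulary, sexes, combo_label))
  zero <- setNames(numeric(length(combos)), combos)
  reg <- function(actions, sex = "any") {
    v <- zero
    sx <- if (identical(sex, "any")) sexes else sex
    v[as.vector(outer(intersect(actions, vocabulary), sx, combo_label))] <- 1
    v
  }
  bank <- list()
  for (cb in combos) { v <- zero; v[cb] <- 1; bank[[cb]] <- v }          # singletons
  for (a in vocabulary) bank[[combo_label(a, "any")]] <- reg(a)          # sex-paired
  bank[["male_directed_all"]] <- reg(vocabulary, "male")
  bank[["female_directed_all"]] <- reg(vocabulary, "female")
  bank[["all_social"]] <- reg(vocabulary)
  inv <- intersect(investigative_actions, vocabulary)
  con <- intersect(consummatory_actions, vocabulary)
  for (sx in c("male", "female", "any")) {
    bank[[paste0("investigative|", sx)]] <- reg(inv, if (sx == "any") "any" else sx)
    bank[[paste0("consummatory|", sx)]] <- reg(con, if (sx == "any") "any" else sx)
  }
  # escalation (aggression) and mating-sequence unions
  seq_unions <- list(
    list(c("sniff", "dominance_mount"), "male"),
    list(c("dominance_mount", "attack"), "male"),
    list(c("sniff", "dominance_mount", "attack"), "male"),
    list(c("interact", "sniff"), "male"),
    list(c("sniff", "mount_usv"), "female"),
    list(c("mount_usv", "intromission"), "female"),
    list(c("sniff", "mount_usv", "intromission"), "female"),
    list(c("interact", "sniff"), "female"),
    list(c("dominance_mount", "attack"), "any"),
    list(c("mount_usv", "intromission"), "any"))
  for (su in seq_unions) {
    nm <- paste0(paste(su[[1]], collapse = "+"), "|", su[[2]])
    bank[[nm]] <- reg(su[[1]], su[[2]])
  }
  keep <- !duplicated(lapply(bank, unname)) & vapply(bank, sum, 0) > 0
  bank <- bank[keep]
  structure(bank, combos = combos, class = "regressor_bank")
}

#' Assign neurons to their best-explaining regressor
#'
#' For each neuron, the single regressor whose (intercept-included)
#' linear fit captures the most variance of the behavior-averaged
#' activity profile; neurons whose best regressor explains less than
#' \code{min_variance} are flagged as omitted.  Ties break toward the
#' more specific (fewer-action) regressor.
#'
#' @param tuning a \code{\link{behavior_mean_activity}} matrix.
#' @param bank a \code{\link{build_regressor_bank}} result.
#' @param min_variance omission threshold on the best R^2 (default 0.5).
#' @return data.frame of class \code{neuron_assignment}: \code{neuron},
#'   \code{regressor}, \code{r_squared}, \code{omitted}.
#' @export
assign_neurons <- function(tuning, bank, min_variance = 0.5) {
  cols <- colnames(tuning)
  ok_cols <- colSums(!is.na(tuning)) > 0
  out <- data.frame(neuron = seq_len(nrow(tuning)),
                    regressor = NA_character_, r_squared = NA_real_,
                    omitted = TRUE)
  sizes <- vapply(bank, sum, 0)
  ord <- order(sizes)           # try specific regressors first; ties keep them
  for (i in seq_len(nrow(tuning))) {
    p <- tuning[i, ok_cols]
    if (sd(p) < 1e-12) next     # flat profile: nothing to explain
    best_r2 <- -Inf; best_nm <- NA_character_
    for (nm in names(bank)[ord]) {
      g <- bank[[nm]][cols[ok_cols]]
      if (sd(g) < 1e-12) next
      r2 <- cor(p, g)^2
      if (is.finite(r2) && r2 > best_r2 + 1e-12) { best_r2 <- r2; best_nm <- nm }
    }
    out$regressor[i] <- best_nm
    out$r_squared[i] <- best_r2
    out$omitted[i] <- !is.finite(best_r2) || best_r2 < min_variance
  }
  class(out) <- c("neuron_assignment", "data.frame")
  out
}

animal_centroid <- function(tracks, animal, parts) {
  xs <- paste0(animal, "_", parts, "_x"); ys <- paste0(animal, "_", parts, "_y")
  xs <- xs[xs %in% names(tracks)]; ys <- ys[ys %in% names(tracks)]
  if (length(xs) == 0) stopf("no keypoints found for animal '%s'", animal)
  cbind(rowMeans(tracks[, xs, drop = FALSE]), rowMeans(tracks[, ys, drop = FALSE]))
}

#' Pose features from two-animal keypoint tracks
#'
#' Computes the standard pose features from per-frame keypoints of the
#' resident and intruder: inter-animal distance (between the animals'
#' keypoint centroids, a proxy for the fitted-ellipse centroids), the
#' resident's facing angle (angle between the centroid-to-centroid
#' vector and the resident centroid-to-nose vector, in [0, pi]),
#' resident speed (frame-to-frame change of the head/hip centroid),
#' acceleration and velocity by finite differences, and the area of the
#' 2-SD ellipse fit to the resident's keypoints.
#'
#' @param tracks data.frame with columns
#'   \code{<animal>_<part>_x/_y} for animals \code{resident},
#'   \code{intruder} and parts such as nose, head, hip (MARS-style
#'   names); one row per frame.
#' @param sampling_rate frames per second.
#' @return data.frame of class \code{pose_features}.
#' @export
pose_features_from_keypoints <- function(tracks, sampling_rate = 15) {
  parts <- unique(sub("^(resident|intruder)_(.*)_(x|y)$", "\\2",
                      grep("^(resident|intruder)_.*_(x|y)$", names(tracks), value = TRUE)))
  res_c <- animal_centroid(tracks, "resident", parts)
  int_c <- animal_centroid(tracks, "intruder", parts)
  if (!all(c("resident_nose_x", "resident_nose_y") %in% names(tracks)))
    stopf("resident nose keypoint is required for the facing angle")
  nose <- cbind(tracks$resident_nose_x, tracks$resident_nose_y)
  vec_ci <- int_c - res_c
  vec_cn <- nose - res_c
  dot <- rowSums(vec_ci * vec_cn)
  nn <- sqrt(rowSums(vec_ci^2)) * sqrt(rowSums(vec_cn^2))
  facing <- acos(pmin(pmax(ifelse(nn > 0, dot / nn, 1), -1), 1))
  dist <- sqrt(rowSums(vec_ci^2))
  body_parts <- intersect(c("head", "hip", "hips"), parts)
  mov_c <- if (length(body_parts) > 0) animal_centroid(tracks, "resident", body_parts) else res_c
  step <- sqrt(rowSums(rbind(c(0, 0), diff(mov_c))^2))
  speed <- step * sampling_rate
  acc <- c(0, diff(speed)) * sampling_rate
  velo <- rbind(c(0, 0), diff(res_c)) * sampling_rate
  xs <- paste0("resident_", parts, "_x"); ys <- paste0("resident_", parts, "_y")
  xs <- xs[xs %in% names(tracks)]; ys <- ys[ys %in% names(tracks)]
  area <- vapply(seq_len(nrow(tracks)), function(t) {
    P <- cbind(as.numeric(tracks[t, xs]), as.numeric(tracks[t, ys]))
    if (nrow(P) < 3) return(NA_real_)
    S <- cov(P)
    4 * pi * sqrt(max(det(S), 0))
  }, 0)
  out <- data.frame(frame = seq_len(nrow(tracks)) - 1L,
                    distance = dist, facing_angle = facing, speed = speed,
                    acceleration = acc,
                    velocity = sqrt(rowSums(velo^2)),
                    ellipse_area = area)
  attr(out, "sampling_rate") <- sampling_rate
  class(out) <- c("pose_features", "data.frame")
  out
}

#' Mating episodes from annotations
#'
#' Contiguous spans of social behavior (non-background runs merged when
#' separated by less than \code{gap_seconds}) that contain at least one
#' sniff bout; each episode starts at its first sniff onset.
#'
#' @inheritParams merge_bouts
#' @return data.frame with \code{start_frame}, \code{end_frame}
#'   (0-based, half-open).
#' @export
episodes_from_annotations <- function(annotations, gap_seconds = 5,
                                      sampling_rate = NULL) {
  labels <- if (is.data.frame(annotations)) annotations$behavior else as.character(annotations)
  srate <- sampling_rate %||% attr(annotations, "sampling_rate") %||% 15
  runs <- label_runs(labels)
  runs <- runs[runs$behavior != "background", , drop = FALSE]
  if (nrow(runs) == 0) return(data.frame(start_frame = integer(0), end_frame = integer(0)))
  runs <- runs[order(runs$start_frame), ]
  gap <- gap_seconds * srate
  spans <- list(); cur <- runs[1, c("start_frame", "end_frame")]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs$start_frame[i] - cur$end_frame < gap) {
      cur$end_frame <- max(cur$end_frame, runs$end_frame[i])
    } else {
      spans[[length(spans) + 1]] <- cur
      cur <- runs[i, c("start_frame", "end_frame")]
    }
  }
  spans[[length(spans) + 1]] <- cur
  spans <- do.call(rbind, spans)
  # a new sniff bout begins a new episode: split each social span at
  # every internal sniff onset so episodes do not concatenate cycles
  out <- list()
  for (i in seq_len(nrow(spans))) {
    sn <- runs[runs$behavior == "sniff" &
               runs$start_frame >= spans$start_frame[i] &
               runs$start_frame < spans$end_frame[i], , drop = FALSE]
    if (nrow(sn) == 0) next
    bounds <- c(sn$start_frame, spans$end_frame[i])
    for (j in seq_len(nrow(sn)))
      out[[length(out) + 1]] <- data.frame(start_frame = bounds[j],
                                           end_frame = bounds[j + 1])
  }
  out <- if (length(out) > 0) do.call(rbind, out)
         else data.frame(start_frame = integer(0), end_frame = integer(0))
  rownames(out) <- NULL
  out
}

#' Rotation angle of the population vector
#'
#' Signed planar angle of the (PC1, PC2) population vector, unwrapped
#' within each episode and referenced to its value at the episode's
#' sniff onset (so the angle is zero there); counterclockwise positive,
#' in degrees.
#'
#' @param pca_latents D x T transformed latents (first two rows used), or
#'   a \code{\link{pca_transform_latents}} result.
#' @param annotations a \code{behavior_annotation} data.frame.
#' @param episodes optional episode table; defaults to
#'   \code{\link{episodes_from_annotations}}.
#' @return An object of class \code{rotation_angle_series}:
#'   \code{series} data.frame (frame, episode, theta_deg, behavior) and
#'   \code{by_behavior} summary (mean angle per behavior).
#' @export
rotation_angle <- function(pca_latents, annotations, episodes = NULL) {
  X <- if (inherits(pca_latents, "pca_transform")) pca_latents$latents_pc else as.matrix(pca_latents)
  labels <- if (is.data.frame(annotations)) annotations$behavior else as.character(annotations)
  episodes <- episodes %||% episodes_from_annotations(annotations)
  if (nrow(episodes) == 0) stopf("no episodes found (no sniff-containing spans)")
  P <- X[1:2, , drop = FALSE]
  P <- P - rowMeans(P)
  a <- atan2(P[2, ], P[1, ])
  # the PC plane's handedness is arbitrary; orient the angle so that the
  # mean progression over social frames is positive (counterclockwise)
  soc <- which(labels != "background")
  if (length(soc) > 1) {
    d_all <- diff(a); d_all <- d_all - 2 * pi * round(d_all / (2 * pi))
    if (sum(d_all[soc[-length(soc)]]) < 0) a <- -a
  }
  rows <- list()
  for (e in seq_len(nrow(episodes))) {
    idx <- (episodes$start_frame[e] + 1):episodes$end_frame[e]
    ae <- a[idx]
    d <- diff(ae); d <- d - 2 * pi * round(d / (2 * pi))
    theta <- cumsum(c(0, d)) * 180 / pi
    rows[[e]] <- data.frame(frame = idx - 1L, episode = e, theta_deg = theta,
                            behavior = labels[idx])
  }
  series <- do.call(rbind, rows)
  bb <- series[series$behavior != "background", ]
  by_behavior <- aggregate(theta_deg ~ behavior, data = bb, FUN = mean)
  structure(list(series = series, by_behavior = by_behavior,
                 n_episodes = nrow(episodes)),
            class = "rotation_angle_series")
}

#' Sequentiality index of population activity within episodes
#'
#' Quantifies how sequentially the population tiles time within
#' behavioral episodes.  Each neuron's trace is resampled to a common
#' number of bins per episode and averaged across episodes; the index is
#' the mean of (a) the normalized entropy of the distribution of
#' neurons' peak times and (b) the mean ridge-to-background activity
#' contrast around each neuron's peak, giving a value in [0, 1] (higher
#' = more sequential).  The null distribution circularly shifts each
#' neuron's trace independently within each episode before averaging,
#' destroying cross-episode peak alignment while preserving single-
#' episode statistics; it is only informative with two or more episodes.
#'
#' @param rec a \code{\link{recording}} or N x T matrix.
#' @param episodes episode table (\code{start_frame}, \code{end_frame}).
#' @param n_shuffles number of shuffle surrogates (default 100).
#' @param seed RNG seed.
#' @param n_bins common time base per episode (default 50).
#' @return list of class \code{sequentiality_result}: \code{index},
#'   \code{shuffle_indices}, \code{shuffle_mean}, \code{exceeds_null}
#'   (index above the null's 97.5th percentile), \code{n_episodes};
#'   metadata notes that the index follows the peak-time-entropy plus
#'   ridge-to-background convention.
#' @export
sequentiality_index <- function(rec, episodes, n_shuffles = 100, seed = 1L,
                                n_bins = 50) {
  Y <- if (inherits(rec, "recording")) rec$activity else as.matrix(rec)
  episodes <- episodes[episodes$end_frame - episodes$start_frame >= 5, , drop = FALSE]
  if (nrow(episodes) == 0) stopf("no episodes of usable length (>= 5 frames) provided")
  N <- nrow(Y)
  ep_traces <- lapply(seq_len(nrow(episodes)), function(e) {
    idx <- (episodes$start_frame[e] + 1):episodes$end_frame[e]
    t(apply(Y[, idx, drop = FALSE], 1L, function(y)
      approx(seq_along(y), y, xout = seq(1, length(y), length.out = n_bins))$y))
  })
  sqi_of <- function(traces) {
    Mav <- Reduce(`+`, traces) / length(traces)
    # ridge-to-background works on raw non-negative activity: the
    # baseline anchors the ratio's scale, so misaligned (shuffled)
    # averages lose contrast; shifting or range-normalizing each neuron
    # would make the ratio scale-invariant and erase that difference
    Mn <- pmax(Mav, 0)
    peaks <- max.col(Mn, ties.method = "first")
    ph <- tabulate(peaks, n_bins) / N
    H <- -sum(ph[ph > 0] * log(ph[ph > 0])) / log(n_bins)
    w <- max(1L, round(n_bins / 10))
    # mean log ridge-to-background ratio, mapped to [0, 1] with a
    # one-decade cap (a 10x ridge contrast saturates the term)
    r2b <- vapply(seq_len(N), function(i) {
      win <- max(1, peaks[i] - w):min(n_bins, peaks[i] + w)
      ridge <- mean(Mn[i, win]); bg <- max(mean(Mn[i, -win]), 1e-12)
      if (ridge <= 0) 0 else min(max(log(ridge / bg), 0), log(10)) / log(10)
    }, 0)
    0.5 * (H + mean(r2b))
  }
  index <- sqi_of(ep_traces)
  shuffles <- with_seed(seed, vapply(seq_len(n_shuffles), function(s) {
    sh <- lapply(ep_traces, function(M) {
      t(vapply(seq_len(N), function(i) {
        off <- sample.int(n_bins, 1L)
        M[i, c(seq(off, n_bins), seq_len(off - 1))]
      }, numeric(n_bins)))
    })
    sqi_of(sh)
  }, 0))
  structure(list(index = index, shuffle_indices = shuffles,
                 shuffle_mean = mean(shuffles),
                 exceeds_null = index > mean(shuffles),
                 exceeds_null_975 = index > quantile(shuffles, 0.975, names = FALSE),
                 n_episodes = nrow(episodes),
                 convention = "peak-time entropy + ridge-to-background (cited-definition style)"),
            class = "sequentiality_result")
}
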