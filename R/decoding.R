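# Behavior decoding from a one-dimensional signal (the integration
# dimension): bout merging into trials, a maximum-margin threshold
# decoder with leave-one-trial-out evaluation, bout-label shuffle nulls,
# cross-animal threshold transfer, per-behavior CDFs, and the
# pose-feature GLM control.

#' Merge behavior bouts into trials
#'
#' Runs of identical frame labels become bouts; bouts of the same
#' behavior separated by less than \code{gap_seconds} are merged into a
#' single "trial" (the merged span, including the short gaps).
#'
#' @param annotations a \code{behavior_annotation} data.frame or a
#'   character vector of frame labels.
#' @param gap_seconds merge gaps shorter than this (default 5 s).
#' @param sampling_rate frames per second; taken from the annotation
#'   attribute when present.
#' @param keep_background include background runs as bouts (default FALSE).
#' @return data.frame of class \code{bout_table} with columns
#'   \code{behavior}, \code{start_frame}, \code{end_frame} (0-based,
#'   half-open), \code{trial_id}.
#' @export
merge_bouts <- function(annotations, gap_seconds = 5, sampling_rate = NULL,
                        keep_background = FALSE) {
  labels <- if (is.data.frame(annotations)) annotations$behavior else as.character(annotations)
  srate <- sampling_rate %||% attr(annotations, "sampling_rate") %||% 15
  runs <- label_runs(labels)
  if (!keep_background) runs <- runs[runs$behavior != "background", , drop = FALSE]
  if (nrow(runs) == 0) {
    out <- data.frame(behavior = character(0), start_frame = integer(0),
                      end_frame = integer(0), trial_id = integer(0))
    class(out) <- c("bout_table", "data.frame")
    return(out)
  }
  gap <- gap_seconds * srate
  out <- list(); tid <- 0L
  for (b in unique(runs$behavior)) {
    rb <- runs[runs$behavior == b, , drop = FALSE]
    rb <- rb[order(rb$start_frame), , drop = FALSE]
    cur <- rb[1, ]
    for (i in seq_len(nrow(rb))[-1]) {
      if (rb$start_frame[i] - cur$end_frame < gap) {
        cur$end_frame <- rb$end_frame[i]
      } else {
        tid <- tid + 1L
        out[[length(out) + 1]] <- data.frame(behavior = b,
                                             start_frame = cur$start_frame,
                                             end_frame = cur$end_frame,
                                             trial_id = tid)
        cur <- rb[i, ]
      }
    }
    tid <- tid + 1L
    out[[length(out) + 1]] <- data.frame(behavior = b,
                                         start_frame = cur$start_frame,
                                         end_frame = cur$end_frame,
                                         trial_id = tid)
  }
  out <- do.call(rbind, out)
  out <- out[order(out$start_frame), ]
  rownames(out) <- NULL
  attr(out, "sampling_rate") <- srate
  class(out) <- c("bout_table", "data.frame")
  out
}

#' Inter-bout-interval pseudo-bouts
#'
#' Builds a bout table of the unannotated gaps between consecutive bouts
#' of one behavior inside the same merged trial, labeled
#' \code{"ibi_<behavior>"}; these can be decoded like any behavior pair.
#'
#' @param annotations frame labels (see \code{\link{merge_bouts}}).
#' @param behavior behavior whose inter-bout intervals to extract.
#' @param gap_seconds trial-merging gap (default 5 s).
#' @inheritParams merge_bouts
#' @return a \code{bout_table} of IBI spans.
#' @export
ibi_bouts <- function(annotations, behavior, gap_seconds = 5, sampling_rate = NULL) {
  labels <- if (is.data.frame(annotations)) annotations$behavior else as.character(annotations)
  srate <- sampling_rate %||% attr(annotations, "sampling_rate") %||% 15
  runs <- label_runs(labels)
  runs <- runs[runs$behavior == behavior, , drop = FALSE]
  trials <- merge_bouts(annotations, gap_seconds, srate)
  trials <- trials[trials$behavior == behavior, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(trials))) {
    rb <- runs[runs$start_frame >= trials$start_frame[i] &
               runs$end_frame <= trials$end_frame[i], , drop = FALSE]
    if (nrow(rb) < 2) next
    rb <- rb[order(rb$start_frame), ]
    for (j in seq_len(nrow(rb) - 1)) {
      if (rb$start_frame[j + 1] > rb$end_frame[j])
        out[[length(out) + 1]] <- data.frame(
          behavior = paste0("ibi_", behavior),
          start_frame = rb$end_frame[j], end_frame = rb$start_frame[j + 1],
          trial_id = trials$trial_id[i])
    }
  }
  out <- if (length(out) > 0) do.call(rbind, out)
         else data.frame(behavior = character(0), start_frame = integer(0),
                         end_frame = integer(0), trial_id = integer(0))
  rownames(out) <- NULL
  attr(out, "sampling_rate") <- srate
  class(out) <- c("bout_table", "data.frame")
  out
}

bout_frames <- function(bouts, behavior) {
  rows <- bouts[bouts$behavior == behavior, , drop = FALSE]
  if (nrow(rows) == 0) return(data.frame(frame = integer(0), trial = integer(0)))
  do.call(rbind, lapply(seq_len(nrow(rows)), function(i)
    data.frame(frame = (rows$start_frame[i] + 1):rows$end_frame[i],
               trial = rows$trial_id[i])))
}

# maximum-margin threshold on a scalar: minimize the class-balanced error
# over all midpoint candidates; ties are broken toward the widest gap
# (the maximum-margin solution among empirical-risk minimizers)
threshold_1d <- function(values, is_pos) {
  o <- order(values)
  v <- values[o]; yp <- is_pos[o]
  nP <- sum(is_pos); nN <- length(is_pos) - nP
  distinct <- which(diff(v) > 0)
  cand <- c(v[1] - 1, (v[distinct] + v[distinct + 1]) / 2, v[length(v)] + 1)
  gapw <- c(0, (v[distinct + 1] - v[distinct]) / 2, 0)
  cum_pos <- cumsum(yp); cum_neg <- cumsum(!yp)
  n_below <- c(0, distinct, length(v))
  pos_below <- c(0, cum_pos[distinct], nP)
  neg_below <- c(0, cum_neg[distinct], nN)
  # orientation A: positive class predicted at/above threshold
  errA <- 0.5 * (pos_below / nP + (nN - neg_below) / nN)
  # orientation B: positive class predicted below threshold
  errB <- 0.5 * ((nP - pos_below) / nP + neg_below / nN)
  pick <- function(err) {
    best <- which(err == min(err))
    best[which.max(gapw[best])]
  }
  if (min(errA) <= min(errB)) {
    i <- pick(errA)
    list(threshold = cand[i], positive_high = TRUE, train_error = errA[i])
  } else {
    i <- pick(errB)
    list(threshold = cand[i], positive_high = FALSE, train_error = errB[i])
  }
}

predict_threshold <- function(th, values) {
  if (th$positive_high) values >= th$threshold else values < th$threshold
}

f1_score <- function(truth, pred) {
  tp <- sum(truth & pred); fp <- sum(!truth & pred); fn <- sum(truth & !pred)
  if (2 * tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

macro_f1 <- function(truth, pred) {
  (f1_score(truth, pred) + f1_score(!truth, !pred)) / 2
}

#' Threshold decoder for a behavior pair
#'
#' Frame-wise 1D decoder: the signal is min-max normalized, a
#' maximum-margin threshold separating the two behaviors' frames is fit
#' with class balancing, and performance is evaluated by
#' leave-one-trial-out cross-validation — each merged trial is held out
#' in turn, the threshold is refit on the remaining trials, and the
#' pooled held-out predictions are scored by macro-averaged F1 (the mean
#' of the two one-vs-rest F1 scores, symmetric under swapping the pair).
#'
#' @param signal numeric vector (one value per frame of the session).
#' @param bouts a \code{bout_table} (see \code{\link{merge_bouts}}).
#' @param pair character vector of two behavior labels; the second is the
#'   positive class.
#' @param cv currently \code{"leave-one-trial-out"} or \code{"none"}
#'   (fit and evaluate on all frames).
#' @return An object of class \code{decoder_result}: \code{pair},
#'   \code{threshold}, \code{positive_high}, \code{f1} (pooled held-out
#'   macro F1), \code{trial_f1} (per-held-out-trial one-class F1),
#'   \code{n_trials}.
#' @export
fit_threshold_decoder <- function(signal, bouts, pair,
                                  cv = c("leave-one-trial-out", "none")) {
  cv <- match.arg(cv)
  stopifnot(length(pair) == 2)
  s <- minmax(signal)
  fa <- bout_frames(bouts, pair[1])
  fb <- bout_frames(bouts, pair[2])
  if (nrow(fa) == 0 || nrow(fb) == 0)
    stopf("both behaviors must be present; '%s' has %d frames and '%s' has %d",
          pair[1], nrow(fa), pair[2], nrow(fb))
  frames <- c(fa$frame, fb$frame)
  is_pos <- c(rep(FALSE, nrow(fa)), rep(TRUE, nrow(fb)))
  trial <- c(fa$trial, fb$trial)
  if (max(frames) > length(s)) stopf("bout table addresses frames beyond the signal")
  v <- s[frames]
  th_full <- threshold_1d(v, is_pos)
  trials <- unique(trial)
  if (cv == "leave-one-trial-out") {
    if (length(unique(trial[is_pos])) < 2 || length(unique(trial[!is_pos])) < 2)
      stopf("leave-one-trial-out needs at least two trials per behavior")
    pred <- logical(length(v))
    trial_f1 <- setNames(numeric(length(trials)), trials)
    for (ti in trials) {
      hold <- trial == ti
      th <- threshold_1d(v[!hold], is_pos[!hold])
      pred[hold] <- predict_threshold(th, v[hold])
      trial_f1[as.character(ti)] <-
        if (any(is_pos[hold])) f1_score(is_pos[hold], pred[hold])
        else f1_score(!is_pos[hold], !pred[hold])
    }
    f1 <- macro_f1(is_pos, pred)
  } else {
    pred <- predict_threshold(th_full, v)
    f1 <- macro_f1(is_pos, pred)
    trial_f1 <- NULL
  }
  structure(list(pair = pair, threshold = th_full$threshold,
                 positive_high = th_full$positive_high,
                 f1 = f1, trial_f1 = trial_f1, n_trials = length(trials)),
            class = "decoder_result")
}

#' @export
print.decoder_result <- function(x, ...) {
  cat(sprintf("Threshold decoder %s vs %s: F1 = %.3f (%d trials, positive %s threshold)\n",
              x$pair[1], x$pair[2], x$f1, x$n_trials,
              if (x$positive_high) "above" else "below"))
  invisible(x)
}

#' Bout-label shuffle null for the threshold decoder
#'
#' Behavior labels are randomly re-assigned to the merged trials
#' (preserving the number of trials per behavior), the decoder is refit
#' and re-evaluated for each shuffle, and the observed F1 is compared
#' against the 97.5th percentile of the null distribution.
#'
#' @inheritParams fit_threshold_decoder
#' @param n_shuffles number of label shuffles (default 1000).
#' @param seed RNG seed.
#' @return An object of class \code{shuffle_distribution}:
#'   \code{observed_f1}, \code{f1} (length \code{n_shuffles}),
#'   \code{percentile_97_5}, \code{significant}.
#' @export
shuffle_null <- function(signal, bouts, pair, n_shuffles = 1000, seed = 1L,
                         cv = "leave-one-trial-out") {
  if (n_shuffles < 1) stopf("n_shuffles must be at least 1")
  obs <- fit_threshold_decoder(signal, bouts, pair, cv = cv)
  sub <- bouts[bouts$behavior %in% pair, , drop = FALSE]
  trials <- unique(sub$trial_id)
  lab_of <- vapply(trials, function(ti) sub$behavior[sub$trial_id == ti][1], "")
  f1s <- with_seed(seed, vapply(seq_len(n_shuffles), function(i) {
    relab <- sample(lab_of)
    shuf <- sub
    shuf$behavior <- relab[match(shuf$trial_id, trials)]
    res <- tryCatch(fit_threshold_decoder(signal, shuf, pair, cv = cv),
                    error = function(e) NULL)
    if (is.null(res)) NA_real_ else res$f1
  }, 0))
  f1s <- f1s[is.finite(f1s)]
  p975 <- quantile(f1s, 0.975, names = FALSE)
  structure(list(observed_f1 = obs$f1, f1 = f1s, n_shuffles = n_shuffles,
                 percentile_97_5 = p975, significant = obs$f1 > p975),
            class = "shuffle_distribution")
}

#' Cross-animal threshold transfer
#'
#' Applies the decoding threshold fit in each session to the normalized
#' integration signal of every other session, guarding against decoders
#' that exploit session-specific slow drift rather than a conserved
#' behavior code.
#'
#' @param sessions list of sessions, each a list with \code{signal} and
#'   \code{bouts}.
#' @param pair the behavior pair to decode.
#' @return An object of class \code{transfer_result}: \code{f1_matrix}
#'   (source session x target session; diagonal = self fit), and
#'   \code{mean_transfer} per source (off-diagonal means).
#' @export
cross_animal_threshold_transfer <- function(sessions, pair) {
  n <- length(sessions)
  if (n < 2) stopf("need at least two sessions")
  ths <- lapply(sessions, function(ss) {
    fa <- bout_frames(ss$bouts, pair[1]); fb <- bout_frames(ss$bouts, pair[2])
    if (nrow(fa) == 0 || nrow(fb) == 0)
      stopf("both behaviors of the pair must be present in every session")
    v <- minmax(ss$signal)[c(fa$frame, fb$frame)]
    threshold_1d(v, c(rep(FALSE, nrow(fa)), rep(TRUE, nrow(fb))))
  })
  M <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ss <- sessions[[j]]
    fa <- bout_frames(ss$bouts, pair[1]); fb <- bout_frames(ss$bouts, pair[2])
    v <- minmax(ss$signal)[c(fa$frame, fb$frame)]
    truth <- c(rep(FALSE, nrow(fa)), rep(TRUE, nrow(fb)))
    M[i, j] <- macro_f1(truth, predict_threshold(ths[[i]], v))
  }
  mt <- vapply(seq_len(n), function(i) mean(M[i, -i]), 0)
  structure(list(f1_matrix = M, mean_transfer = mt, pair = pair),
            class = "transfer_result")
}

#' Per-behavior CDFs of the normalized signal
#'
#' Empirical cumulative distribution of the min-max normalized signal on
#' each behavior's frames, with means for the classic
#' "low / medium / high" comparison across escalating behaviors.
#'
#' @param signal numeric frame-wise signal.
#' @param annotations frame labels.
#' @param behaviors behaviors to include (default: all except background).
#' @return An object of class \code{behavior_cdf}: \code{means}
#'   data.frame and a named list of \code{\link[stats]{ecdf}} functions.
#' @export
behavior_cdf <- function(signal, annotations, behaviors = NULL) {
  labels <- if (is.data.frame(annotations)) annotations$behavior else as.character(annotations)
  if (length(labels) != length(signal))
    stopf("signal covers %d frames but annotations cover %d", length(signal), length(labels))
  s <- minmax(signal)
  behaviors <- behaviors %||% setdiff(unique(labels), "background")
  behaviors <- behaviors[behaviors %in% labels]
  if (length(behaviors) == 0) stopf("no requested behavior has frames")
  cdfs <- lapply(behaviors, function(b) ecdf(s[labels == b]))
  names(cdfs) <- behaviors
  means <- data.frame(behavior = behaviors,
                      mean = vapply(behaviors, function(b) mean(s[labels == b]), 0),
                      n_frames = vapply(behaviors, function(b) sum(labels == b), 0L))
  rownames(means) <- NULL
  structure(list(means = means, cdfs = cdfs), class = "behavior_cdf")
}

#' Pose-feature GLM control for the integration signal
#'
#' How much of the integration-dimension signal is predictable from pose
#' alone: a Gaussian-identity GLM of the signal on the pose features,
#' scored by cross-validated R-squared over contiguous folds (respecting
#' temporal autocorrelation).
#'
#' @param signal numeric frame-wise signal.
#' @param pose a \code{pose_features} data.frame.
#' @param cv_folds number of contiguous folds (default 5).
#' @param features feature columns to use; defaults to distance, facing
#'   angle, speed, acceleration, velocity (those present).
#' @return An object of class \code{glm_report}: \code{r_squared} (mean
#'   cross-validated), \code{fold_r2}, \code{coefficients},
#'   \code{features}.
#' @export
pose_glm <- function(signal, pose, cv_folds = 5,
                     features = c("distance", "facing_angle", "speed",
                                  "acceleration", "velocity")) {
  features <- intersect(features, names(pose))
  if (length(features) == 0) stopf("no usable pose features found")
  df <- data.frame(signal = signal, pose[, features, drop = FALSE])
  T_ <- nrow(df)
  fold <- cut(seq_len(T_), breaks = cv_folds, labels = FALSE)
  r2 <- numeric(cv_folds)
  for (f in seq_len(cv_folds)) {
    train <- df[fold != f, , drop = FALSE]
    test <- df[fold == f, , drop = FALSE]
    fitlm <- lm(signal ~ ., data = train)
    pred <- predict(fitlm, newdata = test)
    r2[f] <- 1 - sum((test$signal - pred)^2) /
      sum((test$signal - mean(train$signal))^2)
  }
  full <- lm(signal ~ ., data = df)
  structure(list(r_squared = mean(r2), fold_r2 = r2,
                 coefficients = coef(full), features = features),
            class = "glm_report")
}

#' Two-group comparison helper
#'
#' Thin wrapper delegating to the standard non-parametric tests used for
#' session-level comparisons: Mann-Whitney (unpaired) or Wilcoxon
#' signed-rank (paired).
#'
#' @param x,y numeric vectors of per-session values.
#' @param paired logical.
#' @return list with \code{statistic}, \code{p_value}, \code{method}.
#' @export
group_comparison <- function(x, y, paired = FALSE) {
  ht <- wilcox.test(x, y, paired = paired, exact = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = ht$method)
}
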