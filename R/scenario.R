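#' Ground-truth scenario for synthetic sessions
#'
#' Describes the generative world for a synthetic imaging session: the
#' dynamical regime, model sizes, recording geometry, the target
#' eigenstructure, and the behavior-bout process coupled to the latent.
#' Defaults emulate a 10-minute resident-intruder session imaged at 15 Hz
#' with 40 neurons, a ground-truth slow (integration) dimension with a
#' 150 s time constant in the line-attractor regime, and a ~10 s rotation
#' period in the rotational regime.
#'
#' @param regime one of \code{"line_attractor"}, \code{"rotational"},
#'   \code{"point_attractor"}.
#' @param K number of discrete states (>= 1).
#' @param D latent dimensionality (>= 2).
#' @param N number of neurons (>= D).
#' @param m number of external inputs.
#' @param sampling_rate frames per second (Hz).
#' @param duration session length in seconds.
#' @param target_slow_tau time constant (seconds) of the slow eigenvalue in
#'   the line-attractor regime; \code{Inf} gives a pure integrator.
#' @param rotation_period full-cycle period (seconds) of the rotational pair.
#' @param rotation_modulus modulus of the rotational eigenvalue pair.
#' @param emission_noise_sd observation noise SD (dF/F units).
#' @param process_noise_sd latent process noise SD.
#' @param behavior_thresholds strictly increasing cut levels (in [0,1]) on
#'   the min-max-normalized slow dimension separating sniff /
#'   dominance-mount / attack frames.
#' @param bout_mean_s mean behavior bout length (seconds).
#' @param ibi_mean_s mean inter-bout interval (seconds).
#' @param intro_delay_s seconds of empty-cage baseline before the intruder
#'   is introduced.
#' @param pose_noise_sd multiplier on the pose-feature noise SDs.
#' @param seed integer seed controlling every random element of the session.
#' @return An object of class \code{ground_truth_scenario}.
#' @export
ground_truth_scenario <- function(regime = c("line_attractor", "rotational", "point_attractor"),
                                  K = 3L, D = 8L, N = 40L, m = 2L,
                                  sampling_rate = 15, duration = 600,
                                  target_slow_tau = 150, rotation_period = 10,
                                  rotation_modulus = 0.999,
                                  emission_noise_sd = 0.1,
                                  process_noise_sd = 0.01,
                                  behavior_thresholds = c(0.35, 0.7),
                                  bout_mean_s = 5, ibi_mean_s = 8,
                                  intro_delay_s = 30,
                                  pose_noise_sd = 1,
                                  seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(K >= 1, D >= 2, N >= D, m >= 0,
            sampling_rate > 0, duration > 0,
            bout_mean_s > 0, ibi_mean_s > 0, intro_delay_s >= 0,
            emission_noise_sd >= 0, process_noise_sd >= 0)
  if (target_slow_tau <= 0) stopf("target_slow_tau must be positive (got %g)", target_slow_tau)
  if (rotation_period <= 0) stopf("rotation_period must be positive")
  if (!(rotation_modulus > 0 && rotation_modulus <= 1))
    stopf("rotation_modulus must lie in (0, 1]")
  if (length(behavior_thresholds) != 2 || any(diff(behavior_thresholds) <= 0) ||
      any(behavior_thresholds <= 0) || any(behavior_thresholds >= 1))
    stopf("behavior_thresholds must be two strictly increasing values in (0, 1)")
  structure(list(regime = regime, K = as.integer(K), D = as.integer(D),
                 N = as.integer(N), m = as.integer(m),
                 sampling_rate = sampling_rate, duration = duration,
                 target_slow_tau = target_slow_tau,
                 rotation_period = rotation_period,
                 rotation_modulus = rotation_modulus,
                 emission_noise_sd = emission_noise_sd,
                 process_noise_sd = process_noise_sd,
                 behavior_thresholds = behavior_thresholds,
                 bout_mean_s = bout_mean_s, ibi_mean_s = ibi_mean_s,
                 intro_delay_s = intro_delay_s,
                 pose_noise_sd = pose_noise_sd,
                 seed = as.integer(seed)),
            class = "ground_truth_scenario")
}

#' @export
print.ground_truth_scenario <- function(x, ...) {
  cat(sprintf("Synthetic scenario [%s]: K=%d D=%d N=%d, %g Hz, %g s, seed %d\n",
              x$regime, x$K, x$D, x$N, x$sampling_rate, x$duration, x$seed))
  invisible(x)
}

#' Neural recording container
#'
#' @param activity N x T matrix of continuous activity (e.g. dF/F).
#' @param sampling_rate frames per second.
#' @param animal_id identifier string.
#' @return An object of class \code{recording}.
#' @export
recording <- function(activity, sampling_rate, animal_id = "animal") {
  activity <- as.matrix(activity)
  if (!all(is.finite(activity))) stopf("recording activity must be finite")
  if (ncol(activity) < 1) stopf("recording must contain at least one frame")
  stopifnot(sampling_rate > 0)
  structure(list(activity = activity, sampling_rate = sampling_rate,
                 animal_id = as.character(animal_id)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("Recording '%s': %d neurons x %d frames at %g Hz (%.1f s)\n",
              x$animal_id, nrow(x$activity), ncol(x$activity),
              x$sampling_rate, ncol(x$activity) / x$sampling_rate))
  invisible(x)
}

#' External input series
#'
#' @param values m x T matrix of input features.
#' @param names feature names; default distance and facing angle proxies.
#' @return An object of class \code{input_series}.
#' @export
input_series <- function(values, names = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stopf("input series must be finite")
  if (is.null(names)) {
    names <- if (nrow(values) == 2) c("distance", "facing_angle")
             else paste0("input", seq_len(nrow(values)))
  }
  stopifnot(length(names) == nrow(values))
  rownames(values) <- names
  structure(list(values = values, names = names), class = "input_series")
}

# evaluate an expression under a temporary RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
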