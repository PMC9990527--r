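# Post-fit dynamical characterization: eigenvalue time constants, the
# line-attractor score, behavior-enriched state selection, and the
# integration dimension.

TAU_SENTINEL_FRAMES <- 1e12   # reported for eigenvalues at/above the unit circle

#' Eigenvalue time constants of a dynamics matrix
#'
#' Converts the eigenvalues \eqn{\lambda_a} of a discrete-time dynamics
#' matrix into time constants \eqn{\tau_a = |1 / \log |\lambda_a||}
#' (frames), and into seconds through the sampling rate.  Complex
#' conjugate pairs share a modulus and therefore a time constant.  By
#' convention \eqn{|\lambda| = 0} gives \eqn{\tau = 0}; moduli within
#' 1e-12 of (or above) the unit circle are reported with the sentinel
#' \code{1e12} frames and flagged \code{at_unit_circle}; moduli above one
#' are additionally flagged \code{unstable}.
#'
#' @param A square dynamics matrix (D x D).
#' @param sampling_rate frames per second.
#' @param state optional state label stored on the result.
#' @return data.frame of class \code{time_constant_spectrum}, sorted by
#'   decreasing \code{tau_frames}, with columns \code{eigenvalue}
#'   (complex), \code{modulus}, \code{tau_frames}, \code{tau_seconds},
#'   \code{at_unit_circle}, \code{unstable}.
#' @export
time_constants <- function(A, sampling_rate, state = NA_integer_) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stopf("dynamics matrix must be square")
  stopifnot(sampling_rate > 0)
  lam <- eigen(A, only.values = FALSE)$values
  mod <- Mod(lam)
  at_unit <- mod >= 1 - 1e-12
  unstable <- mod > 1 + 1e-12
  tau <- ifelse(mod == 0, 0,
         ifelse(at_unit, TAU_SENTINEL_FRAMES, abs(1 / log(mod))))
  if (any(unstable)) warnf("%d eigenvalue(s) outside the unit circle (unstable)",
                           sum(unstable))
  out <- data.frame(eigenvalue = lam, modulus = mod, tau_frames = tau,
                    tau_seconds = tau / sampling_rate,
                    at_unit_circle = at_unit, unstable = unstable)
  out <- out[order(-out$tau_frames, -out$modulus), ]
  rownames(out) <- NULL
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "state") <- state
  class(out) <- c("time_constant_spectrum", "data.frame")
  out
}

#' Line-attractor score
#'
#' Base-2 logarithm of the ratio between the largest and second-largest
#' time constants of a dynamics matrix,
#' \eqn{\mathrm{score} = \log_2(t_n / t_{n-1})}.  A system with a single
#' slow integration dimension scores well above zero; a system whose two
#' slowest modes have comparable time constants (including any complex
#' conjugate pair, which shares its modulus) scores near zero.
#'
#' @param spectrum a \code{time_constant_spectrum} from
#'   \code{\link{time_constants}} (or a numeric vector of time constants).
#' @return scalar score in bits (non-negative by the descending sort).
#' @export
line_attractor_score <- function(spectrum) {
  tau <- if (is.data.frame(spectrum)) spectrum$tau_frames else sort(as.numeric(spectrum), decreasing = TRUE)
  if (length(tau) < 2) stopf("need at least two time constants")
  if (tau[2] == 0) {
    warnf("second-largest time constant is zero; score is infinite")
    return(Inf)
  }
  log2(tau[1] / tau[2])
}

#' Select the behavior-enriched discrete state
#'
#' Retrospectively aligns the inferred discrete states with the behavior
#' annotations and returns the state containing the largest fraction of
#' the target behavior's frames.
#'
#' @param states integer state sequence (length T).
#' @param annotations a \code{behavior_annotation} data.frame (or a
#'   character vector of frame labels).
#' @param target_behavior behavior label to align on (e.g. "attack").
#' @return list with \code{state} (the enriched state index),
#'   \code{enrichment} (data.frame: per-state frame count and fraction of
#'   the target behavior), and \code{tied} flag.  Ties are broken toward
#'   the lower state index with a warning.
#' @export
select_analysis_state <- function(states, annotations, target_behavior) {
  labels <- if (is.data.frame(annotations)) annotations$behavior else as.character(annotations)
  if (length(labels) != length(states))
    stopf("annotations cover %d frames but states cover %d", length(labels), length(states))
  sel <- labels == target_behavior
  if (!any(sel)) stopf("no frames annotated as '%s'", target_behavior)
  K <- max(states)
  cnt <- vapply(seq_len(K), function(k) sum(states[sel] == k), 0)
  frac <- cnt / sum(cnt)
  tied <- sum(frac == max(frac)) > 1
  if (tied) warnf("states %s tie for '%s' enrichment; choosing the lowest index",
                  paste(which(frac == max(frac)), collapse = ", "), target_behavior)
  list(state = which.max(frac),
       enrichment = data.frame(state = seq_len(K), n_frames = cnt, fraction = frac),
       tied = tied)
}

#' Identify the integration dimension of a state's dynamics
#'
#' The integration dimension is the latent direction associated with the
#' largest-time-constant eigenvalue of the selected state's dynamics
#' matrix: the normalized real part of the corresponding eigenvector,
#' with its sign fixed so that the mean projection of the latents over
#' the reference frames is positive.
#'
#' @param fit an \code{rslds_fit} (or list with \code{params} and
#'   \code{posterior_latents}).
#' @param state_index discrete state whose dynamics to analyze.
#' @param reference_frames optional logical/integer frame subset used for
#'   the sign convention (e.g. attack frames); defaults to all frames.
#' @return list with \code{direction} (unit vector, length D),
#'   \code{index} (the latent coordinate with the largest absolute
#'   loading), \code{tau_frames}, \code{tau_seconds}, \code{eigenvalue}.
#' @export
identify_integration_dimension <- function(fit, state_index,
                                           reference_frames = NULL) {
  P <- fit$params
  if (state_index < 1 || state_index > P$K)
    stopf("state index %d out of range 1..%d", state_index, P$K)
  eg <- eigen(P$A[[state_index]])
  tau <- ifelse(Mod(eg$values) == 0, 0,
         ifelse(Mod(eg$values) >= 1 - 1e-12, TAU_SENTINEL_FRAMES,
                abs(1 / log(Mod(eg$values)))))
  j <- which.max(tau)
  v <- Re(eg$vectors[, j])
  if (sqrt(sum(v^2)) < 1e-12) stopf("degenerate eigenvector for the slow mode")
  v <- v / sqrt(sum(v^2))
  X <- fit$posterior_latents
  if (!is.null(X)) {
    ref <- reference_frames %||% seq_len(ncol(X))
    if (mean(drop(t(v) %*% X[, ref, drop = FALSE])) < 0) v <- -v
  }
  srate <- fit$sampling_rate %||% 15
  list(direction = v, index = which.max(abs(v)),
       tau_frames = tau[j], tau_seconds = tau[j] / srate,
       eigenvalue = eg$values[j])
}

#' Integration-dimension signal
#'
#' Projects the posterior latent trajectory onto the integration
#' direction, optionally min-max normalized to [0, 1].
#'
#' @param fit an \code{rslds_fit}.
#' @param direction unit vector from
#'   \code{\link{identify_integration_dimension}}.
#' @param normalize logical; min-max normalize (default TRUE).
#' @return numeric vector of length T.
#' @export
integration_signal <- function(fit, direction, normalize = TRUE) {
  s <- drop(t(direction) %*% fit$posterior_latents)
  if (normalize) minmax(s) else s
}
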