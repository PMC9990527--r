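# Cross-validated model selection, forward simulation error, and
# per-dimension explained variance.

# posterior inference on held-out data with frozen parameters: a few
# rounds of the structured E-step only
infer_posterior <- function(Y, U, params, x1_sd = 10, n_rounds = 3L) {
  T_ <- ncol(Y)
  Wt <- matrix(1 / params$K, T_, params$K)
  est <- NULL; st <- NULL
  for (i in seq_len(n_rounds)) {
    est <- latent_estep(Y, U, params, Wt, x1_sd)
    st <- state_estep(U, params, est)
    Wt <- st$Wt
  }
  elbo <- st$e_dyn + st$e_trans + st$entropy_z + est$entropy_x +
    emission_ell(Y, params, est) + x1_prior_ell(params, est, x1_sd)
  list(est = est, Wt = Wt, elbo = elbo)
}

# fraction of observed variance captured by the smoothed reconstruction
reconstruction_ve <- function(Y, params, est) {
  Yhat <- params$C %*% est$mu + params$d_bias
  1 - sum((Y - Yhat)^2) / sum((Y - rowMeans(Y))^2)
}

#' Cross-validated selection of the number of states and dimensions
#'
#' Fits every (K, D) pair on contiguous-block training folds (random
#' frame-level folds would leak the strong temporal autocorrelation) and
#' evaluates the held-out block with frozen parameters: held-out ELBO per
#' frame and the fraction of held-out variance captured by the smoothed
#' reconstruction.  The chosen model is the smallest pair (ordered by
#' D + K, then D) whose mean variance explained reaches
#' \code{ve_criterion} (default 90\%); if none reaches it, the pair with
#' the highest mean variance explained is chosen with a warning.
#'
#' @param rec a \code{\link{recording}} or N x T matrix.
#' @param inputs optional \code{\link{input_series}} or m x T matrix.
#' @param K_grid,D_grid integer vectors of candidate values.
#' @param n_folds number of contiguous folds (default 5).
#' @param seed RNG seed passed to the fits.
#' @param config fit options (see \code{\link{fit_rslds}}).
#' @param ve_criterion variance-explained selection threshold.
#' @return An object of class \code{rslds_cv}: \code{grid} data.frame with
#'   per-pair mean/sd held-out ELBO per frame and variance explained, and
#'   \code{chosen} = c(K, D).
#' @export
cross_validate_rslds <- function(rec, inputs = NULL, K_grid, D_grid,
                                 n_folds = 5L, seed = 1L, config = list(),
                                 ve_criterion = 0.9) {
  Y <- if (inherits(rec, "recording")) rec$activity else as.matrix(rec)
  U <- if (is.null(inputs)) matrix(0, 0, ncol(Y))
       else if (inherits(inputs, "input_series")) inputs$values
       else as.matrix(inputs)
  T_ <- ncol(Y)
  if (length(K_grid) == 0 || length(D_grid) == 0) stopf("model grid is empty")
  fold_id <- cut(seq_len(T_), breaks = n_folds, labels = FALSE)
  if (min(table(fold_id)) < 10 * max(D_grid))
    stopf("folds of %d frames are too short for D up to %d",
          min(table(fold_id)), max(D_grid))
  rows <- list()
  for (D in sort(D_grid)) for (K in sort(K_grid)) {
    ve <- numeric(n_folds); he <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      test <- fold_id == f
      seg <- split(which(!test), cumsum(c(1, diff(which(!test))) > 1))
      Ys <- lapply(seg, function(ix) Y[, ix, drop = FALSE])
      Us <- lapply(seg, function(ix) U[, ix, drop = FALSE])
      cfg <- modifyList(default_fit_config(), config)
      cfg$seed <- seed + f
      fit <- fit_rslds_segments(Ys, Us, K, D, cfg)
      Yte <- Y[, test, drop = FALSE]
      if (length(fit$dropped_neurons) > 0)
        Yte <- Yte[-fit$dropped_neurons, , drop = FALSE]
      post <- infer_posterior(Yte, U[, test, drop = FALSE], fit$params)
      ve[f] <- reconstruction_ve(Yte, fit$params, post$est)
      he[f] <- post$elbo / ncol(Yte)
    }
    rows[[length(rows) + 1]] <- data.frame(
      K = K, D = D, heldout_elbo_mean = mean(he), heldout_elbo_sd = sd(he),
      ve_mean = mean(ve), ve_sd = sd(ve))
  }
  grid <- do.call(rbind, rows)
  ok <- grid$ve_mean >= ve_criterion
  if (any(ok)) {
    cand <- grid[ok, ]
    cand <- cand[order(cand$D + cand$K, cand$D, cand$K), ]
    chosen <- c(K = cand$K[1], D = cand$D[1])
  } else {
    warnf("no grid point reached %.0f%% variance explained; choosing the best available",
          100 * ve_criterion)
    best <- which.max(grid$ve_mean)
    chosen <- c(K = grid$K[best], D = grid$D[best])
  }
  structure(list(grid = grid, chosen = chosen, n_folds = n_folds,
                 ve_criterion = ve_criterion),
            class = "rslds_cv")
}

#' @export
print.rslds_cv <- function(x, ...) {
  cat(sprintf("rSLDS cross-validation (%d folds): chosen K = %d, D = %d\n",
              x$n_folds, x$chosen["K"], x$chosen["D"]))
  print(x$grid, row.names = FALSE)
  invisible(x)
}

#' Forward simulation error of a fitted model
#'
#' From the posterior latent at each frame t, the latent trajectory is
#' rolled forward \code{horizon_frames} frames under the noiseless mean
#' dynamics of the inferred discrete-state sequence, and compared with the
#' posterior latent at t + horizon by mean squared error across latent
#' dimensions.  The per-frame MSE is min-max normalized across the
#' session; model performance is 1 minus its mean.
#'
#' @param fit an \code{rslds_fit}, or a list with \code{params},
#'   \code{posterior_latents}, \code{most_likely_states}, \code{inputs}.
#' @param horizon_frames prediction horizon in frames (>= 1); default
#'   1 second at the fit's sampling rate.
#' @return An object of class \code{fse_report}: per-frame \code{mse},
#'   \code{normalized} error in [0,1], \code{performance} = 1 - mean
#'   normalized error, and \code{horizon_frames}.
#' @export
forward_simulation_error <- function(fit, horizon_frames = NULL) {
  X <- fit$posterior_latents
  z <- fit$most_likely_states
  U <- fit$inputs %||% matrix(0, fit$params$m, ncol(X))
  T_ <- ncol(X); D <- nrow(X)
  h <- horizon_frames %||% max(1L, round(fit$sampling_rate %||% 15))
  if (h < 1) stopf("horizon must be at least one frame")
  if (h >= T_) stopf("horizon (%d frames) exceeds the session length (%d)", h, T_)
  P <- fit$params
  Xs <- X[, 1:(T_ - h), drop = FALSE]
  for (s in seq_len(h)) {
    idx <- (1 + s - 1):(T_ - h + s - 1)      # source frames of this step
    Xn <- matrix(0, D, length(idx))
    zi <- z[idx + 1]                          # state governing the step into t+1
    for (k in seq_len(P$K)) {
      sel <- zi == k
      if (!any(sel)) next
      Xn[, sel] <- P$A[[k]] %*% Xs[, sel, drop = FALSE] +
        P$V[[k]] %*% U[, idx[sel], drop = FALSE] + P$b[[k]]
    }
    Xs <- Xn
  }
  mse <- colMeans((Xs - X[, (1 + h):T_, drop = FALSE])^2)
  # errors at float-noise level relative to the latent scale count as zero,
  # so an exact model scores performance 1 instead of normalizing dust
  scale_ref <- mean(X^2) + 1e-300
  mse[mse < 1e-15 * scale_ref] <- 0
  normalized <- minmax(mse)
  structure(list(mse = mse, normalized = normalized,
                 performance = 1 - mean(normalized),
                 horizon_frames = h),
            class = "fse_report")
}

#' @export
print.fse_report <- function(x, ...) {
  cat(sprintf("Forward simulation error over %d-frame horizon: performance (1 - FSE) = %.3f\n",
              x$horizon_frames, x$performance))
  invisible(x)
}

#' Explained variance of the activity by latent dimension
#'
#' Fraction of total activity variance attributed to each latent
#' dimension through the emission map.  With
#' \code{orthogonalize = TRUE} (default) dimensions are attributed
#' sequentially (QR of the centered latent trajectory in the given order),
#' so the fractions sum to at most one; otherwise each dimension's
#' marginal reconstruction variance is reported.
#'
#' @param fit an \code{rslds_fit} (or list with \code{params} and
#'   \code{posterior_latents}).
#' @param Y optional activity matrix; defaults to reconstructing the
#'   denominator from the fitted recording if present, otherwise the
#'   latent reconstruction plus observation noise.
#' @param order optional dimension ordering for sequential attribution.
#' @param orthogonalize logical; see above.
#' @return numeric vector of per-dimension fractions in [0, 1].
#' @export
explained_variance_by_dimension <- function(fit, Y = NULL, order = NULL,
                                            orthogonalize = TRUE) {
  P <- fit$params
  X <- fit$posterior_latents
  D <- nrow(X); T_ <- ncol(X)
  Xc <- X - rowMeans(X)
  if (is.null(Y)) {
    sst <- sum((P$C %*% Xc)^2) + T_ * sum(diag(P$obs_noise))
  } else {
    Y <- as.matrix(Y)
    sst <- sum((Y - rowMeans(Y))^2)
  }
  ord <- order %||% seq_len(D)
  if (orthogonalize) {
    qr_ <- qr(t(Xc[ord, , drop = FALSE]))
    Rm <- qr.R(qr_)                          # D x D, rows = orthogonal components
    contrib <- rowSums((Rm %*% t(P$C[, ord, drop = FALSE]))^2)
    ve <- numeric(D); ve[ord] <- contrib / sst
  } else {
    ve <- vapply(seq_len(D), function(j)
      sum((P$C[, j, drop = FALSE] %*% Xc[j, , drop = FALSE])^2) / sst, 0)
  }
  pmin(pmax(ve, 0), 1)
}
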