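#' @name behavior_vocabulary
#' @title Default behavior vocabulary
#' @description Seven annotated social actions plus \code{"background"}
#'   (non-social frames), crossed with intruder sex in the annotation table.
#'   This is a documented stand-in for a full hand-annotation scheme;
#'   investigative actions are sniff / interact / dangle and consummatory
#'   actions are dominance-mount / attack / USV+ mount / intromission.
#' @export
behavior_vocabulary <- c("sniff", "dominance_mount", "attack", "mount_usv",
                         "intromission", "interact", "dangle")

#' @rdname behavior_vocabulary
#' @export
investigative_actions <- c("sniff", "interact", "dangle")

#' @rdname behavior_vocabulary
#' @export
consummatory_actions <- c("dominance_mount", "attack", "mount_usv", "intromission")

# deterministic random orthogonal basis
random_orthogonal <- function(D) {
  M <- matrix(rnorm(D * D), D, D)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  Q %*% diag(sign(diag(qr.R(qr_))), D)
}

#' Construct ground-truth rSLDS parameters for a scenario
#'
#' Builds the dynamics-matrix library with the prescribed eigenstructure:
#' in the line-attractor regime exactly one state carries one real
#' eigenvalue \eqn{\lambda = e^{-1/(\tau f)}} (the integration dimension)
#' while every other eigenvalue of every state has a time constant below
#' 2 s; the rotational regime carries a complex-conjugate pair at the
#' requested modulus and angle \eqn{2\pi/(\mathrm{period} \cdot f)}; the
#' point-attractor regime is uniformly fast.  Transition weights gate the
#' behavior-enriched state (index K) on the slow dimension and on the
#' external drive, the emission matrix is full column rank, and the
#' observation noise is diagonal.
#'
#' @param scenario a \code{\link{ground_truth_scenario}}.
#' @return An \code{\link{rslds_params}} object with a \code{"ground_truth"}
#'   attribute recording the slow axis (or rotational plane) and the
#'   behavior-gating state.
#' @export
make_ground_truth_params <- function(scenario) {
  stopifnot(inherits(scenario, "ground_truth_scenario"))
  f <- scenario$sampling_rate
  D <- scenario$D; K <- scenario$K; N <- scenario$N; m <- scenario$m
  if (scenario$regime == "rotational" && D < 2)
    stopf("rotational regime needs D >= 2 to host a complex-conjugate pair (got D = %d)", D)

  with_seed(scenario$seed + 1000L, {
    O <- random_orthogonal(D)
    # fast eigenvalues: tau < 2 s  <=>  lambda < exp(-1/(2 f))
    lam_fast_max <- min(0.9, exp(-1 / (1.5 * f)))
    fast <- function(n) runif(n, 0.3, lam_fast_max)

    A <- vector("list", K); b <- vector("list", K); V <- vector("list", K)
    gt <- list(regime = scenario$regime, gating_state = K, basis = O)

    if (scenario$regime == "line_attractor") {
      lam_slow <- if (is.finite(scenario$target_slow_tau))
        exp(-1 / (scenario$target_slow_tau * f)) else 1.0
      for (k in seq_len(K)) {
        lams <- fast(D)
        # the integration axis decays just under the 2 s cap outside the
        # gating state, so excursions do not erase the accumulated signal
        lams[1] <- if (k == K) lam_slow else exp(-1 / (1.6 * f))
        A[[k]] <- O %*% diag(lams, D) %*% t(O)
        bk <- numeric(D)
        if (k == K) {
          bk <- (0.05 / f) * O[, 1]   # integrator drift: 0.05 a.u. per second
        } else if (k == 2 && K >= 3) {
          bk <- 0.05 * O %*% c(0, rnorm(D - 1, 0, 1))
        }
        b[[k]] <- as.numeric(bk)
        Vk <- matrix(0, D, max(m, 1))[, seq_len(m), drop = FALSE]
        if (m >= 1 && k >= 2) {
          # drive kicks the fast dimensions and feeds the integrator weakly
          Vk[, 1] <- O %*% c(0.001, runif(D - 1, 0.1, 0.4) * sample(c(-1, 1), D - 1, TRUE))
        }
        V[[k]] <- Vk
      }
      gt$slow_axis <- O[, 1]
      gt$slow_lambda <- lam_slow
      # gating: quiescence without drive; once the drive is on, the gating
      # state dominates and the integrator value makes it stickier, with
      # brief excursions into the intermediate state
      R_tr <- matrix(0, K, D)
      W_tr <- matrix(0, K, max(m, 1))[, seq_len(m), drop = FALSE]
      r_tr <- numeric(K)
      if (K >= 2) {
        R_tr[K, ] <- 1.5 * O[, 1]
        if (K >= 3) R_tr[2, ] <- -0.5 * O[, 1]
        if (m >= 1) {
          W_tr[1, 1] <- -10
          W_tr[K, 1] <- 4
          if (K >= 3) {
            W_tr[2, 1] <- 2
            W_tr[2, min(m, 2)] <- 3
          }
        }
        r_tr <- c(2, rep(-1.5, K - 2), -1)
      }
    } else if (scenario$regime == "rotational") {
      omega <- 2 * pi / (scenario$rotation_period * f)
      lam_rot <- scenario$rotation_modulus
      rot <- lam_rot * matrix(c(cos(omega), sin(omega), -sin(omega), cos(omega)), 2, 2)
      for (k in seq_len(K)) {
        Dk <- diag(fast(D), D)
        if (k == K) Dk[1:2, 1:2] <- rot
        A[[k]] <- O %*% Dk %*% t(O)
        # no in-plane bias or drive: the noise-sustained orbit stays
        # centered at the origin so the latent phase cycles cleanly
        b[[k]] <- numeric(D)
        Vk <- matrix(0, D, max(m, 1))[, seq_len(m), drop = FALSE]
        if (m >= 1 && k == K && D > 2)
          Vk[, 1] <- O %*% c(0, 0, runif(D - 2, 0.05, 0.2))
        V[[k]] <- Vk
      }
      gt$rotation_plane <- O[, 1:2]
      gt$rotation_omega <- omega
      gt$rotation_lambda <- lam_rot
      R_tr <- matrix(0, K, D)
      W_tr <- matrix(0, K, max(m, 1))[, seq_len(m), drop = FALSE]
      r_tr <- numeric(K)
      if (K >= 2) {
        # the orbit needs sustained occupancy of the rotational state:
        # its radius rebuilds only on the 1/(1 - |lambda|^2) timescale
        # after a visit to a fast-decaying state
        if (m >= 1) { W_tr[1, 1] <- -10; W_tr[K, 1] <- 4
                      if (K >= 3) W_tr[2, 1] <- 1 }
        r_tr <- c(1.5, rep(-1.5, K - 2), -1)
      }
    } else { # point_attractor
      for (k in seq_len(K)) {
        A[[k]] <- O %*% diag(fast(D), D) %*% t(O)
        b[[k]] <- as.numeric(if (k == K) 0.3 * O[, 1] else numeric(D))
        Vk <- matrix(0, D, max(m, 1))[, seq_len(m), drop = FALSE]
        if (m >= 1 && k >= 2) Vk[, 1] <- runif(D, 0.05, 0.3)
        V[[k]] <- Vk
      }
      R_tr <- matrix(0, K, D)
      W_tr <- matrix(0, K, max(m, 1))[, seq_len(m), drop = FALSE]
      r_tr <- numeric(K)
      if (K >= 2 && m >= 1) { W_tr[1, 1] <- -5; W_tr[K, 1] <- 2.5 }
      if (K >= 2) r_tr <- c(1.5, rep(0.3, K - 2), -0.5)
    }

    C <- matrix(rnorm(N * D, 0, 0.3), N, D)
    d_bias <- runif(N, 0.05, 0.2)
    Q <- diag(scenario$process_noise_sd^2, D)
    if (scenario$regime == "rotational") {
      # the noise-sustained orbit radius is sigma/sqrt(1 - |lambda|^2);
      # excite the rotational plane more strongly so the orbit rides
      # well above the emission noise floor (behavior-scale oscillation)
      Q <- O %*% diag(c(rep((12 * scenario$process_noise_sd)^2, 2),
                        rep(scenario$process_noise_sd^2, D - 2)), D) %*% t(O)
    }
    params <- rslds_params(A = A, V = V, b = b, C = C, d_bias = d_bias,
                           obs_noise = diag(scenario$emission_noise_sd^2, N),
                           process_noise = symm(Q),
                           R_tr = R_tr, W_tr = W_tr, r_tr = r_tr)
    attr(params, "ground_truth") <- gt
    params
  })
}

#' Generate the external drive inputs for a scenario
#'
#' Produces an \code{\link{input_series}} emulating chemosensory drive
#' proxies (inverted distance and facing alignment, both normalized): zero
#' before intruder introduction, a brief novelty overshoot at entry, then
#' a mean-reverting fluctuation while the intruder is present.
#'
#' @param scenario a \code{\link{ground_truth_scenario}}.
#' @param seed RNG seed (defaults to the scenario seed).
#' @return An \code{\link{input_series}} with \code{m} rows.
#' @export
generate_scenario_inputs <- function(scenario, seed = scenario$seed) {
  T_ <- round(scenario$duration * scenario$sampling_rate)
  f <- scenario$sampling_rate
  m <- scenario$m
  if (m == 0) return(input_series(matrix(0, 0, T_), character(0)))
  with_seed(seed + 2000L, {
    intro <- round(scenario$intro_delay_s * f)
    U <- matrix(0, m, T_)
    ou <- function(n, mu, sdv, tau_s) {
      a <- exp(-1 / (tau_s * f))
      x <- numeric(n); x[1] <- mu
      e <- rnorm(n, 0, sdv * sqrt(1 - a^2))
      for (t in 2:n) x[t] <- mu + a * (x[t - 1] - mu) + e[t]
      x
    }
    if (intro < T_) {
      n_post <- T_ - intro
      drive <- pmax(0, ou(n_post, 0.8, 0.25, 5))
      kick <- min(n_post, round(2 * f))
      drive[seq_len(kick)] <- 1.5
      U[1, (intro + 1):T_] <- drive
      if (m >= 2) U[2, (intro + 1):T_] <- pmin(1, pmax(0, ou(n_post, 0.5, 0.2, 3)))
    }
    input_series(U)
  })
}

#' Simulate an rSLDS trajectory
#'
#' Samples discrete states from the recurrent softmax transition rule,
#' propagates the continuous latents through the state-indexed linear
#' dynamics with Gaussian process noise, and emits observations through
#' the linear-Gaussian observation model.
#'
#' @param params an \code{\link{rslds_params}} object.
#' @param inputs an \code{\link{input_series}}, an m x T matrix, or NULL
#'   (inputs identically zero).
#' @param n_frames number of frames to simulate.
#' @param seed RNG seed.
#' @param sampling_rate stored on the returned recording (Hz).
#' @param animal_id stored on the returned recording.
#' @param x0 initial latent (default zero).
#' @return list with elements \code{states} (integer vector),
#'   \code{latents} (D x T), \code{recording} (a \code{\link{recording}}).
#' @export
simulate_session <- function(params, inputs = NULL, n_frames, seed = 1L,
                             sampling_rate = 15, animal_id = "synthetic",
                             x0 = NULL) {
  stopifnot(inherits(params, "rslds_params"), n_frames >= 1)
  U <- if (is.null(inputs)) matrix(0, params$m, n_frames)
       else if (inherits(inputs, "input_series")) inputs$values
       else as.matrix(inputs)
  if (nrow(U) != params$m) stopf("inputs must have %d rows", params$m)
  if (ncol(U) < n_frames) stopf("inputs provide %d frames but %d requested", ncol(U), n_frames)
  D <- params$D
  with_seed(seed, {
    Lq <- if (max(abs(params$process_noise)) == 0) matrix(0, D, D)
          else t(chol(symm(params$process_noise) + diag(1e-14, D)))
    X <- matrix(0, D, n_frames)
    z <- integer(n_frames)
    x <- if (is.null(x0)) numeric(D) else as.numeric(x0)
    X[, 1] <- x
    z[1] <- sample.int(params$K, 1L)
    guard <- 1e6
    for (t in 2:n_frames) {
      p <- transition_probabilities(params, X[, t - 1], U[, t - 1], z[t - 1])
      z[t] <- sample.int(params$K, 1L, prob = p)
      x <- latent_mean_step(params, z[t], X[, t - 1], U[, t - 1]) +
        drop(Lq %*% rnorm(D))
      if (any(abs(x) > guard)) {
        rho <- max(Mod(eigen(params$A[[z[t]]], only.values = TRUE)$values))
        stopf("latent trajectory exploded at frame %d in state %d (spectral radius %.4f)",
              t, z[t], rho)
      }
      X[, t] <- x
    }
    noise <- matrix(rnorm(params$N * n_frames), params$N, n_frames)
    Lr <- if (max(abs(params$obs_noise)) == 0) matrix(0, params$N, params$N)
          else t(chol(symm(params$obs_noise) + diag(1e-14, params$N)))
    Y <- params$C %*% X + params$d_bias + Lr %*% noise
    list(states = z, latents = X,
         recording = recording(Y, sampling_rate, animal_id))
  })
}

# gamma-bout alternating renewal process over a frame range; shape 2
bout_windows <- function(n_frames, start_frame, mean_bout_frames, mean_ibi_frames) {
  windows <- matrix(numeric(0), ncol = 2)
  t <- start_frame
  while (t < n_frames) {
    ibi <- max(1, round(rgamma(1, shape = 2, scale = mean_ibi_frames / 2)))
    bl <- max(1, round(rgamma(1, shape = 2, scale = mean_bout_frames / 2)))
    s <- t + ibi
    e <- min(n_frames, s + bl)
    if (s >= n_frames) break
    windows <- rbind(windows, c(s, e))
    t <- e
  }
  windows
}

#' Synthesize frame-wise behavior annotations from latents
#'
#' Behaviors are drawn from a gamma bout process restricted to the period
#' after intruder introduction.  In the line-attractor regime the label of
#' each in-bout frame is gated by the min-max-normalized slow-dimension
#' value crossing the scenario thresholds (sniff below t1, dominance-mount
#' between t1 and t2, attack at or above t2), so every attack frame sits at
#' a high integrator value by construction.  In the rotational regime
#' in-bout labels cycle sniff, USV+ mount, intromission with the
#' accumulated latent phase of the rotational plane.  Frames right after
#' introduction are labeled \code{"interact"} (intruder entry); everything
#' else is \code{"background"}.
#'
#' @param latents D x T latent matrix.
#' @param states integer state sequence (unused by the default gating but
#'   kept for alternative couplings).
#' @param scenario a \code{\link{ground_truth_scenario}}.
#' @param params optional ground-truth params carrying the slow axis /
#'   rotation plane; defaults to re-deriving them from the scenario.
#' @param seed RNG seed for the bout process.
#' @return data.frame of class \code{behavior_annotation} with columns
#'   \code{frame} (0-based), \code{behavior}, \code{intruder_sex}, and a
#'   \code{sampling_rate} attribute.
#' @export
synthesize_behavior_annotations <- function(latents, states, scenario,
                                            params = NULL,
                                            seed = scenario$seed) {
  latents <- as.matrix(latents)
  if (!all(is.finite(latents))) stopf("latents must be finite")
  T_ <- ncol(latents)
  f <- scenario$sampling_rate
  gt <- if (!is.null(params)) attr(params, "ground_truth") else
    attr(make_ground_truth_params(scenario), "ground_truth")
  sex <- if (scenario$regime == "rotational") "female" else "male"
  labels <- rep("background", T_)
  intro <- min(T_, round(scenario$intro_delay_s * f))

  with_seed(seed + 3000L, {
    wins <- bout_windows(T_, intro + round(2 * f),
                         scenario$bout_mean_s * f, scenario$ibi_mean_s * f)
    if (scenario$regime == "line_attractor" || scenario$regime == "point_attractor") {
      s <- drop(t(gt$slow_axis %||% rep(1 / sqrt(nrow(latents)), nrow(latents))) %*% latents)
      sn <- minmax(s)
      th <- scenario$behavior_thresholds
      if (nrow(wins) > 0) for (i in seq_len(nrow(wins))) {
        idx <- (wins[i, 1] + 1):wins[i, 2]
        lab <- ifelse(sn[idx] < th[1], "sniff",
               ifelse(sn[idx] < th[2], "dominance_mount", "attack"))
        if (scenario$regime == "point_attractor") lab <- rep("sniff", length(idx))
        labels[idx] <- lab
      }
    } else {
      ph <- latent_phase(latents, gt$rotation_plane)
      Pc <- t(gt$rotation_plane) %*% latents
      Pc <- Pc - rowMeans(Pc)
      radius <- sqrt(colSums(Pc^2))
      r_floor <- 0.4 * quantile(radius, 0.9)
      # episodes begin where the neural cycle begins: snap each bout
      # window to the next upward phase-zero crossing with the orbit
      # engaged (radius above floor), so behavior is phase-locked and
      # neurons activate in a consistent order across episodes
      crossings <- which(diff(floor(ph / (2 * pi))) >= 1) + 1L
      crossings <- crossings[radius[crossings] >= r_floor]
      # each episode runs from a phase-zero crossing through one full
      # cycle: sniff 0-60, USV+ mount 60-120, intromission 120-180, then
      # post-copulatory investigation back to 360 degrees.  Episodes are
      # phase-complete and therefore comparable across the session, and
      # phase-tuned neurons tile the whole episode.
      max_len <- round(3 * scenario$rotation_period * f)
      if (nrow(wins) > 0) for (i in seq_len(nrow(wins))) {
        cr <- crossings[crossings >= wins[i, 1] + 1]
        if (length(cr) == 0) next
        s0 <- cr[1]
        if (i < nrow(wins) && s0 >= wins[i + 1, 1]) next
        span <- s0:min(T_, s0 + max_len)
        theta_all <- (ph[span] - ph[s0]) * 180 / pi
        endi <- which(theta_all >= 360)[1]
        if (is.na(endi)) next
        idx <- span[1:endi]
        # label on the running phase maximum: monotone by construction,
        # so each behavior forms one clean run per cycle
        theta <- cummax(theta_all[1:endi])
        lab <- rep("interact", length(idx))
        lab[theta >= 0 & theta < 60] <- "sniff"
        lab[theta >= 60 & theta < 120] <- "mount_usv"
        lab[theta >= 120 & theta <= 180] <- "intromission"
        labels[idx] <- lab
      }
    }
    if (intro < T_) {
      entry <- (intro + 1):min(T_, intro + round(2 * f))
      labels[entry] <- "interact"
    }
  })
  ann <- data.frame(frame = 0:(T_ - 1), behavior = labels,
                    intruder_sex = sex, stringsAsFactors = FALSE)
  attr(ann, "sampling_rate") <- f
  class(ann) <- c("behavior_annotation", "data.frame")
  ann
}

# unwrapped phase (radians) of latents projected on a 2-column plane
latent_phase <- function(latents, plane) {
  P <- t(plane) %*% latents
  P <- P - rowMeans(P)
  a <- atan2(P[2, ], P[1, ])
  d <- diff(a)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(a[1], d))
}

pose_profiles <- list(
  distance     = c(background = 25, interact = 10, sniff = 8, dominance_mount = 4,
                   attack = 3, mount_usv = 4, intromission = 3.5, dangle = 6),
  facing_angle = c(background = 1.6, interact = 0.6, sniff = 0.4, dominance_mount = 0.35,
                   attack = 0.3, mount_usv = 0.3, intromission = 0.3, dangle = 0.5),
  speed        = c(background = 5, interact = 12, sniff = 6, dominance_mount = 8,
                   attack = 15, mount_usv = 4, intromission = 2, dangle = 6),
  ellipse_area = c(background = 18, interact = 20, sniff = 20, dominance_mount = 24,
                   attack = 24, mount_usv = 26, intromission = 26, dangle = 20))

pose_noise_scales <- c(distance = 2, facing_angle = 0.25, speed = 2, ellipse_area = 1.5)

#' Synthesize pose features from behavior annotations
#'
#' Generates distance between animals (cm), resident facing angle (rad),
#' resident speed (cm/s) and fitted-ellipse area (cm^2) whose means depend
#' on the current behavior label (e.g. small inter-animal distance during
#' attack), plus AR(1) noise; acceleration and a signed range velocity are
#' derived by finite differences.  With \code{pose_noise_sd = 0} in the
#' scenario the features are deterministic functions of the label sequence.
#'
#' @param annotations a \code{behavior_annotation} data.frame.
#' @param scenario a \code{\link{ground_truth_scenario}}.
#' @param seed RNG seed.
#' @return data.frame of class \code{pose_features} with one row per frame.
#' @export
synthesize_pose_features <- function(annotations, scenario, seed = scenario$seed) {
  stopifnot(is.data.frame(annotations), "behavior" %in% names(annotations))
  lab <- annotations$behavior
  T_ <- length(lab)
  f <- scenario$sampling_rate
  with_seed(seed + 4000L, {
    a <- exp(-1 / (0.5 * f))  # 0.5 s noise correlation
    feats <- lapply(names(pose_profiles), function(nm) {
      base <- unname(pose_profiles[[nm]][lab])
      base[is.na(base)] <- pose_profiles[[nm]]["background"]
      sdv <- pose_noise_scales[[nm]] * scenario$pose_noise_sd
      e <- numeric(T_)
      if (sdv > 0) {
        w <- rnorm(T_, 0, sdv * sqrt(1 - a^2))
        e[1] <- rnorm(1, 0, sdv)
        for (t in 2:T_) e[t] <- a * e[t - 1] + w[t]
      }
      base + e
    })
    names(feats) <- names(pose_profiles)
    feats$distance <- pmax(feats$distance, 0.5)
    feats$facing_angle <- pmin(pmax(feats$facing_angle, 0), pi)
    feats$speed <- pmax(feats$speed, 0)
    feats$ellipse_area <- pmax(feats$ellipse_area, 1)
    vel <- c(0, diff(feats$distance)) * f       # range rate, cm/s
    acc <- c(0, diff(feats$speed)) * f          # cm/s^2
    out <- data.frame(frame = 0:(T_ - 1), distance = feats$distance,
                      facing_angle = feats$facing_angle, speed = feats$speed,
                      acceleration = acc, velocity = vel,
                      ellipse_area = feats$ellipse_area)
    attr(out, "sampling_rate") <- f
    class(out) <- c("pose_features", "data.frame")
    out
  })
}

#' Generate a complete synthetic session
#'
#' One-call generator: ground-truth parameters, inputs, latent/state/neural
#' simulation, behavior annotations, and pose features, all driven by the
#' scenario seed.
#'
#' @param scenario a \code{\link{ground_truth_scenario}}.
#' @param animal_id identifier stored on the recording.
#' @return An object of class \code{synthetic_session}: a list with
#'   \code{params}, \code{states}, \code{latents}, \code{recording},
#'   \code{inputs}, \code{annotations}, \code{pose}, \code{scenario}.
#' @export
synthetic_session <- function(scenario, animal_id = paste0("sim", scenario$seed)) {
  params <- make_ground_truth_params(scenario)
  inputs <- generate_scenario_inputs(scenario)
  T_ <- round(scenario$duration * scenario$sampling_rate)
  sim <- simulate_session(params, inputs, T_, seed = scenario$seed,
                          sampling_rate = scenario$sampling_rate,
                          animal_id = animal_id)
  ann <- synthesize_behavior_annotations(sim$latents, sim$states, scenario,
                                         params = params)
  pose <- synthesize_pose_features(ann, scenario)
  structure(list(params = params, states = sim$states, latents = sim$latents,
                 recording = sim$recording, inputs = inputs,
                 annotations = ann, pose = pose, scenario = scenario),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  tab <- table(x$annotations$behavior)
  cat(sprintf("Synthetic %s session: %d neurons x %d frames (%g Hz)\n",
              x$scenario$regime, nrow(x$recording$activity),
              ncol(x$recording$activity), x$scenario$sampling_rate))
  cat("behavior frames:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
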