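# Latent-space geometry: PCA re-parameterization of the fitted system,
# 2D flow fields, slow points, dynamic velocity, and the 3D landscape.

#' PCA re-parameterization of a fitted rSLDS
#'
#' Because the latents are identified only up to invertible linear maps,
#' the fitted system can be re-expressed in principal-component
#' coordinates of the reconstructed activity: (1) center the posterior
#' latents and compute a whitening map \eqn{W} so \eqn{Wx} has identity
#' covariance; (2) update the emission matrix \eqn{C' = C W^{-1}};
#' (3) take the SVD \eqn{C' = U S V^\top} and set \eqn{P = S V^\top};
#' (4) transform \eqn{x'' = P W (x - \bar x)}, giving the observationally
#' equivalent emission \eqn{y \approx U x'' + (d + C \bar x)} whose
#' components are ordered by explained variance (the printed recipe
#' applies \eqn{P^{-1}}, which would order components in reverse; the
#' variance-maximizing direction of the map is used here).  Dynamics and
#' transition parameters are conjugated by the same map.
#'
#' @param fit an \code{rslds_fit} (or list with \code{params} and
#'   \code{posterior_latents}).
#' @return An object of class \code{pca_transform}: \code{whitening},
#'   \code{U}, \code{singular_values}, \code{V}, \code{P}, \code{map}
#'   (\eqn{M = P W}), \code{map_inv}, \code{center}, \code{latents_pc}
#'   (D x T transformed latents), \code{explained} (fractions of
#'   latent-driven variance), and \code{params_pc} (the transformed
#'   \code{\link{rslds_params}}).
#' @export
pca_transform_latents <- function(fit) {
  P0 <- fit$params
  X <- fit$posterior_latents
  if (is.null(X)) stopf("fit carries no posterior latents")
  D <- nrow(X); T_ <- ncol(X)
  ctr <- rowMeans(X)
  Xc <- X - ctr
  Sx <- tcrossprod(Xc) / T_
  ridged <- min(eigen(symm(Sx), only.values = TRUE)$values) < 1e-10 * max(diag(Sx))
  if (ridged) warnf("latent covariance is rank deficient; adding a ridge before whitening")
  Wm <- inv_sqrtm(Sx, ridge = if (ridged) 1e-8 * max(diag(Sx)) else 0)
  Winv <- solve(Wm)
  Cp <- P0$C %*% Winv
  sv <- svd(Cp)
  Pm <- diag(sv$d, D) %*% t(sv$v)
  M <- Pm %*% Wm
  Minv <- solve(M)
  Xpc <- M %*% Xc

  A2 <- lapply(P0$A, function(A) M %*% A %*% Minv)
  V2 <- lapply(P0$V, function(V) M %*% V)
  b2 <- lapply(seq_len(P0$K), function(k)
    as.numeric(M %*% (P0$A[[k]] %*% ctr + P0$b[[k]] - ctr)))
  params_pc <- rslds_params(
    A = A2, V = V2, b = b2, C = sv$u,
    d_bias = as.numeric(P0$d_bias + P0$C %*% ctr),
    obs_noise = P0$obs_noise,
    process_noise = symm(M %*% P0$process_noise %*% t(M)),
    R_tr = P0$R_tr %*% Minv, W_tr = P0$W_tr,
    r_tr = as.numeric(P0$r_tr + P0$R_tr %*% ctr))

  structure(list(whitening = Wm, U = sv$u, singular_values = sv$d, V = sv$v,
                 P = Pm, map = M, map_inv = Minv, center = ctr,
                 latents_pc = Xpc,
                 explained = sv$d^2 / sum(sv$d^2),
                 params_pc = params_pc),
            class = "pca_transform")
}

#' @export
print.pca_transform <- function(x, ...) {
  cat(sprintf("PCA re-parameterization: first two components explain %.1f%% of latent-driven variance\n",
              100 * sum(x$explained[1:2])))
  invisible(x)
}

#' 2D flow field of the fitted dynamics in PC space
#'
#' Evaluates one step of the mean dynamics on a regular grid in the
#' (PC1, PC2) plane.  Each grid point is lifted to the full latent space
#' through the inverse PC map with the non-displayed components at their
#' session means (zero in centered PC coordinates), the governing state is
#' taken as the argmax of the transition logits at the lifted point
#' (\code{state_mode = "transition"}) or held fixed
#' (\code{state_mode = "fixed"}), and the one-step displacement is
#' projected back onto the PC plane.
#'
#' @param fit an \code{rslds_fit}.
#' @param pca a \code{\link{pca_transform_latents}} result for this fit.
#' @param n_grid grid resolution per axis (default 50).
#' @param margin fractional margin around the observed PC trajectory.
#' @param input_policy "zero" (default) or "mean" session input.
#' @param state_mode "transition" (default) or "fixed".
#' @param fixed_state state index used when \code{state_mode = "fixed"}.
#' @return An object of class \code{flow_field}: \code{pc1}, \code{pc2}
#'   axis vectors, matrices \code{vx}, \code{vy}, \code{norm},
#'   \code{state}, and the generating options.
#' @export
flow_field <- function(fit, pca, n_grid = 50, margin = 0.1,
                       input_policy = c("zero", "mean"),
                       state_mode = c("transition", "fixed"),
                       fixed_state = 1L) {
  input_policy <- match.arg(input_policy)
  state_mode <- match.arg(state_mode)
  P <- fit$params
  Xpc <- pca$latents_pc
  u0 <- if (input_policy == "mean" && P$m > 0 && !is.null(fit$inputs))
    rowMeans(fit$inputs) else numeric(P$m)
  r1 <- range(Xpc[1, ]); r2 <- range(Xpc[2, ])
  pad1 <- margin * diff(r1); pad2 <- margin * diff(r2)
  pc1 <- seq(r1[1] - pad1, r1[2] + pad1, length.out = n_grid)
  pc2 <- seq(r2[1] - pad2, r2[2] + pad2, length.out = n_grid)
  D <- P$D
  vx <- vy <- nrm <- st <- matrix(0, n_grid, n_grid)
  for (i in seq_len(n_grid)) for (j in seq_len(n_grid)) {
    xpc <- numeric(D); xpc[1] <- pc1[i]; xpc[2] <- pc2[j]
    x <- drop(pca$map_inv %*% xpc) + pca$center
    k <- if (state_mode == "fixed") as.integer(fixed_state)
         else which.max(drop(P$R_tr %*% x) + drop(P$W_tr %*% u0) + P$r_tr)
    xn <- latent_mean_step(P, k, x, u0)
    delta <- drop(pca$map %*% (xn - pca$center)) - xpc
    vx[i, j] <- delta[1]; vy[i, j] <- delta[2]
    nrm[i, j] <- sqrt(sum(delta[1:2]^2))
    st[i, j] <- k
  }
  structure(list(pc1 = pc1, pc2 = pc2, vx = vx, vy = vy, norm = nrm,
                 state = st, input_policy = input_policy,
                 state_mode = state_mode, n_grid = n_grid, margin = margin),
            class = "flow_field")
}

#' Slow points of a flow field
#'
#' Grid cells whose displacement norm is a local minimum (8-neighborhood)
#' and falls below a percentile threshold of all norms; the retained
#' points are ordered along PC1 into a polyline that traces the
#' attractor.
#'
#' @param field a \code{\link{flow_field}}.
#' @param percentile_threshold percentile of norms (default 5) below
#'   which a local minimum qualifies.
#' @return An object of class \code{slow_point_set}: data.frame
#'   \code{points} (pc1, pc2, norm; ordered by pc1) and the
#'   \code{threshold} used.  A nearly uniform field yields an empty set
#'   with a warning.
#' @export
slow_points <- function(field, percentile_threshold = 5) {
  nrm <- field$norm
  n <- nrow(nrm)
  rng <- range(nrm)
  if (diff(rng) < 1e-12 * max(1, rng[2])) {
    warnf("flow field is uniform; no slow points identified")
    return(structure(list(points = data.frame(pc1 = numeric(0), pc2 = numeric(0),
                                              norm = numeric(0)),
                          threshold = rng[1]),
                     class = "slow_point_set"))
  }
  thr <- quantile(nrm, percentile_threshold / 100)
  pts <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (nrm[i, j] > thr) next
    ni <- max(1, i - 1):min(n, i + 1)
    nj <- max(1, j - 1):min(n, j + 1)
    if (nrm[i, j] <= min(nrm[ni, nj])) {
      pts[[length(pts) + 1]] <- data.frame(pc1 = field$pc1[i],
                                           pc2 = field$pc2[j],
                                           norm = nrm[i, j])
    }
  }
  points <- if (length(pts) > 0) do.call(rbind, pts)
            else data.frame(pc1 = numeric(0), pc2 = numeric(0), norm = numeric(0))
  points <- points[order(points$pc1), , drop = FALSE]
  rownames(points) <- NULL
  structure(list(points = points, threshold = unname(thr)),
            class = "slow_point_set")
}

#' Dynamic velocity by behavior
#'
#' For each behavior b, the norm of the state-dynamics image of the
#' latent, averaged first over that behavior's frames within each visited
#' discrete state and then across states:
#' \deqn{V_b = \frac{1}{n(Z_b)} \sum_{z \in Z_b}
#'       \frac{1}{n(T_{b,z})} \sum_{t \in T_{b,z}} \|A_{z_t} x_t\|}
#' Values are normalized to [0, 1] by the maximum across behaviors.  The
#' default \code{mode = "literal"} uses \eqn{\|A_z x_t\|} exactly as the
#' metric is defined; \code{mode = "displacement"} instead measures the
#' true one-step flow speed \eqn{\|(A_z - I) x_t + V_z u_t + b_z\|},
#' which is the quantity the flow-field/landscape picture visualizes.
#'
#' @param fit an \code{rslds_fit}.
#' @param annotations a \code{behavior_annotation} data.frame (or label
#'   vector) aligned with the fitted frames.
#' @param behaviors behaviors to score (default: all present except
#'   background).
#' @param mode "literal" or "displacement"; see above.
#' @return data.frame of class \code{dynamic_velocity_table} with columns
#'   \code{behavior}, \code{raw}, \code{normalized}.
#' @export
dynamic_velocity <- function(fit, annotations,
                             behaviors = NULL,
                             mode = c("literal", "displacement")) {
  mode <- match.arg(mode)
  labels <- if (is.data.frame(annotations)) annotations$behavior else as.character(annotations)
  X <- fit$posterior_latents
  z <- fit$most_likely_states
  P <- fit$params
  U <- fit$inputs %||% matrix(0, P$m, ncol(X))
  if (length(labels) != ncol(X))
    stopf("annotations cover %d frames but the fit covers %d", length(labels), ncol(X))
  behaviors <- behaviors %||% setdiff(unique(labels), "background")
  raw <- setNames(numeric(0), character(0))
  for (b in behaviors) {
    Tb <- which(labels == b)
    if (length(Tb) == 0) {
      message(sprintf("behavior '%s' has no frames; excluded", b))
      next
    }
    per_state <- c()
    for (k in unique(z[Tb])) {
      idx <- Tb[z[Tb] == k]
      V <- if (mode == "literal") {
        P$A[[k]] %*% X[, idx, drop = FALSE]
      } else {
        (P$A[[k]] - diag(P$D)) %*% X[, idx, drop = FALSE] +
          P$V[[k]] %*% U[, pmax(idx - 1, 1), drop = FALSE] + P$b[[k]]
      }
      per_state <- c(per_state, mean(sqrt(colSums(V^2))))
    }
    raw[b] <- mean(per_state)
  }
  if (length(raw) == 0) stopf("none of the requested behaviors have frames")
  mx <- max(raw)
  out <- data.frame(behavior = names(raw), raw = unname(raw),
                    normalized = if (mx > 0) unname(raw) / mx else rep(0, length(raw)))
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  class(out) <- c("dynamic_velocity_table", "data.frame")
  out
}

#' 3D dynamics landscape
#'
#' Represents a flow field as a height surface: the displacement norm at
#' each grid cell becomes the height, so line attractors appear as
#' troughs and point attractors as cone-shaped basins.
#'
#' @param field a \code{\link{flow_field}}.
#' @return An object of class \code{dynamic_landscape}: \code{pc1},
#'   \code{pc2}, \code{height} (matrix of non-negative norms).
#' @export
landscape <- function(field) {
  structure(list(pc1 = field$pc1, pc2 = field$pc2, height = field$norm),
            class = "dynamic_landscape")
}
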