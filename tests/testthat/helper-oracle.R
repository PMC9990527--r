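# Independent oracles used by the inference tests.

# Exact Kalman-filter log-likelihood of y (N x T) under a FIXED discrete
# state path, matching the generative conventions of the package:
# x_1 ~ N(0, x1_sd^2 I); for t >= 2, x_t = A_{z_t} x_{t-1} + V u + b + N(0, Q);
# y_t = C x_t + d + N(0, S).
kalman_loglik_path <- function(params, z, Y, U = NULL, x1_sd = 10) {
  D <- params$D; T_ <- ncol(Y)
  if (is.null(U)) U <- matrix(0, params$m, T_)
  mu <- numeric(D); Sig <- diag(x1_sd^2, D)
  ll <- 0
  for (t in seq_len(T_)) {
    if (t >= 2) {
      A <- params$A[[z[t]]]
      mu <- drop(A %*% mu) + drop(params$V[[z[t]]] %*% U[, t - 1]) + params$b[[z[t]]]
      Sig <- A %*% Sig %*% t(A) + params$process_noise
    }
    S <- params$C %*% Sig %*% t(params$C) + params$obs_noise
    r <- Y[, t] - drop(params$C %*% mu) - params$d_bias
    L <- chol((S + t(S)) / 2)
    zr <- backsolve(L, r, transpose = TRUE)
    ll <- ll - 0.5 * length(r) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(zr^2)
    Kg <- Sig %*% t(params$C) %*% chol2inv(L)
    mu <- mu + drop(Kg %*% r)
    Sig <- Sig - Kg %*% params$C %*% Sig
  }
  ll
}

# Exhaustive-enumeration log evidence for small T and K, valid when the
# transition logits do not depend on x or u (R = 0, W = 0): the prior over
# paths factorizes and each path integrates exactly by Kalman filtering.
enumeration_log_evidence <- function(params, Y, U = NULL, x1_sd = 10) {
  stopifnot(all(params$R_tr == 0), all(params$W_tr == 0))
  K <- params$K; T_ <- ncol(Y)
  lp_z <- log(exp(params$r_tr) / sum(exp(params$r_tr)))
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  lls <- apply(paths, 1L, function(z) {
    kalman_loglik_path(params, z, Y, U, x1_sd) -
      log(K) + sum(lp_z[z[-1]])
  })
  m <- max(lls)
  m + log(sum(exp(lls - m)))
}

# small dense rslds_params builder for hand-constructed tests
toy_params <- function(K = 1, D = 1, m = 0, N = 2,
                       A = NULL, C = NULL, q = 0.1, r = 0.1,
                       r_tr = numeric(K)) {
  A <- A %||% rep(list(diag(0.5, D)), K)
  if (is.matrix(A)) A <- list(A)
  C <- C %||% matrix(seq_len(N * D) / (N * D), N, D)
  rslds_params(A = A,
               V = rep(list(matrix(0, D, m)), K),
               b = rep(list(numeric(D)), K),
               C = C, d_bias = numeric(N),
               obs_noise = diag(r^2, N),
               process_noise = diag(q^2, D),
               R_tr = matrix(0, K, D), W_tr = matrix(0, K, m),
               r_tr = r_tr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
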