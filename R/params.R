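#' rSLDS parameter set
#'
#' Container for the full parameter set of a recurrent switching linear
#' dynamical system with \code{K} discrete states, \code{D} continuous latent
#' dimensions, \code{m} external inputs and \code{N} observed neurons:
#' \deqn{p(z_{t+1} = k \mid x_t, u_t) \propto \exp\{R_k x_t + W_k u_t + r_k\}}
#' \deqn{x_{t+1} = A_{z_{t+1}} x_t + V_{z_{t+1}} u_t + b_{z_{t+1}} + \epsilon_t}
#' \deqn{y_t = C x_t + d + \eta_t}
#' with \eqn{\epsilon_t \sim N(0, Q)} (process noise) and
#' \eqn{\eta_t \sim N(0, S)} (observation noise, diagonal by default).
#' Transition logits are shared across source states; an optional
#' \code{markov_bias} (K x K log-bias) adds a conventional Markov term.
#'
#' @param A list of K dynamics matrices (D x D).
#' @param V list of K input matrices (D x m); may be all-zero if m = 0.
#' @param b list of K bias vectors (length D).
#' @param C emission matrix (N x D), full column rank.
#' @param d_bias emission offset (length N).
#' @param obs_noise observation noise covariance (N x N, typically diagonal).
#' @param process_noise process noise covariance (D x D), shared across states.
#' @param R_tr transition weights on the latent (K x D).
#' @param W_tr transition weights on the input (K x m).
#' @param r_tr transition offsets (length K).
#' @param markov_bias optional K x K additive log-bias on transitions.
#' @return An object of class \code{rslds_params}.
#' @export
rslds_params <- function(A, V, b, C, d_bias, obs_noise, process_noise,
                         R_tr, W_tr, r_tr, markov_bias = NULL) {
  K <- length(A)
  stopifnot(K >= 1, length(V) == K, length(b) == K)
  D <- nrow(A[[1]])
  for (k in seq_len(K)) {
    A[[k]] <- as.matrix(A[[k]])
    if (!all(dim(A[[k]]) == c(D, D))) stopf("A[[%d]] must be %d x %d", k, D, D)
    b[[k]] <- as.numeric(b[[k]])
    if (length(b[[k]]) != D) stopf("b[[%d]] must have length %d", k, D)
    V[[k]] <- as.matrix(V[[k]])
    if (nrow(V[[k]]) != D) stopf("V[[%d]] must have %d rows", k, D)
  }
  m <- ncol(V[[1]])
  C <- as.matrix(C)
  N <- nrow(C)
  if (ncol(C) != D) stopf("C must have %d columns", D)
  if (N < D) stopf("need at least as many neurons (%d) as latent dimensions (%d)", N, D)
  if (qr(C)$rank < D) stopf("emission matrix C is rank deficient")
  d_bias <- as.numeric(d_bias)
  if (length(d_bias) != N) stopf("d_bias must have length %d", N)
  obs_noise <- as.matrix(obs_noise)
  process_noise <- as.matrix(process_noise)
  stopifnot(all(dim(obs_noise) == c(N, N)), all(dim(process_noise) == c(D, D)))
  if (min(eigen(symm(obs_noise), only.values = TRUE)$values) < -1e-10)
    stopf("obs_noise must be positive semidefinite")
  if (min(eigen(symm(process_noise), only.values = TRUE)$values) < -1e-10)
    stopf("process_noise must be positive semidefinite")
  R_tr <- as.matrix(R_tr); W_tr <- as.matrix(W_tr); r_tr <- as.numeric(r_tr)
  if (!all(dim(R_tr) == c(K, D))) stopf("R_tr must be %d x %d", K, D)
  if (nrow(W_tr) != K || ncol(W_tr) != m) stopf("W_tr must be %d x %d", K, m)
  if (length(r_tr) != K) stopf("r_tr must have length %d", K)
  if (!is.null(markov_bias)) {
    markov_bias <- as.matrix(markov_bias)
    stopifnot(all(dim(markov_bias) == c(K, K)))
  }
  structure(list(K = K, D = D, m = m, N = N,
                 A = A, V = V, b = b, C = C, d_bias = d_bias,
                 obs_noise = obs_noise, process_noise = process_noise,
                 R_tr = R_tr, W_tr = W_tr, r_tr = r_tr,
                 markov_bias = markov_bias),
            class = "rslds_params")
}

#' @export
print.rslds_params <- function(x, ...) {
  cat(sprintf("rSLDS parameters: K = %d states, D = %d latent dims, m = %d inputs, N = %d neurons\n",
              x$K, x$D, x$m, x$N))
  invisible(x)
}

#' Discrete-state transition probabilities
#'
#' Softmax transition rule of the rSLDS: the distribution over the next
#' discrete state given the current latent position and external input,
#' \eqn{p(z_{t+1} = k) \propto \exp\{R_k x_t + W_k u_t + r_k\}}.
#'
#' @param params an \code{\link{rslds_params}} object.
#' @param x_prev latent vector (length D).
#' @param u_prev input vector (length m); defaults to zeros.
#' @param z_prev previous discrete state; only used when \code{markov_bias}
#'   is present.
#' @return length-K probability vector summing to one.
#' @export
transition_probabilities <- function(params, x_prev, u_prev = NULL, z_prev = NULL) {
  if (length(x_prev) != params$D) stopf("x_prev must have length %d", params$D)
  if (is.null(u_prev)) u_prev <- numeric(params$m)
  if (length(u_prev) != params$m) stopf("u_prev must have length %d", params$m)
  logits <- drop(params$R_tr %*% x_prev) + drop(params$W_tr %*% u_prev) + params$r_tr
  if (!is.null(params$markov_bias) && !is.null(z_prev))
    logits <- logits + params$markov_bias[z_prev, ]
  softmax(logits)
}

#' One-step mean latent dynamics
#'
#' Returns \eqn{A_k x + V_k u + b_k}, the conditional mean of the next
#' latent under discrete state \code{k}.
#'
#' @inheritParams transition_probabilities
#' @param k discrete state index in 1..K.
#' @return latent vector of length D.
#' @export
latent_mean_step <- function(params, k, x_prev, u_prev = NULL) {
  if (k < 1 || k > params$K) stopf("state index %d out of range 1..%d", k, params$K)
  if (is.null(u_prev)) u_prev <- numeric(params$m)
  drop(params$A[[k]] %*% x_prev) + drop(params$V[[k]] %*% u_prev) + params$b[[k]]
}

#' Mean emission
#'
#' Returns \eqn{C x + d}, the noiseless observation for a latent position.
#'
#' @inheritParams transition_probabilities
#' @param x latent vector (length D).
#' @return length-N vector of mean activity.
#' @export
emission_mean <- function(params, x) {
  drop(params$C %*% x) + params$d_bias
}

mvn_logdens <- function(x, mu, Sig) {
  d <- length(x)
  L <- chol(symm(Sig))
  z <- backsolve(L, x - mu, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

#' Joint log-probability of a complete rSLDS trajectory
#'
#' Sums the transition, dynamics, and emission log-densities of a fully
#' observed trajectory \code{(z, x, y, u)} under the model.  The initial
#' latent has prior \eqn{N(0, \sigma_0^2 I)} and the initial discrete state
#' is uniform over 1..K.  Mainly used as a brute-force oracle in tests of
#' the inference machinery.
#'
#' @inheritParams transition_probabilities
#' @param z integer state sequence (length T, values in 1..K).
#' @param x latent matrix (D x T).
#' @param y observation matrix (N x T).
#' @param u input matrix (m x T) or NULL for no input.
#' @param x1_sd prior standard deviation on the initial latent.
#' @return scalar log-probability in nats.
#' @export
joint_log_probability <- function(params, z, x, y, u = NULL, x1_sd = 10) {
  x <- as.matrix(x); y <- as.matrix(y)
  T_ <- ncol(x)
  stopifnot(length(z) == T_, ncol(y) == T_)
  if (is.null(u)) u <- matrix(0, params$m, T_)
  lp <- -log(params$K) +
    mvn_logdens(x[, 1], numeric(params$D), diag(x1_sd^2, params$D))
  for (t in seq_len(T_)) {
    if (t >= 2) {
      p <- transition_probabilities(params, x[, t - 1], u[, t - 1], z[t - 1])
      lp <- lp + log(p[z[t]])
      mu <- latent_mean_step(params, z[t], x[, t - 1], u[, t - 1])
      lp <- lp + mvn_logdens(x[, t], mu, params$process_noise)
    }
    lp <- lp + mvn_logdens(y[, t], emission_mean(params, x[, t]), params$obs_noise)
  }
  lp
}
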