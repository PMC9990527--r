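# PCA re-parameterization, flow fields, slow points, dynamic velocity,
# landscapes.

test_that("PCA transform is observationally equivalent and variance-ordered", {
  fit <- short_line_fit()
  pca <- pca_transform_latents(fit)
  Xc <- fit$posterior_latents - rowMeans(fit$posterior_latents)
  err <- max(abs(fit$params$C %*% Xc - pca$U %*% pca$latents_pc))
  expect_lt(err, 1e-8)
  expect_true(all(diff(pca$singular_values) <= 1e-9))
  v <- apply(pca$latents_pc, 1L, var)
  expect_true(all(diff(v) <= 1e-6 * v[1]))
  # whole transformed system reconstructs the same activity
  err2 <- max(abs((fit$params$C %*% fit$posterior_latents + fit$params$d_bias) -
                  (pca$params_pc$C %*% pca$latents_pc + pca$params_pc$d_bias)))
  expect_lt(err2, 1e-8)

  # already-white latents with orthogonal C: the map reduces to a rotation
  set.seed(60)
  T_ <- 5000
  X <- matrix(rnorm(2 * T_), 2, T_)
  X <- X - rowMeans(X)
  X <- solve(t(chol(tcrossprod(X) / T_))) %*% X   # exactly white
  Q <- qr.Q(qr(matrix(rnorm(4), 2)))
  p <- toy_params(K = 1, D = 2, N = 2, C = Q)
  pca2 <- pca_transform_latents(list(params = p, posterior_latents = X))
  M <- pca2$map
  expect_equal(crossprod(M), diag(2), tolerance = 1e-6)
})

test_that("flow fields reflect the fitted dynamics geometry", {
  # identity dynamics, no bias: the field vanishes everywhere
  set.seed(61)
  X <- matrix(rnorm(2 * 400), 2, 400)
  p <- toy_params(K = 1, D = 2, N = 3, A = diag(2),
                  C = matrix(c(1, 0, 0.2, 0, 1, -0.1), 3, 2))
  fit <- list(params = p, posterior_latents = X, inputs = NULL)
  pca <- pca_transform_latents(fit)
  ff0 <- flow_field(fit, pca, n_grid = 11)
  expect_lt(max(ff0$norm), 1e-10)
  expect_warning(slow_points(ff0), "uniform")

  # stable node: vectors point toward the fixed point image
  p2 <- p; p2$A[[1]] <- diag(0.5, 2); p2$b[[1]] <- c(1, 0)
  xstar <- solve(diag(2) - p2$A[[1]], p2$b[[1]])     # = (2, 0)
  fit2 <- list(params = p2, posterior_latents = X, inputs = NULL)
  pca2 <- pca_transform_latents(fit2)
  ff2 <- flow_field(fit2, pca2, n_grid = 15)
  xstar_pc <- drop(pca2$map %*% (xstar - pca2$center))
  ok <- 0; tot <- 0
  for (i in seq_len(15)) for (j in seq_len(15)) {
    pos <- c(ff2$pc1[i], ff2$pc2[j])
    tow <- xstar_pc - pos
    vv <- c(ff2$vx[i, j], ff2$vy[i, j])
    if (sqrt(sum(tow^2)) > 0.5) {
      tot <- tot + 1
      if (sum(tow * vv) > 0) ok <- ok + 1
    }
  }
  expect_equal(ok, tot)

  # rotational dynamics produce a circulating field (nonzero curl)
  th <- 2 * pi / 20
  p3 <- p; p3$A[[1]] <- 0.999 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  fit3 <- list(params = p3, posterior_latents = X, inputs = NULL)
  pca3 <- pca_transform_latents(fit3)
  ff3 <- flow_field(fit3, pca3, n_grid = 15)
  cross <- 0
  for (i in seq_len(15)) for (j in seq_len(15)) {
    pos <- c(ff3$pc1[i], ff3$pc2[j])
    vv <- c(ff3$vx[i, j], ff3$vy[i, j])
    cross <- cross + (pos[1] * vv[2] - pos[2] * vv[1])
  }
  expect_gt(abs(cross), 1)
})

test_that("slow points trace the attractor and sit at landscape minima", {
  runs <- acceptance_line_runs()
  r <- runs[[1]]
  pca <- pca_transform_latents(r$fit)
  ff <- flow_field(r$fit, pca, n_grid = 40)
  sp <- slow_points(ff, percentile_threshold = 5)
  expect_gt(nrow(sp$points), 0)
  expect_true(all(sp$points$norm <= sp$threshold))
  expect_true(!is.unsorted(sp$points$pc1))
  # every slow point is a local minimum of the landscape heights
  ls <- landscape(ff)
  expect_identical(ls$height, ff$norm)
  amin <- which(ls$height == min(ls$height), arr.ind = TRUE)[1, ]
  expect_true(any(abs(sp$points$pc1 - ff$pc1[amin[1]]) < 1e-9 &
                  abs(sp$points$pc2 - ff$pc2[amin[2]]) < 1e-9))
})

test_that("dynamic velocity matches hand arithmetic and conventions", {
  # 2-frame hand case: A = [[0.5,0],[0,1]], x = (2,0) then (0,2)
  p <- toy_params(K = 1, D = 2, N = 2,
                  A = matrix(c(0.5, 0, 0, 1), 2, 2), C = diag(2))
  fit <- list(params = p,
              posterior_latents = matrix(c(2, 0, 0, 2), 2, 2),
              most_likely_states = c(1L, 1L), inputs = NULL)
  vel <- dynamic_velocity(fit, c("attack", "attack"))
  expect_equal(vel$raw, 1.5)          # norms 1 and 2, mean 1.5
  expect_equal(vel$normalized, 1)     # single behavior normalizes to 1

  # all-zero dynamics give an all-zero table
  p0 <- p; p0$A[[1]] <- matrix(0, 2, 2)
  fit0 <- fit; fit0$params <- p0
  vel0 <- dynamic_velocity(fit0, c("attack", "sniff"))
  expect_true(all(vel0$raw == 0))

  # absent behaviors are excluded with a message
  expect_message(dynamic_velocity(fit, c("attack", "attack"),
                                  behaviors = c("attack", "intromission")),
                 "excluded")
})
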