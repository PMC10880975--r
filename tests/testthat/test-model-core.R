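test_that("shape and hyperparameter constructors validate their inputs", {
  expect_s3_class(dpc_shape(10, 4, 2, 3), "dpc_shape")
  expect_error(dpc_shape(0, 4, 2, 3), class = "dpc_invalid_argument")
  expect_error(dpc_shape(10, 4, 2, 0), class = "dpc_invalid_argument")
  expect_error(dpc_hyper(sigma2 = 0), class = "dpc_invalid_argument")
  expect_error(dpc_hyper(sigma_r2 = -1), class = "dpc_invalid_argument")
  expect_error(dpc_hyper(lambda = -0.1), class = "dpc_invalid_argument")
})

test_that("hypernet_forward computes the affine/tanh composition", {
  ## single affine layer with zero weights: w = b for any r_h
  theta <- list(list(W = matrix(0, 3, 2), b = c(1, -2, 0.5)))
  expect_equal(hypernet_forward(c(0.3, -4), theta), c(1, -2, 0.5))
  expect_equal(hypernet_forward(c(0, 0), theta), c(1, -2, 0.5))
  ## two-layer net evaluated by hand at r_h = (1, -1)
  W1 <- matrix(c(1, 0, 0.5, -0.5), 2, 2)  # column-major
  b1 <- c(0.1, 0.2)
  W2 <- matrix(c(2, -1, 1, 0.5), 2, 2)
  b2 <- c(0, 1)
  theta2 <- list(list(W = W1, b = b1), list(W = W2, b = b2))
  h <- tanh(W1 %*% c(1, -1) + b1)
  expect_equal(hypernet_forward(c(1, -1), theta2), drop(W2 %*% h + b2))
  ## matrix input maps columnwise
  R <- cbind(c(1, -1), c(0, 0))
  out <- hypernet_forward(R, theta2)
  expect_equal(out[, 1], drop(W2 %*% h + b2))
  expect_error(hypernet_forward(c(1, 2, 3), theta2),
               class = "dpc_invalid_argument")
})

test_that("mix_transitions is an exact linear combination", {
  V_set <- lapply(1:5, function(k) matrix(k, 2, 2))
  w <- c(0, 0, 1, 0, 0)
  expect_equal(mix_transitions(w, V_set), V_set[[3]])
  expect_equal(mix_transitions(rep(0, 5), V_set), matrix(0, 2, 2))
  A <- matrix(c(1, 2, 3, 4), 2)
  B <- matrix(c(5, 6, 7, 8), 2)
  expect_equal(mix_transitions(c(0.5, 0.5), list(A, B)), (A + B) / 2)
  ## linearity to floating point
  set.seed(1)
  Vs <- lapply(1:3, function(k) matrix(rnorm(9), 3))
  w1 <- rnorm(3); w2 <- rnorm(3); a <- 0.3; b <- -1.7
  expect_equal(mix_transitions(a * w1 + b * w2, Vs),
               a * mix_transitions(w1, Vs) + b * mix_transitions(w2, Vs))
  expect_error(mix_transitions(c(1, 2), Vs), class = "dpc_invalid_argument")
})

test_that("transition_mean applies the rectified linear map", {
  expect_equal(transition_mean(c(1, -2, 3), diag(3)), c(1, 0, 3))
  expect_equal(transition_mean(c(1, 0, 2), -diag(3)), c(0, 0, 0))
  set.seed(2)
  V <- matrix(rnorm(9), 3)
  r <- rnorm(3)
  expect_equal(transition_mean(r, V), pmax(as.vector(V %*% r), 0))
  expect_error(transition_mean(c(1, 2), V), class = "dpc_invalid_argument")
})

test_that("decode_image is the linear readout through U", {
  set.seed(3)
  U <- matrix(rnorm(12), 4, 3)
  expect_equal(decode_image(rep(0, 3), U), rep(0, 4))
  expect_equal(decode_image(c(0, 1, 0), U), U[, 2])
  r <- rnorm(3)
  expect_equal(decode_image(r, U), as.vector(U %*% r))
  expect_error(decode_image(rnorm(4), U), class = "dpc_invalid_argument")
})

test_that("step and first-step losses match hand-computed values", {
  sh <- dpc_shape(M = 1, N = 1, N_h = 1, K = 1, hidden = integer(0))
  p <- dpc_params(sh, seed = 1)
  p$U <- matrix(1)
  hy <- dpc_hyper(sigma2 = 1, sigma_r2 = 1, lambda = 1, lambda_h = 1)
  expect_equal(step_loss(0, 0, 0, 0, p, hy), 0)
  ## 0.5*(2-1)^2 + 0.5*(1-0)^2 + 1*|1| + 1*1^2 = 3
  expect_equal(step_loss(2, 1, 0, 1, p, hy), 3)
  p2 <- p; p2$U <- matrix(2)
  hy2 <- dpc_hyper(sigma2 = 1, sigma_r2 = 1, lambda = 0.5, lambda_h = 0)
  expect_equal(first_step_loss(0, 0, p2, hy2), 0)
  ## 0.5*(4-2)^2 + 0.5*|1| = 2.5
  expect_equal(first_step_loss(4, 1, p2, hy2), 2.5)
  ## first_step_loss equals step_loss in the sigma_r2 -> Inf, lambda_h = 0 limit
  hy3 <- dpc_hyper(sigma2 = 0.7, sigma_r2 = 1e12, lambda = 0.3, lambda_h = 0)
  set.seed(4)
  sh4 <- dpc_shape(M = 6, N = 4, N_h = 2, K = 2)
  p4 <- dpc_params(sh4, seed = 2)
  I <- rnorm(6); r <- rnorm(4)
  expect_equal(step_loss(I, r, rnorm(4), rnorm(2), p4, hy3),
               first_step_loss(I, r, p4, hy3), tolerance = 1e-9)
})

test_that("step_loss is invariant to a simultaneous latent permutation", {
  set.seed(5)
  sh <- dpc_shape(M = 7, N = 5, N_h = 2, K = 2)
  p <- dpc_params(sh, seed = 3)
  hy <- dpc_hyper(sigma2 = 0.5, sigma_r2 = 2, lambda = 0.1, lambda_h = 0.2)
  I <- rnorm(7); r <- rnorm(5); rb <- rnorm(5); rh <- rnorm(2)
  perm <- sample(5)
  p2 <- p
  p2$U <- p$U[, perm]
  expect_equal(step_loss(I, r[perm], rb[perm], rh, p2, hy),
               step_loss(I, r, rb, rh, p, hy))
})

test_that("analytic loss gradients match central finite differences", {
  set.seed(42)
  sh <- dpc_shape(M = 5, N = 4, N_h = 3, K = 2, hidden = 3)
  hy <- dpc_hyper(sigma2 = 0.7, sigma_r2 = 1.3, lambda = 0, lambda_h = 0.05)
  p <- dpc_params(sh, seed = 3)
  for (l in seq_along(p$theta)) {
    p$theta[[l]]$W <- p$theta[[l]]$W * 5
    p$theta[[l]]$b <- rnorm(length(p$theta[[l]]$b)) * 0.5
  }
  I <- rnorm(5); r <- rnorm(4); rh <- rnorm(3); rprev <- rnorm(4)
  lossfun <- function(r, rh) {
    V <- mix_transitions(hypernet_forward(rh, p$theta), p$V_set)
    step_loss(I, r, transition_mean(rprev, V), rh, p, hy)
  }
  num_grad <- function(f, x, eps = 1e-6) vapply(seq_along(x), function(i) {
    xp <- x; xm <- x; xp[i] <- xp[i] + eps; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
  gb <- dpcnet:::grad_step_rh(r, rh, rprev, p, hy)
  gr <- dpcnet:::grad_step_r(I, r, drop(gb$r_bar), p, hy)
  expect_lt(max(abs(drop(gr) - num_grad(function(x) lossfun(x, rh), r))) /
              max(abs(num_grad(function(x) lossfun(x, rh), r))), 1e-5)
  expect_lt(max(abs(drop(gb$d_rh) - num_grad(function(x) lossfun(r, x), rh))) /
              max(abs(num_grad(function(x) lossfun(r, x), rh))), 1e-5)
})

test_that("generative sampling is reproducible and decodes its latents", {
  p <- make_teacher(seed = 9)
  g1 <- sample_generative(p, 8, sigma2 = 0, sigma_r2 = 0, seed = 5)
  g2 <- sample_generative(p, 8, sigma2 = 0, sigma_r2 = 0, seed = 5)
  expect_identical(g1$seq$frames, g2$seq$frames)
  ## zero noise: frames decode exactly from the stored latents
  for (t in 1:8)
    expect_equal(g1$seq$frames[t, ], decode_image(g1$r[, t], p$U))
  ## identity dynamics: the post-rectification state is a fixed point
  sh <- dpc_shape(M = 6, N = 3, N_h = 2, K = 1, hidden = integer(0))
  pid <- dpc_params(sh, seed = 1)
  pid$theta <- list(list(W = matrix(0, 1, 2), b = 1))
  pid$V_set <- list(diag(3))
  gid <- sample_generative(pid, 5, sigma2 = 0, sigma_r2 = 0, seed = 3)
  for (t in 3:5) expect_equal(gid$seq$frames[t, ], gid$seq$frames[2, ])
})

test_that("sampled observation noise has the requested variance", {
  sh <- dpc_shape(M = 50, N = 4, N_h = 2, K = 1, hidden = integer(0))
  p <- dpc_params(sh, seed = 2)
  p$U <- p$U * 0   # frames are pure noise
  p$theta <- list(list(W = matrix(0, 1, 2), b = 1))
  g <- sample_generative(p, 200, sigma2 = 0.04, sigma_r2 = 0, seed = 7)
  expect_lt(abs(stats::var(as.vector(g$seq$frames)) - 0.04) / 0.04, 0.05)
})
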