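test_that("parameter gradients match finite differences on a tiny model", {
  set.seed(21)
  sh <- dpc_shape(M = 4, N = 3, N_h = 2, K = 2, hidden = 2)
  hy <- dpc_hyper(sigma2 = 0.6, sigma_r2 = 1.4, lambda = 0.05, lambda_h = 0.02)
  p <- dpc_params(sh, seed = 5)
  for (l in seq_along(p$theta)) {
    p$theta[[l]]$W <- p$theta[[l]]$W * 4
    p$theta[[l]]$b <- rnorm(length(p$theta[[l]]$b)) * 0.5
  }
  T_len <- 3; B <- 2
  frames <- array(rnorm(T_len * 4 * B), c(T_len, 4, B))
  lat <- list(r_hat = array(rnorm(3 * T_len * B), c(3, T_len, B)),
              r_h_hat = array(rnorm(2 * T_len * B), c(2, T_len, B)))
  g <- dpcnet:::loss_and_param_grads(frames, lat, p, hy)
  totloss <- function(p2) dpcnet:::loss_and_param_grads(frames, lat, p2, hy)$loss
  eps <- 1e-6
  fd <- function(mutate) {
    p2 <- mutate(p, eps); lp <- totloss(p2)
    p2 <- mutate(p, -eps); lm <- totloss(p2)
    (lp - lm) / (2 * eps)
  }
  rel <- function(a, b, ref) abs(a - b) / max(abs(ref), 1e-8)
  expect_lt(rel(g$dU[2, 3],
                fd(function(p, e) { p$U[2, 3] <- p$U[2, 3] + e; p }),
                g$dU), 1e-4)
  expect_lt(rel(g$dV[[2]][1, 3],
                fd(function(p, e) { p$V_set[[2]][1, 3] <- p$V_set[[2]][1, 3] + e; p }),
                g$dV[[2]]), 1e-4)
  expect_lt(rel(g$dtheta[[1]]$W[2, 1],
                fd(function(p, e) { p$theta[[1]]$W[2, 1] <- p$theta[[1]]$W[2, 1] + e; p }),
                g$dtheta[[1]]$W), 1e-4)
  expect_lt(rel(g$dtheta[[2]]$b[1],
                fd(function(p, e) { p$theta[[2]]$b[1] <- p$theta[[2]]$b[1] + e; p }),
                g$dtheta[[2]]$b), 1e-4)
})

test_that("training with zero learning rate leaves parameters bit-identical", {
  p <- make_teacher(seed = 11)
  ds <- teacher_dataset(p, 6, 600)
  fit <- train_two_level(ds, p$shape, teacher_hyper(),
                         dpc_options(max_iters = 10, backtrack = FALSE),
                         n_epochs = 2, batch_size = 3, lr = 0, params = p,
                         seed = 1)
  expect_identical(fit$params$U, p$U)
  expect_identical(fit$params$V_set, p$V_set)
  expect_identical(fit$params$theta, p$theta)
})

test_that("training overfits a single repeated sequence", {
  p <- make_teacher(seed = 12)
  g <- sample_generative(p, 10, sigma2 = 1e-3, sigma_r2 = 1e-3, seed = 4)
  frames <- array(rep(g$seq$frames, 8), c(10, 16, 8))
  ds <- dpc_dataset(frames, c(1, 16))
  opts <- dpc_options(lr_r = 0.02, lr_rh = 0.05, max_iters = 40, tol = 1e-5,
                      backtrack = FALSE)
  fit <- train_two_level(ds, p$shape, dpc_hyper(), opts, n_epochs = 150,
                         batch_size = 8, lr = 5e-3, seed = 2)
  expect_gt(fit$history$mean_loss[1] / tail(fit$history$mean_loss, 1), 10)
  expect_true(isTRUE(fit$params$trained))
  ## spatial filters stay unit-norm
  expect_equal(colSums(fit$params$U^2), rep(1, 8), tolerance = 1e-12)
})

test_that("teacher-student training recovers predictive dynamics", {
  ts <- teacher_student_run()
  ## mean epoch loss decreases overall and ends well below the start
  expect_lt(tail(ts$fit$history$mean_loss, 1),
            0.2 * ts$fit$history$mean_loss[1])
  expect_gt(ts$r2, 0.8)
})

test_that("epoch losses are non-increasing in most short seeded runs", {
  p <- make_teacher(seed = 14)
  hy_tr <- dpc_hyper(sigma2 = 0.1, sigma_r2 = 1, lambda = 0.001,
                     lambda_h = 1e-4)
  opts <- dpc_options(lr_r = 0.05, lr_rh = 0.1, max_iters = 30, tol = 1e-5,
                      backtrack = FALSE)
  ok <- vapply(1:5, function(s) {
    ds <- teacher_dataset(p, 100, 2000 + 500 * s)
    fit <- train_two_level(ds, p$shape, hy_tr, opts, n_epochs = 8,
                           batch_size = 50, lr = 5e-3, seed = s)
    all(diff(fit$history$mean_loss) <= 1e-6)
  }, logical(1))
  expect_gte(sum(ok), 4)
})

test_that("whitening is linear, removes DC, and flattens 1/f input spectra", {
  S <- 16
  set.seed(31)
  mk <- function(slope) {
    fy <- c(0:(S / 2), -((S / 2) - 1):-1) / S
    f <- sqrt(outer(fy^2, fy^2, "+")); f[1, 1] <- 1
    fr <- array(0, c(2, S * S))
    for (t in 1:2) {
      X <- stats::fft(matrix(rnorm(S * S), S, S)) * f^slope
      fr[t, ] <- dpcnet:::frame_to_vec(Re(stats::fft(X, inverse = TRUE)) / S^2)
    }
    fr
  }
  ## DC frame is annihilated by the spatial ramp
  dc <- dpc_sequence(matrix(1, 2, S * S), c(S, S))
  wdc <- whiten_sequences(dc, temporal = FALSE)
  expect_lt(max(abs(wdc$frames)), 1e-10)
  ## linearity
  X <- dpc_sequence(mk(0), c(S, S)); Y <- dpc_sequence(mk(0), c(S, S))
  Z <- dpc_sequence(2 * X$frames - 3 * Y$frames, c(S, S))
  expect_equal(whiten_sequences(Z)$frames,
               2 * whiten_sequences(X)$frames - 3 * whiten_sequences(Y)$frames,
               tolerance = 1e-10)
  ## 1/f-amplitude (natural-statistics) input comes out spectrally flat
  n <- 250
  fr <- array(0, c(2, S * S, n))
  for (i in 1:n) fr[, , i] <- mk(-1)
  wds <- whiten_sequences(dpc_dataset(fr, c(S, S)), temporal = FALSE)
  fy <- c(0:(S / 2), -((S / 2) - 1):-1) / S
  f <- sqrt(outer(fy^2, fy^2, "+"))
  P <- matrix(0, S, S)
  for (i in 1:n)
    P <- P + Mod(stats::fft(dpcnet:::vec_to_frame(wds$frames[1, , i], c(S, S))))^2
  ratio <- mean(P[f > 0.2 & f < 0.3]) / mean(P[f > 0.05 & f <= 0.15])
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
  ## temporal filtering needs at least two frames
  expect_error(whiten_sequences(dpc_sequence(matrix(1, 1, S * S), c(S, S))),
               class = "dpc_invalid_argument")
})
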