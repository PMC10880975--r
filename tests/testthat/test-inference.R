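test_that("first-step inference solves the sparse reconstruction problem", {
  sh <- dpc_shape(M = 4, N = 3, N_h = 2, K = 1)
  p <- dpc_params(sh, seed = 1)
  hy <- dpc_hyper(lambda = 0.1)
  ## zero input with a sparse prior keeps the estimate at zero
  out <- infer_first_step(rep(0, 4), p, hy)
  expect_equal(out$r_hat, rep(0, 3))
  ## scalar case, lambda = 0: the minimizer is r = I / U
  sh1 <- dpc_shape(M = 1, N = 1, N_h = 1, K = 1)
  p1 <- dpc_params(sh1, seed = 1); p1$U <- matrix(1)
  hy1 <- dpc_hyper(sigma2 = 1, lambda = 0)
  o1 <- infer_first_step(3, p1, hy1,
                         dpc_options(lr_r = 0.5, max_iters = 500, tol = 1e-10))
  expect_equal(o1$r_hat, 3, tolerance = 1e-6)
  ## lasso zero-solution condition: lambda >= ||U' I||_inf / sigma2
  set.seed(2)
  I0 <- rnorm(4)
  lam <- max(abs(crossprod(p$U, I0))) / 0.1 * 1.01
  hyz <- dpc_hyper(sigma2 = 0.1, lambda = lam)
  oz <- infer_first_step(I0, p, hyz)
  expect_equal(oz$r_hat, rep(0, 3))
  ## recorded loss is non-increasing with backtracking
  o2 <- infer_first_step(I0, p, dpc_hyper(lambda = 0.01),
                         dpc_options(backtrack = TRUE, max_iters = 100))
  expect_true(all(diff(o2$loss_history) <= 1e-10))
})

test_that("step inference reduces to first-step inference when the temporal and prior terms vanish", {
  p <- make_teacher(seed = 4)
  set.seed(8)
  I <- rnorm(16)
  hy <- dpc_hyper(sigma2 = 0.1, sigma_r2 = 1e9, lambda = 0.005, lambda_h = 0)
  opts <- dpc_options(lr_r = 0.02, lr_rh = 0.01, max_iters = 2000, tol = 1e-12,
                      backtrack = FALSE)
  st <- infer_step(I, rnorm(8), rnorm(2), p, hy, opts)
  fs <- infer_first_step(I, p, hy, opts)
  expect_equal(st$r_hat, fs$r_hat, tolerance = 1e-4)
})

test_that("step inference tracks model-generated data given the true higher-level state", {
  p <- make_teacher(seed = 5)
  hy <- dpc_hyper(sigma2 = 0.1, sigma_r2 = 0.1, lambda = 0, lambda_h = 0)
  opts <- dpc_options(lr_r = 0.02, lr_rh = 1e-9, max_iters = 4000, tol = 1e-12,
                      backtrack = FALSE)
  g <- sample_generative(p, 4, sigma2 = 0, sigma_r2 = 0, seed = 11)
  st <- infer_step(g$seq$frames[3, ], g$r[, 2], g$r_h, p, hy, opts)
  expect_lt(max(abs(st$r_hat - g$r[, 3])), 1e-4)
})

test_that("one descent step moves r_h against its gradient", {
  p <- make_teacher(seed = 6)
  set.seed(9)
  I <- rnorm(16); rprev <- abs(rnorm(8)); rh <- rnorm(2)
  hy <- dpc_hyper(sigma2 = 0.5, sigma_r2 = 0.5, lambda = 0, lambda_h = 0.5)
  ## freeze r at its warm start (lr_r tiny), run one iteration
  opts <- dpc_options(lr_r = 1e-12, lr_rh = 1e-3, max_iters = 1, tol = 0,
                      backtrack = FALSE)
  st <- infer_step(I, rprev, rh, p, hy, opts)
  ## finite-difference gradient of the loss w.r.t. rh at the warm start
  V0 <- mix_transitions(hypernet_forward(rh, p$theta), p$V_set)
  r0 <- transition_mean(rprev, V0)
  f <- function(x) {
    V <- mix_transitions(hypernet_forward(x, p$theta), p$V_set)
    step_loss(I, r0, transition_mean(rprev, V), x, p, hy)
  }
  num <- vapply(1:2, function(i) {
    e <- rep(0, 2); e[i] <- 1e-6
    (f(rh + e) - f(rh - e)) / 2e-6
  }, numeric(1))
  expect_equal(st$r_h_hat - rh, -1e-3 * num, tolerance = 1e-4)
})

test_that("filtering a sequence is causal and order-sensitive", {
  p <- make_teacher(seed = 7)
  hy <- teacher_hyper()
  opts <- dpc_options(lr_r = 0.02, lr_rh = 0.05, max_iters = 50, tol = 1e-6,
                      backtrack = FALSE)
  g <- sample_generative(p, 8, sigma2 = 1e-3, sigma_r2 = 1e-3, seed = 13)
  tr_full <- filter_sequence(g$seq, p, hy, opts)
  tr_prefix <- filter_sequence(g$seq$frames[1:5, ], p, hy, opts)
  expect_equal(tr_prefix$r_hat, tr_full$r_hat[, 1:5])
  expect_equal(tr_prefix$r_h_hat, tr_full$r_h_hat[, 1:5])
  tr_rev <- filter_sequence(g$seq$frames[8:1, ], p, hy, opts)
  expect_gt(max(abs(tr_rev$r_hat[, 8:1] - tr_full$r_hat)), 1e-3)
  ## first prediction is the zero vector; trajectory series share length
  expect_equal(tr_full$r_bar[, 1], rep(0, 8))
  expect_equal(ncol(tr_full$w), 8)
  expect_true(all(tr_full$pred_err_l2 >= 0))
})

test_that("an all-zero sequence yields silent responses and zero errors", {
  p <- make_teacher(seed = 8)
  hy <- dpc_hyper(sigma2 = 0.1, sigma_r2 = 1, lambda = 0.05, lambda_h = 0.01)
  tr <- filter_sequence(matrix(0, 5, 16), p, hy,
                        dpc_options(max_iters = 100, backtrack = FALSE))
  expect_equal(tr$r_hat, matrix(0, 8, 5))
  expect_equal(tr$pred_err_l2, rep(0, 5))
})

test_that("batched filtering agrees with per-sequence filtering", {
  p <- make_teacher(seed = 10)
  hy <- teacher_hyper()
  opts <- dpc_options(lr_r = 0.02, lr_rh = 0.05, max_iters = 40, tol = 1e-6,
                      backtrack = FALSE)
  ds <- teacher_dataset(p, 3, 500)
  lat <- filter_dataset(ds, p, hy, opts)
  for (i in 1:3) {
    tr <- filter_sequence(get_sequence(ds, i), p, hy, opts)
    expect_equal(lat$r_hat[, , i], tr$r_hat, tolerance = 1e-10)
    expect_equal(lat$r_h_hat[, , i], tr$r_h_hat, tolerance = 1e-10)
  }
})

test_that("mixing weights are recovered on sequences from a known small model", {
  p <- make_teacher()
  hy <- teacher_hyper()
  opts <- dpc_options(lr_r = 0.02, lr_rh = 0.05, max_iters = 1500, tol = 1e-9,
                      backtrack = FALSE)
  cs <- vapply(1:10, function(i) {
    g <- sample_generative(p, 10, sigma2 = 1e-4, sigma_r2 = 1e-4, seed = i)
    tr <- filter_sequence(g$seq, p, hy, opts)
    dpcnet:::cosine_sim(g$w, tr$w[, 10])
  }, numeric(1))
  expect_gt(mean(cs), 0.9)
})
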