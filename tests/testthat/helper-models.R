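## Shared fixtures: a stabilized teacher network for self-consistency
## checks, and lazily trained sprite/bouncing networks reused by the
## acceptance tests (cached across test files within one run).

.dpc_test_cache <- new.env(parent = emptyenv())

cache_get <- function(key, fn) {
  if (!exists(key, envir = .dpc_test_cache))
    assign(key, fn(), envir = .dpc_test_cache)
  get(key, envir = .dpc_test_cache)
}

## Small generative teacher with well-conditioned, stable modulated
## dynamics (worst-case spectral radius of the mixed transition <= 0.95).
make_teacher <- function(seed = 1, N = 8, N_h = 2, K = 2, M = 16) {
  sh <- dpc_shape(M = M, N = N, N_h = N_h, K = K, hidden = 4)
  p <- dpc_params(sh, seed = seed)
  set.seed(seed + 100)
  p$V_set <- lapply(seq_len(K), function(k) {
    P <- diag(N)[sample(N), ]
    0.7 * P + 0.3 * diag(N)
  })
  for (l in seq_along(p$theta)) {
    p$theta[[l]]$W <- matrix(rnorm(length(p$theta[[l]]$W), sd = 0.8),
                             nrow(p$theta[[l]]$W))
    p$theta[[l]]$b <- rnorm(length(p$theta[[l]]$b), sd = 0.3)
  }
  p$theta[[length(p$theta)]]$b <- rep(0.6, K)
  rad <- max(vapply(1:50, function(i) {
    w <- hypernet_forward(rnorm(N_h), p$theta)
    max(Mod(eigen(mix_transitions(w, p$V_set), only.values = TRUE)$values))
  }, numeric(1)))
  p$V_set <- lapply(p$V_set, function(V) V * 0.95 / rad)
  p
}

teacher_hyper <- function() dpc_hyper(sigma2 = 0.1, sigma_r2 = 0.1,
                                      lambda = 0.001, lambda_h = 1e-4)

teacher_dataset <- function(p, n, seed0) {
  M <- p$shape$M
  frames <- array(0, c(10, M, n))
  for (i in seq_len(n))
    frames[, , i] <- sample_generative(p, 10, sigma2 = 1e-4, sigma_r2 = 1e-4,
                                       seed = seed0 + i)$seq$frames
  dpc_dataset(frames, c(1, M))
}

## Experiment-scale settings for the sprite studies (see methods vignette).
sprite_shape <- function() dpc_shape(M = 324, N = 64, N_h = 16, K = 5,
                                     hidden = 32)
train_opts <- function() dpc_options(lr_r = 0.05, lr_rh = 0.1, max_iters = 25,
                                     tol = 1e-5, backtrack = FALSE)
eval_opts <- function(max_iters = 60) dpc_options(lr_r = 0.05, lr_rh = 0.1,
                                                  max_iters = max_iters,
                                                  tol = 1e-6, backtrack = FALSE)

## One seeded sprite study: train on 2000 sprite sequences, filter held-out
## sprites and white-noise stimuli, cache the lot.
sprite_run <- function(seed) cache_get(paste0("sprite", seed), function() {
  hy <- dpc_hyper()
  ds <- make_moving_sprites(sprite_spec(2000, seed = 100 * seed + 11))
  fit <- train_two_level(ds, sprite_shape(), hy, train_opts(),
                         n_epochs = 6, batch_size = 200, lr = 5e-3,
                         seed = seed)
  held <- make_moving_sprites(sprite_spec(300, seed = 100 * seed + 77))
  lat <- filter_dataset(held, fit$params, hy, eval_opts())
  J <- 100
  nf <- array(0, c(50, 324, J))
  for (j in seq_len(J))
    nf[, , j] <- make_white_noise(50, 324, seed = 100 * seed + 300 + j)$frames
  lat_noise <- filter_dataset(dpc_dataset(nf, c(18, 18)), fit$params, hy,
                              eval_opts())
  list(params = fit$params, held = held, lat = lat, lat_noise = lat_noise)
})

## Two-level base network trained on mixed bouncing data plus the gating
## threshold; shared by the three-level acceptance runs.
bounce_base <- function() cache_get("bounce_base", function() {
  hy <- dpc_hyper()
  mk <- function(rule, n, seed)
    make_bouncing_dataset(sprite_spec(n, T_len = 20, seed = seed),
                          bounce_rule = rule)
  str_tr <- mk("straight", 600, 21)
  clk_tr <- mk("clockwise", 600, 22)
  mixed <- dpc_dataset(array(c(str_tr$frames, clk_tr$frames),
                             c(20, 324, 1200)), c(18, 18),
                       labels = rbind(str_tr$labels, clk_tr$labels),
                       metadata = c(str_tr$metadata, clk_tr$metadata))
  fit <- train_two_level(mixed, sprite_shape(), hy, train_opts(),
                         n_epochs = 12, batch_size = 200, lr = 5e-3, seed = 1)
  sub <- subset_dataset(mixed, seq(1, 1200, by = 4))
  lat <- filter_dataset(sub, fit$params, hy, eval_opts())
  rel <- relative_pred_err(lat, sub)
  rho <- estimate_threshold(as.vector(rel[3:20, ]), 0.75)
  list(base = fit$params, rho = rho)
})

trials_array <- function(a) aperm(a, c(3, 2, 1))  # N x T x B -> B x T x N

## Teacher-student protocol: train a student from scratch on teacher data,
## score held-out one-step prediction R^2 (cached; used by the training
## tests and the generative self-consistency acceptance check).
teacher_student_run <- function() cache_get("ts_run", function() {
  p <- make_teacher()
  hy_tr <- dpc_hyper(sigma2 = 0.1, sigma_r2 = 1, lambda = 0.001,
                     lambda_h = 1e-4)
  train <- teacher_dataset(p, 1000, 1000)
  test <- teacher_dataset(p, 50, 9000)
  fit <- train_two_level(train, p$shape, hy_tr,
                         dpc_options(lr_r = 0.05, lr_rh = 0.1, max_iters = 60,
                                     tol = 1e-6, backtrack = FALSE),
                         n_epochs = 60, batch_size = 50, lr = 1e-2, seed = 1)
  r2 <- prediction_r2(fit$params, test, hy_tr,
                      dpc_options(lr_r = 0.05, lr_rh = 0.1, max_iters = 300,
                                  tol = 1e-8, backtrack = FALSE))
  list(teacher = p, fit = fit, r2 = r2)
})
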