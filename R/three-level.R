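#' Parameters of the three-level DPC extension
#'
#' Adds to a trained two-level network: `K2` second-level transition
#' matrices, a second hypernetwork mapping the third-level state `r^(3)` to
#' second-level modulation weights `w^(2)`, and a first-level
#' prediction-error threshold `rho` that gates second-level transitions
#' (the analogue of terminal states in a hierarchical HMM: the second
#' level transitions only when the first level fails to predict).
#'
#' @param base Trained two-level `dpc_params` (levels 1-2).
#' @param N3 Third-level state dimensionality.
#' @param K2 Number of second-level transition matrices (default 2).
#' @param rho First-level prediction-error threshold (> 0); see
#'   [estimate_threshold()].
#' @param sigma_r2_level2 Second-level transition-noise variance.
#' @param hidden2 Hidden width of the second hypernetwork.
#' @param lambda_3 Gaussian prior penalty on `r^(3)` during inference.
#' @param seed Seed for initializing the new components.
#' @return Object of class `dpc3_params`.
#' @export
three_level_params <- function(base, N3 = 8, K2 = 2, rho,
                               sigma_r2_level2 = 1, hidden2 = 16,
                               lambda_3 = 0.01, seed = 1) {
  stopifnot(inherits(base, "dpc_params"))
  K2 <- check_positive_int(K2, "K2")
  N3 <- check_positive_int(N3, "N3")
  if (rho <= 0) stop_invalid("rho must be > 0")
  N_h <- base$shape$N_h
  with_seed(seed, {
    V2_set <- lapply(seq_len(K2), function(k)
      diag(N_h) + matrix(stats::rnorm(N_h^2, sd = 0.05 / sqrt(N_h)), N_h, N_h))
    theta2 <- init_hypernet(N3, K2, hidden2)
    structure(list(base = base, V2_set = V2_set, theta2 = theta2,
                   N3 = N3, K2 = K2, rho = rho,
                   sigma_r2_level2 = sigma_r2_level2, lambda_3 = lambda_3),
              class = "dpc3_params")
  })
}

#' Estimate the transition-gating threshold from training errors
#'
#' The threshold `rho` is the empirical quantile (linear interpolation) of
#' per-step first-level prediction errors collected on the training set;
#' steps whose error exceeds it are treated as changes of dynamics.
#'
#' @param first_level_errors Numeric vector of per-step prediction errors.
#' @param quantile Cumulative density at which to cut (default 0.75).
#' @return The threshold `rho`.
#' @export
estimate_threshold <- function(first_level_errors, quantile = 0.75) {
  first_level_errors <- first_level_errors[is.finite(first_level_errors)]
  if (!length(first_level_errors)) stop_invalid("no errors supplied")
  unname(stats::quantile(first_level_errors, probs = quantile, type = 7))
}

#' Gated second-level step loss
#'
#' The per-step loss of the three-level model: first-level reconstruction
#' and transition terms are always on; the second-level transition term is
#' multiplied by the binary gate `b_t`; the sparsity penalty applies to the
#' first-level state.
#'
#' @param I_t Frame vector.
#' @param r1,r1_bar First-level state and its top-down prediction.
#' @param r2,r2_bar Second-level state and its (gated) prediction.
#' @param b_t Gate, 0 or 1.
#' @param U Spatial filters.
#' @param hyper A [dpc_hyper()].
#' @param sigma_r2_level2 Second-level transition-noise variance.
#' @return Scalar loss.
#' @export
masked_level2_loss <- function(I_t, r1, r1_bar, r2, r2_bar, b_t, U, hyper,
                               sigma_r2_level2 = 1) {
  if (!b_t %in% c(0, 1)) stop_invalid("b_t must be 0 or 1")
  0.5 / hyper$sigma2 * l2sq(I_t - decode_image(r1, U)) +
    0.5 / hyper$sigma_r2 * l2sq(r1 - r1_bar) +
    b_t * 0.5 / sigma_r2_level2 * l2sq(r2 - r2_bar) +
    hyper$lambda * sum(abs(r1))
}

#' Relative first-level prediction errors of a filtered dataset
#'
#' The gating signal of the three-level model: the L2 norm of the image
#' prediction error at each step divided by the frame norm (floored at 1
#' so empty frames cannot inflate the ratio). Normalizing makes one
#' threshold work across stimuli of different contrast and size.
#'
#' @param lat Output of [filter_dataset()] (uses `pred_err`).
#' @param ds The corresponding [dpc_dataset()].
#' @return `T x n` matrix of relative errors.
#' @export
relative_pred_err <- function(lat, ds) {
  nrm <- sqrt(apply(ds$frames^2, c(1, 3), sum))
  lat$pred_err / pmax(nrm, 1)
}

## First-level (relative) prediction errors and second-level latents for a
## dataset under the two-level filter; threshold estimation / pretraining.
collect_level2_stats <- function(ds, base, hyper, opts) {
  lat <- filter_dataset(ds, base, hyper, opts)
  list(pred_err = relative_pred_err(lat, ds), r2 = lat$r_h_hat, lat = lat)
}

#' Pretrain second-level transition matrices, one per bounce type
#'
#' For each bounce type separately, runs the two-level filter over the
#' corpus, gates steps whose first-level prediction error exceeds `rho`,
#' and learns a single second-level transition matrix `V2` by gradient
#' descent on the gated second-level prediction error
#' `sum_t b_t ||r2_t - V2 r2_{t-1}||^2`, with the latents held at their
#' MAP estimates.
#'
#' @param straight_ds,clockwise_ds Datasets of the two bounce types.
#' @param base Trained two-level `dpc_params`.
#' @param hyper,opts Model hyperparameters and inference options.
#' @param rho Gating threshold (see [estimate_threshold()]).
#' @param sigma_r2_level2 Second-level noise variance.
#' @param n_iters Gradient iterations (Adam).
#' @param lr Learning rate (0 leaves the matrices at initialization).
#' @return List with `V2_set` (straight then clockwise), the gated-step
#'   counts, and the final losses.
#' @export
pretrain_second_level <- function(straight_ds, clockwise_ds, base, hyper,
                                  opts, rho, sigma_r2_level2 = 1,
                                  n_iters = 300, lr = 0.05) {
  fit_one <- function(ds) {
    st <- collect_level2_stats(ds, base, hyper, opts)
    d <- dim(st$r2)  # N_h x T x B
    N_h <- d[1]; T_len <- d[2]; B <- d[3]
    prev <- list(); cur <- list()
    for (t in 2:T_len) {
      flag <- st$pred_err[t, ] > rho
      if (any(flag)) {
        prev[[length(prev) + 1L]] <- matrix(st$r2[, t - 1, flag], N_h)
        cur[[length(cur) + 1L]] <- matrix(st$r2[, t, flag], N_h)
      }
    }
    if (!length(prev))
      stop_invalid("no steps exceeded rho; use longer sequences or a lower threshold")
    Rp <- do.call(cbind, prev); Rc <- do.call(cbind, cur)
    V2 <- diag(N_h)
    stt <- adam_state(list(V2))[[1]]
    n_ev <- ncol(Rp)
    loss <- NA_real_
    for (it in seq_len(n_iters)) {
      E <- (V2 %*% Rp - Rc) / sigma_r2_level2
      loss <- 0.5 * sigma_r2_level2 * l2sq(E) / n_ev
      if (lr > 0) {
        up <- adam_step(V2, (E %*% t(Rp)) / n_ev, stt, lr, it)
        V2 <- up$x; stt <- up$state
      }
    }
    list(V2 = V2, n_events = n_ev, loss = loss)
  }
  a <- fit_one(straight_ds); b <- fit_one(clockwise_ds)
  list(V2_set = list(a$V2, b$V2), n_events = c(a$n_events, b$n_events),
       loss = c(a$loss, b$loss))
}

## Mixed second-level prediction and gradients, batched.
## r3: N3 x B, r2_prev: N_h x B. Returns r2_bar and a closure context.
level2_prediction <- function(r3, r2_prev, p3) {
  cache <- hypernet_forward_cache(r3, p3$theta2)
  w2 <- cache$w
  V2kR <- lapply(p3$V2_set, function(V) V %*% r2_prev)
  r2_bar <- V2kR[[1]] * rep(w2[1, ], each = nrow(r2_prev))
  for (k in seq_along(V2kR)[-1])
    r2_bar <- r2_bar + V2kR[[k]] * rep(w2[k, ], each = nrow(r2_prev))
  list(r2_bar = r2_bar, w2 = w2, V2kR = V2kR, cache = cache)
}

#' Three-level filtering of a sequence or batch
#'
#' Runs the gated three-level inference: at each step the first-level
#' prediction error decides (`> rho`) whether the second level transitions
#' under the dynamics predicted by the third level; the third-level state
#' persists across the sequence and is corrected only by gated
#' second-level prediction errors.
#'
#' @param x A [dpc_sequence()], frame matrix, or [dpc_dataset()] (batched).
#' @param p3 A [three_level_params()].
#' @param hyper,opts Model hyperparameters and inference options; `lr_rh`
#'   is used for both the second- and third-level updates.
#' @param force_b Optional fixed gate value (0 disables all second-level
#'   transitions; used for reduction checks); `NULL` gates by `rho`.
#' @param lambda_h_level2 Gaussian penalty applied to `r^(2)` during
#'   inference (0 by default; set to `hyper$lambda_h` to reproduce the
#'   two-level filter when `force_b = 0`).
#' @return For a single sequence, a `dpc3_trajectory`: matrices `r1`
#'   (N x T), `r2` (N_h x T), `r3` (N3 x T), `w1` (K x T), `w2` (K2 x T),
#'   gates `b` and `pred_err`. For a dataset, arrays with a trailing
#'   sequence dimension.
#' @export
infer_three_level <- function(x, p3, hyper, opts = dpc_options(),
                              force_b = NULL, lambda_h_level2 = 0) {
  base <- p3$base
  s <- base$shape
  batched <- inherits(x, "dpc_dataset")
  frames <- if (batched) x$frames
            else if (inherits(x, "dpc_sequence")) array(x$frames, c(dim(x$frames), 1))
            else array(as.matrix(x), c(dim(as.matrix(x)), 1))
  T_len <- dim(frames)[1]; M <- dim(frames)[2]; B <- dim(frames)[3]
  U <- base$U
  r1 <- array(0, c(s$N, T_len, B))
  r2 <- array(0, c(s$N_h, T_len, B))
  r3 <- array(0, c(p3$N3, T_len, B))
  w1 <- array(0, c(s$K, T_len, B))
  w2 <- array(0, c(p3$K2, T_len, B))
  bmat <- matrix(0, T_len, B)
  pred_err <- matrix(0, T_len, B)
  opts$backtrack <- FALSE

  I1 <- matrix(frames[1, , ], M, B)
  r1[, 1, ] <- infer_first_step(I1, base, hyper, opts)$r_hat
  pred_err[1, ] <- sqrt(colSums(I1^2))
  r2_cur <- matrix(0, s$N_h, B)
  r3_cur <- matrix(0, p3$N3, B)
  w1[, 1, ] <- hypernet_forward(r2_cur, base$theta)
  w2[, 1, ] <- hypernet_forward(r3_cur, p3$theta2)

  if (T_len > 1) for (t in 2:T_len) {
    It <- matrix(frames[t, , ], M, B)
    r1_prev <- matrix(r1[, t - 1, ], s$N, B)
    r2_prev <- r2_cur
    Vk_rprev <- lapply(base$V_set, function(V) V %*% r1_prev)

    pre <- grad_step_rh(matrix(0, s$N, B), r2_prev, r1_prev, base, hyper,
                        Vk_rprev)
    pred_err[t, ] <- sqrt(colSums((It - U %*% pre$r_bar)^2))
    rel_err <- pred_err[t, ] / pmax(sqrt(colSums(It^2)), 1)
    bvec <- if (is.null(force_b)) as.numeric(rel_err > p3$rho)
            else rep(as.numeric(force_b), B)
    bmat[t, ] <- bvec
    brow_N_h <- rep(bvec, each = s$N_h)

    l2p <- level2_prediction(r3_cur, r2_prev, p3)
    ## gated second level: transition prediction where flagged, hold where not
    r2_bar_init <- l2p$r2_bar * brow_N_h + r2_prev * (1 - brow_N_h)
    r1_cur <- pre$r_bar
    r2_c <- r2_bar_init
    r3_c <- r3_cur
    for (it in seq_len(opts$max_iters)) {
      gb <- grad_step_rh(r1_cur, r2_c, r1_prev, base, hyper, Vk_rprev)
      g_r1 <- crossprod(U, U %*% r1_cur - It) / hyper$sigma2 +
        (r1_cur - gb$r_bar) / hyper$sigma_r2
      l2p <- level2_prediction(r3_c, r2_prev, p3)
      g_r2 <- gb$d_rh - 2 * hyper$lambda_h * r2_c +    # d_rh included lambda_h
        2 * lambda_h_level2 * r2_c +
        ((r2_c - l2p$r2_bar) / p3$sigma_r2_level2) * brow_N_h
      e2 <- ((l2p$r2_bar - r2_c) / p3$sigma_r2_level2) * brow_N_h
      dw2 <- do.call(rbind, lapply(l2p$V2kR, function(v) colSums(v * e2)))
      bk2 <- hypernet_backward(dw2, p3$theta2, l2p$cache)
      g_r3 <- bk2$d_rh + 2 * p3$lambda_3 * r3_c
      r1_new <- l1_step(r1_cur, g_r1, opts$lr_r, hyper$lambda, opts$prox_l1)
      r2_new <- r2_c - opts$lr_rh * g_r2
      r3_new <- r3_c - opts$lr_rh * g_r3
      delta <- max(max(abs(r1_new - r1_cur)), max(abs(r2_new - r2_c)),
                   max(abs(r3_new - r3_c)))
      r1_cur <- r1_new; r2_c <- r2_new; r3_c <- r3_new
      if (delta < opts$tol) break
    }
    r1[, t, ] <- r1_cur
    r2_cur <- r2_c; r3_cur <- r3_c
    r2[, t, ] <- r2_c; r3[, t, ] <- r3_c
    w1[, t, ] <- hypernet_forward(r2_c, base$theta)
    w2[, t, ] <- hypernet_forward(r3_c, p3$theta2)
  }
  ## copy step-1 carried states
  r2[, 1, ] <- 0; r3[, 1, ] <- 0
  out <- list(r1 = r1, r2 = r2, r3 = r3, w1 = w1, w2 = w2,
              b = bmat, pred_err = pred_err)
  if (!batched && B == 1) {
    out <- list(r1 = out$r1[, , 1], r2 = out$r2[, , 1],
                r3 = matrix(out$r3[, , 1], p3$N3, T_len),
                w1 = out$w1[, , 1],
                w2 = matrix(out$w2[, , 1], p3$K2, T_len),
                b = out$b[, 1], pred_err = out$pred_err[, 1])
    class(out) <- "dpc3_trajectory"
  }
  out
}

#' Train the third-level top-down network
#'
#' Alternates batched three-level inference with Adam updates of the
#' second hypernetwork (and optionally the second-level transition
#' matrices) on the summed gated loss at the MAP latents.
#'
#' @param ds Training [dpc_dataset()] (mixed bounce types).
#' @param p3 A [three_level_params()] with pretrained `V2_set`.
#' @param hyper,opts Model hyperparameters and inference options.
#' @param n_epochs,batch_size,lr Optimization settings (`lr = 0` leaves
#'   parameters unchanged).
#' @param finetune_V2 Also update the second-level transition matrices.
#' @param seed Shuffling seed.
#' @return List with updated `p3` and a history data frame of epoch mean
#'   gated second-level losses.
#' @export
train_three_level <- function(ds, p3, hyper, opts = dpc_options(max_iters = 30,
                                                                tol = 1e-4),
                              n_epochs = 5, batch_size = 64, lr = 1e-2,
                              finetune_V2 = FALSE, seed = 1) {
  if (!inherits(ds, "dpc_dataset") || n_sequences(ds) < 1)
    stop_invalid("training needs a non-empty dpc_dataset")
  if (lr < 0) stop_invalid("lr must be >= 0")
  n <- n_sequences(ds)
  st_theta <- lapply(p3$theta2, function(l)
    list(W = adam_state(list(l$W))[[1]], b = adam_state(list(l$b))[[1]]))
  st_V2 <- adam_state(p3$V2_set)
  history <- numeric(n_epochs)
  step_count <- 0L
  for (ep in seq_len(n_epochs)) {
    ord <- with_seed(derive_seed(seed, paste0("l3epoch", ep)), sample.int(n))
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    ep_loss <- 0; ep_n <- 0
    for (bi in batches) {
      sub <- subset_dataset(ds, bi)
      lat <- infer_three_level(sub, p3, hyper, opts)
      d <- dim(lat$r2); T_len <- d[2]; B <- d[3]
      dtheta <- lapply(p3$theta2, function(l) list(W = l$W * 0, b = l$b * 0))
      dV2 <- lapply(p3$V2_set, function(V) V * 0)
      loss <- 0
      for (t in 2:T_len) {
        bvec <- lat$b[t, ]
        if (!any(bvec > 0)) next
        r3_t <- matrix(lat$r3[, t, ], p3$N3, B)
        r2_prev <- matrix(lat$r2[, t - 1, ], dim(lat$r2)[1], B)
        r2_t <- matrix(lat$r2[, t, ], dim(lat$r2)[1], B)
        l2p <- level2_prediction(r3_t, r2_prev, p3)
        E <- ((l2p$r2_bar - r2_t) / p3$sigma_r2_level2) *
          rep(bvec, each = nrow(r2_t))
        loss <- loss + 0.5 * p3$sigma_r2_level2 * l2sq(E)
        dw2 <- do.call(rbind, lapply(l2p$V2kR, function(v) colSums(v * E)))
        bk <- hypernet_backward(dw2, p3$theta2, l2p$cache, want_theta = TRUE)
        for (l in seq_along(dtheta)) {
          dtheta[[l]]$W <- dtheta[[l]]$W + bk$d_theta[[l]]$W
          dtheta[[l]]$b <- dtheta[[l]]$b + bk$d_theta[[l]]$b
        }
        if (finetune_V2) for (k in seq_along(dV2))
          dV2[[k]] <- dV2[[k]] +
            (E * rep(l2p$w2[k, ], each = nrow(r2_t))) %*% t(r2_prev)
      }
      ep_loss <- ep_loss + loss; ep_n <- ep_n + B
      if (lr > 0) {
        step_count <- step_count + 1L
        for (l in seq_along(p3$theta2)) {
          up <- adam_step(p3$theta2[[l]]$W, dtheta[[l]]$W / B,
                          st_theta[[l]]$W, lr, step_count)
          p3$theta2[[l]]$W <- up$x; st_theta[[l]]$W <- up$state
          up <- adam_step(p3$theta2[[l]]$b, dtheta[[l]]$b / B,
                          st_theta[[l]]$b, lr, step_count)
          p3$theta2[[l]]$b <- up$x; st_theta[[l]]$b <- up$state
        }
        if (finetune_V2) for (k in seq_along(p3$V2_set)) {
          up <- adam_step(p3$V2_set[[k]], dV2[[k]] / B, st_V2[[k]], lr,
                          step_count)
          p3$V2_set[[k]] <- up$x; st_V2[[k]] <- up$state
        }
      }
    }
    history[ep] <- ep_loss / max(ep_n, 1)
  }
  list(p3 = p3,
       history = data.frame(epoch = seq_len(n_epochs), mean_loss = history))
}
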