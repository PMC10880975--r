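#' Spatially and temporally whiten image sequences
#'
#' Emulates retinal/LGN preprocessing of natural movies: each frame is
#' filtered in the 2-D frequency domain with the amplitude profile
#' `|f| * exp(-(f / f0)^4)` (a ramp that flattens the 1/f spectrum of
#' natural images, rolled off before the Nyquist frequency), then each
#' pixel's time series is passed through a first-order temporal
#' decorrelation filter `y_t = x_t - a * x_{t-1}` (first frame kept as is).
#' The DC component is removed by the spatial ramp, so whitened sequences
#' have approximately zero mean. The whole operation is linear.
#'
#' @param x A [dpc_dataset()] or [dpc_sequence()].
#' @param f0 Spatial roll-off frequency in cycles/pixel (default 0.8 times
#'   the Nyquist frequency, i.e. 0.4).
#' @param temporal Apply the temporal decorrelation filter (requires at
#'   least two frames).
#' @param temporal_coef AR coefficient `a` removed by the temporal filter.
#' @return An object of the same class with whitened frames; the filter
#'   settings are recorded in the metadata.
#' @export
whiten_sequences <- function(x, f0 = 0.4, temporal = TRUE,
                             temporal_coef = 0.8) {
  fs <- x$frame_shape
  H <- fs[1]; W <- fs[2]
  filt <- spatial_whitening_filter(H, W, f0)
  whiten_mat <- function(frames) {        # frames: T x M
    T_len <- nrow(frames)
    if (temporal && T_len < 2)
      stop_invalid("temporal whitening needs at least 2 frames")
    out <- frames
    for (t in seq_len(T_len)) {
      fr <- vec_to_frame(frames[t, ], fs)
      Ff <- stats::fft(fr) * filt
      out[t, ] <- frame_to_vec(Re(stats::fft(Ff, inverse = TRUE)) / (H * W))
    }
    if (temporal && T_len > 1)
      out[2:T_len, ] <- out[2:T_len, , drop = FALSE] -
        temporal_coef * out[1:(T_len - 1), , drop = FALSE]
    out
  }
  info <- list(whitened = TRUE, f0 = f0, temporal = temporal,
               temporal_coef = temporal_coef)
  if (inherits(x, "dpc_sequence")) {
    dpc_sequence(whiten_mat(x$frames), fs, metadata = c(x$metadata, info))
  } else if (inherits(x, "dpc_dataset")) {
    fr <- x$frames
    for (i in seq_len(dim(fr)[3]))
      fr[, , i] <- whiten_mat(matrix(x$frames[, , i], dim(fr)[1], dim(fr)[2]))
    out <- dpc_dataset(fr, fs, labels = x$labels, metadata = x$metadata)
    out$whitening <- info
    out
  } else stop_invalid("x must be a dpc_sequence or dpc_dataset")
}

## |f| exp(-(f/f0)^4) on the 2-D DFT grid (cycles/pixel); kills DC.
spatial_whitening_filter <- function(H, W, f0) {
  fy <- c(0:floor(H / 2), -(ceiling(H / 2) - 1):-1)[1:H] / H
  fx <- c(0:floor(W / 2), -(ceiling(W / 2) - 1):-1)[1:W] / W
  f <- sqrt(outer(fy^2, fx^2, "+"))
  f * exp(-(f / f0)^4)
}

## Total filtering loss and analytic gradients w.r.t. U, V_k, theta at
## fixed MAP latents, for one batch. frames: T x M x B array;
## lat: output of filter_dataset. Loss is summed over time and averaged
## across sequences.
loss_and_param_grads <- function(frames, lat, params, hyper) {
  d <- dim(frames); T_len <- d[1]; M <- d[2]; B <- d[3]
  s <- params$shape
  U <- params$U
  dU <- matrix(0, s$M, s$N)
  dV <- lapply(params$V_set, function(V) V * 0)
  dtheta <- lapply(params$theta, function(l) list(W = l$W * 0, b = l$b * 0))
  loss <- 0
  for (t in seq_len(T_len)) {
    It <- matrix(frames[t, , ], M, B)
    Rt <- matrix(lat$r_hat[, t, ], s$N, B)
    Erec <- (U %*% Rt - It) / hyper$sigma2
    dU <- dU + Erec %*% t(Rt)
    loss <- loss + 0.5 * hyper$sigma2 * l2sq(Erec) + hyper$lambda * sum(abs(Rt))
    if (t > 1) {
      Rprev <- matrix(lat$r_hat[, t - 1, ], s$N, B)
      RH <- matrix(lat$r_h_hat[, t, ], s$N_h, B)
      cache <- hypernet_forward_cache(RH, params$theta)
      w <- cache$w
      VkR <- lapply(params$V_set, function(V) V %*% Rprev)
      a <- VkR[[1]] * rep(w[1, ], each = s$N)
      for (k in seq_len(s$K)[-1]) a <- a + VkR[[k]] * rep(w[k, ], each = s$N)
      mask <- a > 0
      Rbar <- a * mask
      Gbar <- (Rbar - Rt) / hyper$sigma_r2
      Ga <- Gbar * mask
      loss <- loss + 0.5 * hyper$sigma_r2 * l2sq(Gbar) +
        hyper$lambda_h * l2sq(RH)
      for (k in seq_len(s$K))
        dV[[k]] <- dV[[k]] + (Ga * rep(w[k, ], each = s$N)) %*% t(Rprev)
      dw <- do.call(rbind, lapply(VkR, function(v) colSums(v * Ga)))
      bk <- hypernet_backward(dw, params$theta, list(acts = cache$acts),
                              want_theta = TRUE)
      for (l in seq_along(dtheta)) {
        dtheta[[l]]$W <- dtheta[[l]]$W + bk$d_theta[[l]]$W
        dtheta[[l]]$b <- dtheta[[l]]$b + bk$d_theta[[l]]$b
      }
    }
  }
  scale <- 1 / B
  list(loss = loss * scale,
       dU = dU * scale,
       dV = lapply(dV, function(g) g * scale),
       dtheta = lapply(dtheta, function(g)
         list(W = g$W * scale, b = g$b * scale)))
}

## Minimal Adam optimizer over a named list of numeric arrays.
adam_state <- function(template) {
  lapply(template, function(x) list(m = x * 0, v = x * 0))
}

adam_step <- function(x, g, st, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g * g
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  list(x = x - lr * mhat / (sqrt(vhat) + eps), state = st)
}

#' Train a two-level DPC network
#'
#' Alternates (i) batched MAP filtering of each minibatch under the current
#' parameters with (ii) one Adam update of the spatial filters `U`, the
#' transition matrices and the hypernetwork on the gradient of the summed
#' per-step losses evaluated at the MAP latents. Columns of `U` are
#' renormalized to unit L2 norm after every update to remove the
#' sparse-coding scale degeneracy.
#'
#' @param ds Training [dpc_dataset()] of equal-length sequences.
#' @param shape A [dpc_shape()] (ignored when `params` is supplied).
#' @param hyper A [dpc_hyper()].
#' @param opts Inference options used during filtering; backtracking is
#'   disabled in the batched inner loop.
#' @param n_epochs Number of passes over the data.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate for all parameters (`lr = 0` leaves the
#'   parameters untouched).
#' @param params Optional warm-start `dpc_params`.
#' @param seed Integer seed controlling initialization and minibatch
#'   shuffling.
#' @param verbose Print the mean loss each epoch.
#' @return List with `params` (trained `dpc_params`) and `history`
#'   (data frame of epoch mean losses).
#' @export
train_two_level <- function(ds, shape, hyper, opts = dpc_options(max_iters = 30,
                                                                 tol = 1e-4),
                            n_epochs = 10, batch_size = 64, lr = 1e-3,
                            params = NULL, seed = 1, verbose = FALSE) {
  if (!inherits(ds, "dpc_dataset") || n_sequences(ds) < 1)
    stop_invalid("training needs a non-empty dpc_dataset")
  if (lr < 0) stop_invalid("lr must be >= 0")
  n <- n_sequences(ds)
  params <- params %||% dpc_params(shape, seed = derive_seed(seed, "init"))
  st <- list(U = adam_state(list(params$U))[[1]],
             V = adam_state(params$V_set),
             theta = lapply(params$theta, function(l)
               list(W = adam_state(list(l$W))[[1]], b = adam_state(list(l$b))[[1]])))
  history <- numeric(n_epochs)
  step_count <- 0L
  for (ep in seq_len(n_epochs)) {
    ord <- with_seed(derive_seed(seed, paste0("epoch", ep)), sample.int(n))
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    ep_loss <- 0
    for (bi in batches) {
      sub <- subset_dataset(ds, bi)
      lat <- filter_dataset(sub, params, hyper, opts)
      g <- loss_and_param_grads(sub$frames, lat, params, hyper)
      if (!is.finite(g$loss))
        stop_divergence("training loss diverged (lr = ", format(lr), ")")
      ep_loss <- ep_loss + g$loss * length(bi)
      if (lr > 0) {
        step_count <- step_count + 1L
        up <- adam_step(params$U, g$dU, st$U, lr, step_count)
        params$U <- normalize_columns(up$x); st$U <- up$state
        for (k in seq_along(params$V_set)) {
          up <- adam_step(params$V_set[[k]], g$dV[[k]], st$V[[k]], lr, step_count)
          params$V_set[[k]] <- up$x; st$V[[k]] <- up$state
        }
        for (l in seq_along(params$theta)) {
          up <- adam_step(params$theta[[l]]$W, g$dtheta[[l]]$W,
                          st$theta[[l]]$W, lr, step_count)
          params$theta[[l]]$W <- up$x; st$theta[[l]]$W <- up$state
          up <- adam_step(params$theta[[l]]$b, g$dtheta[[l]]$b,
                          st$theta[[l]]$b, lr, step_count)
          params$theta[[l]]$b <- up$x; st$theta[[l]]$b <- up$state
        }
      }
    }
    history[ep] <- ep_loss / n
    if (verbose)
      message(sprintf("epoch %d/%d  mean loss %.4f", ep, n_epochs, history[ep]))
  }
  if (lr > 0) params$trained <- TRUE
  list(params = params,
       history = data.frame(epoch = seq_len(n_epochs), mean_loss = history))
}

#' One-step image prediction R-squared on held-out sequences
#'
#' Filters each sequence and compares the top-down predictions
#' `U r_bar_t` with the observed frames; returns the coefficient of
#' determination pooled over pixels, steps and sequences. The first
#' `t_min - 1` steps are excluded: the filter needs two frames to lock on
#' to a sequence's dynamics, so predictions before that measure adaptation
#' rather than the learned model.
#'
#' @param params Trained `dpc_params`.
#' @param ds Held-out [dpc_dataset()].
#' @param t_min First step entering the score (default 3).
#' @inheritParams train_two_level
#' @return Scalar R-squared.
#' @export
prediction_r2 <- function(params, ds, hyper, opts = dpc_options(max_iters = 50,
                                                                tol = 1e-5),
                          t_min = 3) {
  lat <- filter_dataset(ds, params, hyper, opts)
  d <- dim(ds$frames); T_len <- d[1]
  ss_res <- 0
  all_obs <- c()
  for (t in t_min:T_len) {
    It <- matrix(ds$frames[t, , ], d[2], d[3])
    Pt <- params$U %*% matrix(lat$r_bar[, t, ], params$shape$N, d[3])
    ss_res <- ss_res + l2sq(It - Pt)
    all_obs <- c(all_obs, as.vector(It))
  }
  1 - ss_res / l2sq(all_obs - mean(all_obs))
}
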