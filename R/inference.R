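#' Options controlling MAP inference
#'
#' Latent states are estimated per time step by gradient descent on the
#' step loss (prediction-error minimization). The L1 sparsity term is
#' handled by proximal soft-thresholding by default; with
#' `prox_l1 = FALSE` a subgradient step is used instead (subgradient at 0
#' defined as 0).
#'
#' @param lr_r Step size for lower-level state updates.
#' @param lr_rh Step size for higher-level state updates.
#' @param max_iters Inner-loop iteration cap per time step.
#' @param tol Convergence threshold on the max-abs change of the estimates
#'   between iterations.
#' @param prox_l1 Use the proximal soft-threshold for the L1 term.
#' @param backtrack Halve step sizes whenever a step would increase the
#'   loss (guarantees a non-increasing loss over accepted iterations).
#' @param joint Update `r_t` and `r_h` simultaneously (the default);
#'   `FALSE` alternates one `r_t` step with one `r_h` step.
#' @return An object of class `dpc_options`.
#' @export
dpc_options <- function(lr_r = 0.05, lr_rh = 0.01, max_iters = 300,
                        tol = 1e-5, prox_l1 = TRUE, backtrack = TRUE,
                        joint = TRUE) {
  if (lr_r <= 0 || lr_rh <= 0) stop_invalid("step sizes must be > 0")
  max_iters <- check_positive_int(max_iters, "max_iters")
  if (tol < 0) stop_invalid("tol must be >= 0")
  structure(list(lr_r = lr_r, lr_rh = lr_rh, max_iters = max_iters,
                 tol = tol, prox_l1 = isTRUE(prox_l1),
                 backtrack = isTRUE(backtrack), joint = isTRUE(joint)),
            class = "dpc_options")
}

## One proximal (or subgradient) L1 step on r given the smooth gradient.
l1_step <- function(r, grad, lr, lambda, prox) {
  if (prox) {
    soft_threshold(r - lr * grad, lr * lambda)
  } else {
    r - lr * (grad + lambda * sign(r))
  }
}

#' MAP estimate of the first-step latent state
#'
#' Minimizes the reduced first-step loss (reconstruction + sparsity) by
#' iterative descent from the zero vector.
#'
#' @param I_0 First frame vector (length `M`), or an `M x B` matrix to
#'   infer a batch of first frames in parallel.
#' @param params A `dpc_params`.
#' @param hyper A [dpc_hyper()].
#' @param opts A [dpc_options()].
#' @return For vector input, a list with `r_hat`, `loss_history`, `iters`;
#'   for matrix input `r_hat` is `N x B` and the loss history is summed
#'   over the batch.
#' @export
infer_first_step <- function(I_0, params, hyper, opts = dpc_options()) {
  I <- as_col(I_0)
  if (nrow(I) != nrow(params$U))
    stop_invalid("frame length ", nrow(I), " != M = ", nrow(params$U))
  U <- params$U
  r <- matrix(0, ncol(U), ncol(I))
  lr <- opts$lr_r
  loss_of <- function(r) {
    0.5 / hyper$sigma2 * l2sq(I - U %*% r) + hyper$lambda * sum(abs(r))
  }
  losses <- numeric(0)
  prev <- loss_of(r)
  iters <- 0L
  for (it in seq_len(opts$max_iters)) {
    g <- crossprod(U, U %*% r - I) / hyper$sigma2
    repeat {
      r_new <- l1_step(r, g, lr, hyper$lambda, opts$prox_l1)
      cur <- loss_of(r_new)
      if (!is.finite(cur))
        stop_divergence("non-finite loss during first-step inference (lr_r = ",
                        format(lr), ")")
      if (!opts$backtrack || cur <= prev + 1e-12) break
      lr <- lr / 2
      if (lr < 1e-12)
        stop_divergence("first-step inference cannot decrease the loss (lr_r = ",
                        format(lr), ")")
    }
    delta <- max(abs(r_new - r))
    r <- r_new; prev <- cur; losses <- c(losses, cur); iters <- it
    if (delta < opts$tol) break
  }
  list(r_hat = if (is.matrix(I_0)) r else drop(r),
       loss_history = losses, iters = iters)
}

#' One filtering step: joint MAP update of the lower- and higher-level state
#'
#' Computes the top-down prediction
#' `r_bar_t = ReLU(mix(H(r_h)) %*% r_prev_hat)` once before correction,
#' then descends the step loss jointly in `r_t` (warm-started at
#' `r_bar_t`) and `r_h` (warm-started at the carried estimate). During the
#' descent the temporal prediction is re-evaluated at the current `r_h`, so
#' prediction errors flow back to the higher level.
#'
#' @param I_t Frame vector at time t (length `M`), or `M x B` matrix.
#' @param r_prev_hat Converged lower-level estimate from step t-1
#'   (length `N` or `N x B`).
#' @param r_h_current Carried higher-level estimate (length `N_h` or
#'   `N_h x B`).
#' @inheritParams infer_first_step
#' @param record_rh Optionally record the `r_h` iterate at given fractions
#'   of `max_iters` (used by the latency sweep); `NULL` records nothing.
#' @return A list with `r_hat`, `r_h_hat`, `r_bar` (pre-correction
#'   prediction), `w` (modulation weights at the final `r_h`),
#'   `loss_history`, `iters`, `pred_err` (L2 norm of the pre-correction
#'   image prediction error) and, if requested, `rh_trace`.
#' @export
infer_step <- function(I_t, r_prev_hat, r_h_current, params, hyper,
                       opts = dpc_options(), record_rh = NULL) {
  I <- as_col(I_t)
  r_prev <- as_col(r_prev_hat)
  r_h <- as_col(r_h_current)
  U <- params$U
  if (nrow(I) != nrow(U)) stop_invalid("frame length != M")
  if (nrow(r_prev) != ncol(U)) stop_invalid("r_prev length != N")
  B <- ncol(I)
  Vk_rprev <- lapply(params$V_set, function(V) V %*% r_prev)

  rb0 <- grad_step_rh(matrix(0, nrow(r_prev), B), r_h, r_prev, params, hyper,
                      Vk_rprev)
  r_bar_pre <- rb0$r_bar
  pred_err <- sqrt(colSums((I - U %*% r_bar_pre)^2))

  loss_of <- function(r, r_bar, r_h) {
    0.5 / hyper$sigma2 * l2sq(I - U %*% r) +
      0.5 / hyper$sigma_r2 * l2sq(r - r_bar) +
      hyper$lambda * sum(abs(r)) + hyper$lambda_h * l2sq(r_h)
  }

  r <- r_bar_pre
  lr_r <- opts$lr_r; lr_rh <- opts$lr_rh
  track <- opts$backtrack || !isFALSE(opts$track_loss)
  prev <- if (track) loss_of(r, r_bar_pre, r_h) else NA_real_
  losses <- numeric(0)
  iters <- 0L
  rec_at <- if (!is.null(record_rh))
    pmax(0L, pmin(opts$max_iters, round(record_rh * opts$max_iters)))
  rh_trace <- if (!is.null(record_rh)) vector("list", length(rec_at))
  if (!is.null(record_rh)) {
    for (j in which(rec_at == 0L)) rh_trace[[j]] <- drop(r_h)
  }
  for (it in seq_len(opts$max_iters)) {
    gb <- grad_step_rh(r, r_h, r_prev, params, hyper, Vk_rprev)
    g_r <- crossprod(U, U %*% r - I) / hyper$sigma2 + (r - gb$r_bar) / hyper$sigma_r2
    repeat {
      r_new <- l1_step(r, g_r, lr_r, hyper$lambda, opts$prox_l1)
      if (opts$joint) {
        rh_new <- r_h - lr_rh * gb$d_rh
      } else {
        ## alternating: even iterations move r, odd iterations move r_h
        if (it %% 2L == 1L) rh_new <- r_h else { r_new <- r; rh_new <- r_h - lr_rh * gb$d_rh }
      }
      if (!track) { cur <- NA_real_; break }
      gb2 <- grad_step_rh(r_new, rh_new, r_prev, params, hyper, Vk_rprev)
      cur <- loss_of(r_new, gb2$r_bar, rh_new)
      if (!is.finite(cur))
        stop_divergence("non-finite loss during step inference (lr_r = ",
                        format(lr_r), ", lr_rh = ", format(lr_rh), ")")
      if (!opts$backtrack || cur <= prev + 1e-12) break
      lr_r <- lr_r / 2; lr_rh <- lr_rh / 2
      if (lr_r < 1e-12)
        stop_divergence("step inference cannot decrease the loss (lr_r = ",
                        format(lr_r), ")")
    }
    delta <- max(max(abs(r_new - r)), max(abs(rh_new - r_h)))
    r <- r_new; r_h <- rh_new; prev <- cur
    if (track) losses <- c(losses, cur)
    iters <- it
    if (!is.null(record_rh)) {
      for (j in which(rec_at == it)) rh_trace[[j]] <- drop(r_h)
    }
    if (delta < opts$tol) break
  }
  if (!is.null(record_rh)) {
    for (j in which(rec_at > iters)) rh_trace[[j]] <- drop(r_h)
  }
  vec_in <- !is.matrix(I_t)
  out <- list(r_hat = if (vec_in) drop(r) else r,
              r_h_hat = if (vec_in) drop(r_h) else r_h,
              r_bar = if (vec_in) drop(r_bar_pre) else r_bar_pre,
              w = if (vec_in) drop(hypernet_forward(r_h, params$theta))
                  else hypernet_forward(r_h, params$theta),
              loss_history = losses, iters = iters, pred_err = pred_err)
  if (!is.null(record_rh)) out$rh_trace <- rh_trace
  out
}

#' Filter a sequence: per-step MAP inference of both latent levels
#'
#' Runs first-step inference at t = 1, then the joint per-step correction
#' for t = 2..T, carrying the higher-level estimate across steps (Bayesian
#' filtering with a point-mass posterior approximation). The first entry of
#' the prediction series `r_bar` is the zero vector.
#'
#' @param seq A [dpc_sequence()] (or `T x M` matrix of frames).
#' @inheritParams infer_first_step
#' @param rh_init Initial higher-level state (default: zero vector).
#' @return A `dpc_trajectory`: list with matrices `r_hat` (N x T), `r_bar`
#'   (N x T), `r_h_hat` (N_h x T), `w` (K x T), vector `pred_err_l2`
#'   (per-step L2 norm of the image prediction error) and `loss_history`
#'   (list of per-step inner-loop losses).
#' @export
filter_sequence <- function(seq, params, hyper, opts = dpc_options(),
                            rh_init = NULL) {
  frames <- if (inherits(seq, "dpc_sequence")) seq$frames else as.matrix(seq)
  T_len <- nrow(frames)
  s <- params$shape
  rh <- rh_init %||% numeric(s$N_h)
  r_hat <- matrix(0, s$N, T_len)
  r_bar <- matrix(0, s$N, T_len)
  rh_hat <- matrix(0, s$N_h, T_len)
  w <- matrix(0, s$K, T_len)
  pred_err <- numeric(T_len)
  loss_history <- vector("list", T_len)

  fs <- infer_first_step(frames[1, ], params, hyper, opts)
  r_hat[, 1] <- fs$r_hat
  rh_hat[, 1] <- rh
  w[, 1] <- hypernet_forward(rh, params$theta)
  pred_err[1] <- sqrt(sum(frames[1, ]^2))   # prediction at t=1 is zero
  loss_history[[1]] <- fs$loss_history
  if (T_len > 1) for (t in 2:T_len) {
    st <- infer_step(frames[t, ], r_hat[, t - 1], rh, params, hyper, opts)
    r_hat[, t] <- st$r_hat
    r_bar[, t] <- st$r_bar
    rh <- st$r_h_hat
    rh_hat[, t] <- rh
    w[, t] <- st$w
    pred_err[t] <- st$pred_err
    loss_history[[t]] <- st$loss_history
  }
  structure(list(r_hat = r_hat, r_bar = r_bar, r_h_hat = rh_hat, w = w,
                 pred_err_l2 = pred_err, loss_history = loss_history),
            class = "dpc_trajectory")
}

#' @export
print.dpc_trajectory <- function(x, ...) {
  cat(sprintf("<dpc_trajectory> T=%d N=%d N_h=%d\n",
              ncol(x$r_hat), nrow(x$r_hat), nrow(x$r_h_hat)))
  invisible(x)
}

#' Filter a whole dataset in one vectorized batch
#'
#' Identical model to [filter_sequence()] but all sequences advance in
#' lock-step, which keeps the inner gradient loop in dense matrix algebra.
#' Backtracking is disabled in batch mode (fixed step sizes).
#'
#' @param ds A [dpc_dataset()].
#' @inheritParams infer_first_step
#' @param rh_init Optional `N_h x n` matrix of initial higher-level states.
#' @return A list of arrays: `r_hat` (N x T x n), `r_bar`, `r_h_hat`
#'   (N_h x T x n), `w` (K x T x n), `pred_err` (T x n matrix).
#' @export
filter_dataset <- function(ds, params, hyper, opts = dpc_options(),
                           rh_init = NULL) {
  frames <- ds$frames
  T_len <- dim(frames)[1]; B <- dim(frames)[3]
  s <- params$shape
  opts$backtrack <- FALSE
  opts$track_loss <- FALSE
  r_hat <- array(0, c(s$N, T_len, B))
  r_bar <- array(0, c(s$N, T_len, B))
  rh_hat <- array(0, c(s$N_h, T_len, B))
  w_arr <- array(0, c(s$K, T_len, B))
  pred_err <- matrix(0, T_len, B)

  I1 <- matrix(frames[1, , ], dim(frames)[2], B)
  fs <- infer_first_step(I1, params, hyper, opts)
  r_hat[, 1, ] <- fs$r_hat
  rh <- rh_init %||% matrix(0, s$N_h, B)
  rh_hat[, 1, ] <- rh
  w_arr[, 1, ] <- hypernet_forward(rh, params$theta)
  pred_err[1, ] <- sqrt(colSums(I1^2))
  if (T_len > 1) for (t in 2:T_len) {
    It <- matrix(frames[t, , ], dim(frames)[2], B)
    st <- infer_step(It, matrix(r_hat[, t - 1, ], s$N, B), rh, params, hyper, opts)
    r_hat[, t, ] <- st$r_hat
    r_bar[, t, ] <- st$r_bar
    rh <- st$r_h_hat
    rh_hat[, t, ] <- rh
    w_arr[, t, ] <- st$w
    pred_err[t, ] <- st$pred_err
  }
  list(r_hat = r_hat, r_bar = r_bar, r_h_hat = rh_hat, w = w_arr,
       pred_err = pred_err)
}
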