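#' Model dimensions for a two-level dynamic predictive coding network
#'
#' A dynamic predictive coding (DPC) network explains a vectorized image
#' sequence `I_t` (length `M` per frame) with a sparse lower-level state
#' `r_t` (length `N`) whose transition dynamics are a mixture of `K` learned
#' transition matrices. The mixture weights are produced from the
#' higher-level state `r_h` (length `N_h`) by a small feedback network (a
#' hypernetwork).
#'
#' @param M Input dimensionality: pixels per vectorized frame.
#' @param N Lower-level latent dimensionality.
#' @param N_h Higher-level latent dimensionality.
#' @param K Number of lower-level transition matrices (`K >= 1`).
#' @param hidden Integer vector of hidden-layer widths for the hypernetwork;
#'   `integer(0)` gives a single affine layer.
#' @return An object of class `dpc_shape`.
#' @examples
#' dpc_shape(M = 324, N = 64, N_h = 16, K = 5)
#' @export
dpc_shape <- function(M, N = 128, N_h = 32, K = 5, hidden = 64) {
  M <- check_positive_int(M, "M")
  N <- check_positive_int(N, "N")
  N_h <- check_positive_int(N_h, "N_h")
  K <- check_positive_int(K, "K")
  hidden <- as.integer(hidden)
  if (any(hidden < 1)) stop_invalid("hidden widths must be positive")
  structure(list(M = M, N = N, N_h = N_h, K = K, hidden = hidden),
            class = "dpc_shape")
}

#' Hyperparameters of the generative model's priors and noise terms
#'
#' @param sigma2 Observation-noise variance of the image likelihood.
#' @param sigma_r2 Transition-noise variance of the lower-level dynamics.
#' @param lambda L1 sparsity penalty on the lower-level state.
#' @param lambda_h Squared-norm (Gaussian prior) penalty on the higher-level
#'   state.
#' @return An object of class `dpc_hyper`.
#' @export
dpc_hyper <- function(sigma2 = 0.1, sigma_r2 = 1, lambda = 0.01, lambda_h = 0.001) {
  if (!is.finite(sigma2) || sigma2 <= 0) stop_invalid("sigma2 must be > 0")
  if (!is.finite(sigma_r2) || sigma_r2 <= 0) stop_invalid("sigma_r2 must be > 0")
  if (!is.finite(lambda) || lambda < 0) stop_invalid("lambda must be >= 0")
  if (!is.finite(lambda_h) || lambda_h < 0) stop_invalid("lambda_h must be >= 0")
  structure(list(sigma2 = sigma2, sigma_r2 = sigma_r2,
                 lambda = lambda, lambda_h = lambda_h),
            class = "dpc_hyper")
}

## Hypernetwork weights: list of affine layers (W, b) with tanh between
## layers and a linear output of size K.
## Output bias starts at 1/K so the initial mixed dynamics are the mean of
## the transition matrices; a zero initialization is a saddle point (the
## transition-matrix gradient is proportional to w).
init_hypernet <- function(N_h, K, hidden, scale = 0.5) {
  widths <- c(N_h, hidden, K)
  layers <- vector("list", length(widths) - 1L)
  for (l in seq_along(layers)) {
    layers[[l]] <- list(
      W = matrix(stats::rnorm(widths[l + 1] * widths[l], sd = scale / sqrt(widths[l])),
                 widths[l + 1], widths[l]),
      b = numeric(widths[l + 1]))
  }
  layers[[length(layers)]]$b <- rep(1 / K, K)
  layers
}

#' Initialize parameters of a two-level DPC network
#'
#' Spatial filters `U` are drawn Gaussian and column-normalized to unit L2
#' norm; transition matrices are initialized near the identity so that the
#' untrained network approximately holds its state; the hypernetwork starts
#' with small weights.
#'
#' @param shape A [dpc_shape()].
#' @param seed Optional integer seed for reproducible initialization.
#' @param v_scale Standard deviation of the perturbation added to the
#'   identity initialization of each transition matrix.
#' @return An object of class `dpc_params` with elements `U` (M x N),
#'   `V_set` (list of K N x N matrices), `theta` (hypernetwork layers) and
#'   `shape`.
#' @export
dpc_params <- function(shape, seed = NULL, v_scale = 0.1) {
  stopifnot(inherits(shape, "dpc_shape"))
  make <- function() {
    U <- matrix(stats::rnorm(shape$M * shape$N), shape$M, shape$N)
    U <- normalize_columns(U)
    V_set <- lapply(seq_len(shape$K), function(k)
      diag(shape$N) + matrix(stats::rnorm(shape$N^2, sd = v_scale / sqrt(shape$N)),
                             shape$N, shape$N))
    theta <- init_hypernet(shape$N_h, shape$K, shape$hidden)
    structure(list(U = U, V_set = V_set, theta = theta, shape = shape),
              class = "dpc_params")
  }
  if (is.null(seed)) make() else with_seed(seed, make())
}

normalize_columns <- function(U) {
  nrm <- sqrt(colSums(U^2))
  nrm[nrm == 0] <- 1
  sweep(U, 2, nrm, "/")
}

#' @export
print.dpc_params <- function(x, ...) {
  s <- x$shape
  cat(sprintf("<dpc_params> M=%d N=%d N_h=%d K=%d hypernet hidden: %s\n",
              s$M, s$N, s$N_h, s$K,
              if (length(s$hidden)) paste(s$hidden, collapse = ",") else "none"))
  invisible(x)
}

#' Hypernetwork forward pass: higher-level state to modulation weights
#'
#' Maps the higher-level state `r_h` to the K-vector of modulation weights
#' `w` through the feedback network: affine layers with a tanh nonlinearity
#' between them and a linear output.
#'
#' @param r_h Higher-level state: a length-`N_h` vector or an `N_h x B`
#'   matrix of column states.
#' @param theta Hypernetwork layers, as stored in `dpc_params$theta`.
#' @return A length-`K` vector (or `K x B` matrix for matrix input).
#' @export
hypernet_forward <- function(r_h, theta) {
  x <- as_col(r_h)
  if (nrow(x) != ncol(theta[[1]]$W))
    stop_invalid("r_h has length ", nrow(x), " but the hypernetwork expects ",
                 ncol(theta[[1]]$W))
  L <- length(theta)
  for (l in seq_len(L)) {
    x <- theta[[l]]$W %*% x + theta[[l]]$b
    if (l < L) x <- tanh(x)
  }
  if (is.matrix(r_h)) x else drop(x)
}

## Forward pass that caches layer activations for backpropagation.
## Returns list(w = K x B, acts = list of inputs to each layer).
hypernet_forward_cache <- function(r_h, theta) {
  x <- as_col(r_h)
  L <- length(theta)
  acts <- vector("list", L)
  for (l in seq_len(L)) {
    acts[[l]] <- x
    x <- theta[[l]]$W %*% x + theta[[l]]$b
    if (l < L) x <- tanh(x)
  }
  list(w = x, acts = acts)
}

## Backpropagate dL/dw (K x B) through the hypernetwork.
## Returns list(d_rh = N_h x B, d_theta = layer gradients or NULL if
## want_theta is FALSE). tanh'(u) computed from the cached output.
hypernet_backward <- function(dw, theta, cache, want_theta = FALSE) {
  L <- length(theta)
  g <- dw
  d_theta <- if (want_theta) vector("list", L) else NULL
  for (l in rev(seq_len(L))) {
    a <- cache$acts[[l]]
    if (want_theta)
      d_theta[[l]] <- list(W = g %*% t(a), b = rowSums(g))
    g <- crossprod(theta[[l]]$W, g)
    if (l > 1) {
      h <- cache$acts[[l]]           # input to layer l = tanh output of l-1
      g <- g * (1 - h * h)
    }
  }
  list(d_rh = g, d_theta = d_theta)
}

#' Mix transition matrices with modulation weights
#'
#' Computes the effective transition matrix `V = sum_k w_k V_k`.
#'
#' @param w Length-`K` modulation weight vector.
#' @param V_set List of `K` square transition matrices.
#' @return The mixed `N x N` transition matrix.
#' @export
mix_transitions <- function(w, V_set) {
  if (length(w) != length(V_set))
    stop_invalid("length(w) = ", length(w), " but there are ",
                 length(V_set), " transition matrices")
  V <- w[1] * V_set[[1]]
  for (k in seq_along(V_set)[-1]) V <- V + w[k] * V_set[[k]]
  V
}

#' Transition mean of the lower-level dynamics
#'
#' `r_mu = ReLU(V %*% r_prev)`: the rectified linear image of the previous
#' state under the (mixed) transition matrix.
#'
#' @param r_prev Previous lower-level state (length `N`).
#' @param V Transition matrix (`N x N`).
#' @return The predicted next-state mean (length `N`).
#' @export
transition_mean <- function(r_prev, V) {
  if (length(r_prev) != ncol(V))
    stop_invalid("r_prev has length ", length(r_prev),
                 " but V is ", nrow(V), " x ", ncol(V))
  drop(relu(V %*% r_prev))
}

#' Decode an image frame from a lower-level state
#'
#' @param r Lower-level state vector (length `N`), or an `N x B` matrix.
#' @param U Spatial filter matrix (`M x N`).
#' @return The predicted frame vector `U %*% r` (no clipping).
#' @export
decode_image <- function(r, U) {
  x <- as_col(r)
  if (nrow(x) != ncol(U))
    stop_invalid("r has length ", nrow(x), " but U has ", ncol(U), " columns")
  out <- U %*% x
  if (is.matrix(r)) out else drop(out)
}

#' Per-step inference loss of the two-level model
#'
#' The negative log posterior (up to constants) of the latent states at one
#' time step: image reconstruction error, temporal prediction error against
#' the top-down prediction `r_bar_t`, L1 sparsity on `r_t`, and the Gaussian
#' prior penalty on `r_h`.
#'
#' @param I_t Observed frame vector.
#' @param r_t Lower-level state under evaluation.
#' @param r_bar_t Top-down temporal prediction `ReLU(V r_hat_{t-1})`.
#' @param r_h Higher-level state under evaluation.
#' @param params A `dpc_params`.
#' @param hyper A [dpc_hyper()].
#' @return Non-negative scalar loss.
#' @export
step_loss <- function(I_t, r_t, r_bar_t, r_h, params, hyper) {
  stopifnot(inherits(hyper, "dpc_hyper"))
  0.5 / hyper$sigma2 * l2sq(I_t - decode_image(r_t, params$U)) +
    0.5 / hyper$sigma_r2 * l2sq(r_t - r_bar_t) +
    hyper$lambda * sum(abs(r_t)) +
    hyper$lambda_h * l2sq(r_h)
}

#' Reduced loss for the first step of a sequence
#'
#' At `t = 0` there is no previous state, so the loss keeps only the
#' reconstruction term and the sparsity penalty.
#'
#' @inheritParams step_loss
#' @param I_0 First observed frame vector.
#' @param r_0 First-step lower-level state.
#' @return Non-negative scalar loss.
#' @export
first_step_loss <- function(I_0, r_0, params, hyper) {
  stopifnot(inherits(hyper, "dpc_hyper"))
  0.5 / hyper$sigma2 * l2sq(I_0 - decode_image(r_0, params$U)) +
    hyper$lambda * sum(abs(r_0))
}

## Smooth-part gradient of step_loss w.r.t. r_t (excludes the L1 term,
## which is handled proximally during inference).
grad_step_r <- function(I_t, r_t, r_bar_t, params, hyper) {
  crossprod(params$U, decode_image(r_t, params$U) - I_t) / hyper$sigma2 +
    (r_t - r_bar_t) / hyper$sigma_r2
}

## Gradient of step_loss w.r.t. r_h, flowing through
## r_bar = ReLU(sum_k w_k V_k r_prev), w = H_theta(r_h).
## Vk_rprev is the precomputed list of V_k %*% r_prev (vectors or N x B).
## Returns list(d_rh, dw, mask, cache) for reuse.
grad_step_rh <- function(r_t, r_h, r_prev, params, hyper, Vk_rprev = NULL) {
  if (is.null(Vk_rprev))
    Vk_rprev <- lapply(params$V_set, function(V) V %*% as_col(r_prev))
  cache <- hypernet_forward_cache(r_h, params$theta)
  w <- cache$w
  a <- Vk_rprev[[1]] * rep(w[1, ], each = nrow(Vk_rprev[[1]]))
  for (k in seq_along(Vk_rprev)[-1])
    a <- a + Vk_rprev[[k]] * rep(w[k, ], each = nrow(Vk_rprev[[k]]))
  mask <- a > 0
  r_bar <- a * mask
  g_bar <- (r_bar - as_col(r_t)) / hyper$sigma_r2   # dL/d r_bar
  g_a <- g_bar * mask
  dw <- do.call(rbind, lapply(Vk_rprev, function(v) colSums(v * g_a)))
  bk <- hypernet_backward(dw, params$theta, cache)
  d_rh <- bk$d_rh + 2 * hyper$lambda_h * as_col(r_h)
  list(d_rh = d_rh, dw = dw, g_a = g_a, r_bar = r_bar, w = w, cache = cache)
}

#' Sample an image sequence from the generative model
#'
#' Draws `r_h` i.i.d. standard normal, the initial state `r_0` from an
#' i.i.d. normal prior, rolls the dynamics
#' `r_{t+1} = ReLU(V r_t) + m`, `m ~ N(0, sigma_r2 I)`, and emits frames
#' `I_t = U r_t + n`, `n ~ N(0, sigma2 I)`.
#'
#' @param params A `dpc_params`.
#' @param T_len Number of frames (`>= 1`).
#' @param sigma2,sigma_r2 Observation and transition noise variances
#'   (either may be 0 for noiseless sampling).
#' @param r0_sd Standard deviation of the `r_0` prior (default 1).
#' @param seed Optional integer seed; the draw is reproducible given it.
#' @param frame_shape Optional `c(H, W)`; defaults to a 1 x M strip.
#' @return A list with `seq` (a `dpc_sequence`), and true latents `r`
#'   (N x T), `r_h`, `w`.
#' @export
sample_generative <- function(params, T_len, sigma2 = 0, sigma_r2 = 0,
                              r0_sd = 1, seed = NULL, frame_shape = NULL) {
  stopifnot(inherits(params, "dpc_params"))
  T_len <- check_positive_int(T_len, "T_len")
  if (sigma2 < 0 || sigma_r2 < 0) stop_invalid("noise variances must be >= 0")
  s <- params$shape
  run <- function() {
    r_h <- stats::rnorm(s$N_h)
    w <- hypernet_forward(r_h, params$theta)
    V <- mix_transitions(w, params$V_set)
    r <- matrix(0, s$N, T_len)
    r[, 1] <- stats::rnorm(s$N, sd = r0_sd)
    if (T_len > 1) for (t in 2:T_len) {
      r[, t] <- transition_mean(r[, t - 1], V)
      if (sigma_r2 > 0) r[, t] <- r[, t] + stats::rnorm(s$N, sd = sqrt(sigma_r2))
    }
    frames <- t(params$U %*% r)
    if (sigma2 > 0) frames <- frames + matrix(stats::rnorm(length(frames), sd = sqrt(sigma2)),
                                              nrow = T_len)
    fs <- frame_shape %||% c(1L, s$M)
    list(seq = dpc_sequence(frames, fs), r = r, r_h = r_h, w = w)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Construct an image sequence object
#'
#' @param frames `T x M` matrix of vectorized frames (row-major
#'   vectorization from the top-left pixel).
#' @param frame_shape `c(H, W)` with `H * W == ncol(frames)`.
#' @param metadata Optional list of labels (direction, sprite id, bounce
#'   events, ...).
#' @return An object of class `dpc_sequence`.
#' @export
dpc_sequence <- function(frames, frame_shape, metadata = list()) {
  frames <- as.matrix(frames)
  if (nrow(frames) < 1) stop_invalid("a sequence needs at least one frame")
  if (prod(frame_shape) != ncol(frames))
    stop_invalid("frame_shape ", frame_shape[1], "x", frame_shape[2],
                 " does not match frame length ", ncol(frames))
  structure(list(frames = frames, frame_shape = as.integer(frame_shape),
                 metadata = metadata),
            class = "dpc_sequence")
}

#' @export
print.dpc_sequence <- function(x, ...) {
  cat(sprintf("<dpc_sequence> %d frames of %d x %d\n",
              nrow(x$frames), x$frame_shape[1], x$frame_shape[2]))
  invisible(x)
}
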