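#' Associative memory parameters
#'
#' The memory layer binds the concatenated state `s = [r_0; r_h]` of a
#' sequence (initial content and dynamics) into a memory vector `m` through
#' the generative map `s | m ~ N(G m, sigma_m2 I)`. Before conditioning,
#' `G` holds small random entries so recall is near-null.
#'
#' @param N,N_h Lower- and higher-level state dimensions of the attached
#'   DPC network.
#' @param P Memory dimensionality (default `N + N_h`).
#' @param lambda_m Ridge penalty on `m`.
#' @param eta_G Storage learning rate for the Hebbian update of `G`;
#'   `NULL` selects the exact minimizing step for the quadratic storage
#'   objective at each repetition.
#' @param sigma_m2 Observation variance of the memory likelihood.
#' @param init_scale Scale of the random initialization of `G`.
#' @param seed Integer seed for the initialization.
#' @return Object of class `dpc_memory` with matrix `G` ((N+N_h) x P).
#' @export
memory_params <- function(N, N_h, P = N + N_h, lambda_m = 0.1, eta_G = 0.01,
                          sigma_m2 = 1, init_scale = 1e-3, seed = 1) {
  P <- check_positive_int(P, "P")
  if (!is.null(eta_G) && eta_G <= 0) stop_invalid("eta_G must be > 0")
  if (lambda_m < 0) stop_invalid("lambda_m must be >= 0")
  G <- with_seed(seed, matrix(stats::rnorm((N + N_h) * P, sd = init_scale),
                              N + N_h, P))
  structure(list(G = G, N = as.integer(N), N_h = as.integer(N_h), P = P,
                 lambda_m = lambda_m, eta_G = eta_G, sigma_m2 = sigma_m2),
            class = "dpc_memory")
}

## Ridge descent core: minimize ||s - A m||^2 + lambda ||m||^2 by gradient
## descent with the exact Lipschitz step 1/(2 (sigma_max(A)^2 + lambda)).
ridge_descent <- function(A, s, lambda, max_iters = 2000, tol = 1e-10) {
  L <- 2 * (norm(A, "2")^2 + lambda)
  step <- 1 / L
  m <- numeric(ncol(A))
  for (it in seq_len(max_iters)) {
    g <- 2 * crossprod(A, A %*% m - s) + 2 * lambda * m
    m_new <- m - step * g
    if (!all(is.finite(m_new))) stop_divergence("memory inference diverged")
    if (max(abs(m_new - m)) < tol) { m <- m_new; break }
    m <- m_new
  }
  drop(m)
}

#' Infer the memory vector for a full state observation
#'
#' Minimizes `||s - G m||^2 + lambda_m ||m||^2` by gradient descent; for
#' this quadratic objective the result coincides with the closed-form
#' ridge solution.
#'
#' @param s Concatenated state `[r_0; r_h]`.
#' @param G Memory matrix (or a `dpc_memory`).
#' @param lambda_m Ridge penalty (taken from the object if omitted).
#' @return The converged memory estimate `m_hat`.
#' @export
memory_infer <- function(s, G, lambda_m = NULL) {
  if (inherits(G, "dpc_memory")) { lambda_m <- lambda_m %||% G$lambda_m; G <- G$G }
  if (length(s) != nrow(G)) stop_invalid("state length does not match G")
  ridge_descent(G, s, lambda_m %||% 0.1)
}

#' Hebbian storage of an episode
#'
#' Conditioning: for each of `n_reps` repetitions the memory vector is
#' re-inferred and the weights receive one Hebbian update
#' `G <- G + 2 eta (s - G m_hat) m_hat^T` (presynaptic memory activity
#' times postsynaptic prediction error). The DPC network itself is frozen.
#'
#' @param mem A [memory_params()] object.
#' @param r0_hat,rh_hat MAP estimates of the episode's initial content and
#'   dynamics vectors from the (frozen) DPC network.
#' @param n_reps Number of repetitions (default 5).
#' @param eta_G Learning rate; defaults to the object's setting; `NULL`
#'   uses the exact minimizing step per repetition.
#' @return The updated `dpc_memory`, with a `store_errors` attribute giving
#'   the reconstruction error `||s - G m_hat||` after each repetition.
#' @export
memory_store <- function(mem, r0_hat, rh_hat, n_reps = 5, eta_G = mem$eta_G) {
  stopifnot(inherits(mem, "dpc_memory"))
  s <- c(r0_hat, rh_hat)
  if (length(s) != nrow(mem$G)) stop_invalid("state length does not match G")
  errs <- numeric(n_reps)
  for (rep in seq_len(n_reps)) {
    m_hat <- memory_infer(s, mem$G, mem$lambda_m)
    eta <- eta_G %||% (1 / (2 * sum(m_hat^2) + 1e-12))
    mem$G <- mem$G + 2 * eta * tcrossprod(s - drop(mem$G %*% m_hat), m_hat)
    errs[rep] <- sqrt(l2sq(s - mem$G %*% memory_infer(s, mem$G, mem$lambda_m)))
  }
  attr(mem, "store_errors") <- errs
  mem
}

#' Cue-triggered recall of the dynamics vector
#'
#' Given only the content cue `r_0`, minimizes the masked objective
#' `||s_tilde - b * (G m)||^2 + lambda_m ||m||^2` where
#' `s_tilde = [r0_cue; 0]` and the binary mask `b` is 1 on the first `N`
#' entries (the missing dynamics block carries no prediction error:
#' robust predictive coding). The dynamics vector is then read out as the
#' masked-out block of the top-down prediction `G m_tilde`.
#'
#' @param mem A `dpc_memory` (after conditioning).
#' @param r0_cue Lower-level state inferred from the cue frame.
#' @param lambda_m Ridge penalty (defaults to the object's setting).
#' @return List with `m` (the memory estimate) and `rh` (recalled dynamics
#'   vector, length `N_h`).
#' @export
recall_from_cue <- function(mem, r0_cue, lambda_m = mem$lambda_m) {
  stopifnot(inherits(mem, "dpc_memory"))
  if (length(r0_cue) != mem$N) stop_invalid("cue must have length N")
  G1 <- mem$G[seq_len(mem$N), , drop = FALSE]   # rows kept by the mask
  m_tilde <- ridge_descent(G1, r0_cue, lambda_m)
  pred <- drop(mem$G %*% m_tilde)
  list(m = m_tilde, rh = pred[mem$N + seq_len(mem$N_h)])
}

#' Roll out a predicted sequence from a content cue and recalled dynamics
#'
#' Iterates the generative dynamics from `r_0` with the recalled dynamics
#' vector fixed (`w = H(rh)`, `r_{t+1} = ReLU(V r_t)`) and decodes each
#' state through the spatial filters.
#'
#' @param params Trained `dpc_params`.
#' @param r0 Initial lower-level state.
#' @param rh Dynamics vector driving the rollout.
#' @param T_len Number of steps (default 5).
#' @param frame_shape Frame shape for the output sequence.
#' @return List with `seq` (predicted [dpc_sequence()]) and `r` (N x T
#'   matrix of lower-level responses).
#' @export
rollout_recall <- function(params, r0, rh, T_len = 5, frame_shape = NULL) {
  s <- params$shape
  V <- mix_transitions(hypernet_forward(rh, params$theta), params$V_set)
  r <- matrix(0, s$N, T_len)
  r[, 1] <- r0
  if (T_len > 1) for (t in 2:T_len) r[, t] <- transition_mean(r[, t - 1], V)
  frames <- t(params$U %*% r)
  fs <- frame_shape %||% c(1L, s$M)
  list(seq = dpc_sequence(frames, fs), r = r)
}

#' Pairwise response cross-correlation versus receptive-field distance
#'
#' Each neuron's receptive-field (RF) position is the center of mass of the
#' absolute value of its spatial filter. For each ordered neuron pair with
#' positive RF separation along `direction`, the normalized
#' cross-correlation of their response time courses is computed at integer
#' lags; the peak lag of each pair is related to the pair's RF distance
#' (sequential firing produces peak lags growing with distance).
#'
#' @param responses `T x N` matrix of response time courses.
#' @param U Spatial filter matrix (M x N).
#' @param frame_shape `c(H, W)`.
#' @param max_lag Maximum lag in steps (clipped to `T - 2`).
#' @param direction Unit 2-vector (x, y) defining "downstream"; `NULL`
#'   projects RF positions on their first principal axis.
#' @param min_activity Neurons whose response standard deviation or filter
#'   norm falls below this are excluded (count reported).
#' @param n_bins Number of RF-distance bins for the averaged correlogram.
#' @return List with `pairs` (data frame: i, j, dist, peak_lag,
#'   peak_corr), `binned` (distance-binned mean correlogram, bins x lags),
#'   `lags`, `bin_centers`, `n_excluded`.
#' @export
rf_distance_crosscorr <- function(responses, U, frame_shape, max_lag = 3,
                                  direction = NULL, min_activity = 1e-8,
                                  n_bins = 5) {
  T_len <- nrow(responses); N <- ncol(responses)
  max_lag <- min(max_lag, T_len - 2)
  fnorm <- sqrt(colSums(U^2))
  sds <- apply(responses, 2, stats::sd)
  keep <- which(fnorm > min_activity & sds > min_activity)
  n_excl <- N - length(keep)
  if (n_excl > 0) message(n_excl, " inactive/degenerate neurons excluded")
  pos <- t(vapply(keep, function(i)
    center_of_mass(abs(U[, i]), frame_shape), numeric(2)))
  if (is.null(direction)) {
    pc <- stats::prcomp(pos)$rotation[, 1]
    direction <- pc / sqrt(sum(pc^2))
  }
  proj <- pos %*% direction
  lags <- -max_lag:max_lag
  cc_at <- function(x, y, l) {
    if (l >= 0) { a <- x[1:(T_len - l)]; b <- y[(1 + l):T_len] }
    else { a <- x[(1 - l):T_len]; b <- y[1:(T_len + l)] }
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(NA_real_)
    stats::cor(a, b)
  }
  rows <- list(); ccs <- list()
  for (ii in seq_along(keep)) for (jj in seq_along(keep)) {
    if (ii == jj) next
    d <- proj[jj] - proj[ii]
    if (d <= 0) next                       # ordered pairs along direction
    cc <- vapply(lags, function(l)
      cc_at(responses[, keep[ii]], responses[, keep[jj]], l), numeric(1))
    if (all(is.na(cc))) next
    pk <- which.max(replace(cc, is.na(cc), -Inf))
    rows[[length(rows) + 1L]] <- data.frame(
      i = keep[ii], j = keep[jj], dist = d,
      peak_lag = lags[pk], peak_corr = cc[pk])
    ccs[[length(ccs) + 1L]] <- cc
  }
  pairs <- do.call(rbind, rows)
  binned <- NULL; centers <- NULL
  if (!is.null(pairs) && nrow(pairs) >= n_bins) {
    br <- stats::quantile(pairs$dist, probs = seq(0, 1, length.out = n_bins + 1))
    br[1] <- br[1] - 1e-9
    bin <- cut(pairs$dist, br, labels = FALSE)
    ccm <- do.call(rbind, ccs)
    binned <- t(vapply(seq_len(n_bins), function(b)
      colMeans(ccm[bin == b, , drop = FALSE], na.rm = TRUE),
      numeric(length(lags))))
    centers <- vapply(seq_len(n_bins), function(b)
      mean(pairs$dist[bin == b]), numeric(1))
  }
  list(pairs = pairs, binned = binned, lags = lags, bin_centers = centers,
       n_excluded = n_excl)
}

#' Slope of peak cross-correlation lag versus RF distance
#'
#' Linear regression of per-pair peak lags on RF distances; a positive
#' slope indicates a traveling wave of activity (farther neurons fire
#' later). For a binned correlogram difference (e.g. after minus before
#' conditioning), supply the matrix and bin centers instead.
#'
#' @param x Either the result of [rf_distance_crosscorr()] (slope over
#'   `pairs`), or a bins x lags matrix of correlogram differences.
#' @param lags,bin_centers Required in the matrix case.
#' @return Slope in steps per pixel.
#' @export
peak_lag_slope <- function(x, lags = NULL, bin_centers = NULL) {
  if (is.list(x) && !is.null(x$pairs)) {
    fit <- stats::lm(peak_lag ~ dist, data = x$pairs)
    return(unname(stats::coef(fit)[2]))
  }
  pk <- lags[apply(x, 1, which.max)]
  unname(stats::coef(stats::lm(pk ~ bin_centers))[2])
}

#' Conditioning-and-recall experiment on one episode
#'
#' Freezes the DPC network, infers `(r_0, r_h)` for the episode, stores the
#' binding in the associative memory over `n_reps` repetitions, and probes
#' recall with the start, middle and end frames as cues. For each cue the
#' rollout's frames are correlated with the episode's frames. Responses
#' to the start cue are also collected before conditioning for the
#' cross-correlation analysis.
#'
#' @param params Trained `dpc_params`.
#' @param episode A [dpc_sequence()] (typically 5 frames).
#' @param hyper,opts Model hyperparameters and inference options.
#' @param mem Optional [memory_params()]; default constructed to match.
#' @param n_reps Conditioning repetitions (default 5).
#' @param eta_G Storage learning rate; `NULL` = exact quadratic step.
#' @return List with `recall_cor` (named mean frame correlations for
#'   start/middle/end cues), per-cue rollouts, the before/after response
#'   matrices to the start cue, and the conditioned memory.
#' @export
run_recall_experiment <- function(params, episode, hyper,
                                  opts = dpc_options(), mem = NULL,
                                  n_reps = 5, eta_G = NULL) {
  s <- params$shape
  T_len <- nrow(episode$frames)
  traj <- filter_sequence(episode, params, hyper, opts)
  r0_hat <- traj$r_hat[, 1]
  rh_hat <- traj$r_h_hat[, T_len]
  mem <- mem %||% memory_params(s$N, s$N_h, eta_G = eta_G, seed = 1)
  mem_before <- mem
  mem <- memory_store(mem, r0_hat, rh_hat, n_reps = n_reps, eta_G = eta_G)

  cue_idx <- c(start = 1L, middle = as.integer(ceiling(T_len / 2)),
               end = T_len)
  probe <- function(memx, idx) {
    r0_cue <- infer_first_step(episode$frames[idx, ], params, hyper, opts)$r_hat
    rec <- recall_from_cue(memx, r0_cue)
    rollout_recall(params, r0_cue, rec$rh, T_len, episode$frame_shape)
  }
  rollouts <- lapply(cue_idx, function(i) probe(mem, i))
  frame_cor <- vapply(rollouts, function(ro) {
    mean(vapply(seq_len(T_len), function(t) {
      a <- episode$frames[t, ]; b <- ro$seq$frames[t, ]
      if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(0)
      stats::cor(a, b)
    }, numeric(1)))
  }, numeric(1))
  before <- probe(mem_before, 1L)
  list(recall_cor = frame_cor, rollouts = rollouts,
       responses_after = t(rollouts[["start"]]$r),
       responses_before = t(before$r),
       memory = mem, r0_hat = r0_hat, rh_hat = rh_hat)
}
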