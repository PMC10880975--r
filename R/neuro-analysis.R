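#' Space-time receptive fields by reverse correlation
#'
#' Computes, for every model neuron, the response-weighted average of the
#' `tau` stimulus frames preceding each response (the spike-triggered
#' average generalized to graded responses):
#' `STRF_i = 1/(J(T-tau)) * sum_j sum_t r_{t,i,j} I_{t-tau:t-1,j}`.
#'
#' @param stimuli A [dpc_dataset()] (J sequences of T frames) or a single
#'   [dpc_sequence()].
#' @param responses Array `J x T x N` of neuron responses aligned to the
#'   stimulus frames (a matrix `T x N` for a single sequence).
#' @param tau Window length in frames (default 7).
#' @return Object of class `dpc_strf`: array `M x tau x N` (lag column `l`
#'   holds the frame `tau - l + 1` steps before the response) plus the
#'   frame shape.
#' @export
compute_strf <- function(stimuli, responses, tau = 7) {
  if (inherits(stimuli, "dpc_sequence")) {
    stimuli <- dpc_dataset(array(stimuli$frames,
                                 c(dim(stimuli$frames), 1)),
                           stimuli$frame_shape)
  }
  if (is.matrix(responses)) responses <- array(responses, c(1, dim(responses)))
  d <- dim(stimuli$frames)   # T x M x J
  T_len <- d[1]; M <- d[2]; J <- d[3]
  tau <- check_positive_int(tau, "tau")
  if (T_len <= tau) stop_invalid("sequences must be longer than tau")
  if (dim(responses)[1] != J || dim(responses)[2] != T_len)
    stop_invalid("responses must be J x T x N aligned to the stimuli")
  N <- dim(responses)[3]
  strf <- array(0, c(M, tau, N))
  t_idx <- (tau + 1):T_len
  for (j in seq_len(J)) {
    R <- matrix(responses[j, t_idx, ], length(t_idx), N)
    for (l in seq_len(tau)) {
      F_l <- matrix(stimuli$frames[t_idx - tau + l - 1, , j], length(t_idx), M)
      strf[, l, ] <- strf[, l, ] + crossprod(F_l, R)
    }
  }
  strf <- strf / (J * (T_len - tau))
  structure(list(strf = strf, frame_shape = stimuli$frame_shape, tau = tau),
            class = "dpc_strf")
}

#' Collapse a space-time receptive field to a space x lag map
#'
#' Reshapes each lag of a neuron's STRF to the frame and sums over the
#' spatial axis whose marginal profile varies least across lags (the
#' time-invariant axis), yielding an X-T or Y-T map in which an oriented
#' ridge indicates direction selectivity. Ties prefer collapsing Y.
#'
#' @param strf A `dpc_strf` (from [compute_strf()]) or a single `M x tau`
#'   matrix.
#' @param frame_shape Required when `strf` is a bare matrix.
#' @param neuron Neuron index when `strf` holds several neurons.
#' @return List with `map` (space x lag matrix), `axis_collapsed`
#'   (`"Y"` or `"X"`) and the two variability scores.
#' @export
collapse_strf_xt <- function(strf, frame_shape = NULL, neuron = 1) {
  if (inherits(strf, "dpc_strf")) {
    frame_shape <- strf$frame_shape
    strf <- matrix(strf$strf[, , neuron], dim(strf$strf)[1], dim(strf$strf)[2])
  }
  if (is.null(frame_shape)) stop_invalid("frame_shape required")
  H <- frame_shape[1]; W <- frame_shape[2]
  tau <- ncol(strf)
  profY <- matrix(0, H, tau)   # marginal along Y (rows), per lag
  profX <- matrix(0, W, tau)
  for (l in seq_len(tau)) {
    fr <- vec_to_frame(strf[, l], frame_shape)
    profY[, l] <- rowMeans(fr)
    profX[, l] <- colMeans(fr)
  }
  varY <- mean(apply(profY, 1, stats::var))
  varX <- mean(apply(profX, 1, stats::var))
  ## collapse the time-invariant axis (lower across-lag variability)
  axis <- if (varY <= varX) "Y" else "X"
  map <- matrix(0, if (axis == "Y") W else H, tau)
  for (l in seq_len(tau)) {
    fr <- vec_to_frame(strf[, l], frame_shape)
    map[, l] <- if (axis == "Y") colSums(fr) else rowSums(fr)
  }
  list(map = map, axis_collapsed = axis, var_y = varY, var_x = varX)
}

#' Population autocorrelation of neural responses
#'
#' Computes per-neuron, per-trial autocorrelations with the per-series mean
#' removed and normalized by the per-series variance so that `rho(0) = 1`,
#' then averages across neurons and trials. Zero-variance series are
#' excluded (their count is reported).
#'
#' @param responses Array `J x T x N` (trials x time x neurons) or a
#'   `T x N` matrix for a single trial.
#' @param k_max Maximum lag (`T > k_max`).
#' @return Object of class `dpc_autocorr`: list with `rho` (lags
#'   `0..k_max`), `lags`, `n_neurons`, `n_trials`, `n_excluded`.
#' @export
response_autocorrelation <- function(responses, k_max) {
  if (is.matrix(responses)) responses <- array(responses, c(1, dim(responses)))
  J <- dim(responses)[1]; T_len <- dim(responses)[2]; N <- dim(responses)[3]
  k_max <- check_positive_int(k_max + 1L, "k_max + 1") - 1L
  if (T_len <= k_max) stop_invalid("need T > k_max")
  acc <- numeric(k_max + 1)
  used <- 0L
  for (j in seq_len(J)) {
    X <- matrix(responses[j, , ], T_len, N)
    mu <- colMeans(X)
    Xc <- sweep(X, 2, mu)
    v <- colMeans(Xc^2)                       # population variance, 1/T
    ok <- v > 1e-24
    if (!any(ok)) next
    Xc <- Xc[, ok, drop = FALSE]; v <- v[ok]
    for (k in 0:k_max) {
      num <- colSums(Xc[1:(T_len - k), , drop = FALSE] *
                     Xc[(1 + k):T_len, , drop = FALSE]) / (T_len - k)
      acc[k + 1] <- acc[k + 1] + sum(num / v)
    }
    used <- used + sum(ok)
  }
  excl <- J * N - used
  if (excl > 0)
    message(excl, " zero-variance neuron/trial series excluded from autocorrelation")
  structure(list(rho = acc / used, lags = 0:k_max,
                 n_neurons = N, n_trials = J, n_excluded = excl),
            class = "dpc_autocorr")
}

#' Fit an exponential decay to an autocorrelation curve
#'
#' Nonlinear least squares of `rho_fit(k) = a * exp(-k / tau) + b` with
#' multi-start over `tau` in `{0.5, 1, 2, 5, 10}`; the best-residual fit is
#' kept. `tau` is the response timescale.
#'
#' @param rho Autocorrelation values (or a `dpc_autocorr`).
#' @param lags Lags matching `rho` (taken from the object if omitted).
#' @return List with `a`, `b`, `tau`, `resid` (residual sum of squares),
#'   `fit_ok` and `tau_reliable` (FALSE for a flat curve where the decay
#'   amplitude is negligible).
#' @export
fit_exponential_decay <- function(rho, lags = NULL) {
  if (inherits(rho, "dpc_autocorr")) { lags <- rho$lags; rho <- rho$rho }
  if (length(rho) < 4) stop_invalid("need at least 4 lag points")
  df <- data.frame(k = lags, y = rho)
  amp <- max(rho) - min(rho)
  if (amp < 1e-10) {
    return(list(a = 0, b = mean(rho), tau = NA_real_, resid = 0,
                fit_ok = TRUE, tau_reliable = FALSE))
  }
  ## separable least squares: for fixed tau the model is linear in (a, b),
  ## so scan a tau grid seeded at the multi-start values, then polish the
  ## best candidate with Levenberg-Marquardt
  sep_fit <- function(tau) {
    x <- exp(-lags / tau)
    co <- stats::coef(stats::lm(rho ~ x))
    list(a = unname(co[2]), b = unname(co[1]), tau = tau,
         resid = sum((rho - co[1] - co[2] * x)^2))
  }
  grid <- sort(unique(c(c(0.5, 1, 2, 5, 10),
                        exp(seq(log(0.05), log(4 * max(lags)), length.out = 40)))))
  cands <- lapply(grid, function(t0) tryCatch(sep_fit(t0), error = function(e) NULL))
  cands <- Filter(function(z) !is.null(z) && is.finite(z$resid), cands)
  if (!length(cands))
    return(list(a = NA_real_, b = NA_real_, tau = NA_real_,
                resid = NA_real_, fit_ok = FALSE, tau_reliable = FALSE))
  best <- cands[[which.min(vapply(cands, `[[`, numeric(1), "resid"))]]
  pol <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-k / tau) + b, data = df,
                      start = list(a = best$a, b = best$b, tau = best$tau),
                      lower = c(a = -Inf, b = -Inf, tau = 1e-4),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(pol) && sum(stats::residuals(pol)^2) < best$resid) {
    cf <- stats::coef(pol)
    best <- list(a = unname(cf["a"]), b = unname(cf["b"]),
                 tau = unname(cf["tau"]), resid = sum(stats::residuals(pol)^2))
  }
  c(best, list(fit_ok = TRUE, tau_reliable = abs(best$a) > 1e-6))
}

#' Fitted response timescale of a population
#'
#' Convenience wrapper: autocorrelation of `responses` up to `k_max`
#' followed by the exponential-decay fit; returns the fitted `tau`.
#'
#' @inheritParams response_autocorrelation
#' @param k_max Maximum lag.
#' @return Fitted timescale in steps (NA if the fit failed).
#' @export
response_timescale <- function(responses, k_max) {
  ac <- response_autocorrelation(responses, k_max)
  fit_exponential_decay(ac)$tau
}

#' Cross-validated decoding accuracy with an RBF-kernel SVM
#'
#' Stratified k-fold classification with a radial-basis-function
#' support-vector machine (default regularization). Chance accuracy is
#' computed per fold as the number of majority labels in the test set
#' divided by the total number of test labels, then averaged.
#'
#' @param features `n x p` numeric matrix.
#' @param labels Length-`n` factor (or coercible).
#' @param n_folds Number of folds (default 10; reduced to the smallest
#'   class count if necessary samples are missing is an error).
#' @param seed Seed for the fold assignment.
#' @return List with `accuracy` (mean), `sd`, `chance`, `per_fold`.
#' @export
crossval_decode <- function(features, labels, n_folds = 10, seed = 1) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop_invalid("need at least two classes")
  if (min(table(labels)) < n_folds)
    stop_invalid("need at least n_folds samples per class")
  features <- as.matrix(features)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  acc <- numeric(n_folds); chance <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f; te <- !tr
    fit <- e1071::svm(features[tr, , drop = FALSE], labels[tr],
                      kernel = "radial")
    pred <- stats::predict(fit, features[te, , drop = FALSE])
    acc[f] <- mean(pred == labels[te])
    chance[f] <- max(table(labels[te])) / sum(te)
  }
  list(accuracy = mean(acc), sd = stats::sd(acc), chance = mean(chance),
       per_fold = acc)
}

#' Project features onto their first principal components
#'
#' Thin wrapper over [stats::prcomp()] used to visualize higher-level
#' response clusters.
#'
#' @param features `n x p` matrix.
#' @param k Number of components (default 2).
#' @return `n x k` matrix of scores.
#' @export
pca_project <- function(features, k = 2) {
  p <- stats::prcomp(as.matrix(features), center = TRUE, scale. = FALSE)
  p$x[, seq_len(min(k, ncol(p$x))), drop = FALSE]
}
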