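#' Select subsequences with consistent horizontal motion
#'
#' Extracts, from a labeled sprite dataset, windows of `len` frames whose
#' motion direction is constant leftward or rightward with no bounce inside
#' the window (the stimulus set used for the flash-lag simulation). The
#' first qualifying window of each sequence is taken.
#'
#' @param ds A labeled [dpc_dataset()] from [make_moving_sprites()].
#' @param len Window length (default 5).
#' @return A [dpc_dataset()] of `len`-frame subsequences with labels
#'   `direction` and `source`; empty (with a warning) if nothing qualifies.
#' @export
select_consistent_sequences <- function(ds, len = 5) {
  if (is.null(ds$metadata)) stop_invalid("dataset has no motion metadata")
  T_len <- dim(ds$frames)[1]; M <- dim(ds$frames)[2]
  keep_frames <- list(); dir_lab <- character(0); src <- integer(0)
  for (i in seq_len(n_sequences(ds))) {
    dirs <- ds$metadata[[i]]$dirs
    for (t0 in seq_len(T_len - len + 1)) {
      win <- dirs[t0:(t0 + len - 2)]
      if (all(win %in% c("left", "right")) && length(unique(win)) == 1) {
        keep_frames[[length(keep_frames) + 1L]] <-
          ds$frames[t0:(t0 + len - 1), , i]
        dir_lab <- c(dir_lab, win[1]); src <- c(src, i)
        break
      }
    }
  }
  if (!length(keep_frames)) {
    warning("no consistent horizontal windows found")
    return(dpc_dataset(array(0, c(len, M, 0)), ds$frame_shape,
                       labels = data.frame(direction = character(0),
                                           source = integer(0))))
  }
  frames <- array(0, c(len, M, length(keep_frames)))
  for (i in seq_along(keep_frames)) frames[, , i] <- keep_frames[[i]]
  dpc_dataset(frames, ds$frame_shape,
              labels = data.frame(direction = dir_lab, source = src,
                                  stringsAsFactors = FALSE))
}

#' Center of mass of an image
#'
#' Positive-rectified intensity-weighted mean pixel position. Pixel centers
#' sit at integer coordinates with the origin at the top-left pixel
#' `(x = 1, y = 1)`; `x` runs along columns (rightward), `y` along rows
#' (downward).
#'
#' @param v Frame vector (row-major) or matrix.
#' @param frame_shape `c(H, W)` (ignored if `v` is a matrix).
#' @return Named vector `c(x, y)`.
#' @export
center_of_mass <- function(v, frame_shape = NULL) {
  fr <- if (is.matrix(v)) v else vec_to_frame(v, frame_shape)
  fr <- relu(fr)
  tot <- sum(fr)
  if (tot <= 0) stop_invalid("center of mass undefined: no positive pixels")
  x <- sum(sweep(fr, 2, seq_len(ncol(fr)), "*")) / tot
  y <- sum(sweep(fr, 1, seq_len(nrow(fr)), "*")) / tot
  c(x = x, y = y)
}

#' Signed perceptual displacement between moving and flashed objects
#'
#' Positive displacements lie along the original trajectory of the moving
#' object: for rightward motion the displacement is
#' `x_moving - x_flash`, for leftward motion `x_flash - x_moving`.
#'
#' @param x_moving Horizontal center-of-mass of the moving-object percept.
#' @param x_flash Horizontal center-of-mass of the flashed-object percept
#'   (or reference image).
#' @param direction `"left"` or `"right"`.
#' @return Signed scalar displacement in pixels.
#' @export
displacement <- function(x_moving, x_flash, direction) {
  if (!direction %in% c("left", "right"))
    stop_invalid("direction must be 'left' or 'right'")
  if (any(is.na(c(x_moving, x_flash))))
    stop_invalid("undefined percept location")
  if (direction == "right") x_moving - x_flash else x_flash - x_moving
}

#' Construct one flash-lag test condition
#'
#' @param window A 5-frame [dpc_sequence()] or `5 x M` frame matrix of
#'   consistent motion (constant direction over its first three steps).
#' @param direction Motion direction label (`"left"` or `"right"`).
#' @param trajectory `"with_initial"` (higher-level state inferred from the
#'   first three frames) or `"without_initial"` (zero-initialized).
#' @param motion_case Input shown at the probe step: `"continuous"`,
#'   `"stopped"`, `"reversed"` or `"terminated"` (empty frame). The flashed
#'   object corresponds to `without_initial` + `terminated`.
#' @param frame_shape `c(H, W)` when `window` is a bare matrix.
#' @return An object of class `flash_lag_condition`.
#' @export
flash_lag_condition <- function(window, direction,
                                trajectory = c("with_initial", "without_initial"),
                                motion_case = c("continuous", "stopped",
                                                "reversed", "terminated"),
                                frame_shape = NULL) {
  trajectory <- match.arg(trajectory)
  motion_case <- match.arg(motion_case)
  if (inherits(window, "dpc_sequence")) {
    frame_shape <- window$frame_shape
    window <- window$frames
  }
  if (nrow(window) < 4) stop_invalid("window needs at least 4 frames")
  probe <- switch(motion_case,
                  continuous = window[4, ],
                  stopped = window[3, ],
                  reversed = window[2, ],
                  terminated = numeric(ncol(window)))
  structure(list(frames = window, probe = probe, direction = direction,
                 trajectory = trajectory, motion_case = motion_case,
                 frame_shape = frame_shape),
            class = "flash_lag_condition")
}

## Infer the latent state just before the probe step: with an initial
## trajectory the first three frames are filtered; without, the object is
## shown only at the step before the probe and r_h starts at zero.
prime_condition <- function(cond, params, hyper, opts) {
  if (cond$trajectory == "with_initial") {
    traj <- filter_sequence(cond$frames[1:3, ], params, hyper, opts)
    list(r2 = traj$r_hat[, 3], rh = traj$r_h_hat[, 3])
  } else {
    fs <- infer_first_step(cond$frames[3, ], params, hyper, opts)
    list(r2 = fs$r_hat, rh = numeric(params$shape$N_h))
  }
}

#' Model percept at the probe step of a flash-lag condition
#'
#' Applies the probe input, lets prediction-error minimization correct the
#' higher-level state, and reads out the percept as the corrected top-down
#' spatiotemporal prediction `U ReLU(Vbar r_hat_2)` with `Vbar` mixed from
#' the post-correction higher-level estimate.
#'
#' @param params Trained `dpc_params` (a warning is issued for an
#'   untrained network).
#' @param cond A [flash_lag_condition()].
#' @param hyper,opts Model hyperparameters and inference options.
#' @return List with `percept` (frame vector), `location` (`c(x, y)` or
#'   `NA` with `location_defined = FALSE`), and the corrected `r_h`.
#' @export
percept_at_step <- function(params, cond, hyper, opts = dpc_options()) {
  if (!isTRUE(params$trained))
    warning("percept_at_step called with an untrained (random-filter) network")
  pre <- prime_condition(cond, params, hyper, opts)
  st <- infer_step(cond$probe, pre$r2, pre$rh, params, hyper, opts)
  w_bar <- hypernet_forward(st$r_h_hat, params$theta)
  V_bar <- mix_transitions(w_bar, params$V_set)
  percept <- decode_image(transition_mean(pre$r2, V_bar), params$U)
  loc <- tryCatch(center_of_mass(percept, cond$frame_shape),
                  error = function(e) c(x = NA_real_, y = NA_real_))
  list(percept = percept, location = loc,
       location_defined = !any(is.na(loc)), r_h = st$r_h_hat)
}

#' Run the full flash-lag experiment over a stimulus set
#'
#' For every consistent-motion window, every trajectory condition and
#' every motion case, computes the percept displacement between the moving
#' object and the flashed object (the `without_initial` + `terminated`
#' percept of the same window), following the sign convention of
#' [displacement()].
#'
#' @param params Trained `dpc_params`.
#' @param windows A [dpc_dataset()] from [select_consistent_sequences()].
#' @param hyper,opts Model hyperparameters and inference options.
#' @return Data frame with one row per (window, trajectory, motion case).
#' @export
flash_lag_experiment <- function(params, windows, hyper,
                                 opts = dpc_options()) {
  out <- list()
  for (i in seq_len(n_sequences(windows))) {
    win <- windows$frames[, , i]
    dirn <- windows$labels$direction[i]
    flash_cond <- flash_lag_condition(win, dirn, "without_initial",
                                      "terminated", windows$frame_shape)
    flash <- percept_at_step(params, flash_cond, hyper, opts)
    if (!flash$location_defined) next
    for (traj in c("with_initial", "without_initial")) {
      for (mc in c("continuous", "stopped", "reversed", "terminated")) {
        cond <- flash_lag_condition(win, dirn, traj, mc, windows$frame_shape)
        per <- percept_at_step(params, cond, hyper, opts)
        if (!per$location_defined) next
        out[[length(out) + 1L]] <- data.frame(
          window = i, direction = dirn, trajectory = traj, motion_case = mc,
          x_moving = per$location["x"], x_flash = flash$location["x"],
          displacement = displacement(per$location["x"], flash$location["x"],
                                      dirn),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Percept displacement as a function of correction latency
#'
#' For a reversed-motion condition with an initial trajectory, records the
#' higher-level iterate at given fractions of the inner-loop iterations of
#' the probe step and computes, at each latency, the displacement of the
#' top-down percept relative to the input image at the step before
#' reversal (positive = along the original trajectory).
#'
#' @param params Trained `dpc_params`.
#' @param cond A `with_initial` + `reversed` [flash_lag_condition()].
#' @param hyper,opts Model hyperparameters and inference options.
#' @param fractions Iteration fractions in `[0, 1]` at which to probe.
#' @return Data frame with `fraction` and `displacement`.
#' @export
latency_sweep <- function(params, cond, hyper, opts = dpc_options(),
                          fractions = seq(0, 1, by = 0.1)) {
  if (cond$trajectory != "with_initial" || cond$motion_case != "reversed")
    stop_invalid("latency sweep requires the with_initial + reversed condition")
  fr_sorted <- sort(unique(fractions))
  iter_at <- round(fr_sorted * opts$max_iters)
  if (anyDuplicated(iter_at))
    stop_invalid("max_iters too small to resolve the requested fractions")
  pre <- prime_condition(cond, params, hyper, opts)
  st <- infer_step(cond$probe, pre$r2, pre$rh, params, hyper, opts,
                   record_rh = fractions)
  ref <- center_of_mass(cond$frames[3, ], cond$frame_shape)["x"]
  disp <- vapply(st$rh_trace, function(rh) {
    w_bar <- hypernet_forward(rh, params$theta)
    percept <- decode_image(transition_mean(pre$r2,
                                            mix_transitions(w_bar, params$V_set)),
                            params$U)
    loc <- tryCatch(center_of_mass(percept, cond$frame_shape)["x"],
                    error = function(e) NA_real_)
    displacement(loc, ref, cond$direction)
  }, numeric(1))
  data.frame(fraction = fractions, displacement = disp)
}
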