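#' Bank of programmatically drawn sprites
#'
#' Returns the named list of glyph-drawing functions used by the sprite
#' generators: high-contrast shapes (bars, cross, diagonal cross, ring,
#' blob, L- and T-shapes) standing in for handwritten digits, so the
#' package needs no external image data.
#'
#' @param size Sprite side length in pixels (odd values center best).
#' @return Named list of `size x size` matrices with values in `[0, 1]`.
#' @export
sprite_bank <- function(size = 9) {
  size <- check_positive_int(size, "size")
  g <- function() matrix(0, size, size)
  mid <- (size + 1) / 2
  half <- floor(size / 6)
  band <- max(1, round(size / 3))
  bar_v <- g(); bar_v[, (mid - half):(mid + half)] <- 1
  bar_h <- t(bar_v)
  cross <- pmax(bar_v, bar_h)
  xs <- g()
  for (i in seq_len(size)) for (d in -half:half) {
    j <- i + d
    if (j >= 1 && j <= size) { xs[i, j] <- 1; xs[i, size - j + 1] <- 1 }
  }
  cc <- abs(row(g()) - mid)^2 + abs(col(g()) - mid)^2
  ring <- ifelse(cc <= (mid - 1)^2 & cc >= (mid - 1 - band)^2, 1, 0)
  blob <- exp(-cc / (2 * (size / 4)^2))
  ell <- g(); ell[, 1:(2 * half + 1)] <- 1; ell[(size - 2 * half):size, ] <- 1
  tee <- g(); tee[1:(2 * half + 1), ] <- 1; tee[, (mid - half):(mid + half)] <- 1
  list(bar_v = bar_v, bar_h = bar_h, cross = cross, xcross = xs,
       ring = ring, blob = blob, ell = ell, tee = tee)
}

#' Specification of a moving-sprite dataset
#'
#' Describes sequences in which a single sprite translates at fixed speed
#' in one of four cardinal directions inside a bounded arena, changing
#' direction at the boundary according to a bounce rule: `"straight"`
#' inverts the direction (left to right, up to down, and vice versa) while
#' `"clockwise"` rotates it (left to up, up to right, right to down, down
#' to left). Motion reflects before the sprite would exit, so pixel mass is
#' conserved in every frame.
#'
#' @param n_sequences Number of sequences to draw.
#' @param frame_size Frame side length in pixels.
#' @param T_len Frames per sequence.
#' @param directions Subset of `c("up","down","left","right")` the initial
#'   direction is drawn from.
#' @param speed Pixels per frame (`>= 1`).
#' @param bounce_rule `"straight"` or `"clockwise"`.
#' @param sprite_size Sprite side length (must fit inside the frame).
#' @param sprites Names from [sprite_bank()] to use.
#' @param seed Integer seed; the dataset is a pure function of the spec.
#' @return An object of class `sprite_spec`.
#' @export
sprite_spec <- function(n_sequences, frame_size = 18, T_len = 10,
                        directions = c("up", "down", "left", "right"),
                        speed = 2, bounce_rule = c("straight", "clockwise"),
                        sprite_size = 9, sprites = NULL, seed = 1) {
  bounce_rule <- match.arg(bounce_rule)
  if (sprite_size >= frame_size) stop_invalid("sprite must be smaller than frame")
  if (speed < 1) stop_invalid("speed must be >= 1")
  if (T_len < 2) stop_invalid("T_len must be >= 2")
  directions <- match.arg(directions, c("up", "down", "left", "right"),
                          several.ok = TRUE)
  bank <- sprite_bank(sprite_size)
  sprites <- sprites %||% names(bank)
  stopifnot(all(sprites %in% names(bank)))
  structure(list(n_sequences = check_positive_int(n_sequences, "n_sequences"),
                 frame_size = as.integer(frame_size), T_len = as.integer(T_len),
                 directions = directions, speed = as.integer(speed),
                 bounce_rule = bounce_rule, sprite_size = as.integer(sprite_size),
                 sprites = sprites, seed = as.integer(seed)),
            class = "sprite_spec")
}

dir_vectors <- list(up = c(-1L, 0L), down = c(1L, 0L),
                    left = c(0L, -1L), right = c(0L, 1L))

next_direction <- function(dir, rule) {
  if (rule == "straight") {
    switch(dir, left = "right", right = "left", up = "down", down = "up")
  } else {
    switch(dir, left = "up", up = "right", right = "down", down = "left")
  }
}

## Simulate one trajectory of top-left positions; reflect before exit.
simulate_path <- function(start, dir, T_len, speed, lim, rule) {
  pos <- matrix(0L, T_len, 2)
  dirs <- character(T_len - 1)
  pos[1, ] <- start
  bounce_times <- integer(0)
  cur <- dir
  for (t in seq_len(T_len - 1)) {
    tries <- 0
    repeat {
      np <- pos[t, ] + dir_vectors[[cur]] * speed
      if (all(np >= 1L & np <= lim)) break
      cur <- next_direction(cur, rule)
      bounce_times <- union(bounce_times, t)
      tries <- tries + 1
      if (tries > 4) stop_invalid("no valid direction; arena too small")
    }
    dirs[t] <- cur
    pos[t + 1, ] <- pos[t, ] + dir_vectors[[cur]] * speed
  }
  list(positions = pos, dirs = dirs, bounce_times = bounce_times)
}

render_sprite_sequence <- function(glyph, path, frame_size) {
  g <- nrow(glyph)
  T_len <- nrow(path$positions)
  frames <- matrix(0, T_len, frame_size^2)
  for (t in seq_len(T_len)) {
    fr <- matrix(0, frame_size, frame_size)
    p <- path$positions[t, ]
    fr[p[1]:(p[1] + g - 1), p[2]:(p[2] + g - 1)] <- glyph
    frames[t, ] <- frame_to_vec(fr)
  }
  frames
}

#' Generate a moving-sprite dataset
#'
#' Each sequence shows one sprite translating at fixed speed in one of four
#' cardinal directions, reflecting at the arena boundary under the spec's
#' bounce rule. No whitening is applied. Labels record the sprite identity,
#' the initial direction and the bounce times exactly.
#'
#' @param spec A [sprite_spec()].
#' @return A [dpc_dataset()] with labels `sprite`, `direction` (initial),
#'   `n_bounces`, and per-sequence metadata `positions` (T x 2 top-left
#'   coordinates), `dirs` (per-step motion direction) and `bounce_times`.
#' @export
make_moving_sprites <- function(spec) {
  stopifnot(inherits(spec, "sprite_spec"))
  bank <- sprite_bank(spec$sprite_size)
  S <- spec$frame_size; g <- spec$sprite_size
  lim <- S - g + 1L
  with_seed(spec$seed, {
    n <- spec$n_sequences
    frames <- array(0, c(spec$T_len, S^2, n))
    sprite_ids <- sample(spec$sprites, n, replace = TRUE)
    dirs0 <- sample(spec$directions, n, replace = TRUE)
    meta <- vector("list", n)
    for (i in seq_len(n)) {
      start <- c(sample.int(lim, 1), sample.int(lim, 1))
      path <- simulate_path(start, dirs0[i], spec$T_len, spec$speed, lim,
                            spec$bounce_rule)
      frames[, , i] <- render_sprite_sequence(bank[[sprite_ids[i]]], path, S)
      meta[[i]] <- path
      dirs0[i] <- path$dirs[1]   # actual initial direction (immediate bounces)
    }
    labels <- data.frame(sprite = sprite_ids, direction = dirs0,
                         n_bounces = vapply(meta, function(m)
                           length(m$bounce_times), integer(1)),
                         bounce_rule = spec$bounce_rule,
                         stringsAsFactors = FALSE)
    dpc_dataset(frames, c(S, S), labels = labels, metadata = meta)
  })
}

#' Generate a bouncing-dynamics dataset
#'
#' Longer sequences (default 20 frames) guaranteed to contain at least two
#' boundary bounces, under either the straight or the clockwise bounce
#' rule. Used to expose higher-order transition structure (the bounce type)
#' that a sequence-level state cannot capture.
#'
#' @inheritParams make_moving_sprites
#' @param T_len Frames per sequence (default 20).
#' @param bounce_rule `"straight"` or `"clockwise"`.
#' @return A [dpc_dataset()]; see [make_moving_sprites()].
#' @export
make_bouncing_dataset <- function(spec, T_len = 20,
                                  bounce_rule = c("straight", "clockwise")) {
  stopifnot(inherits(spec, "sprite_spec"))
  bounce_rule <- match.arg(bounce_rule)
  spec$T_len <- as.integer(T_len)
  spec$bounce_rule <- bounce_rule
  span <- spec$frame_size - spec$sprite_size
  if ((spec$T_len - 1) * spec$speed < 2 * span + spec$speed)
    stop_invalid("T_len too short to guarantee two bounces at this speed")
  make_moving_sprites(spec)
}

#' Generate a Gaussian white-noise stimulus sequence
#'
#' Every pixel is an i.i.d. draw from `N(0, variance)`.
#'
#' @param T_len Number of frames.
#' @param M Pixels per frame.
#' @param variance Pixel variance (default 0.0075).
#' @param seed Integer seed.
#' @param frame_shape Optional `c(H, W)`; defaults to a square frame when
#'   `M` is a perfect square, else `c(1, M)`.
#' @return A [dpc_sequence()].
#' @export
make_white_noise <- function(T_len, M, variance = 0.0075, seed = 1,
                             frame_shape = NULL) {
  if (variance <= 0) stop_invalid("variance must be > 0")
  if (is.null(frame_shape)) {
    s <- round(sqrt(M))
    frame_shape <- if (s * s == M) c(s, s) else c(1L, M)
  }
  with_seed(seed, {
    frames <- matrix(stats::rnorm(T_len * M, sd = sqrt(variance)), T_len, M)
    dpc_sequence(frames, frame_shape,
                 metadata = list(kind = "white_noise", variance = variance))
  })
}

#' Generate whitened drifting-texture sequences
#'
#' Surrogate for short natural-movie patches: a band-pass filtered noise
#' texture translates with a per-sequence constant velocity whose direction
#' is drawn from a continuous uniform distribution; translation is
#' implemented as an exact (sub-pixel, periodic) Fourier shift, so the
#' stored velocity is recoverable by cross-correlation. Sequences are then
#' spatially and temporally whitened by [whiten_sequences()] unless
#' `whiten = FALSE`.
#'
#' @param n_sequences Number of sequences.
#' @param frame_size Frame side length (default 16).
#' @param T_len Frames per sequence (default 10).
#' @param speed Drift speed in pixels/frame (0 gives static textures).
#' @param band Pass-band in cycles/pixel for the texture filter.
#' @param whiten Apply [whiten_sequences()] to the result.
#' @param seed Integer seed.
#' @return A [dpc_dataset()] with labels `vx`, `vy` (velocity components,
#'   x = columns rightward, y = rows downward) and `angle`.
#' @export
make_drifting_surrogate <- function(n_sequences, frame_size = 16, T_len = 10,
                                    speed = 1, band = c(0.05, 0.25),
                                    whiten = TRUE, seed = 1) {
  n <- check_positive_int(n_sequences, "n_sequences")
  S <- as.integer(frame_size)
  fy <- c(0:floor(S / 2), -(ceiling(S / 2) - 1):-1)[1:S] / S
  fgrid <- sqrt(outer(fy^2, fy^2, "+"))
  bp <- fgrid >= band[1] & fgrid <= band[2]
  with_seed(seed, {
    frames <- array(0, c(T_len, S^2, n))
    angle <- stats::runif(n, 0, 2 * pi)
    vx <- speed * cos(angle); vy <- speed * sin(angle)
    for (i in seq_len(n)) {
      tex <- matrix(stats::rnorm(S^2), S, S)
      Ft <- stats::fft(tex) * bp
      for (t in seq_len(T_len)) {
        dy <- (t - 1) * vy[i]; dx <- (t - 1) * vx[i]
        phase <- exp(-2i * pi * (outer(fy * dy, rep(1, S)) +
                                 outer(rep(1, S), fy * dx)))
        fr <- Re(stats::fft(Ft * phase, inverse = TRUE)) / S^2
        frames[t, , i] <- frame_to_vec(fr)
      }
      frames[, , i] <- frames[, , i] / stats::sd(frames[, , i])
    }
    ds <- dpc_dataset(frames, c(S, S),
                      labels = data.frame(vx = vx, vy = vy, angle = angle))
    if (whiten) whiten_sequences(ds) else ds
  })
}

#' Estimate per-sequence drift velocity by phase correlation
#'
#' Registers consecutive frames of each sequence by cross-correlation in
#' the Fourier domain and returns the median frame-to-frame displacement.
#' Used as an independent check that generated drifting textures move at
#' their stored velocity.
#'
#' @param ds A [dpc_dataset()].
#' @return A data frame with `vx`, `vy` estimates per sequence.
#' @export
estimate_drift_velocity <- function(ds) {
  S <- ds$frame_shape[1]
  n <- n_sequences(ds); T_len <- dim(ds$frames)[1]
  ## evaluate the cross-correlation surface on a subpixel grid via the
  ## phase spectrum, using a plain argmax over integer+half shifts
  shifts <- seq(-3, 3, by = 0.25)
  fy <- c(0:floor(S / 2), -(ceiling(S / 2) - 1):-1)[1:S] / S
  est <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    vs <- matrix(0, T_len - 1, 2)
    for (t in seq_len(T_len - 1)) {
      A <- stats::fft(vec_to_frame(ds$frames[t, , i], ds$frame_shape))
      B <- stats::fft(vec_to_frame(ds$frames[t + 1, , i], ds$frame_shape))
      X <- A * Conj(B)
      best <- c(0, 0); bestv <- -Inf
      for (dy in shifts) for (dx in shifts) {
        ph <- exp(-2i * pi * (outer(fy * dy, rep(1, S)) +
                              outer(rep(1, S), fy * dx)))
        v <- Re(sum(X * ph))
        if (v > bestv) { bestv <- v; best <- c(dx, dy) }
      }
      vs[t, ] <- best
    }
    est[i, ] <- apply(vs, 2, stats::median)
  }
  data.frame(vx = est[, 1], vy = est[, 2])
}
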