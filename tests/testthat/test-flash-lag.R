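test_that("consistent-motion selection matches a kinematic audit", {
  ds_lr <- make_moving_sprites(sprite_spec(40, directions = c("left", "right"),
                                           T_len = 5, seed = 6))
  ## short horizontal sequences with no bounce are all selected
  no_bounce <- which(ds_lr$labels$n_bounces == 0)
  win <- select_consistent_sequences(ds_lr)
  expect_true(all(no_bounce %in% win$labels$source))
  ## vertical-only motion yields an empty subset
  ds_ud <- make_moving_sprites(sprite_spec(10, directions = c("up", "down"),
                                           seed = 7))
  expect_warning(win_ud <- select_consistent_sequences(ds_ud), "no consistent")
  expect_equal(n_sequences(win_ud), 0)
  ## selected windows really move horizontally at constant direction
  ds <- make_moving_sprites(sprite_spec(60, seed = 8))
  win2 <- select_consistent_sequences(ds)
  for (i in seq_len(n_sequences(win2))) {
    dx <- vapply(1:4, function(t)
      (center_of_mass(win2$frames[t + 1, , i], c(18, 18)) -
         center_of_mass(win2$frames[t, , i], c(18, 18)))[["x"]], numeric(1))
    dirn <- if (win2$labels$direction[i] == "right") 2 else -2
    expect_equal(dx, rep(dirn, 4))
  }
})

test_that("center of mass follows the rectified intensity-weighted mean", {
  fr <- matrix(0, 9, 9); fr[7, 4] <- 1   # row 7, column 4
  expect_equal(center_of_mass(fr), c(x = 4, y = 7))
  fr2 <- matrix(0, 9, 9); fr2[5, 2] <- 1; fr2[5, 6] <- 1
  expect_equal(center_of_mass(fr2), c(x = 4, y = 5))
  set.seed(51)
  v <- abs(rnorm(81))
  fr3 <- matrix(v, 9, 9)
  xs <- sum(fr3 * col(fr3)) / sum(fr3)
  ys <- sum(fr3 * row(fr3)) / sum(fr3)
  expect_equal(center_of_mass(fr3), c(x = xs, y = ys))
  expect_error(center_of_mass(-fr), class = "dpc_invalid_argument")
})

test_that("displacement uses the trajectory-aligned sign convention", {
  expect_equal(displacement(5, 5, "right"), 0)
  expect_equal(displacement(6, 5, "right"), 1)
  expect_equal(displacement(4, 5, "left"), 1)
  expect_equal(displacement(6, 5, "left"), -1)
  expect_error(displacement(1, 2, "up"), class = "dpc_invalid_argument")
})

test_that("percept computation guards degenerate and untrained networks", {
  p <- dpc_params(sprite_shape(), seed = 2)
  ds <- make_moving_sprites(sprite_spec(5, directions = "right", T_len = 5,
                                        seed = 9))
  win <- select_consistent_sequences(ds)
  cond <- flash_lag_condition(win$frames[, , 1], "right", "with_initial",
                              "continuous", c(18, 18))
  expect_warning(percept_at_step(p, cond, dpc_hyper(),
                                 dpc_options(max_iters = 5, backtrack = FALSE)),
                 "untrained")
  pz <- p; pz$U <- pz$U * 0; pz$trained <- TRUE
  out <- percept_at_step(pz, cond, dpc_hyper(),
                         dpc_options(max_iters = 5, backtrack = FALSE))
  expect_false(out$location_defined)
  expect_true(all(out$percept == 0))
})

test_that("latency sweep endpoints agree with its definitions", {
  run <- sprite_run(1)
  p <- run$params
  hy <- dpc_hyper()
  win <- select_consistent_sequences(run$held)
  cond <- flash_lag_condition(win$frames[, , 1], win$labels$direction[1],
                              "with_initial", "reversed", c(18, 18))
  opts <- dpc_options(lr_r = 0.05, lr_rh = 5e-4, max_iters = 200, tol = 0,
                      backtrack = FALSE)
  sw <- latency_sweep(p, cond, hy, opts, fractions = c(0, 0.5, 1))
  ## fraction 0: pure top-down extrapolation along the original direction
  pre <- dpcnet:::prime_condition(cond, p, hy, opts)
  w0 <- hypernet_forward(pre$rh, p$theta)
  percept0 <- decode_image(transition_mean(pre$r2,
                                           mix_transitions(w0, p$V_set)), p$U)
  ref <- center_of_mass(cond$frames[3, ], c(18, 18))["x"]
  d0 <- displacement(center_of_mass(percept0, c(18, 18))["x"], ref,
                     cond$direction)
  expect_equal(sw$displacement[1], unname(d0))
  expect_gt(sw$displacement[1], 0)
  ## fraction 1 equals running the step to its iteration cap
  st <- infer_step(cond$probe, pre$r2, pre$rh, p, hy, opts)
  w1 <- hypernet_forward(st$r_h_hat, p$theta)
  percept1 <- decode_image(transition_mean(pre$r2,
                                           mix_transitions(w1, p$V_set)), p$U)
  d1 <- displacement(center_of_mass(percept1, c(18, 18))["x"], ref,
                     cond$direction)
  expect_equal(sw$displacement[3], unname(d1), tolerance = 1e-8)
  ## unresolvable fractions are rejected
  expect_error(latency_sweep(p, cond, hy,
                             dpc_options(max_iters = 3, backtrack = FALSE),
                             fractions = seq(0, 1, 0.1)),
               class = "dpc_invalid_argument")
  ## only the reversed + with_initial condition is accepted
  cond2 <- flash_lag_condition(win$frames[, , 1], win$labels$direction[1],
                               "with_initial", "stopped", c(18, 18))
  expect_error(latency_sweep(p, cond2, hy, opts),
               class = "dpc_invalid_argument")
})
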