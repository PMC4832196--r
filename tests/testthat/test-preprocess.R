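test_that("delta-F/F normalization follows its defining identities", {
  # constant movie -> dff identically 0
  g <- geom_sp(4, 10)
  mv <- vsd_movie(array(120, c(2, 10, 4, 4)), g, "spontaneous")
  expect_true(all(compute_dff(mv)$data == 0))

  # baseline (100, 100, 100) then 105 -> 0.05
  g1 <- vsd_geometry(n_rows = 1, n_cols = 1, n_frames = 4)
  mv1 <- vsd_movie(array(c(100, 100, 100, 105), c(1, 4, 1, 1)), g1, "blank")
  expect_equal(compute_dff(mv1)$data[1, 4, 1, 1], 0.05)

  # per-pixel scale invariance: F -> c(x, y) * F leaves dff unchanged
  set.seed(42)
  raw <- array(stats::runif(3 * 10 * 4 * 4, 50, 150), c(3, 10, 4, 4))
  mv <- vsd_movie(raw, g, "spontaneous")
  scale <- matrix(stats::runif(16, 0.5, 2), 4, 4)
  raw2 <- raw
  for (i in 1:3) for (f in 1:10) raw2[i, f, , ] <- raw[i, f, , ] * scale
  expect_equal(compute_dff(vsd_movie(raw2, g, "spontaneous"))$data,
               compute_dff(mv)$data, tolerance = 1e-12)

  # degenerate baseline errors and names the pixel
  bad <- array(10, c(1, 5, 2, 2)); bad[1, 1:3, 2, 1] <- 0
  expect_error(compute_dff(vsd_movie(bad, geom_sp(2, 5), "blank")),
               "row 2, col 1")

  # noise-free synthetic evoked trial: dff equals the injected response field
  ge <- geom_ev(15, 31, 11)
  p <- params_noise_free()
  ev <- generate_evoked_trial(ge, p, c(8, 8), rng_seed = 1)
  expect_equal(compute_dff(ev)$data[1, , , ],
               evoked_response_field(ge, p, c(8, 8)), tolerance = 1e-12)
})

test_that("blank subtraction removes shared artifacts", {
  g <- geom_ev(6, 21, 11)
  p <- ctrl_params()
  ev <- generate_evoked_trial(g, p, c(3, 3), 5, n_trials = 3)
  bl <- generate_blank_trial(g, p, 9, n_trials = 3)
  dev <- compute_dff(ev); dbl <- compute_dff(bl)

  # evoked set equal to the blank average -> output identically 0
  out0 <- subtract_blank(dbl, dbl)
  blank_mean <- apply(dbl$data, c(2, 3, 4), mean)
  for (i in 1:3) expect_equal(out0$data[i, , , ], dbl$data[i, , , ] - blank_mean)
  one <- dbl; one$data <- dbl$data[1, , , , drop = FALSE]
  same <- subtract_blank(one, one)
  expect_true(all(abs(same$data) < 1e-15))

  # a single blank trial is subtracted exactly
  out1 <- subtract_blank(dev, one)
  expect_equal(out1$data[2, , , ], dev$data[2, , , ] - dbl$data[1, , , ])

  # geometry mismatch and empty blank set raise errors
  expect_error(subtract_blank(dev, list()), "missing blank")
  small <- compute_dff(generate_blank_trial(geom_ev(5, 21, 11), p, 1))
  expect_error(subtract_blank(dev, small), "shape error")

  # bleaching trend: slope of the spatial-mean trace shrinks >= 5x after
  # subtraction (noise off, spontaneous fluctuations on; 20 seeds)
  pq <- ctrl_params(noise_sd = 1e-12, spont_amplitude = 5e-4, bleach_tau = 3000)
  tt <- frame_times(g)
  slopes <- vapply(1:20, function(s) {
    e <- compute_dff(generate_blank_trial(g, pq, rng_seed = 100 + s))
    b <- compute_dff(generate_blank_trial(g, pq, rng_seed = 200 + s, n_trials = 4))
    before <- stats::coef(stats::lm(apply(e$data[1, , , ], 1, mean) ~ tt))[2]
    aftr <- subtract_blank(e, b)
    after <- stats::coef(stats::lm(apply(aftr$data[1, , , ], 1, mean) ~ tt))[2]
    c(abs(before), abs(after))
  }, c(0, 0))
  expect_gt(mean(slopes[1, ]) / mean(slopes[2, ]), 5)
})

test_that("blank-subtracted blanks average to approximately zero", {
  g <- geom_ev(10, 21, 11)
  p <- ctrl_params(spont_amplitude = 1e-12) # shot noise only
  n_a <- 6L; n_b <- 6L
  da <- compute_dff(generate_blank_trial(g, p, 31, n_trials = n_a))
  db <- compute_dff(generate_blank_trial(g, p, 32, n_trials = n_b))
  out <- subtract_blank(da, db)
  avg <- apply(out$data, c(2, 3, 4), mean)
  expect_lt(mean(abs(avg)), 3 * p$noise_sd / sqrt(n_a))
})

test_that("vessel detection recovers a dark line and nothing far from it", {
  # spatially uniform frame -> empty mask
  expect_equal(sum(detect_vessels(matrix(500, 20, 20))$mask), 0)
  expect_error(detect_vessels(matrix(c(1, NA), 4, 4)), "input error")

  # slowly varying background with shot noise and one dark 1-px line; the
  # threshold is set so the line (a ~25-count residual) is far above it while
  # the sigma-2 high-pass halo beyond 2 px (< 2 counts) stays safely below
  set.seed(7)
  nr <- 40
  bg <- 1000 + 10 * sin(outer(1:nr, rep(1, nr)) / 15) +
    8 * cos(outer(rep(1, nr), 1:nr) / 18)
  frame <- bg + matrix(stats::rnorm(nr * nr, sd = 1), nr, nr)
  frame[20, 5:35] <- 0.97 * frame[20, 5:35]
  vm <- detect_vessels(frame, highpass_sigma = 2, threshold_k = 5)
  line_px <- cbind(20, 5:35)
  expect_true(all(vm$mask[line_px]))
  hit <- which(vm$mask, arr.ind = TRUE)
  # every flagged pixel lies within 2 px of the line
  dist_to_line <- apply(hit, 1, function(px)
    min(abs(px[1] - 20) + pmax(0, abs(px[2] - 20) - 15)))
  expect_true(all(dist_to_line <= 2))

  # the high-pass residual matches a direct tabulated-kernel convolution
  blur <- gaussian_blur(frame, 2)
  oracle <- oracle_gaussian_blur_interior(frame, 2)
  inner <- !is.na(oracle)
  expect_equal(blur[inner], oracle[inner], tolerance = 1e-10)
})

test_that("trial averaging is a missing-aware elementwise mean", {
  g <- geom_sp(3, 8)
  x <- array(stats::rnorm(3 * 8 * 3 * 3, sd = 0.01), c(3, 8, 3, 3))
  mask <- matrix(FALSE, 3, 3); mask[2, 2] <- TRUE
  dff <- dff_from_values(x, vessel_mask = mask)
  mm <- average_trials(dff)
  for (f in 1:8) for (r in 1:3) for (cc in 1:3) {
    if (mask[r, cc]) expect_true(is.na(mm$data[f, r, cc]))
    else expect_equal(mm$data[f, r, cc], mean(dff$data[, f, r, cc]))
  }
  # one trial -> identity; a and -a -> zero
  one <- dff; one$data <- dff$data[1, , , , drop = FALSE]
  expect_equal(average_trials(one)$data, dff$data[1, , , ])
  pm <- array(0, c(2, 8, 3, 3))
  pm[1, 4:8, , ] <- 0.2; pm[2, 4:8, , ] <- -0.2
  expect_true(all(average_trials(dff_from_values(pm))$data == 0))
})

test_that("display smoothing is identity-safe and kernel-exact", {
  m <- matrix(stats::rnorm(100), 10, 10)
  expect_identical(smooth_for_display(m, 0), m)
  cm <- matrix(3.5, 12, 12); cm[4, 7] <- NA
  sm <- smooth_for_display(cm, 1.5)
  expect_equal(sm[!is.na(sm)], rep(3.5, 143), tolerance = 1e-12)
  expect_true(is.na(sm[4, 7])) # vessel pixels stay flagged
  # delta image reproduces the tabulated kernel
  dl <- matrix(0, 21, 21); dl[11, 11] <- 1
  sm <- smooth_for_display(dl, 1.5)
  rad <- ceiling(3 * 1.5)
  k1 <- exp(-(-rad:rad)^2 / (2 * 1.5^2)); k2 <- outer(k1, k1) / sum(outer(k1, k1))
  expect_equal(sm[(11 - rad):(11 + rad), (11 - rad):(11 + rad)], k2,
               tolerance = 1e-12)
})
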