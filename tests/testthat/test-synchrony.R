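test_that("residualization removes the trial-invariant component exactly", {
  set.seed(5)
  x <- array(stats::rnorm(3 * 20 * 4 * 4, sd = 0.01), c(3, 20, 4, 4))
  res <- residuals_from_values(x)
  # per-pixel trial mean of residuals is zero to machine precision
  expect_lt(max(abs(apply(res$data, c(2, 3, 4), mean))), 1e-15)
  # identical trials -> all-zero residuals
  same <- x; same[2, , , ] <- x[1, , , ]; same[3, , , ] <- x[1, , , ]
  expect_true(all(abs(residuals_from_values(same)$data) < 1e-15))
  # two trials a, b -> (a-b)/2 and (b-a)/2 (baseline frames carry 0)
  two <- x[1:2, , , , drop = FALSE]
  two[, 1:3, , ] <- 0
  r2 <- residuals_from_values(two)
  expect_equal(r2$data[1, , , ], (two[1, , , ] - two[2, , , ]) / 2,
               tolerance = 1e-12)
  expect_equal(r2$data[1, , , ], -r2$data[2, , , ], tolerance = 1e-15)
  # a single trial is rejected
  expect_error(residuals_from_values(x[1, , , , drop = FALSE]),
               "insufficient trials")

  # adding any trial-invariant spatiotemporal pattern changes nothing
  pat <- array(0, c(3, 20, 4, 4))
  common <- array(stats::rnorm(17 * 16, sd = 0.05), c(17, 4, 4))
  for (i in 1:3) pat[i, 4:20, , ] <- common
  res_shift <- residuals_from_values(x + pat)
  expect_equal(res_shift$data, res$data, tolerance = 1e-12)
})

test_that("sliding-window correlations match a brute-force Pearson loop", {
  # hand-built +/- pattern: perfectly anti-correlated pixels
  x <- array(0, c(2, 20, 2, 2))
  sig <- sin(seq_len(17))
  x[1, 4:20, 1, 1] <- sig;  x[2, 4:20, 1, 1] <- -sig
  x[1, 4:20, 2, 1] <- -sig; x[2, 4:20, 2, 1] <- sig
  x[1, 4:20, 1, 2] <- sig;  x[2, 4:20, 1, 2] <- -sig
  res <- residuals_from_values(x)
  self <- sliding_window_correlation(res, c(1, 1), c(1, 1))
  expect_true(all(self$r == 1))
  anti <- sliding_window_correlation(res, c(1, 1), c(2, 1))
  expect_true(all(anti$r == -1))
  same <- sliding_window_correlation(res, c(1, 1), c(1, 2))
  expect_true(all(same$r == 1))

  # 3-pixel, 12-frame, 2-trial toy set against the nested-loop oracle
  set.seed(8)
  y <- array(stats::rnorm(2 * 15 * 3 * 1, sd = 0.02), c(2, 15, 3, 1))
  resy <- residuals_from_values(y)
  for (target in 1:3) {
    got <- sliding_window_correlation(resy, c(1, 1), c(target, 1),
                                      window_halfwidth_frames = 2)
    want <- colMeans(rbind(
      oracle_window_corr(resy$data[1, , 1, 1], resy$data[1, , target, 1], 2),
      oracle_window_corr(resy$data[2, , 1, 1], resy$data[2, , target, 1], 2)))
    expect_equal(got$r, want, tolerance = 1e-12)
  }
  # zero-variance windows are missing, never zero
  z <- array(0, c(2, 15, 2, 1))
  z[1, 10, 1, 1] <- 0.5; z[2, 10, 1, 1] <- -0.5 # lone spike, flat elsewhere
  resz <- residuals_from_values(z)
  rz <- sliding_window_correlation(resz, c(1, 1), c(2, 1),
                                   window_halfwidth_frames = 2)
  expect_true(all(is.na(rz$r)))
  expect_gt(rz$n_undefined, 0)
})

test_that("seed maps have the documented geometry and trivial limits", {
  # spatially uniform residuals (same series everywhere, scaled) -> r = 1
  x <- array(0, c(2, 20, 9, 9))
  sig <- 0.3 * cos(seq_len(17) / 2)
  scale <- matrix(stats::runif(81, 0.5, 2), 9, 9)
  for (r in 1:9) for (cc in 1:9) {
    x[1, 4:20, r, cc] <- sig * scale[r, cc]
    x[2, 4:20, r, cc] <- -sig * scale[r, cc]
  }
  res <- residuals_from_values(x)
  map <- seed_correlation_map(res, c(5, 5), half_width_px = 3)
  expect_equal(dim(map$r), c(7, 7))
  expect_true(is.na(map$r[4, 4])) # center excluded by definition
  expect_lt(max(abs(map$r[-c(25)] - 1), na.rm = TRUE), 1e-8)
  expect_true(map$center_excluded)

  # off-grid cells are missing: seed near the corner
  mapc <- seed_correlation_map(res, c(2, 2), half_width_px = 3)
  expect_true(all(is.na(mapc$r[1:2, ])))
  expect_true(all(is.na(mapc$r[, 1:2])))
  sub <- mapc$r[3:7, 3:7]
  expect_true(is.na(sub[2, 2])) # the excluded seed cell
  sub[2, 2] <- 0
  expect_false(anyNA(sub))

  # vessel seeds are rejected
  mask <- matrix(FALSE, 9, 9); mask[5, 5] <- TRUE
  resv <- residuals_from_values(x, vessel_mask = mask)
  expect_error(seed_correlation_map(resv, c(5, 5)), "vessel seed")

  # white-noise residuals: off-center cells average to ~0 (10 seeded sets)
  acc <- matrix(0, 7, 7)
  for (s in 1:10) {
    set.seed(s)
    w <- array(stats::rnorm(10 * 253 * 11 * 11, sd = 0.01), c(10, 253, 11, 11))
    resw <- residuals_from_values(w)
    acc <- acc + seed_correlation_map(resw, c(6, 6), half_width_px = 3)$r
  }
  expect_lt(max(abs(acc / 10), na.rm = TRUE), 0.02)
})

test_that("aligned-map averaging is missing-aware", {
  # identical maps average to themselves; one map is the identity
  x <- array(stats::rnorm(2 * 23 * 8 * 8, sd = 0.01), c(2, 23, 8, 8))
  res <- residuals_from_values(x)
  m1 <- seed_correlation_map(res, c(4, 4), half_width_px = 2)
  expect_equal(average_aligned_maps(list(m1))$r, m1$r)
  expect_equal(average_aligned_maps(list(m1, m1, m1))$r, m1$r)

  # staggered missing cells: loop-computed missing-aware mean
  m2 <- seed_correlation_map(res, c(2, 2), half_width_px = 2) # clipped corner
  m3 <- seed_correlation_map(res, c(7, 7), half_width_px = 2)
  avg <- average_aligned_maps(list(m1, m2, m3))
  for (i in 1:5) for (j in 1:5) {
    cell <- c(m1$r[i, j], m2$r[i, j], m3$r[i, j])
    want <- if (all(is.na(cell))) NA_real_ else mean(cell, na.rm = TRUE)
    expect_equal(avg$r[i, j], want, tolerance = 1e-12)
  }
})

test_that("the unaligned whole-field variant matches its definition", {
  x <- array(stats::rnorm(2 * 23 * 7 * 7, sd = 0.01), c(2, 23, 7, 7))
  res <- residuals_from_values(x)
  # single-seed ROI: that seed's full-field map (self cell excluded)
  um <- unaligned_field_map(res, px_mat(4, 4))
  expect_equal(dim(um$r), c(7, 7))
  expect_true(is.na(um$r[4, 4]))
  aligned <- seed_correlation_map(res, c(4, 4), half_width_px = 3)
  expect_equal(um$r[1:7, 1:7], aligned$r, tolerance = 1e-12)

  # uniform residual field -> all-ones map
  u <- array(0, c(2, 20, 5, 5))
  sig <- sin(seq_len(17) / 3)
  for (r in 1:5) for (cc in 1:5) { u[1, 4:20, r, cc] <- sig; u[2, 4:20, r, cc] <- -sig }
  resu <- residuals_from_values(u)
  umu <- unaligned_field_map(resu, px_mat(3, 3, 3, 4))
  expect_true(all(umu$r == 1, na.rm = TRUE))

  # toy instance against the nested-loop oracle (2-seed average)
  seeds <- px_mat(3, 3, 5, 4)
  um2 <- unaligned_field_map(res, seeds)
  manual <- matrix(0, 7, 7); cnt <- matrix(0, 7, 7)
  for (k in 1:2) {
    sfull <- matrix(NA_real_, 7, 7)
    for (r in 1:7) for (cc in 1:7) {
      vals <- c(oracle_window_corr(res$data[1, , seeds[k, 1], seeds[k, 2]],
                                   res$data[1, , r, cc], 4),
                oracle_window_corr(res$data[2, , seeds[k, 1], seeds[k, 2]],
                                   res$data[2, , r, cc], 4))
      sfull[r, cc] <- mean(vals, na.rm = TRUE)
    }
    sfull[seeds[k, 1], seeds[k, 2]] <- NA
    ok <- !is.na(sfull)
    manual[ok] <- manual[ok] + sfull[ok]; cnt <- cnt + ok
  }
  manual <- manual / cnt
  expect_equal(um2$r, manual, tolerance = 1e-12)
})

test_that("neighborhood synchrony averages the 48-cell annulus", {
  x <- array(stats::rnorm(2 * 23 * 11 * 11, sd = 0.01), c(2, 23, 11, 11))
  res <- residuals_from_values(x)
  map <- seed_correlation_map(res, c(6, 6), half_width_px = 5)
  # brute-force lattice enumeration over the <= 48 in-radius cells
  manual <- c()
  for (dr in -4:4) for (dc in -4:4) {
    d <- sqrt(dr^2 + dc^2)
    if (d > 0 && d <= 4) manual <- c(manual, map$r[6 + dr, 6 + dc])
  }
  expect_length(manual, 48L)
  expect_equal(neighborhood_synchrony(map, 200), mean(manual),
               tolerance = 1e-12)
  # constant maps give back the constant
  mapc <- map; mapc$r[] <- 0.37; mapc$r[6, 6] <- NA
  expect_equal(neighborhood_synchrony(mapc, 200), 0.37)
  expect_error(neighborhood_synchrony(
    unaligned_field_map(res, px_mat(6, 6))), "aligned")
  # direct per-seed route agrees with the map route for an interior seed
  expect_equal(roi_neighborhood_synchrony(res, px_mat(6, 6)),
               neighborhood_synchrony(map, 200), tolerance = 1e-12)
})

test_that("synchrony time course is flat for stationary input and bounded", {
  g <- geom_sp(16, 60)
  p <- ctrl_params()
  sp <- generate_spontaneous_trial(g, p, rng_seed = 21, n_trials = 20)
  res <- make_residuals(compute_dff(sp), 600)
  stc <- synchrony_timecourse(res, px_mat(4, 4, 4, 12, 12, 4, 12, 12, 8, 8))
  # first valid center frame sits half a window in
  expect_equal(length(stc$r), dim(res$data)[2] - 8)
  expect_equal(stc$time_ms[1], res$time_ms[5])
  expect_true(all(stc$r >= -1 & stc$r <= 1))
  expect_lt(stats::sd(stc$r), 0.02)

  # the +/- pattern from the residual trivial case gives |r| = 1
  x <- array(0, c(2, 20, 2, 2))
  sig <- sin(seq_len(17))
  for (r in 1:2) for (cc in 1:2) {
    x[1, 4:20, r, cc] <- sig; x[2, 4:20, r, cc] <- -sig
  }
  stc1 <- synchrony_timecourse(residuals_from_values(x), px_mat(1, 1),
                               radius_um = 100)
  expect_true(all(abs(stc1$r) == 1))
})

test_that("the spatial shuffle destroys structure but keeps frame content", {
  g <- geom_sp(20, 60)
  sp <- generate_spontaneous_trial(g, ctrl_params(), rng_seed = 31, n_trials = 3)
  res <- make_residuals(compute_dff(sp), 600)
  roi <- px_mat(10, 10, 10, 11, 11, 10)
  obs <- roi_neighborhood_synchrony(res, roi)
  null <- shuffle_null(res, roi, n_shuffles = 30, rng_seed = 9)
  expect_length(null, 30L)
  expect_identical(null, shuffle_null(res, roi, n_shuffles = 30, rng_seed = 9))
  expect_gt(obs, max(null)) # strong structure >> any shuffle iterate
  # on a small 14 x 14 field the shuffle-invariant frame mean leaves a small
  # positive floor; it must stay well below the observed synchrony
  expect_lt(abs(mean(null)), obs / 3)
})
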