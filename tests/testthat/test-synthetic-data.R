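test_that("generators are deterministic and sources can be switched off", {
  g <- geom_ev(20, 31, 11)
  p <- ctrl_params()
  a <- generate_evoked_trial(g, p, c(10, 10), rng_seed = 7, n_trials = 2)
  b <- generate_evoked_trial(g, p, c(10, 10), rng_seed = 7, n_trials = 2)
  expect_identical(a$data, b$data)
  sg <- geom_sp(12, 30)
  s1 <- generate_spontaneous_trial(sg, p, rng_seed = 3)
  s2 <- generate_spontaneous_trial(sg, p, rng_seed = 3)
  expect_identical(s1$data, s2$data)
  expect_false(identical(s1$data,
                         generate_spontaneous_trial(sg, p, rng_seed = 4)$data))

  # every fluctuation off -> movie constant at F0
  off <- vsd_params(label = "off", evoked_amplitude = 0, spread_sigma0 = 120,
                    spread_growth = 2, propagation_speed = 15, rise_tau = 25,
                    decay_tau = 120, spont_corr_length = 200,
                    spont_amplitude = 0, noise_sd = 0, heartbeat_amp = 0,
                    bleach_tau = Inf)
  ev <- generate_evoked_trial(g, off, c(10, 10), rng_seed = 1)
  expect_equal(range(ev$data), c(1000, 1000))
  bl <- generate_blank_trial(g, off, rng_seed = 1)
  expect_equal(range(bl$data), c(1000, 1000))
})

test_that("evoked center trace peaks at the closed-form argmax and onset is
           monotone in distance", {
  g <- geom_ev(25, 41, 11)
  p <- params_noise_free()
  center <- c(13, 13)
  R <- evoked_response_field(g, p, center)
  tt <- frame_times(g)
  # frame of maximal R at the center = frame-grid argmax of the closed form
  ctr_trace <- R[, 13, 13]
  g_closed <- evoked_waveform(p, tt)
  expect_equal(which.max(ctr_trace), which.max(g_closed))
  expect_lt(abs(tt[which.max(ctr_trace)] - evoked_peak_time(p)),
            10) # within one frame of the continuous argmax
  # peak amplitude at the center is the injected amplitude (up to the offset
  # between the 10 ms frame grid and the continuous-time argmax)
  expect_equal(max(ctr_trace), p$evoked_amplitude, tolerance = 1e-3)
  # local onset time non-decreasing with distance from the center
  d <- sqrt(outer((1:25 - 13)^2, (1:25 - 13)^2, `+`))
  onset_frame <- apply(R, c(2, 3), function(v) {
    k <- which(v > 0); if (length(k)) k[1] else Inf
  })
  ord <- order(as.vector(d))
  expect_true(all(diff(onset_frame[ord]) >= 0 | diff(as.vector(d)[ord]) == 0 |
                    !is.finite(onset_frame[ord][-1])))
  # errors
  expect_error(generate_evoked_trial(g, p, c(0, 5), 1), "out of bounds")
  expect_error(generate_evoked_trial(geom_sp(25, 41), p, c(13, 13), 1),
               "condition mismatch")
})

test_that("blank trials match evoked trials except where the response is on,
           and their expectation reproduces the heartbeat-bleach trend", {
  g <- geom_ev(16, 31, 11)
  p <- ctrl_params()
  ev <- generate_evoked_trial(g, p, c(8, 8), rng_seed = 11, n_trials = 2)
  bl <- generate_blank_trial(g, p, rng_seed = 11, n_trials = 2)
  R <- evoked_response_field(g, p, c(8, 8))
  for (i in 1:2) {
    diffs <- ev$data[i, , , ] - bl$data[i, , , ]
    expect_true(all((abs(diffs) > 1e-12) == (R > 0)))
  }

  # mean over 200 seeded blanks ~ F0 * (1 + H(t)) * B(t) at fixed phase
  sg <- geom_sp(8, 40)
  acc <- 0
  for (s in 1:200) acc <- acc + generate_blank_trial(sg, p, rng_seed = s)$data[1, , 4, 4]
  acc <- acc / 200
  t_abs <- (0:39) * 10
  expected <- 1000 * (1 + p$heartbeat_amp *
                        sin(2 * pi * p$heartbeat_freq * t_abs / 1000)) *
    exp(-t_abs / p$bleach_tau)
  expect_lt(max(abs(acc - expected)), 0.6) # ~5 sd of the Monte-Carlo error
})

test_that("vessel masks follow the documented random walk and stay sparse", {
  g100 <- vsd_geometry(n_frames = 5)
  expect_equal(generate_vessel_mask(g100, 0, 1),
               matrix(FALSE, 100, 100))
  m1 <- generate_vessel_mask(g100, 3, 7)
  expect_identical(m1, generate_vessel_mask(g100, 3, 7))
  # scripted replay of the walk rules reproduces the mask exactly
  expect_identical(m1, oracle_vessel_mask(100, 100, 3, 7))
  expect_lte(mean(m1), 0.15)
  expect_gt(sum(m1), 0)
  # masked fraction stays bounded even on small grids / many vessels
  gs <- vsd_geometry(n_rows = 20, n_cols = 20, n_frames = 5)
  for (s in 1:5) expect_lte(mean(generate_vessel_mask(gs, 10, s)), 0.15 + 2 / 400)
  expect_error(generate_vessel_mask(
    vsd_geometry(n_rows = 0, n_cols = 10, n_frames = 5), 1, 1))
})

test_that("spontaneous spatial correlation tracks spont_corr_length", {
  sg <- geom_sp(16, 100)
  neighbor_r <- function(corr_um, seeds) {
    # mean correlation over every horizontally adjacent pixel pair; the slow
    # AR(1) dynamics make single-pair estimates noisy, so pool widely
    mean(vapply(seeds, function(s) {
      p <- ctrl_params(spont_corr_length = corr_um, noise_sd = 1e-12,
                       heartbeat_amp = 0, bleach_tau = Inf)
      mv <- generate_spontaneous_trial(sg, p, rng_seed = s)
      x <- mv$data[1, , , ]
      dim(x) <- c(100, 16 * 16)
      cm <- stats::cor(x)
      idx <- cbind(rep(1:16, 15) + 16 * (rep(1:15, each = 16) - 1),
                   rep(1:16, 15) + 16 * rep(1:15, each = 16))
      mean(cm[idx])
    }, 0))
  }
  # kernel much narrower than a pixel: neighbors uncorrelated
  r_tiny <- neighbor_r(1, 1:10)       # 0.02 px
  expect_lt(abs(r_tiny), 0.02)
  # 4 px correlation length beats 1 px
  r_small <- neighbor_r(50, 1:10)     # 1 px
  r_large <- neighbor_r(200, 1:10)    # 4 px
  expect_gt(r_large, r_small)
  expect_gt(r_large, 0.5)
  expect_error(ctrl_params(spont_corr_length = -5), "invalid parameter")
})

test_that("cohorts have the right structure and respect jitter settings", {
  g <- geom_ev(18, 21, 11)
  co <- generate_cohort(g, ctrl_params(), tg_params(),
                        n_animals_per_group = c(3L, 2L),
                        n_trials_per_condition = 2L, rng_seed = 5,
                        n_spont_trials = 2L, spont_n_frames = 20L,
                        n_vessels = 1L)
  expect_length(co$animals, 5L)
  expect_equal(vapply(co$animals, `[[`, "", "group"),
               c("Ctrl", "Ctrl", "Ctrl", "Tg", "Tg"))
  expect_true(all(vapply(co$animals, function(a) n_trials(a$evoked), 0L) == 2L))
  expect_true(all(vapply(co$animals, function(a) n_trials(a$spontaneous), 0L) == 2L))
  # jitter produces distinct per-animal parameters...
  amps <- vapply(co$animals[1:3], function(a) a$params$evoked_amplitude, 0)
  expect_gt(stats::sd(amps), 0)
  # ...and zero jitter makes same-group animals identical
  co0 <- generate_cohort(g, ctrl_params(), tg_params(),
                         n_animals_per_group = c(2L, 1L),
                         n_trials_per_condition = 1L, rng_seed = 5,
                         n_spont_trials = 1L, spont_n_frames = 20L,
                         n_vessels = 0L, jitter_sd = 0)
  expect_identical(co0$animals[[1]]$params, co0$animals[[2]]$params)
})
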