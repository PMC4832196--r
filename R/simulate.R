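# Synthetic VSDI movie generator.
#
# Signal model (multiplicative, so that delta-F/F preprocessing recovers the
# injected components exactly in the noise-free limit):
#
#   F(t, x, y) = F0(x, y) * (1 + R + S + H(t)) * B(t) + eps
#
# R  evoked response: peak-normalized double-exponential in local time,
#    Gaussian in distance, with a propagation delay beyond the initial
#    footprint (see evoked_response_field).
# S  spatially correlated spontaneous fluctuation (Gaussian-smoothed white
#    noise with AR(1) temporal dynamics).
# H  spatially uniform heart-beat sinusoid; phase fixed across trials by
#    default, emulating ECG-locked acquisition (what makes blank subtraction
#    remove it).
# B  shared single-exponential photobleaching.
# eps white measurement noise, sd = noise_sd * F0.
#
# Vessel pixels carry a depressed resting fluorescence (0.5 * F0).

# temporal AR(1) time constant of spontaneous activity, ms (fixed; the slow
# component of anesthetized cortical VSD fluctuations)
SPONT_AR_TAU_MS <- 100

# ---- low-level spatial helpers ----------------------------------------------

# symmetric 1-D Gaussian kernel, truncated at 3 sd (radius >= 1 px)
gaussian_kernel <- function(sigma_px) {
  rad <- max(1L, as.integer(ceiling(3 * sigma_px)))
  k <- exp(-(seq(-rad, rad))^2 / (2 * max(sigma_px, 1e-8)^2))
  k
}

# banded convolution matrix for one axis; rows optionally renormalized so a
# constant image maps to itself at the borders
band_matrix <- function(n, kernel, renormalize = TRUE) {
  rad <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (off in -rad:rad) {
    idx <- seq_len(n)
    ok <- idx + off >= 1L & idx + off <= n
    K[cbind(idx[ok], (idx + off)[ok])] <- kernel[off + rad + 1L]
  }
  if (renormalize) K <- K / rowSums(K)
  K
}

# spatially correlated, temporally AR(1), unit-variance (grid interior) field
# [frame, row, col]; consumes n_frames * n_rows * n_cols normal draws
spont_field <- function(n_rows, n_cols, n_frames, sigma_px, dt_ms = 10) {
  k <- gaussian_kernel(sigma_px)
  Kr <- band_matrix(n_rows, k, renormalize = FALSE)
  Kc <- band_matrix(n_cols, k, renormalize = FALSE)
  # exact per-pixel sd of the separable convolution of unit white noise, so
  # the field has unit variance everywhere (edges and kernels wider than the
  # grid included)
  norm <- sqrt(outer(rowSums(Kr^2), rowSums(Kc^2)))
  rho <- exp(-dt_ms / SPONT_AR_TAU_MS)
  innov <- sqrt(1 - rho^2)
  out <- array(0, c(n_frames, n_rows, n_cols))
  prev <- NULL
  for (f in seq_len(n_frames)) {
    w <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
    sm <- (Kr %*% w %*% t(Kc)) / norm
    prev <- if (f == 1L) sm else rho * prev + innov * sm
    out[f, , ] <- prev
  }
  out
}

# ---- vessel mask ------------------------------------------------------------

#' Simulate a blood-vessel mask
#'
#' Draws `n_vessels` curvilinear vessels as correlated random walks. The walk
#' rules are fixed so the procedure can be replayed independently: for each
#' vessel, in order, draw the width `w` with `sample(1:2, 1)`; the entry side
#' with `sample(1:4, 1)` (1 top, 2 bottom, 3 left, 4 right); the entry
#' coordinate along that side with `runif(1, 1, extent)`; and a heading
#' pointing into the grid perturbed by `runif(1, -0.5, 0.5)` radians. Then
#' take unit-length steps, each preceded by a heading increment
#' `rnorm(1, 0, 0.3)`; after every step the nearest pixel is marked, plus its
#' perpendicular neighbor (heading rotated +90 degrees, rounded) when
#' `w == 2`. A vessel ends when its walk leaves the grid or after
#' `2 * max(n_rows, n_cols)` steps. Drawing stops before any step that would
#' push the masked fraction above 15%.
#'
#' @param geometry A [vsd_geometry()].
#' @param n_vessels Number of vessels (>= 0).
#' @param rng_seed Integer seed; the mask is a pure function of
#'   `(geometry, n_vessels, rng_seed)`.
#' @return Logical `n_rows x n_cols` matrix, `TRUE` on vessels.
#' @export
generate_vessel_mask <- function(geometry, n_vessels, rng_seed) {
  stopifnot(inherits(geometry, "vsd_geometry"))
  if (n_vessels < 0) stop_vsdi("n_vessels must be >= 0")
  nr <- geometry$n_rows; nc <- geometry$n_cols
  mask <- matrix(FALSE, nr, nc)
  if (n_vessels == 0L) return(mask)
  max_frac <- 0.15
  max_steps <- 2L * max(nr, nc)
  with_seed(rng_seed, {
    for (v in seq_len(n_vessels)) {
      w <- sample(1:2, 1L)
      side <- sample(1:4, 1L)
      if (side <= 2L) { # top/bottom
        pos <- c(if (side == 1L) 1 else nr, stats::runif(1, 1, nc))
        heading <- if (side == 1L) pi / 2 else -pi / 2
      } else {          # left/right
        pos <- c(stats::runif(1, 1, nr), if (side == 3L) 1 else nc)
        heading <- if (side == 3L) 0 else pi
      }
      heading <- heading + stats::runif(1, -0.5, 0.5)
      for (s in seq_len(max_steps)) {
        heading <- heading + stats::rnorm(1, 0, 0.3)
        # heading measured as (d_col, d_row) = (cos, sin) in matrix coords
        pos <- pos + c(sin(heading), cos(heading))
        r <- as.integer(round(pos[1])); c_ <- as.integer(round(pos[2]))
        if (r < 1L || r > nr || c_ < 1L || c_ > nc) break
        hits <- cbind(r, c_)
        if (w == 2L) {
          pr <- r + as.integer(round(sin(heading + pi / 2)))
          pc <- c_ + as.integer(round(cos(heading + pi / 2)))
          if (pr >= 1L && pr <= nr && pc >= 1L && pc <= nc)
            hits <- rbind(hits, c(pr, pc))
        }
        cand <- mask
        cand[hits] <- TRUE
        if (mean(cand) > max_frac) return(mask)
        mask <- cand
      }
    }
    mask
  })
}

# ---- evoked response field --------------------------------------------------

#' Noise-free evoked response field
#'
#' The deterministic delta-F/F component injected into evoked trials. At a
#' pixel a distance `d` um from the wavefront center the local time is
#' `tau = t - max(0, d - spread_sigma0) / propagation_speed` (the initial
#' footprint of width `spread_sigma0` activates synchronously; the wave
#' travels outward from its edge). For `tau > 0` the response is
#'
#'   `evoked_amplitude * g(tau)/g(t*) * exp(-d^2 / (2 * sigma(tau)^2))`
#'
#' with `g` the rise/decay double-exponential, `t*` its analytic argmax (see
#' [evoked_peak_time()]) and `sigma(tau) = spread_sigma0 + spread_growth *
#' tau`. At the center the peak equals `evoked_amplitude` exactly.
#'
#' @param geometry A [vsd_geometry()] with a stimulus onset.
#' @param params A [vsd_params()].
#' @param center Wavefront center, `c(row, col)`.
#' @return Array `[frame, row, col]` of delta-F/F values.
#' @export
evoked_response_field <- function(geometry, params, center) {
  if (is.null(geometry$stim_onset_frame))
    stop_vsdi("condition mismatch: evoked trials need a stim_onset_frame")
  if (center[1] < 1 || center[1] > geometry$n_rows ||
      center[2] < 1 || center[2] > geometry$n_cols)
    stop_vsdi("center out of bounds")
  d_um <- pixel_distance(geometry$n_rows, geometry$n_cols, center) *
    geometry$pixel_size
  delay <- pmax(0, d_um - params$spread_sigma0) / params$propagation_speed
  tt <- frame_times(geometry)
  gpk <- {
    ts <- evoked_peak_time(params)
    exp(-ts / params$decay_tau) - exp(-ts / params$rise_tau)
  }
  out <- array(0, c(geometry$n_frames, geometry$n_rows, geometry$n_cols))
  for (f in seq_len(geometry$n_frames)) {
    tau <- tt[f] - delay
    on <- tau > 0
    if (!any(on)) next
    taup <- tau[on]
    sig <- params$spread_sigma0 + params$spread_growth * taup
    g <- exp(-taup / params$decay_tau) - exp(-taup / params$rise_tau)
    frame <- matrix(0, geometry$n_rows, geometry$n_cols)
    frame[on] <- params$evoked_amplitude * (g / gpk) *
      exp(-d_um[on]^2 / (2 * sig^2))
    out[f, , ] <- frame
  }
  out
}

# ---- trial generators -------------------------------------------------------

# shared machinery: one RNG layout for all conditions so that blank and evoked
# trials from the same seed differ only through the response field R
generate_trials_impl <- function(geometry, params, rng_seed, n_trials,
                                 condition, center = NULL, vessel_mask = NULL,
                                 f0 = 1000, heartbeat_phase = 0) {
  stopifnot(inherits(geometry, "vsd_geometry"), inherits(params, "vsd_params"))
  nr <- geometry$n_rows; nc <- geometry$n_cols; nf <- geometry$n_frames
  mask <- as_mask(vessel_mask, geometry)
  F0 <- matrix(f0, nr, nc)
  F0[mask] <- 0.5 * f0
  t_abs <- (seq_len(nf) - 1L) * frame_dt_ms(geometry)
  H <- params$heartbeat_amp *
    sin(2 * pi * params$heartbeat_freq * t_abs / 1000 + heartbeat_phase)
  B <- if (is.finite(params$bleach_tau)) exp(-t_abs / params$bleach_tau)
       else rep(1, nf)
  R <- if (condition == "evoked") evoked_response_field(geometry, params, center)
       else array(0, c(nf, nr, nc))
  sigma_px <- params$spont_corr_length / geometry$pixel_size
  trial_seeds <- with_seed(rng_seed, draw_seeds(n_trials))
  data <- array(NA_real_, c(n_trials, nf, nr, nc))
  f0v <- as.vector(F0)
  rmat <- R
  dim(rmat) <- c(nf, nr * nc)
  for (i in seq_len(n_trials)) {
    with_seed(trial_seeds[i], {
      S <- params$spont_amplitude *
        spont_field(nr, nc, nf, sigma_px, frame_dt_ms(geometry))
      dim(S) <- c(nf, nr * nc)
      m <- (1 + rmat + S + H) * B          # H, B recycle along the frame axis
      m <- sweep(m, 2L, f0v, `*`)
      eps <- matrix(stats::rnorm(nf * nr * nc), nf)
      m <- m + params$noise_sd * sweep(eps, 2L, f0v, `*`)
      data[i, , , ] <- array(m, c(nf, nr, nc))
    })
  }
  gt <- list(list(condition = condition, params = params, center = center,
                  trial_seeds = trial_seeds, rng_seed = rng_seed,
                  vessel_mask = mask, f0 = f0,
                  heartbeat_phase = heartbeat_phase,
                  evoked_amplitude = if (condition == "evoked")
                    rep(params$evoked_amplitude, n_trials) else NULL,
                  spont_corr_length = params$spont_corr_length))
  new_vsd_movie(data, geometry, condition, group = params$label,
                ground_truth = gt)
}

#' Simulate whisker-evoked trials
#'
#' Generates raw fluorescence movies containing the evoked response field of
#' [evoked_response_field()] on top of spontaneous fluctuations, a heart-beat
#' oscillation, photobleaching and shot noise. Output is a pure function of
#' `(geometry, params, center, rng_seed, ...)`; the returned movie carries a
#' `ground_truth` record (injected amplitude, center, per-trial seeds, vessel
#' mask) from which the noise-free delta-F/F is exactly reconstructible.
#'
#' @param geometry A [vsd_geometry()]; must have `stim_onset_frame`.
#' @param params A [vsd_params()].
#' @param center Wavefront center `c(row, col)`, inside the grid.
#' @param rng_seed Integer seed.
#' @param n_trials Trials to generate (sharing center and parameters).
#' @param vessel_mask Optional logical matrix (or [detect_vessels()] result);
#'   vessel pixels get a depressed resting fluorescence.
#' @param f0 Resting fluorescence level in camera counts.
#' @param heartbeat_phase Heart-beat phase (radians) shared by all trials;
#'   the default 0 emulates ECG-locked acquisition. Pass e.g.
#'   `runif(1, 0, 2*pi)` per trial set for unlocked recordings.
#' @return A `vsd_movie` with `n_trials` trials.
#' @export
generate_evoked_trial <- function(geometry, params, center, rng_seed,
                                  n_trials = 1L, vessel_mask = NULL,
                                  f0 = 1000, heartbeat_phase = 0) {
  generate_trials_impl(geometry, params, rng_seed, n_trials, "evoked",
                       center = center, vessel_mask = vessel_mask, f0 = f0,
                       heartbeat_phase = heartbeat_phase)
}

#' Simulate blank (no-stimulation) trials
#'
#' Identical to [generate_evoked_trial()] with the response field forced to
#' zero but all nuisance components retained; with the same seed and
#' parameters, blank and evoked movies differ only where the response field is
#' positive.
#'
#' @inheritParams generate_evoked_trial
#' @return A `vsd_movie`.
#' @export
generate_blank_trial <- function(geometry, params, rng_seed, n_trials = 1L,
                                 vessel_mask = NULL, f0 = 1000,
                                 heartbeat_phase = 0) {
  generate_trials_impl(geometry, params, rng_seed, n_trials, "blank",
                       vessel_mask = vessel_mask, f0 = f0,
                       heartbeat_phase = heartbeat_phase)
}

#' Simulate spontaneous-activity trials
#'
#' The spontaneous field is spatiotemporal white noise convolved with an
#' isotropic Gaussian of sd `spont_corr_length` and filtered by a first-order
#' autoregression in time (time constant 100 ms), scaled to per-pixel sd
#' `spont_amplitude`. Heart beat, bleaching and shot noise are added as in
#' [generate_evoked_trial()].
#'
#' @inheritParams generate_evoked_trial
#' @param geometry A [vsd_geometry()]; no stimulus onset required.
#' @return A `vsd_movie`.
#' @export
generate_spontaneous_trial <- function(geometry, params, rng_seed,
                                       n_trials = 1L, vessel_mask = NULL,
                                       f0 = 1000, heartbeat_phase = 0) {
  generate_trials_impl(geometry, params, rng_seed, n_trials, "spontaneous",
                       vessel_mask = vessel_mask, f0 = f0,
                       heartbeat_phase = heartbeat_phase)
}

# ---- cohort -----------------------------------------------------------------

# log-normal multiplicative jitter applied per animal to the response-shape
# and spontaneous-structure parameters
jitter_params <- function(params, sd) {
  if (sd <= 0) return(params)
  fields <- c("evoked_amplitude", "spread_sigma0", "spread_growth",
              "rise_tau", "decay_tau", "spont_corr_length", "spont_amplitude")
  p <- unclass(params)
  for (nm in fields) p[[nm]] <- p[[nm]] * exp(stats::rnorm(1, 0, sd))
  do.call(vsd_params, p)
}

#' Simulate a two-group cohort of animals
#'
#' For each animal: a vessel mask, evoked trials, blank trials and spontaneous
#' trials, with per-animal multiplicative log-normal jitter on the generator
#' parameters so that between-animal variance is nonzero. Group sizes default
#' to 8 control-like and 6 transgenic-like animals with 20 trials per
#' stimulated condition.
#'
#' @param geometry Evoked-trial [vsd_geometry()] (with stimulus onset).
#' @param ctrl_params,tg_params [vsd_params()] sets for the two groups.
#' @param n_animals_per_group Length-2 integer vector `c(n_ctrl, n_tg)`.
#' @param n_trials_per_condition Evoked and blank trials per animal.
#' @param rng_seed Integer seed; the whole cohort is reproducible from it.
#' @param n_spont_trials Spontaneous trials per animal.
#' @param spont_n_frames Frames per spontaneous trial (default 250 = 2500 ms
#'   at 100 Hz).
#' @param n_vessels Vessels per animal (see [generate_vessel_mask()]).
#' @param jitter_sd Log-scale sd of the per-animal parameter jitter
#'   (default 0.10); 0 gives identical parameters within a group.
#' @param f0 Resting fluorescence in counts.
#' @return A list of class `vsd_cohort`: `animals` (each with `animal_id`,
#'   `group`, jittered `params`, `center`, `vessel_mask` and the three
#'   `vsd_movie`s), plus the geometries and the seed.
#' @export
generate_cohort <- function(geometry, ctrl_params, tg_params,
                            n_animals_per_group = c(8L, 6L),
                            n_trials_per_condition = 20L,
                            rng_seed = 1L,
                            n_spont_trials = 10L,
                            spont_n_frames = 250L,
                            n_vessels = 3L,
                            jitter_sd = 0.10,
                            f0 = 1000) {
  stopifnot(length(n_animals_per_group) == 2L,
            all(n_animals_per_group >= 1L), n_trials_per_condition >= 1L)
  spont_geom <- vsd_geometry(geometry$n_rows, geometry$n_cols,
                             geometry$pixel_size, geometry$frame_rate,
                             n_frames = spont_n_frames)
  n_total <- sum(n_animals_per_group)
  groups <- rep(c(ctrl_params$label, tg_params$label), n_animals_per_group)
  base <- list(ctrl_params, tg_params)[rep(1:2, n_animals_per_group)]
  # central third of the grid keeps the 800 um ring radius mostly on-chip
  rlo <- max(1L, floor(geometry$n_rows / 3)); rhi <- ceiling(2 * geometry$n_rows / 3)
  clo <- max(1L, floor(geometry$n_cols / 3)); chi <- ceiling(2 * geometry$n_cols / 3)
  animals <- with_seed(rng_seed, {
    lapply(seq_len(n_total), function(a) {
      p <- jitter_params(base[[a]], jitter_sd)
      center <- c(sample(rlo:rhi, 1L), sample(clo:chi, 1L))
      seeds <- draw_seeds(4L)
      mask <- generate_vessel_mask(geometry, n_vessels, seeds[1])
      if (mask[center[1], center[2]]) { # keep the barrel center off vessels
        free <- which(!mask, arr.ind = TRUE)
        d <- (free[, 1] - center[1])^2 + (free[, 2] - center[2])^2
        center <- as.integer(free[which.min(d), ])
      }
      ev <- generate_evoked_trial(geometry, p, center, seeds[2],
                                  n_trials = n_trials_per_condition,
                                  vessel_mask = mask, f0 = f0)
      bl <- generate_blank_trial(geometry, p, seeds[3],
                                 n_trials = n_trials_per_condition,
                                 vessel_mask = mask, f0 = f0)
      sp <- generate_spontaneous_trial(spont_geom, p, seeds[4],
                                       n_trials = n_spont_trials,
                                       vessel_mask = mask, f0 = f0)
      id <- sprintf("%s_%02d", groups[a], a)
      for (m in c("ev", "bl", "sp")) {
        mv <- get(m); mv$animal_id <- id; mv$group <- groups[a]; assign(m, mv)
      }
      list(animal_id = id, group = groups[a], params = p, center = center,
           vessel_mask = mask, seeds = seeds,
           evoked = ev, blank = bl, spontaneous = sp)
    })
  })
  structure(list(animals = animals, geometry = geometry,
                 spont_geometry = spont_geom, rng_seed = rng_seed),
            class = "vsd_cohort")
}

#' @export
print.vsd_cohort <- function(x, ...) {
  groups <- vapply(x$animals, `[[`, "", "group")
  cat(sprintf("<vsd_cohort> %d animals (%s)\n", length(x$animals),
              paste(sprintf("%s n=%d", names(table(groups)), table(groups)),
                    collapse = ", ")))
  invisible(x)
}
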