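# Fixture builders and independent oracles shared by the test files.
# Oracles are deliberately naive (nested loops, direct enumeration) and never
# reuse package internals beyond public constructors.

# geometry shorthand
geom_ev <- function(n = 30L, n_frames = 41L, onset = 11L)
  vsd_geometry(n_rows = n, n_cols = n, n_frames = n_frames,
               stim_onset_frame = onset)

geom_sp <- function(n = 20L, n_frames = 80L)
  vsd_geometry(n_rows = n, n_cols = n, n_frames = n_frames)

# noise-free parameter variants
params_noise_free <- function(base = ctrl_params(), ...) {
  do.call(ctrl_params, utils::modifyList(
    list(noise_sd = 0, spont_amplitude = 1e-30, heartbeat_amp = 0,
         bleach_tau = Inf, label = base$label), list(...)))
}

# build a dff_movie whose delta-F/F values equal `x` exactly: raw = 1 + x with
# the baseline frames forced to exactly 1 (x = 0 there)
dff_from_values <- function(x, condition = "spontaneous", pixel_size = 50,
                            vessel_mask = NULL) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  x[, 1:3, , ] <- 0
  g <- vsd_geometry(n_rows = d[3], n_cols = d[4], pixel_size = pixel_size,
                    n_frames = d[2])
  compute_dff(vsd_movie(1 + x, g, condition), vessel_mask = vessel_mask)
}

# residual_movie carrying exactly the values in `x` (trial means removed the
# same way the package does, through the public path)
residuals_from_values <- function(x, ...) {
  make_residuals(dff_from_values(x, ...), window_ms = dim(x)[2] * 10)
}

# ---- naive oracles ----------------------------------------------------------

# windowed Pearson r between two traces, loop form
oracle_window_corr <- function(a, b, hw) {
  n <- length(a)
  centers <- (hw + 1L):(n - hw)
  vapply(centers, function(t) {
    ia <- a[(t - hw):(t + hw)]; ib <- b[(t - hw):(t + hw)]
    if (stats::sd(ia) == 0 || stats::sd(ib) == 0) return(NA_real_)
    stats::cor(ia, ib)
  }, 0)
}

# full aligned-map pipeline, nested loops: mean over window centers and trials
# per cell, then cellwise mean across seed maps
oracle_aligned_map <- function(res_arr, seeds, hw_frames, half_width_px) {
  d <- dim(res_arr) # trial, frame, row, col
  side <- 2L * half_width_px + 1L
  maps <- array(NA_real_, c(side, side, nrow(seeds)))
  for (s in seq_len(nrow(seeds))) {
    sr <- seeds[s, 1]; sc <- seeds[s, 2]
    for (dr in -half_width_px:half_width_px) {
      for (dc in -half_width_px:half_width_px) {
        if (dr == 0 && dc == 0) next
        tr <- sr + dr; tc <- sc + dc
        if (tr < 1 || tr > d[3] || tc < 1 || tc > d[4]) next
        vals <- c()
        for (i in seq_len(d[1])) {
          vals <- c(vals, oracle_window_corr(res_arr[i, , sr, sc],
                                             res_arr[i, , tr, tc], hw_frames))
        }
        if (any(!is.na(vals)))
          maps[dr + half_width_px + 1L, dc + half_width_px + 1L, s] <-
            mean(vals, na.rm = TRUE)
      }
    }
  }
  out <- apply(maps, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  out
}

# direct 2-D convolution with an explicitly tabulated, normalized Gaussian
# kernel; valid in the interior only (no edge handling)
oracle_gaussian_blur_interior <- function(x, sigma) {
  rad <- max(1L, ceiling(3 * sigma))
  k1 <- exp(-(-rad:rad)^2 / (2 * sigma^2))
  k2 <- outer(k1, k1); k2 <- k2 / sum(k2)
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(NA_real_, nr, nc)
  for (i in (rad + 1):(nr - rad)) {
    for (j in (rad + 1):(nc - rad)) {
      out[i, j] <- sum(k2 * x[(i - rad):(i + rad), (j - rad):(j + rad)])
    }
  }
  out
}

# exact two-sided rank-sum p by exhaustive enumeration of group assignments
# (no ties assumed); mirrors the standard two-sided convention
oracle_rank_sum_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); n <- length(pooled)
  w_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, `>`))
  }
  w_obs <- w_of(seq_len(n1))
  wnull <- utils::combn(n, n1, w_of)
  mid <- n1 * (n - n1) / 2
  p <- if (w_obs > mid) mean(wnull >= w_obs) else mean(wnull <= w_obs)
  min(1, 2 * p)
}

# exact two-sided signed-rank p by enumeration of all sign assignments
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vnull <- as.vector(signs %*% rk)
  mid <- n * (n + 1) / 4
  p <- if (v_obs > mid) mean(vnull >= v_obs) else mean(vnull <= v_obs)
  min(1, 2 * p)
}

# replay of the documented vessel random-walk procedure (same RNG call order)
oracle_vessel_mask <- function(n_rows, n_cols, n_vessels, rng_seed) {
  mask <- matrix(FALSE, n_rows, n_cols)
  if (n_vessels == 0) return(mask)
  set.seed(as.integer(rng_seed))
  max_steps <- 2L * max(n_rows, n_cols)
  for (v in seq_len(n_vessels)) {
    w <- sample(1:2, 1)
    side <- sample(1:4, 1)
    if (side <= 2) {
      pos <- c(if (side == 1) 1 else n_rows, stats::runif(1, 1, n_cols))
      heading <- if (side == 1) pi / 2 else -pi / 2
    } else {
      pos <- c(stats::runif(1, 1, n_rows), if (side == 3) 1 else n_cols)
      heading <- if (side == 3) 0 else pi
    }
    heading <- heading + stats::runif(1, -0.5, 0.5)
    for (s in seq_len(max_steps)) {
      heading <- heading + stats::rnorm(1, 0, 0.3)
      pos <- pos + c(sin(heading), cos(heading))
      r <- as.integer(round(pos[1])); cc <- as.integer(round(pos[2]))
      if (r < 1 || r > n_rows || cc < 1 || cc > n_cols) break
      hits <- cbind(r, cc)
      if (w == 2) {
        pr <- r + as.integer(round(sin(heading + pi / 2)))
        pc <- cc + as.integer(round(cos(heading + pi / 2)))
        if (pr >= 1 && pr <= n_rows && pc >= 1 && pc <= n_cols)
          hits <- rbind(hits, c(pr, pc))
      }
      cand <- mask
      cand[hits] <- TRUE
      if (mean(cand) > 0.15) return(mask)
      mask <- cand
    }
  }
  mask
}

# continuous-time pooled ring response from the closed-form field model,
# evaluated independently of the generator's frame sampling
oracle_ring_peak_time <- function(params, ring_pixels, center, pixel_size,
                                  t_grid = seq(0, 300, 0.1)) {
  d_um <- sqrt((ring_pixels[, 1] - center[1])^2 +
               (ring_pixels[, 2] - center[2])^2) * pixel_size
  delay <- pmax(0, d_um - params$spread_sigma0) / params$propagation_speed
  gpk <- {
    ts <- log(params$decay_tau / params$rise_tau) * params$rise_tau *
      params$decay_tau / (params$decay_tau - params$rise_tau)
    exp(-ts / params$decay_tau) - exp(-ts / params$rise_tau)
  }
  trace <- vapply(t_grid, function(t) {
    tau <- t - delay
    on <- tau > 0
    if (!any(on)) return(0)
    sig <- params$spread_sigma0 + params$spread_growth * tau[on]
    g <- exp(-tau[on] / params$decay_tau) - exp(-tau[on] / params$rise_tau)
    sum(g / gpk * exp(-d_um[on]^2 / (2 * sig^2))) / length(d_um)
  }, 0)
  t_grid[which.max(trace)]
}

# 1-row pixel matrix in the package's (row, col) layout
px_mat <- function(...) {
  m <- matrix(as.integer(c(...)), ncol = 2, byrow = TRUE)
  colnames(m) <- c("row", "col")
  m
}
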