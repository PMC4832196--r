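# Seed-pixel spatial correlation analysis.
#
# All correlations are zero-lag Pearson r over short sliding windows (80 ms =
# center frame +/- 4 at 100 Hz), computed per trial on residual movies (the
# trial-averaged response removed), then averaged — plain averaging of r, not
# Fisher-z — over window positions, trials and seed pixels. The hot path uses
# cumulative sums so each (seed, trial) costs O(frames x pixels).

#' Residual movie: single trials minus the trial-averaged response
#'
#' Removes the stimulus-locked (or slow shared) component so that the
#' remaining correlations reflect internal covariability rather than the
#' common evoked response. The analysis window defaults to 150 ms from
#' stimulus onset for evoked trials and the first 2500 ms for spontaneous or
#' blank trials (clipped to the trial length).
#'
#' @param dff A `dff_movie` with at least 2 trials.
#' @param window_ms Length of the analysis window in ms, measured from t = 0;
#'   `NULL` uses the condition default above.
#' @return An object of class `residual_movie` (4-D residual data restricted
#'   to the window, per-pixel trial means exactly zero).
#' @export
make_residuals <- function(dff, window_ms = NULL) {
  stopifnot(inherits(dff, "dff_movie"))
  if (n_trials(dff) < 2L)
    stop_vsdi("insufficient trials: residuals need >= 2 trials")
  g <- dff$geometry
  if (is.null(window_ms))
    window_ms <- if (identical(dff$condition, "evoked")) 150 else 2500
  dt <- frame_dt_ms(g)
  tt <- frame_times(g)
  frames <- which(tt >= 0 & tt < window_ms)
  if (length(frames) < 2L) stop_vsdi("window error: analysis window too short")
  dat <- dff$data[, frames, , , drop = FALSE]
  m <- trialwise_mean(dat)
  for (i in seq_len(dim(dat)[1])) {
    di <- dat[i, , , , drop = FALSE]
    dim(di) <- dim(dat)[2:4]
    dat[i, , , ] <- di - m
  }
  structure(list(data = dat, geometry = g, frames = frames,
                 time_ms = tt[frames], vessel_mask = dff$vessel_mask,
                 condition = dff$condition, window_ms = window_ms),
            class = "residual_movie")
}

#' @export
print.residual_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<residual_movie> %s: %d trials x %d frames (%g ms window) x %d x %d px\n",
              x$condition, d[1], d[2], x$window_ms, d[3], d[4]))
  invisible(x)
}

# ---- sliding-window Pearson core -------------------------------------------
# m: frames x pixels matrix for one trial; returns centers x length(cols)
# matrix of windowed r against the seed column. Zero-variance windows are NA.
window_corr_matrix <- function(m, seed_col, hw, cols = seq_len(ncol(m))) {
  n_f <- nrow(m)
  if (n_f < 2L * hw + 1L) stop_vsdi("window error: fewer frames than one window")
  L <- 2L * hw + 1L
  centers <- (hw + 1L):(n_f - hw)
  x <- m[, cols, drop = FALSE]
  y <- m[, seed_col]
  csx  <- rbind(0, apply(x, 2L, cumsum))
  csx2 <- rbind(0, apply(x * x, 2L, cumsum))
  csxy <- rbind(0, apply(x * y, 2L, cumsum))
  csy  <- c(0, cumsum(y))
  csy2 <- c(0, cumsum(y * y))
  hi <- centers + hw + 1L; lo <- centers - hw
  Sx  <- csx[hi, , drop = FALSE]  - csx[lo, , drop = FALSE]
  Sx2 <- csx2[hi, , drop = FALSE] - csx2[lo, , drop = FALSE]
  Sxy <- csxy[hi, , drop = FALSE] - csxy[lo, , drop = FALSE]
  Sy  <- csy[hi] - csy[lo]
  Sy2 <- csy2[hi] - csy2[lo]
  varx <- L * Sx2 - Sx^2
  vary <- L * Sy2 - Sy^2          # recycles down columns (length = n centers)
  num <- L * Sxy - Sy * Sx
  # relative tolerance guards windows that are constant up to rounding
  badx <- is.na(varx) | !(varx > 1e-12 * L * Sx2)
  bady <- is.na(vary) | !(vary > 1e-12 * L * Sy2)
  r <- num / sqrt(varx * vary)
  r[badx | bady] <- NA_real_
  pmin(pmax(r, -1), 1)
}

trial_matrix <- function(res, i) {
  d <- dim(res$data)
  m <- res$data[i, , , ]
  dim(m) <- c(d[2], d[3] * d[4])
  m
}

check_seed <- function(res, seed) {
  if (seed[1] < 1 || seed[1] > res$geometry$n_rows ||
      seed[2] < 1 || seed[2] > res$geometry$n_cols)
    stop_vsdi("seed out of bounds")
  if (res$vessel_mask[seed[1], seed[2]])
    stop_vsdi("vessel seed: seed pixel is vessel-masked")
}

#' Sliding-window correlation between two pixels
#'
#' Pearson r between the seed and target residual traces in a window of
#' `2 * window_halfwidth_frames + 1` frames around each valid center frame
#' (default +/- 4 frames = an 80 ms window at 100 Hz), averaged across trials.
#' Zero-variance windows are missing, never zero.
#'
#' @param res A `residual_movie`.
#' @param seed,target `c(row, col)` pixel coordinates (non-vessel).
#' @param window_halfwidth_frames Half-width of the window in frames (>= 1).
#' @return List: `r` (per center frame), `time_ms`, `n` (trials contributing
#'   per center), `n_undefined` (zero-variance trial-windows encountered).
#' @export
sliding_window_correlation <- function(res, seed, target,
                                       window_halfwidth_frames = 4L) {
  stopifnot(inherits(res, "residual_movie"), window_halfwidth_frames >= 1L)
  check_seed(res, seed); check_seed(res, target)
  nr <- res$geometry$n_rows
  scol <- pixel_index(seed[1], seed[2], nr)
  tcol <- pixel_index(target[1], target[2], nr)
  nt <- dim(res$data)[1]
  acc <- n <- NULL
  n_undef <- 0L
  for (i in seq_len(nt)) {
    m <- trial_matrix(res, i)
    r <- window_corr_matrix(m, scol, window_halfwidth_frames, cols = tcol)[, 1]
    n_undef <- n_undef + sum(is.na(r))
    if (is.null(acc)) { acc <- numeric(length(r)); n <- integer(length(r)) }
    ok <- !is.na(r)
    acc[ok] <- acc[ok] + r[ok]
    n <- n + ok
  }
  hw <- window_halfwidth_frames
  centers <- (hw + 1L):(dim(res$data)[2] - hw)
  out <- acc / n
  out[n == 0L] <- NA_real_
  list(r = out, time_ms = res$time_ms[centers], n = n, n_undefined = n_undef)
}

# full-field mean windowed correlation against one seed (mean over trials and
# window centers); cols may restrict the target pixels
seed_field_stats <- function(res, seed, hw, cols = NULL) {
  nr <- res$geometry$n_rows; nc <- res$geometry$n_cols
  scol <- pixel_index(seed[1], seed[2], nr)
  if (is.null(cols)) cols <- seq_len(nr * nc)
  nt <- dim(res$data)[1]
  rsum <- numeric(length(cols)); rn <- integer(length(cols))
  for (i in seq_len(nt)) {
    m <- trial_matrix(res, i)
    r <- window_corr_matrix(m, scol, hw, cols = cols)
    rsum <- rsum + colSums(r, na.rm = TRUE)
    rn <- rn + colSums(!is.na(r))
  }
  mean_r <- rsum / rn
  mean_r[rn == 0L] <- NA_real_
  list(mean_r = mean_r, n = rn, cols = cols)
}

new_correlation_map <- function(r, n, type, seed, half_width, pixel_size) {
  structure(list(r = r, n = n, type = type, seed = seed,
                 half_width = half_width, pixel_size = pixel_size,
                 center_excluded = TRUE),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("<correlation_map> %s, %d x %d cells, mean r (defined) = %.4f\n",
              x$type, nrow(x$r), ncol(x$r), mean(x$r, na.rm = TRUE)))
  invisible(x)
}

#' Seed-centered spatial correlation map
#'
#' Computes the windowed Pearson correlation of one seed pixel with every
#' pixel in a square matrix of half-width `half_width_px` centered on the
#' seed (default 25, i.e. a 51 x 51 px window, +/- 1.25 mm at 50 um/px),
#' averaged over trials and all valid window positions in the analysis
#' interval. Cells outside the imaged frame or on vessels are missing; the
#' central cell (the seed with itself, r = 1 by definition) is excluded.
#'
#' @param res A `residual_movie`.
#' @param seed `c(row, col)` non-vessel seed pixel.
#' @param half_width_px Half-width of the square map in pixels.
#' @param window_halfwidth_frames Sliding-window half-width in frames.
#' @return A `correlation_map` (type `"aligned"`).
#' @export
seed_correlation_map <- function(res, seed, half_width_px = 25L,
                                 window_halfwidth_frames = 4L) {
  stopifnot(inherits(res, "residual_movie"))
  check_seed(res, seed)
  nr <- res$geometry$n_rows; nc <- res$geometry$n_cols
  hwp <- as.integer(half_width_px)
  offs <- expand.grid(dr = -hwp:hwp, dc = -hwp:hwp)
  rr <- seed[1] + offs$dr; cc <- seed[2] + offs$dc
  inside <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  cols <- pixel_index(rr[inside], cc[inside], nr)
  st <- seed_field_stats(res, seed, window_halfwidth_frames, cols = cols)
  side <- 2L * hwp + 1L
  rmat <- matrix(NA_real_, side, side)
  nmat <- matrix(0L, side, side)
  rmat[inside] <- st$mean_r
  nmat[inside] <- st$n
  ctr <- hwp + 1L
  rmat[ctr, ctr] <- NA_real_
  new_correlation_map(rmat, nmat, "aligned", as.integer(seed), hwp,
                      res$geometry$pixel_size)
}

#' Average seed-aligned correlation maps
#'
#' Cell-wise missing-aware mean of maps that share their seed-centered
#' alignment; the result represents the mean cross-correlation of all ROI
#' pixels with their surroundings.
#'
#' @param maps List of aligned `correlation_map`s of equal size.
#' @return A `correlation_map` (type `"aligned"`, seed `NULL`).
#' @export
average_aligned_maps <- function(maps) {
  stopifnot(length(maps) >= 1L)
  for (m in maps) stopifnot(inherits(m, "correlation_map"),
                            identical(dim(m$r), dim(maps[[1]]$r)))
  rs <- vapply(maps, function(m) m$r, maps[[1]]$r)
  dim(rs) <- c(dim(maps[[1]]$r), length(maps))
  n_def <- apply(!is.na(rs), c(1, 2), sum)
  rmean <- apply(rs, c(1, 2), function(v) mean(v, na.rm = TRUE))
  rmean[n_def == 0] <- NA_real_
  new_correlation_map(rmean, n_def, "aligned", NULL, maps[[1]]$half_width,
                      maps[[1]]$pixel_size)
}

#' Mean seed-aligned correlation map of an ROI
#'
#' Runs [seed_correlation_map()] for every ROI pixel and averages the aligned
#' maps.
#'
#' @param res A `residual_movie`.
#' @param roi A `barrel_roi` or m x 2 pixel matrix of seed pixels.
#' @param half_width_px,window_halfwidth_frames As in
#'   [seed_correlation_map()].
#' @return A `correlation_map`.
#' @export
aligned_synchrony_map <- function(res, roi, half_width_px = 25L,
                                  window_halfwidth_frames = 4L) {
  seeds <- if (inherits(roi, "barrel_roi")) roi$pixels else as_pixel_matrix(roi)
  if (nrow(seeds) == 0L) stop_vsdi("empty ROI")
  maps <- lapply(seq_len(nrow(seeds)), function(i)
    seed_correlation_map(res, seeds[i, ], half_width_px,
                         window_halfwidth_frames))
  average_aligned_maps(maps)
}

#' Unaligned whole-field correlation map
#'
#' The full-field variant: each ROI seed is correlated with every pixel of
#' the imaged area and the seed maps are averaged in image coordinates,
#' without aligning on the seed (each seed's own cell is excluded from its
#' map before averaging).
#'
#' @param res A `residual_movie`.
#' @param roi Seed ROI (`barrel_roi` or pixel matrix).
#' @param window_halfwidth_frames Sliding-window half-width in frames.
#' @return A `correlation_map` of type `"unaligned"` covering the full grid.
#' @export
unaligned_field_map <- function(res, roi, window_halfwidth_frames = 4L) {
  seeds <- if (inherits(roi, "barrel_roi")) roi$pixels else as_pixel_matrix(roi)
  if (nrow(seeds) == 0L) stop_vsdi("empty ROI")
  nr <- res$geometry$n_rows; nc <- res$geometry$n_cols
  rsum <- matrix(0, nr, nc); rn <- matrix(0L, nr, nc)
  for (i in seq_len(nrow(seeds))) {
    st <- seed_field_stats(res, seeds[i, ], window_halfwidth_frames)
    r <- matrix(st$mean_r, nr, nc)
    r[seeds[i, 1], seeds[i, 2]] <- NA_real_ # self-correlation excluded
    ok <- !is.na(r)
    rsum[ok] <- rsum[ok] + r[ok]
    rn <- rn + ok
  }
  rmean <- rsum / rn
  rmean[rn == 0L] <- NA_real_
  new_correlation_map(rmean, rn, "unaligned", NULL, NA_integer_,
                      res$geometry$pixel_size)
}

#' Neighborhood synchrony of an aligned correlation map
#'
#' Mean correlation over all defined cells within `radius_um` of the map
#' center (default 200 um = 4 px at 50 um/px; 48 lattice cells), excluding
#' the center cell itself.
#'
#' @param map An aligned `correlation_map`.
#' @param radius_um Neighborhood radius in micrometers.
#' @return Scalar mean r.
#' @export
neighborhood_synchrony <- function(map, radius_um = 200) {
  stopifnot(inherits(map, "correlation_map"))
  if (!identical(map$type, "aligned"))
    stop_vsdi("neighborhood synchrony requires a seed-aligned map")
  radius_px <- floor(radius_um / map$pixel_size)
  hwp <- map$half_width
  offs <- expand.grid(dr = -hwp:hwp, dc = -hwp:hwp)
  d <- sqrt(offs$dr^2 + offs$dc^2)
  sel <- d > 0 & d <= radius_px
  vals <- map$r[as.matrix(offs[sel, ] + hwp + 1L)]
  if (all(is.na(vals)))
    stop_vsdi("empty neighborhood: no defined cells within the radius")
  mean(vals, na.rm = TRUE)
}

#' Observed neighborhood synchrony of an ROI
#'
#' The scalar synchrony statistic computed directly: for every ROI seed, the
#' mean windowed correlation with its neighbors within `radius_um` (averaged
#' over trials and window positions), then averaged across seeds. Identical
#' in definition to running [aligned_synchrony_map()] and
#' [neighborhood_synchrony()], but avoids building full-size maps, which is
#' what makes the 100-iteration shuffle null affordable; [shuffle_null()]
#' uses the same route so observed and null values are exactly comparable.
#'
#' @param res A `residual_movie`.
#' @param roi Seed ROI (`barrel_roi` or m x 2 pixel matrix).
#' @param window_halfwidth_frames Sliding-window half-width in frames.
#' @param radius_um Neighborhood radius in micrometers.
#' @return Scalar mean r.
#' @export
roi_neighborhood_synchrony <- function(res, roi, window_halfwidth_frames = 4L,
                                       radius_um = 200) {
  seeds <- if (inherits(roi, "barrel_roi")) roi$pixels else as_pixel_matrix(roi)
  if (nrow(seeds) == 0L) stop_vsdi("empty ROI")
  nr <- res$geometry$n_rows; nc <- res$geometry$n_cols
  radius_px <- floor(radius_um / res$geometry$pixel_size)
  offs <- expand.grid(dr = -radius_px:radius_px, dc = -radius_px:radius_px)
  d <- sqrt(offs$dr^2 + offs$dc^2)
  offs <- offs[d > 0 & d <= radius_px, ]
  per_seed <- rep(NA_real_, nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    rr <- seeds[i, 1] + offs$dr; cc <- seeds[i, 2] + offs$dc
    inside <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    if (!any(inside)) next
    cols <- pixel_index(rr[inside], cc[inside], nr)
    st <- seed_field_stats(res, seeds[i, ], window_halfwidth_frames, cols = cols)
    per_seed[i] <- mean(st$mean_r, na.rm = TRUE)
  }
  if (all(is.na(per_seed)))
    stop_vsdi("empty neighborhood: no defined cells within the radius")
  mean(per_seed, na.rm = TRUE)
}

#' Spatial-shuffle null distribution of neighborhood synchrony
#'
#' For each iteration the residual values are randomly permuted across
#' non-vessel pixel positions, independently in every frame of every trial
#' (a fresh permutation per frame), destroying spatial structure while
#' preserving each frame's value distribution; the seed-aligned pipeline and
#' its neighborhood-synchrony scalar are then recomputed in full.
#'
#' @param res A `residual_movie`.
#' @param roi Seed ROI.
#' @param n_shuffles Number of iterations (default 100).
#' @param rng_seed Integer seed for the permutations.
#' @param window_halfwidth_frames,radius_um As in the observed pipeline.
#' @return Numeric vector of `n_shuffles` null synchrony values.
#' @export
shuffle_null <- function(res, roi, n_shuffles = 100L, rng_seed = 1L,
                         window_halfwidth_frames = 4L, radius_um = 200) {
  stopifnot(inherits(res, "residual_movie"), n_shuffles >= 1L)
  d <- dim(res$data)
  nv <- which(!as.vector(res$vessel_mask))
  with_seed(rng_seed, {
    vapply(seq_len(n_shuffles), function(s) {
      shuf <- res
      for (i in seq_len(d[1])) {
        m <- trial_matrix(res, i)
        for (f in seq_len(d[2]))
          m[f, nv] <- m[f, nv[sample.int(length(nv))]]
        shuf$data[i, , , ] <- array(m, c(d[2], d[3], d[4]))
      }
      roi_neighborhood_synchrony(shuf, roi, window_halfwidth_frames, radius_um)
    }, 0)
  })
}

#' Time course of neighborhood synchrony
#'
#' For every valid window center frame: the mean windowed correlation between
#' each ROI seed and its neighbors within `radius_um`, averaged over trials
#' and seeds. The first valid center is frame `window_halfwidth_frames + 1`
#' of the analysis window.
#'
#' @param res A `residual_movie`.
#' @param roi Seed ROI.
#' @param window_halfwidth_frames Sliding-window half-width in frames.
#' @param radius_um Neighborhood radius in micrometers.
#' @return List: `r` (per center frame), `time_ms`.
#' @export
synchrony_timecourse <- function(res, roi, window_halfwidth_frames = 4L,
                                 radius_um = 200) {
  seeds <- if (inherits(roi, "barrel_roi")) roi$pixels else as_pixel_matrix(roi)
  if (nrow(seeds) == 0L) stop_vsdi("empty ROI")
  nr <- res$geometry$n_rows; nc <- res$geometry$n_cols
  radius_px <- floor(radius_um / res$geometry$pixel_size)
  offs <- expand.grid(dr = -radius_px:radius_px, dc = -radius_px:radius_px)
  dd <- sqrt(offs$dr^2 + offs$dc^2)
  offs <- offs[dd > 0 & dd <= radius_px, ]
  hw <- window_halfwidth_frames
  n_f <- dim(res$data)[2]
  centers <- (hw + 1L):(n_f - hw)
  acc <- numeric(length(centers)); cnt <- integer(length(centers))
  nt <- dim(res$data)[1]
  for (i in seq_len(nrow(seeds))) {
    rr <- seeds[i, 1] + offs$dr; cc <- seeds[i, 2] + offs$dc
    inside <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    if (!any(inside)) next
    cols <- pixel_index(rr[inside], cc[inside], nr)
    scol <- pixel_index(seeds[i, 1], seeds[i, 2], nr)
    for (tr in seq_len(nt)) {
      m <- trial_matrix(res, tr)
      r <- window_corr_matrix(m, scol, hw, cols = cols)
      acc <- acc + rowSums(r, na.rm = TRUE)
      cnt <- cnt + rowSums(!is.na(r))
    }
  }
  out <- acc / cnt
  out[cnt == 0L] <- NA_real_
  list(r = out, time_ms = res$time_ms[centers])
}
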