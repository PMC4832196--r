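# Preprocessing: raw fluorescence -> artifact-corrected delta-F/F.
# Fixed pipeline order: compute_dff -> subtract_blank -> vessel exclusion ->
# analysis. smooth_for_display is terminal-only and must never feed a
# quantitative step.

#' Gaussian blur of a 2-D map
#'
#' Separable Gaussian smoothing with the kernel truncated at 3 sd. At the
#' image border the kernel is renormalized over its in-grid support, so a
#' constant map is preserved exactly. With `na_aware = TRUE` missing (vessel)
#' pixels are excluded from the kernel sum (normalized convolution) and stay
#' missing in the output.
#'
#' @param x Numeric matrix.
#' @param sigma Kernel sd in pixels; 0 returns `x` unchanged.
#' @param na_aware Exclude NA pixels from the kernel sum.
#' @return Smoothed matrix of the same shape.
#' @export
gaussian_blur <- function(x, sigma, na_aware = FALSE) {
  stopifnot(is.matrix(x), sigma >= 0)
  if (sigma == 0) return(x)
  k <- gaussian_kernel(sigma)
  Kr <- band_matrix(nrow(x), k, renormalize = TRUE)
  Kc <- band_matrix(ncol(x), k, renormalize = TRUE)
  if (!na_aware) return(Kr %*% x %*% t(Kc))
  miss <- is.na(x)
  x0 <- x; x0[miss] <- 0
  num <- Kr %*% x0 %*% t(Kc)
  den <- Kr %*% (!miss) %*% t(Kc)
  out <- num / den
  out[den == 0] <- NA_real_
  out[miss] <- NA_real_
  out
}

#' Normalize a raw movie to delta-F/F
#'
#' Divides each pixel's trace by its own pre-stimulus baseline: for evoked
#' trials the baseline is the mean over the `baseline_n_frames` frames
#' immediately before stimulus onset (30 ms at 100 Hz with the default 3);
#' unstimulated trials use the first `baseline_n_frames` frames. The result is
#' `dff = F / baseline - 1`. Vessel pixels are set missing in every frame and
#' stay missing through the rest of the pipeline.
#'
#' @param movie A `vsd_movie`.
#' @param baseline_n_frames Frames in the baseline window (>= 1; >= 3
#'   available pre-stimulus frames are guaranteed by the geometry).
#' @param vessel_mask Optional logical matrix or [detect_vessels()] result.
#' @return A `dff_movie`.
#' @export
compute_dff <- function(movie, baseline_n_frames = 3L, vessel_mask = NULL) {
  stopifnot(inherits(movie, "vsd_movie"))
  g <- movie$geometry
  mask <- as_mask(vessel_mask, g)
  onset <- g$stim_onset_frame
  base_frames <- if (!is.null(onset)) {
    if (baseline_n_frames > onset - 1L)
      stop_vsdi("baseline window extends before the trial start")
    (onset - baseline_n_frames):(onset - 1L)
  } else seq_len(min(baseline_n_frames, g$n_frames))
  nt <- n_trials(movie)
  out <- array(NA_real_, dim(movie$data))
  for (i in seq_len(nt)) {
    trial <- movie$data[i, , , , drop = TRUE]
    dim(trial) <- c(g$n_frames, g$n_rows * g$n_cols)
    f0 <- colMeans(trial[base_frames, , drop = FALSE])
    bad <- f0 <= 0 & !as.vector(mask)
    if (any(bad)) {
      px <- which(bad)[1]
      stop_vsdi(sprintf(
        "degenerate baseline: non-positive baseline mean at pixel (row %d, col %d), trial %d",
        ((px - 1L) %% g$n_rows) + 1L, ((px - 1L) %/% g$n_rows) + 1L, i))
    }
    dff <- sweep(trial, 2L, f0, `/`) - 1
    dff[, as.vector(mask)] <- NA_real_
    out[i, , , ] <- array(dff, c(g$n_frames, g$n_rows, g$n_cols))
  }
  new_dff_movie(out, g, movie$condition, mask,
                provenance = list(baseline_frames = base_frames,
                                  blank_subtracted = FALSE),
                group = movie$group, animal_id = movie$animal_id)
}

#' Subtract the average blank signal
#'
#' Removes the heart-beat oscillation and photobleaching trend by subtracting
#' the trial-averaged blank (no-stimulation) delta-F/F from every evoked
#' trial, frame by frame and pixel by pixel.
#'
#' @param evoked A `dff_movie` of evoked trials.
#' @param blanks A `dff_movie` of blank trials (or a list of them), sharing
#'   geometry, frame count and vessel mask with `evoked`.
#' @return A `dff_movie` with `provenance$blank_subtracted = TRUE`.
#' @export
subtract_blank <- function(evoked, blanks) {
  stopifnot(inherits(evoked, "dff_movie"))
  if (inherits(blanks, "dff_movie")) blanks <- list(blanks)
  if (length(blanks) == 0L)
    stop_vsdi("missing blank: at least one blank trial set is required")
  for (b in blanks) {
    stopifnot(inherits(b, "dff_movie"))
    if (!same_geometry(b$geometry, evoked$geometry) ||
        b$geometry$n_frames != evoked$geometry$n_frames)
      stop_vsdi("shape error: blank and evoked geometries differ")
    if (!identical(b$vessel_mask, evoked$vessel_mask))
      stop_vsdi("blank and evoked movies carry different vessel masks")
  }
  bdat <- do.call(abind_trials, lapply(blanks, `[[`, "data"))
  blank_mean <- trialwise_mean(bdat)
  out <- evoked$data
  for (i in seq_len(n_trials(evoked))) {
    ei <- evoked$data[i, , , , drop = FALSE]
    dim(ei) <- dim(out)[2:4]
    out[i, , , ] <- ei - blank_mean
  }
  prov <- evoked$provenance
  prov$blank_subtracted <- TRUE
  prov$n_blank_trials <- dim(bdat)[1]
  new_dff_movie(out, evoked$geometry, evoked$condition, evoked$vessel_mask,
                prov, evoked$group, evoked$animal_id)
}

#' Detect blood-vessel pixels in a blank-condition frame average
#'
#' Vessels appear as dark curvilinear structures in the resting fluorescence.
#' They are isolated with a spatial high-pass (the frame minus its Gaussian
#' blur, sigma 2 px) and thresholded at `threshold_k` robust standard
#' deviations of the residual (median absolute deviation x 1.4826). The
#' threshold rule is this package's choice; only the high-pass filter width is
#' prescribed by the imaging literature.
#'
#' @param blank_frame_average 2-D matrix: raw fluorescence averaged over blank
#'   trials and frames.
#' @param highpass_sigma High-pass Gaussian sd in pixels (default 2).
#' @param threshold_k Robust-z threshold (default 3).
#' @return An object of class `vessel_mask`: `mask` (logical matrix) plus the
#'   detection parameters.
#' @export
detect_vessels <- function(blank_frame_average, highpass_sigma = 2,
                           threshold_k = 3) {
  stopifnot(is.matrix(blank_frame_average))
  if (!all(is.finite(blank_frame_average)))
    stop_vsdi("input error: non-finite values in blank frame average")
  if (!(highpass_sigma > 0)) stop_vsdi("highpass_sigma must be > 0")
  residual <- blank_frame_average -
    gaussian_blur(blank_frame_average, highpass_sigma)
  scale <- stats::mad(residual) # includes the 1.4826 consistency factor
  mask <- abs(residual) > threshold_k * scale
  structure(list(mask = mask, highpass_sigma = highpass_sigma,
                 threshold_k = threshold_k),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> %d/%d px masked (high-pass sigma %g px, k = %g)\n",
              sum(x$mask), length(x$mask), x$highpass_sigma, x$threshold_k))
  invisible(x)
}

#' Average a delta-F/F movie across trials
#'
#' Per-pixel, per-frame mean over trials; missing (vessel) entries are
#' excluded and remain missing if no trial contributes.
#'
#' @param dff A `dff_movie` with at least one trial.
#' @return A `mean_movie` (3-D `[frame, row, col]` plus metadata).
#' @export
average_trials <- function(dff) {
  stopifnot(inherits(dff, "dff_movie"))
  nt <- n_trials(dff)
  if (nt < 1L) stop_vsdi("empty input: no trials to average")
  m <- if (nt == 1L) array(dff$data[1, , , ], dim(dff$data)[2:4])
       else trialwise_mean(dff$data, na_rm = TRUE)
  m[is.nan(m)] <- NA_real_
  new_mean_movie(m, dff$geometry, dff$condition, dff$vessel_mask, nt)
}

#' Smooth a map for display
#'
#' Missing-aware Gaussian low-pass (default sigma 1.5 px) for figures only.
#' Quantitative analyses must run on the unsmoothed data; nothing in this
#' package feeds the result of this function into a downstream computation.
#'
#' @param map 2-D numeric matrix (NA on vessels).
#' @param sigma Kernel sd in pixels; 0 is the identity.
#' @return Smoothed matrix with the original NA pattern.
#' @export
smooth_for_display <- function(map, sigma = 1.5) {
  gaussian_blur(map, sigma, na_aware = TRUE)
}
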