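# ROI time courses and the temporal response metrics: peak amplitude,
# time-to-peak, derivative extrema of the peak-normalized trace, and
# time-to-half-peak decay.

new_time_course <- function(values, time_ms, n_pixels, label = NULL) {
  structure(list(values = values, time_ms = time_ms, n_pixels = n_pixels,
                 label = label),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("<time_course> %d frames (%g..%g ms), pooled over %d px\n",
              length(x$values), min(x$time_ms), max(x$time_ms),
              max(x$n_pixels)))
  invisible(x)
}

#' Pool a delta-F/F movie over an ROI
#'
#' Per-frame mean over the ROI pixels, excluding missing (vessel) entries and
#' reporting the effective pixel count per frame.
#'
#' @param x A `mean_movie` (or a `dff_movie`, which is trial-averaged first).
#' @param roi A `barrel_roi`, or an m x 2 matrix of `(row, col)` pixels (as in
#'   the rings of [define_rings()]).
#' @return A `time_course`.
#' @export
roi_timecourse <- function(x, roi) {
  if (inherits(x, "dff_movie")) x <- average_trials(x)
  stopifnot(inherits(x, "mean_movie"))
  pixels <- if (inherits(roi, "barrel_roi")) roi$pixels else as_pixel_matrix(roi)
  if (nrow(pixels) == 0L) stop_vsdi("empty ROI")
  g <- x$geometry
  dat <- x$data
  dim(dat) <- c(g$n_frames, g$n_rows * g$n_cols)
  cols <- pixel_index(pixels[, 1], pixels[, 2], g$n_rows)
  sub <- dat[, cols, drop = FALSE]
  n_eff <- rowSums(!is.na(sub))
  if (all(n_eff == 0)) stop_vsdi("empty ROI: all pixels are vessel-masked")
  vals <- rowMeans(sub, na.rm = TRUE)
  vals[n_eff == 0] <- NA_real_
  new_time_course(vals, frame_times(g), n_eff)
}

#' Peak amplitude and time-to-peak of a time course
#'
#' Maximum of the trace inside the search window (default: all post-stimulus
#' frames, t >= 0) and the time at which it occurs; exact ties resolve to the
#' earliest frame.
#'
#' @param tc A `time_course`.
#' @param search_window Optional `c(lo, hi)` in ms.
#' @return List with `peak_amplitude` and `time_to_peak` (ms).
#' @export
peak_response <- function(tc, search_window = NULL) {
  stopifnot(inherits(tc, "time_course"))
  keep <- if (is.null(search_window)) tc$time_ms >= 0 else
    tc$time_ms >= search_window[1] & tc$time_ms <= search_window[2]
  if (!any(keep) || all(is.na(tc$values[keep])))
    stop_vsdi("window error: empty or all-missing search window")
  v <- tc$values[keep]; t <- tc$time_ms[keep]
  i <- which(v == max(v, na.rm = TRUE))[1] # earliest tie
  list(peak_amplitude = v[i], time_to_peak = t[i])
}

#' Normalize a time course to its peak
#'
#' @param tc A `time_course` with a positive post-stimulus peak.
#' @return A `time_course` whose maximum is exactly 1.
#' @export
normalize_timecourse <- function(tc) {
  pk <- peak_response(tc)$peak_amplitude
  if (!(pk > 0)) stop_vsdi("degenerate trace: peak amplitude must be > 0")
  out <- tc
  out$values <- tc$values / pk
  out
}

#' Derivative extrema of a peak-normalized time course
#'
#' First differences `v[k+1] - v[k]` of the normalized trace on the raw frame
#' grid (no smoothing): the maximum over the rising extent (frames up to the
#' peak) and the minimum over the descending extent (frames after the peak).
#' Units are normalized amplitude per frame (divide by the frame duration in
#' ms for a per-ms rate).
#'
#' @param norm_tc A normalized `time_course` (max = 1, see
#'   [normalize_timecourse()]).
#' @return List with `max_derivative` and `min_derivative` (NA when the
#'   corresponding extent is empty).
#' @export
derivative_extrema <- function(norm_tc) {
  stopifnot(inherits(norm_tc, "time_course"))
  v <- norm_tc$values
  if (length(v) < 2L) stop_vsdi("length error: trace shorter than 2 frames")
  d <- diff(v)
  p <- which(v == max(v, na.rm = TRUE))[1]
  rising <- d[seq_len(p - 1L)]
  falling <- if (p <= length(d)) d[p:length(d)] else numeric(0)
  list(max_derivative = if (length(rising)) max(rising, na.rm = TRUE) else NA_real_,
       min_derivative = if (length(falling)) min(falling, na.rm = TRUE) else NA_real_)
}

#' Time to half-peak decay
#'
#' Time of the first post-peak crossing of half the peak amplitude, linearly
#' interpolated between the bracketing frames.
#'
#' @param tc A `time_course`.
#' @return Time in ms.
#' @export
time_to_half_peak <- function(tc) {
  stopifnot(inherits(tc, "time_course"))
  v <- tc$values; t <- tc$time_ms
  keep <- t >= 0
  v <- v[keep]; t <- t[keep]
  p <- which(v == max(v, na.rm = TRUE))[1]
  half <- v[p] / 2
  for (k in seq(p + 1L, length.out = max(0L, length(v) - p))) {
    if (!is.na(v[k]) && v[k] <= half) {
      if (v[k] == half || is.na(v[k - 1L])) return(t[k])
      return(t[k - 1L] + (t[k] - t[k - 1L]) * (v[k - 1L] - half) / (v[k - 1L] - v[k]))
    }
  }
  stop_vsdi("no crossing: trace never falls below half-peak in the trial")
}

#' All response metrics of an ROI time course
#'
#' Convenience wrapper returning the temporal metrics used in group
#' comparisons.
#'
#' @param tc A `time_course`.
#' @return List: `peak_amplitude`, `time_to_peak`, `max_derivative`,
#'   `min_derivative` (of the peak-normalized trace, per frame),
#'   `time_to_half_peak` (NA when the trace never decays to half within the
#'   trial).
#' @export
response_metrics <- function(tc) {
  pk <- peak_response(tc)
  dv <- derivative_extrema(normalize_timecourse(tc))
  th <- tryCatch(time_to_half_peak(tc), error = function(e) NA_real_)
  list(peak_amplitude = pk$peak_amplitude, time_to_peak = pk$time_to_peak,
       max_derivative = dv$max_derivative, min_derivative = dv$min_derivative,
       time_to_half_peak = th)
}
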