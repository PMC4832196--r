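#' Acquisition geometry of a VSDI recording
#'
#' Describes the camera grid and timing of a trial-based voltage-sensitive dye
#' imaging acquisition. The defaults mirror a MiCam-type recording of mouse
#' barrel cortex: a 100 x 100 pixel sensor at 50 um per pixel, sampled at
#' 100 Hz.
#'
#' Time is carried in milliseconds. For evoked trials the stimulus defines
#' t = 0: frame `k` occurs at `(k - stim_onset_frame) * 1000 / frame_rate` ms.
#' Trials without a stimulus (spontaneous, blank) start at t = 0 on their
#' first frame.
#'
#' @param n_rows,n_cols Grid size in pixels.
#' @param pixel_size Pixel pitch in micrometers.
#' @param frame_rate Acquisition rate in Hz.
#' @param n_frames Number of frames per trial.
#' @param stim_onset_frame 1-based index of the frame at which the stimulus is
#'   delivered, or `NULL` for unstimulated trials. At least 3 pre-stimulus
#'   frames are required (the 30 ms baseline window at 100 Hz).
#' @return An object of class `vsd_geometry`.
#' @examples
#' geom <- vsd_geometry(n_frames = 41, stim_onset_frame = 11)
#' frame_times(geom)[11] # 0 ms at stimulus onset
#' @export
vsd_geometry <- function(n_rows = 100L, n_cols = 100L, pixel_size = 50,
                         frame_rate = 100, n_frames,
                         stim_onset_frame = NULL) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  n_frames <- as.integer(n_frames)
  if (n_rows < 1L || n_cols < 1L)
    stop_vsdi("invalid geometry: grid must have at least one row and column")
  if (n_frames < 1L) stop_vsdi("invalid geometry: n_frames must be >= 1")
  if (!(pixel_size > 0)) stop_vsdi("invalid geometry: pixel_size must be > 0")
  if (!(frame_rate > 0)) stop_vsdi("invalid geometry: frame_rate must be > 0")
  if (!is.null(stim_onset_frame)) {
    stim_onset_frame <- as.integer(stim_onset_frame)
    if (stim_onset_frame < 4L || stim_onset_frame > n_frames - 1L)
      stop_vsdi("invalid geometry: stim_onset_frame must leave >= 3 ",
                "pre-stimulus frames and >= 1 post-stimulus frame")
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, pixel_size = pixel_size,
         frame_rate = frame_rate, n_frames = n_frames,
         stim_onset_frame = stim_onset_frame),
    class = "vsd_geometry")
}

#' @export
print.vsd_geometry <- function(x, ...) {
  cat(sprintf("<vsd_geometry> %d x %d px (%g um/px), %d frames @ %g Hz",
              x$n_rows, x$n_cols, x$pixel_size, x$n_frames, x$frame_rate))
  if (!is.null(x$stim_onset_frame))
    cat(sprintf(", stimulus at frame %d", x$stim_onset_frame))
  cat("\n")
  invisible(x)
}

# frame duration in ms
frame_dt_ms <- function(geometry) 1000 / geometry$frame_rate

#' Frame times in milliseconds
#'
#' @param geometry A [vsd_geometry()].
#' @return Numeric vector of frame times in ms; t = 0 at the stimulus-onset
#'   frame for evoked geometries, at the first frame otherwise.
#' @export
frame_times <- function(geometry) {
  dt <- frame_dt_ms(geometry)
  origin <- geometry$stim_onset_frame %||% 1L
  (seq_len(geometry$n_frames) - origin) * dt
}

#' Map a time in ms to the nearest frame index
#'
#' @param geometry A [vsd_geometry()].
#' @param t_ms Time in ms on the geometry's time axis (see [frame_times()]).
#' @return Integer frame index.
#' @export
frame_at_ms <- function(geometry, t_ms) {
  dt <- frame_dt_ms(geometry)
  origin <- geometry$stim_onset_frame %||% 1L
  k <- origin + as.integer(round(t_ms / dt))
  if (k < 1L || k > geometry$n_frames)
    stop_vsdi(sprintf("time %g ms falls outside the trial (frame %d of %d)",
                      t_ms, k, geometry$n_frames))
  k
}

same_geometry <- function(a, b) {
  identical(a$n_rows, b$n_rows) && identical(a$n_cols, b$n_cols) &&
    isTRUE(all.equal(a$pixel_size, b$pixel_size)) &&
    isTRUE(all.equal(a$frame_rate, b$frame_rate))
}
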