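# Movie containers. Data are kept as dense 4-D arrays [trial, frame, row, col]
# in raw camera counts (vsd_movie) or dimensionless delta-F/F (dff_movie,
# vessel pixels NA). Trial-averaged movies are 3-D [frame, row, col].

#' Construct a raw fluorescence movie
#'
#' Wraps a 4-D array of raw camera counts `[trial, frame, row, col]` together
#' with its acquisition geometry and condition label. This is the entry point
#' for data that did not come from the built-in simulator.
#'
#' @param data Numeric 4-D array `[trial, frame, row, col]`, finite and
#'   non-negative, with dimensions matching `geometry`.
#' @param geometry A [vsd_geometry()]; evoked movies need a
#'   `stim_onset_frame`.
#' @param condition `"evoked"`, `"blank"` or `"spontaneous"`.
#' @param group,animal_id Optional labels carried through the pipeline.
#' @return A `vsd_movie`.
#' @export
vsd_movie <- function(data, geometry,
                      condition = c("evoked", "blank", "spontaneous"),
                      group = NA_character_, animal_id = NA_character_) {
  condition <- match.arg(condition)
  stopifnot(inherits(geometry, "vsd_geometry"))
  d <- dim(data)
  if (length(d) != 4L || !identical(as.integer(d[2:4]),
                                    c(geometry$n_frames, geometry$n_rows,
                                      geometry$n_cols)))
    stop_vsdi("data dimensions [trial, frame, row, col] do not match geometry")
  if (!all(is.finite(data)) || any(data < 0))
    stop_vsdi("raw fluorescence must be finite and non-negative")
  if (condition == "evoked" && is.null(geometry$stim_onset_frame))
    stop_vsdi("condition mismatch: evoked movies need a stim_onset_frame")
  new_vsd_movie(data, geometry, condition, group, animal_id)
}

new_vsd_movie <- function(data, geometry, condition, group = NA_character_,
                          animal_id = NA_character_, ground_truth = NULL) {
  stopifnot(length(dim(data)) == 4L)
  structure(
    list(data = data, geometry = geometry, condition = condition,
         group = group, animal_id = animal_id, ground_truth = ground_truth),
    class = "vsd_movie")
}

#' @export
print.vsd_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vsd_movie> %s: %d trial(s) x %d frames x %d x %d px\n",
              x$condition, d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Number of trials in a movie
#' @param movie A `vsd_movie` or `dff_movie`.
#' @return Integer trial count.
#' @export
n_trials <- function(movie) dim(movie$data)[1]

#' Combine single-condition movies trial-wise
#'
#' @param movies List of `vsd_movie` objects sharing geometry and condition.
#' @return One `vsd_movie` with all trials stacked.
#' @export
bind_trials <- function(movies) {
  stopifnot(length(movies) >= 1L)
  g <- movies[[1]]$geometry
  for (m in movies) {
    if (!same_geometry(m$geometry, g) || m$geometry$n_frames != g$n_frames)
      stop_vsdi("bind_trials: geometry mismatch")
  }
  dat <- do.call(abind_trials, lapply(movies, `[[`, "data"))
  new_vsd_movie(dat, g, movies[[1]]$condition, movies[[1]]$group,
                movies[[1]]$animal_id,
                ground_truth = do.call(c, lapply(movies, `[[`, "ground_truth")))
}

# rbind along the trial axis of 4-D arrays
abind_trials <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[1], 0L))
  out <- array(NA_real_, c(n, d[2], d[3], d[4]))
  at <- 0L
  for (p in parts) {
    k <- dim(p)[1]
    out[at + seq_len(k), , , ] <- p
    at <- at + k
  }
  out
}

new_dff_movie <- function(data, geometry, condition, vessel_mask, provenance,
                          group = NA_character_, animal_id = NA_character_) {
  structure(
    list(data = data, geometry = geometry, condition = condition,
         vessel_mask = vessel_mask, provenance = provenance,
         group = group, animal_id = animal_id),
    class = "dff_movie")
}

#' @export
print.dff_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dff_movie> %s: %d trial(s) x %d frames x %d x %d px; %d vessel px; blank-subtracted: %s\n",
              x$condition, d[1], d[2], d[3], d[4], sum(x$vessel_mask),
              isTRUE(x$provenance$blank_subtracted)))
  invisible(x)
}

new_mean_movie <- function(data, geometry, condition, vessel_mask, n_trials) {
  structure(
    list(data = data, geometry = geometry, condition = condition,
         vessel_mask = vessel_mask, n_trials = n_trials),
    class = "mean_movie")
}

#' @export
print.mean_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mean_movie> %s: mean of %d trial(s), %d frames x %d x %d px\n",
              x$condition, x$n_trials, d[1], d[2], d[3]))
  invisible(x)
}

# accept a plain logical matrix or a vessel_mask object
as_mask <- function(mask, geometry = NULL) {
  if (is.null(mask)) {
    if (is.null(geometry)) stop_vsdi("mask or geometry required")
    return(matrix(FALSE, geometry$n_rows, geometry$n_cols))
  }
  if (inherits(mask, "vessel_mask")) mask <- mask$mask
  stopifnot(is.logical(mask), is.matrix(mask))
  mask
}
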