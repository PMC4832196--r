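# Concentric ring ROIs for spatial-spread profiling.

#' Define concentric ring ROIs around the barrel center
#'
#' Partitions the area outside the center pixel into `n_rings` non-overlapping
#' annuli of width `ring_width_um` (default 4 rings x 200 um = 4 px at
#' 50 um/px, reaching an 800 um radius). Ring `i` contains the non-vessel
#' pixels whose center-to-center Euclidean distance `d` from the center
#' satisfies `(i-1)*w < d <= i*w` (half-open annuli; the center pixel itself,
#' d = 0, belongs to no ring). Pixels falling outside the imaged grid are
#' dropped and counted as clipped; a warning is issued when more than 20% of a
#' ring is clipped or vessel-masked.
#'
#' @param center `c(row, col)` barrel center.
#' @param geometry A [vsd_geometry()].
#' @param vessel_mask Optional logical matrix or [detect_vessels()] result.
#' @param ring_width_um Ring width in micrometers.
#' @param n_rings Number of rings.
#' @return An object of class `ring_set`: `rings` (list of m x 2 pixel
#'   matrices), `n_pixels`, `n_clipped`, `n_masked` per ring, plus geometry
#'   bookkeeping.
#' @export
define_rings <- function(center, geometry, vessel_mask = NULL,
                         ring_width_um = 200, n_rings = 4L) {
  stopifnot(inherits(geometry, "vsd_geometry"), ring_width_um > 0, n_rings >= 1L)
  mask <- as_mask(vessel_mask, geometry)
  if (mask[center[1], center[2]])
    stop_vsdi("vessel center: ring center is a masked pixel")
  w_px <- ring_width_um / geometry$pixel_size
  rad <- ceiling(n_rings * w_px)
  offs <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  d <- sqrt(offs$dr^2 + offs$dc^2)
  rings <- vector("list", n_rings)
  n_clipped <- n_masked <- integer(n_rings)
  for (i in seq_len(n_rings)) {
    sel <- d > (i - 1) * w_px & d <= i * w_px
    rr <- center[1] + offs$dr[sel]; cc <- center[2] + offs$dc[sel]
    inside <- rr >= 1 & rr <= geometry$n_rows & cc >= 1 & cc <= geometry$n_cols
    n_clipped[i] <- sum(!inside)
    rr <- rr[inside]; cc <- cc[inside]
    on_vessel <- mask[cbind(rr, cc)]
    n_masked[i] <- sum(on_vessel)
    px <- cbind(rr[!on_vessel], cc[!on_vessel])
    rings[[i]] <- as_pixel_matrix(px[order(px[, 1], px[, 2]), , drop = FALSE])
    lost <- (n_clipped[i] + n_masked[i]) / sum(sel)
    if (lost > 0.2)
      warning(sprintf("ring %d: %.0f%% of its pixels are clipped or masked",
                      i, 100 * lost), call. = FALSE)
  }
  structure(list(rings = rings, center = as.integer(center),
                 ring_width_um = ring_width_um, ring_width_px = w_px,
                 n_rings = n_rings, pixel_size = geometry$pixel_size,
                 n_pixels = vapply(rings, nrow, 0L),
                 n_clipped = n_clipped, n_masked = n_masked),
            class = "ring_set")
}

#' @export
print.ring_set <- function(x, ...) {
  cat(sprintf("<ring_set> %d rings x %g um around (%d, %d); px per ring: %s\n",
              x$n_rings, x$ring_width_um, x$center[1], x$center[2],
              paste(x$n_pixels, collapse = ", ")))
  invisible(x)
}

#' Pooled time course of each ring
#'
#' Averages the trial-averaged delta-F/F over the pixels of each ring. With
#' `normalize = "inner"` (default) every ring trace is divided by the peak of
#' the innermost ring, preserving relative amplitudes across rings;
#' `"self"` divides each ring by its own peak, emphasizing latency
#' differences; `"none"` returns raw pooled traces. Empty rings are reported
#' with a warning and returned as all-NA traces.
#'
#' @param mean_movie A `mean_movie`.
#' @param rings A `ring_set`.
#' @param normalize `"inner"`, `"self"`, or `"none"`.
#' @return List of `time_course` objects, one per ring.
#' @export
ring_timecourses <- function(mean_movie, rings,
                             normalize = c("inner", "self", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(rings, "ring_set"))
  tcs <- lapply(seq_len(rings$n_rings), function(i) {
    if (nrow(rings$rings[[i]]) == 0L) {
      warning(sprintf("ring %d is empty; skipped", i), call. = FALSE)
      return(new_time_course(rep(NA_real_, mean_movie$geometry$n_frames),
                             frame_times(mean_movie$geometry), 0L,
                             label = sprintf("ring%d", i)))
    }
    tc <- roi_timecourse(mean_movie, rings$rings[[i]])
    tc$label <- sprintf("ring%d", i)
    tc
  })
  if (normalize == "inner") {
    ref <- peak_response(tcs[[1]])$peak_amplitude
    tcs <- lapply(tcs, function(tc) { tc$values <- tc$values / ref; tc })
  } else if (normalize == "self") {
    tcs <- lapply(tcs, function(tc) {
      if (all(is.na(tc$values))) return(tc)
      tc$values <- tc$values / peak_response(tc)$peak_amplitude
      tc
    })
  }
  tcs
}

#' Spatial spread profile across rings
#'
#' Mean delta-F/F of each ring at the requested times, normalized to the
#' inner-ring value at 20 ms after stimulus onset (the early-response
#' reference, which is 1 by construction).
#'
#' @param mean_movie A `mean_movie`.
#' @param rings A `ring_set`.
#' @param sample_times_ms Times (ms after onset) at which to sample; default
#'   20, 50 and 80 ms.
#' @param reference_time_ms Time of the inner-ring reference value.
#' @return A data.frame with columns `ring`, `time_ms`, `value`, `n_pixels`.
#' @export
spatial_profile <- function(mean_movie, rings, sample_times_ms = c(20, 50, 80),
                            reference_time_ms = 20) {
  stopifnot(inherits(mean_movie, "mean_movie"), inherits(rings, "ring_set"))
  tcs <- ring_timecourses(mean_movie, rings, normalize = "none")
  g <- mean_movie$geometry
  ref <- tcs[[1]]$values[frame_at_ms(g, reference_time_ms)]
  if (is.na(ref) || ref == 0)
    stop_vsdi("degenerate reference: inner-ring value at the reference time")
  out <- do.call(rbind, lapply(seq_along(tcs), function(i) {
    fr <- vapply(sample_times_ms, function(t) frame_at_ms(g, t), 0L)
    data.frame(ring = i, time_ms = sample_times_ms,
               value = tcs[[i]]$values[fr] / ref,
               n_pixels = tcs[[i]]$n_pixels[fr])
  }))
  rownames(out) <- NULL
  out
}
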