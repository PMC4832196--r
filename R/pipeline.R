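# End-to-end workflow: simulate a cohort, preprocess, extract per-animal
# metrics, and compare groups.

#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end analysis with defaults at the
#' conventional values for this preparation: 100 x 100 px at 50 um and
#' 100 Hz; 30 ms (3-frame) baseline; vessel detection with a 2 px high-pass
#' and robust-z threshold 3; barrel ROI from the 20 ms frame at 77.5% of
#' peak; 4 rings x 200 um; 80 ms (+/- 40 ms) correlation window; 200 um
#' synchrony radius; 100 spatial shuffles; 2500 ms spontaneous and 150 ms
#' evoked analysis windows; alpha 0.05; cohort of 8 control-like and 6
#' transgenic-like animals with 20 trials per stimulated condition.
#'
#' @param ... Overrides of any listed default.
#' @return A list of class `pipeline_config`.
#' @seealso [demo_config()] for a reduced-scale configuration.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    n_rows = 100L, n_cols = 100L, pixel_size = 50, frame_rate = 100,
    n_frames_evoked = 41L, stim_onset_frame = 11L, n_frames_spont = 250L,
    n_animals_per_group = c(8L, 6L), n_trials_per_condition = 20L,
    n_spont_trials = 10L, n_vessels = 3L, jitter_sd = 0.10, f0 = 1000,
    ctrl = ctrl_params(), tg = tg_params(),
    baseline_n_frames = 3L, vessel_sigma = 2, vessel_k = 3,
    early_time_ms = 20, threshold_fraction = 0.775,
    ring_width_um = 200, n_rings = 4L, profile_times_ms = c(20, 50, 80),
    window_halfwidth_frames = 4L, radius_um = 200, n_shuffles = 100L,
    spont_window_ms = 2500, evoked_window_ms = 150,
    max_seeds = Inf, alpha = 0.05, seed = 1L)
  cfg <- utils::modifyList(defaults, list(...))
  structure(cfg, class = "pipeline_config")
}

#' Reduced-scale demonstration configuration
#'
#' The same pipeline on a 40 x 40 px grid with 3 + 3 animals, 12 trials per
#' stimulated condition, 4 spontaneous trials of 1200 ms, at most 8
#' correlation seeds per ROI and 15 shuffles — small enough to run end to end
#' in about a minute on one CPU while exercising every stage. Per-animal
#' estimates are accordingly noisier than at the full scale of
#' [pipeline_config()].
#'
#' @param ... Further overrides passed to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
demo_config <- function(...) {
  pipeline_config(n_rows = 40L, n_cols = 40L, n_frames_spont = 120L,
                  n_animals_per_group = c(3L, 3L),
                  n_trials_per_condition = 12L, n_spont_trials = 4L,
                  n_shuffles = 15L, max_seeds = 8L,
                  spont_window_ms = 1200, ...)
}

config_geometries <- function(cfg) {
  list(evoked = vsd_geometry(cfg$n_rows, cfg$n_cols, cfg$pixel_size,
                             cfg$frame_rate, cfg$n_frames_evoked,
                             cfg$stim_onset_frame),
       spont = vsd_geometry(cfg$n_rows, cfg$n_cols, cfg$pixel_size,
                            cfg$frame_rate, cfg$n_frames_spont))
}

# deterministic subsample: at most k seeds, evenly spaced through the ROI
cap_seeds <- function(roi, k) {
  px <- roi$pixels
  if (!is.finite(k) || nrow(px) <= k) return(roi)
  idx <- unique(round(seq(1, nrow(px), length.out = k)))
  roi$pixels <- px[idx, , drop = FALSE]
  roi$n_pixels <- nrow(roi$pixels)
  roi
}

#' Analyze one animal's recordings
#'
#' The per-animal arm of the pipeline: delta-F/F conversion, blank
#' subtraction, vessel detection from the blank condition, trial averaging,
#' barrel-ROI definition, temporal response metrics, ring latencies and
#' spatial profile, and spontaneous/evoked neighborhood synchrony with a
#' spatial-shuffle null.
#'
#' @param evoked,blank,spont `vsd_movie`s for the three conditions.
#' @param cfg A [pipeline_config()].
#' @param shuffle_seed Seed for the shuffle null.
#' @return List with the per-animal `metrics` row (data.frame), the ROI, the
#'   ring latencies, the spatial profile and the synchrony results.
#' @export
analyze_animal <- function(evoked, blank, spont, cfg, shuffle_seed = 1L) {
  # vessel detection from the blank condition (raw fluorescence average)
  blank_avg <- apply(blank$data, c(3, 4), mean)
  vm <- detect_vessels(blank_avg, cfg$vessel_sigma, cfg$vessel_k)
  dff_ev <- compute_dff(evoked, cfg$baseline_n_frames, vm)
  dff_bl <- compute_dff(blank, cfg$baseline_n_frames, vm)
  dff_ev <- subtract_blank(dff_ev, dff_bl)
  mm <- average_trials(dff_ev)
  roi <- define_roi(mm, cfg$early_time_ms, cfg$threshold_fraction)
  tc <- roi_timecourse(mm, roi)
  met <- response_metrics(tc)
  rings <- suppressWarnings(
    define_rings(roi$center, mm$geometry, vm, cfg$ring_width_um, cfg$n_rings))
  ring_tcs <- suppressWarnings(
    ring_timecourses(mm, rings, normalize = "self"))
  ring_ttp <- vapply(ring_tcs, function(x) {
    tryCatch(peak_response(x)$time_to_peak, error = function(e) NA_real_)
  }, 0)
  ring_thalf <- vapply(ring_tcs, function(x) {
    tryCatch(time_to_half_peak(x), error = function(e) NA_real_)
  }, 0)
  profile <- spatial_profile(mm, rings, cfg$profile_times_ms)
  seeds <- cap_seeds(roi, cfg$max_seeds)
  # spontaneous synchrony + shuffle null
  dff_sp <- compute_dff(spont, cfg$baseline_n_frames, vm)
  res_sp <- make_residuals(dff_sp, cfg$spont_window_ms)
  sync_sp <- roi_neighborhood_synchrony(res_sp, seeds,
                                        cfg$window_halfwidth_frames,
                                        cfg$radius_um)
  null_sp <- shuffle_null(res_sp, seeds, cfg$n_shuffles, shuffle_seed,
                          cfg$window_halfwidth_frames, cfg$radius_um)
  # evoked-state synchrony (150 ms window), no shuffle
  res_ev <- make_residuals(dff_ev, cfg$evoked_window_ms)
  sync_ev <- roi_neighborhood_synchrony(res_ev, seeds,
                                        cfg$window_halfwidth_frames,
                                        cfg$radius_um)
  metrics <- data.frame(
    animal_id = evoked$animal_id, group = evoked$group,
    peak_amplitude = met$peak_amplitude, time_to_peak = met$time_to_peak,
    max_derivative = met$max_derivative, min_derivative = met$min_derivative,
    time_to_half_peak = met$time_to_half_peak,
    roi_n_pixels = roi$n_pixels,
    spont_synchrony = sync_sp, spont_null_mean = mean(null_sp),
    evoked_synchrony = sync_ev,
    stringsAsFactors = FALSE)
  for (i in seq_along(ring_ttp)) {
    metrics[[sprintf("ring%d_time_to_peak", i)]] <- ring_ttp[i]
    metrics[[sprintf("ring%d_time_to_half_peak", i)]] <- ring_thalf[i]
  }
  list(metrics = metrics, roi = roi, rings = rings, profile = profile,
       spont_null = null_sp, time_course = tc)
}

#' Run the full simulated-cohort pipeline
#'
#' Simulates a two-group cohort with [generate_cohort()]-style per-animal
#' streaming (one animal in memory at a time), runs [analyze_animal()] on
#' each, and compares the groups metric by metric with Wilcoxon rank-sum
#' tests plus a per-group signed-rank test of observed spontaneous synchrony
#' against its shuffle-null mean. Deterministic: the same configuration
#' (including `cfg$seed`) reproduces the result exactly.
#'
#' @param cfg A [pipeline_config()] or [demo_config()].
#' @return A list of class `vsd_results`: `per_animal` (data.frame),
#'   `comparisons` (named list of `group_comparison`), `shuffle_tests`
#'   (per-group signed-rank results), `profiles` (long data.frame), `config`.
#' @export
run_pipeline <- function(cfg = demo_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  geoms <- config_geometries(cfg)
  n_total <- sum(cfg$n_animals_per_group)
  groups <- rep(c(cfg$ctrl$label, cfg$tg$label), cfg$n_animals_per_group)
  base <- list(cfg$ctrl, cfg$tg)[rep(1:2, cfg$n_animals_per_group)]
  animal_seeds <- with_seed(cfg$seed, draw_seeds(n_total))
  rows <- list(); profiles <- list(); nulls <- list()
  rlo <- max(1L, floor(cfg$n_rows / 3)); rhi <- ceiling(2 * cfg$n_rows / 3)
  clo <- max(1L, floor(cfg$n_cols / 3)); chi <- ceiling(2 * cfg$n_cols / 3)
  for (a in seq_len(n_total)) {
    an <- with_seed(animal_seeds[a], {
      p <- jitter_params(base[[a]], cfg$jitter_sd)
      center <- c(sample(rlo:rhi, 1L), sample(clo:chi, 1L))
      seeds <- draw_seeds(5L)
      mask <- generate_vessel_mask(geoms$evoked, cfg$n_vessels, seeds[1])
      if (mask[center[1], center[2]]) {
        free <- which(!mask, arr.ind = TRUE)
        d <- (free[, 1] - center[1])^2 + (free[, 2] - center[2])^2
        center <- as.integer(free[which.min(d), ])
      }
      list(params = p, center = center, seeds = seeds, mask = mask)
    })
    id <- sprintf("%s_%02d", groups[a], a)
    ev <- generate_evoked_trial(geoms$evoked, an$params, an$center,
                                an$seeds[2], cfg$n_trials_per_condition,
                                an$mask, cfg$f0)
    bl <- generate_blank_trial(geoms$evoked, an$params, an$seeds[3],
                               cfg$n_trials_per_condition, an$mask, cfg$f0)
    sp <- generate_spontaneous_trial(geoms$spont, an$params, an$seeds[4],
                                     cfg$n_spont_trials, an$mask, cfg$f0)
    ev$animal_id <- bl$animal_id <- sp$animal_id <- id
    ev$group <- bl$group <- sp$group <- groups[a]
    res <- analyze_animal(ev, bl, sp, cfg, shuffle_seed = an$seeds[5])
    rows[[a]] <- res$metrics
    pr <- res$profile; pr$animal_id <- id; pr$group <- groups[a]
    profiles[[a]] <- pr
    nulls[[a]] <- res$spont_null
  }
  per_animal <- do.call(rbind, rows)
  ctrl_lab <- cfg$ctrl$label; tg_lab <- cfg$tg$label
  is_ctrl <- per_animal$group == ctrl_lab
  test_metrics <- c("peak_amplitude", "time_to_peak", "max_derivative",
                    "min_derivative", "time_to_half_peak", "roi_n_pixels",
                    "spont_synchrony", "evoked_synchrony")
  comparisons <- lapply(test_metrics, function(mname) {
    tryCatch(
      rank_sum_test(per_animal[[mname]][is_ctrl],
                    per_animal[[mname]][!is_ctrl],
                    metric = mname, labels = c(ctrl_lab, tg_lab),
                    alpha = cfg$alpha),
      error = function(e) NULL)
  })
  names(comparisons) <- test_metrics
  shuffle_tests <- lapply(c(ctrl_lab, tg_lab), function(gl) {
    sel <- per_animal$group == gl
    tryCatch(
      signed_rank_test(per_animal$spont_synchrony[sel],
                       per_animal$spont_null_mean[sel],
                       metric = "spont_synchrony vs shuffle null",
                       labels = c("observed", "shuffle null"),
                       alpha = cfg$alpha),
      error = function(e) NULL)
  })
  names(shuffle_tests) <- c(ctrl_lab, tg_lab)
  structure(list(per_animal = per_animal, comparisons = comparisons,
                 shuffle_tests = shuffle_tests,
                 profiles = do.call(rbind, profiles),
                 config = cfg),
            class = "vsd_results")
}

#' @export
print.vsd_results <- function(x, ...) {
  cat("<vsd_results>\n")
  cat(sprintf("  %d animals: %s\n", nrow(x$per_animal),
              paste(sprintf("%s n=%d", names(table(x$per_animal$group)),
                            table(x$per_animal$group)), collapse = ", ")))
  for (cmp in x$comparisons) {
    if (is.null(cmp)) next
    cat(sprintf("  %-18s %s %.4g +/- %.2g vs %s %.4g +/- %.2g, p = %.4g %s\n",
                cmp$metric, cmp$group_a$label, cmp$group_a$mean,
                cmp$group_a$sem, cmp$group_b$label, cmp$group_b$mean,
                cmp$group_b$sem, cmp$p_value, significance_stars(cmp$p_value)))
  }
  for (gl in names(x$shuffle_tests)) {
    st <- x$shuffle_tests[[gl]]
    if (is.null(st)) next
    cat(sprintf("  %s observed vs shuffle null: p = %.4g %s\n", gl,
                st$p_value, significance_stars(st$p_value)))
  }
  invisible(x)
}

#' Write a results bundle to disk
#'
#' Plain-text outputs: `per_animal.csv`, `comparisons.csv`, `profiles.csv`
#' and a `summary.json` carrying group means, test results and the full
#' configuration (including all seeds) for provenance.
#'
#' @param results A `vsd_results` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "vsd_results"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(per_animal = file.path(dir, "per_animal.csv"),
             comparisons = file.path(dir, "comparisons.csv"),
             profiles = file.path(dir, "profiles.csv"),
             summary = file.path(dir, "summary.json"))
  utils::write.csv(results$per_animal, paths["per_animal"], row.names = FALSE)
  comp_df <- do.call(rbind, lapply(results$comparisons, function(cmp) {
    if (is.null(cmp)) return(NULL)
    data.frame(metric = cmp$metric, test = cmp$test, method = cmp$method,
               statistic = cmp$statistic, p_value = cmp$p_value,
               mean_a = cmp$group_a$mean, sem_a = cmp$group_a$sem,
               n_a = cmp$group_a$n, mean_b = cmp$group_b$mean,
               sem_b = cmp$group_b$sem, n_b = cmp$group_b$n,
               significant = cmp$significant)
  }))
  utils::write.csv(comp_df, paths["comparisons"], row.names = FALSE)
  utils::write.csv(results$profiles, paths["profiles"], row.names = FALSE)
  summary <- list(
    comparisons = comp_df,
    shuffle_tests = lapply(results$shuffle_tests, function(st) {
      if (is.null(st)) return(NULL)
      list(p_value = st$p_value, method = st$method,
           observed_mean = st$group_a$mean, null_mean = st$group_b$mean)
    }),
    config = unclass(results$config))
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, force = TRUE, pretty = TRUE)
  invisible(paths)
}
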