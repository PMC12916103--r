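# ROI-fluorescence analysis: dF/F0 with a block-percentile interpolated
# baseline, field-of-view hypersynchronous-discharge detection, per-cell
# transient detection, locomotion-state epoching, per-cell activity
# metrics and threshold-robustness sweeps.

#' dF/F0 with block-percentile baseline
#'
#' For each cell, F0 is the 10th percentile of the fluorescence computed
#' per block of `block_frames` frames (a shorter tail block gets its own
#' percentile), linearly interpolated between block centres and held
#' constant beyond the first/last centre. dF/F0 = (F - F0) / F0. The
#' result is invariant to positive rescaling of F and identically zero on
#' constant traces.
#'
#' @param x A [roi_fluorescence()] or numeric cells x frames matrix.
#' @param frame_rate_hz Frame rate (used when `x` is a bare matrix).
#' @param block_frames Block length for the percentile baseline (1000).
#' @param percentile Baseline percentile in \[0, 1\] (0.1).
#' @param rolling An alternative reading of the baseline rule: block means
#'   of a rolling percentile instead of per-block percentiles. Default
#'   FALSE (per-block percentiles).
#' @return List of class `dff_matrix`: `dff` and `F0` matrices (cells x
#'   frames) and `frame_rate_hz`.
#' @export
compute_dff <- function(x, frame_rate_hz = NULL, block_frames = 1000,
                        percentile = 0.1, rolling = FALSE) {
  if (inherits(x, "roi_fluorescence")) {
    F <- x$F; frame_rate_hz <- x$frame_rate_hz
  } else {
    F <- as.matrix(x)
    if (is.null(frame_rate_hz)) stopf("frame_rate_hz required for bare matrices")
  }
  nf <- ncol(F)
  if (nf < 1L) stopf("empty fluorescence matrix")
  starts <- seq(1L, nf, by = block_frames)
  ends <- pmin(starts + block_frames - 1L, nf)
  centers <- (starts + ends) / 2
  F0 <- t(apply(F, 1L, function(f) {
    if (rolling) {
      w <- min(block_frames, nf)
      roll <- vapply(seq_len(nf), function(i) {
        lo <- max(1L, i - w %/% 2L); hi <- min(nf, i + w %/% 2L)
        stats::quantile(f[lo:hi], percentile, names = FALSE)
      }, numeric(1))
      vals <- vapply(seq_along(starts),
                     function(b) mean(roll[starts[b]:ends[b]]), numeric(1))
    } else {
      vals <- vapply(seq_along(starts),
                     function(b) stats::quantile(f[starts[b]:ends[b]],
                                                 percentile, names = FALSE),
                     numeric(1))
    }
    if (length(vals) == 1L) rep(vals, nf)
    else stats::approx(centers, vals, xout = seq_len(nf), rule = 2)$y
  }))
  if (any(F0 <= 0))
    stopf("baseline F0 <= 0; offset the raw fluorescence to positive values before dF/F0")
  structure(list(dff = (F - F0) / F0, F0 = F0, frame_rate_hz = frame_rate_hz),
            class = "dff_matrix")
}

#' Detect hypersynchronous discharges in the field-of-view mean
#'
#' High-pass filters the FOV-mean dF/F0 at 1 Hz (2nd-order Butterworth,
#' zero phase), z-scores the filtered trace, and reports peaks with
#' z > `min_z` (5) separated by at least `min_separation_s` (1 s).
#' Constant traces yield no events.
#'
#' @param fov_dff FOV-mean dF/F0 trace.
#' @param frame_rate_hz Frame rate (Hz).
#' @param min_z z-score threshold (events require z > 5).
#' @param highpass_hz High-pass corner frequency.
#' @param min_separation_s Minimum inter-event separation.
#' @param speed Optional locomotion speed trace (same frames) used to set
#'   the `coincident_locomotion` flag.
#' @param rest_threshold Speed below which the mouse counts as stationary.
#' @return Data.frame `time_s`, `frame`, `z_score`,
#'   `coincident_locomotion`.
#' @export
detect_discharges <- function(fov_dff, frame_rate_hz, min_z = 5,
                              highpass_hz = 1, min_separation_s = 1,
                              speed = NULL, rest_threshold = 0.5) {
  if (stats::sd(fov_dff) == 0)
    return(data.frame(time_s = numeric(0), frame = integer(0),
                      z_score = numeric(0), coincident_locomotion = logical(0)))
  bf <- signal::butter(2, highpass_hz / (frame_rate_hz / 2), type = "high")
  filt <- signal::filtfilt(bf, fov_dff)
  z <- zscore_trace(filt)
  peaks <- local_maxima(z)
  peaks <- peaks[z[peaks] > min_z]
  peaks <- thin_peaks(peaks, z[peaks],
                      max(1L, round(min_separation_s * frame_rate_hz)))
  loco <- if (!is.null(speed)) speed[peaks] >= rest_threshold
          else rep(NA, length(peaks))
  data.frame(time_s = (peaks - 1) / frame_rate_hz, frame = peaks,
             z_score = z[peaks], coincident_locomotion = loco)
}

#' Detect calcium transients in one dF/F0 trace
#'
#' Smooths with a moving mean (`smooth_frames`, default 5 frames ~167 ms
#' at 30 Hz), z-scores the smoothed trace (classical mean/SD or robust
#' median/MAD), and keeps peaks with z >= `min_z`, prominence >=
#' `min_prominence_z`, and at least `min_distance_ms` between kept peaks
#' (taller peaks win). Peak times are refined to the unsmoothed maximum
#' within half a smoothing window.
#'
#' @param dff One cell's dF/F0 trace.
#' @param frame_rate_hz Frame rate (Hz).
#' @param min_z Minimum peak z-score (1).
#' @param min_distance_ms Minimum inter-transient distance (200 ms).
#' @param min_prominence_z Minimum peak prominence in z units (0.5).
#' @param smooth_frames Moving-mean window in frames.
#' @param robust Use median/MAD z-scoring.
#' @return Data.frame `peak_time_s`, `frame`, `peak_z`, `peak_dff`,
#'   `prominence_z`.
#' @export
detect_transients <- function(dff, frame_rate_hz, min_z = 1,
                              min_distance_ms = 200, min_prominence_z = 0.5,
                              smooth_frames = 5, robust = FALSE) {
  empty <- data.frame(peak_time_s = numeric(0), frame = integer(0),
                      peak_z = numeric(0), peak_dff = numeric(0),
                      prominence_z = numeric(0))
  if (stats::sd(dff) == 0) return(empty)
  sm <- moving_mean(dff, smooth_frames)
  z <- zscore_trace(sm, robust = robust)
  peaks <- local_maxima(z)
  peaks <- peaks[z[peaks] >= min_z]
  if (!length(peaks)) return(empty)
  prom <- peak_prominence(z, peaks)
  keep <- prom >= min_prominence_z
  peaks <- peaks[keep]; prom <- prom[keep]
  if (!length(peaks)) return(empty)
  min_dist <- max(1L, round(min_distance_ms / 1000 * frame_rate_hz))
  kept <- thin_peaks(peaks, z[peaks], min_dist)
  prom <- prom[match(kept, peaks)]
  # report times at the unsmoothed peak near each smoothed peak
  half <- as.integer(max(1, smooth_frames %/% 2))
  refined <- vapply(kept, function(p) {
    lo <- max(1L, p - half); hi <- min(length(dff), p + half)
    as.integer(lo + which.max(dff[lo:hi]) - 1L)
  }, integer(1))
  data.frame(peak_time_s = (refined - 1) / frame_rate_hz, frame = refined,
             peak_z = z[kept], peak_dff = dff[refined], prominence_z = prom)
}

#' Segment a speed trace into quiet-rest and locomotion epochs
#'
#' Quiet rest = speed below `rest_threshold` sustained for at least
#' `min_duration_s`; locomotion is the complement. Gaps shorter than
#' `merge_gap_s` inside an epoch are absorbed.
#'
#' @param speed Locomotion speed (cm/s), one value per frame.
#' @param frame_rate_hz Frame rate (Hz).
#' @param rest_threshold Speed threshold (cm/s).
#' @param min_duration_s Minimum epoch duration.
#' @param merge_gap_s Maximum gap absorbed into a surrounding epoch.
#' @return Data.frame `onset_s`, `offset_s`, `label`
#'   (quiet_rest/locomotion); intervals are disjoint and cover the frames
#'   belonging to qualifying epochs.
#' @export
segment_epochs <- function(speed, frame_rate_hz, rest_threshold = 0.5,
                           min_duration_s = 1, merge_gap_s = 0.2) {
  n <- length(speed)
  rest <- speed < rest_threshold
  # absorb short gaps
  gap_max <- round(merge_gap_s * frame_rate_hz)
  fill_short_runs <- function(mask, max_len) {
    r <- rle(mask)
    short <- !r$values & r$lengths <= max_len
    # only interior gaps (surrounded by the epoch state)
    if (length(r$values) > 2L) {
      interior <- seq_along(r$values) > 1L & seq_along(r$values) < length(r$values)
      r$values[short & interior] <- TRUE
    }
    inverse.rle(r)
  }
  if (gap_max > 0) rest <- fill_short_runs(rest, gap_max)
  min_len <- round(min_duration_s * frame_rate_hz)
  r <- rle(rest)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- lapply(seq_along(r$values), function(i) {
    if (r$lengths[i] < min_len && r$values[i]) return(NULL)  # too-short rest
    label <- if (r$values[i]) "quiet_rest" else "locomotion"
    data.frame(onset_s = (starts[i] - 1) / frame_rate_hz,
               offset_s = ends[i] / frame_rate_hz, label = label)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      label = character(0))
  rownames(out) <- NULL
  out
}

#' Per-cell activity metrics
#'
#' Transient rate during quiet rest (transients whose peak falls inside a
#' rest epoch, per rest minute), mean peak height (in both z and dF/F0
#' units), and an activity flag (at least one transient anywhere in the
#' recording).
#'
#' @param transients Named list of [detect_transients()] tables, one per
#'   cell (names = cell ids), or a single table for one cell.
#' @param epochs An epoch table from [segment_epochs()].
#' @param cell_labels Optional labels copied into the output.
#' @return Data.frame, one row per cell: `cell`, `label`, `n_transients`,
#'   `transients_per_min_rest`, `mean_peak_z`, `mean_peak_dff`, `active`.
#'   The rest rate is `NA` (flagged) when total rest time is zero.
#' @export
per_cell_metrics <- function(transients, epochs, cell_labels = NULL) {
  if (is.data.frame(transients)) transients <- list(cell_1 = transients)
  rest <- epochs[epochs$label == "quiet_rest", , drop = FALSE]
  rest_min <- sum(rest$offset_s - rest$onset_s) / 60
  in_rest <- function(t) {
    if (!nrow(rest)) return(logical(length(t)))
    vapply(t, function(ti) any(ti >= rest$onset_s & ti < rest$offset_s),
           logical(1))
  }
  rows <- lapply(seq_along(transients), function(i) {
    tt <- transients[[i]]
    nr <- if (rest_min > 0) sum(in_rest(tt$peak_time_s)) / rest_min else NA_real_
    data.frame(cell = names(transients)[i] %||% as.character(i),
               label = if (is.null(cell_labels)) "unknown" else cell_labels[i],
               n_transients = nrow(tt),
               transients_per_min_rest = nr,
               mean_peak_z = if (nrow(tt)) mean(tt$peak_z) else NA_real_,
               mean_peak_dff = if (nrow(tt)) mean(tt$peak_dff) else NA_real_,
               active = nrow(tt) > 0)
  })
  out <- do.call(rbind, rows)
  if (is.na(rest_min) || rest_min == 0)
    attr(out, "rest_rate_undefined") <- TRUE
  out
}

#' Threshold-robustness sweep for transient detection
#'
#' Re-runs [detect_transients()] over a grid of `min_z` and
#' `min_prominence_z` values and tabulates event counts. Counts are
#' monotonically non-increasing in each threshold.
#'
#' @param dff One cell's dF/F0 trace.
#' @param frame_rate_hz Frame rate (Hz).
#' @param min_z_grid,min_prominence_grid Threshold grids.
#' @param ... Passed to [detect_transients()].
#' @return Data.frame `min_z`, `min_prominence_z`, `n_transients`.
#' @export
threshold_robustness_sweep <- function(dff, frame_rate_hz,
                                       min_z_grid = c(0.5, 1, 1.5, 2, 3),
                                       min_prominence_grid = c(0.25, 0.5, 1),
                                       ...) {
  grid <- expand.grid(min_z = min_z_grid,
                      min_prominence_z = min_prominence_grid)
  grid$n_transients <- vapply(seq_len(nrow(grid)), function(i) {
    nrow(detect_transients(dff, frame_rate_hz, min_z = grid$min_z[i],
                           min_prominence_z = grid$min_prominence_z[i], ...))
  }, numeric(1))
  grid
}
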