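# Cardiac quantification from the lumen-area trace: beat detection and the
# five standard dorsal-vessel read-outs (HR, EDA, ESA, FS, AI).

#' Smooth an area trace with a centered moving average
#'
#' @param trace an [area_trace()].
#' @param window_s averaging window in seconds; rounded to an odd number of
#'   frames (minimum 1). `0` is the identity. Windows shrink symmetrically
#'   at the trace ends.
#' @return A smoothed `area_trace` (validity flags preserved).
#' @export
smooth_trace <- function(trace, window_s = 0.04) {
  stopifnot(inherits(trace, "area_trace"), window_s >= 0)
  fps <- attr(trace, "fps")
  w <- max(1L, round(window_s * fps))
  if (w %% 2L == 0L) w <- w + 1L
  n <- nrow(trace)
  if (w > n) stopf("smoothing window (%d frames) longer than trace (%d)", w, n)
  if (w == 1L) return(trace)
  r <- (w - 1L) %/% 2L
  x <- trace$area_um2
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  k <- pmin(r, i - 1L, n - i)          # symmetric shrink at the edges
  sm <- (cs[i + k + 1L] - cs[i - k]) / (2L * k + 1L)
  out <- trace
  out$area_um2 <- sm
  out
}

#' Detect beats (diastolic peaks and systolic valleys)
#'
#' Finds local maxima and minima of the trace subject to: topographic
#' prominence at least `min_prominence_frac` of the trace's global range;
#' minimum separation `fps / hr_max_hz` frames between same-type extrema
#' (more extreme candidates win); plateau and tied candidates resolved to
#' the leftmost frame; extrema at the first/last sample discarded; strict
#' peak/valley alternation enforced by keeping the more extreme of adjacent
#' same-type extrema.
#'
#' @param trace an [area_trace()] (typically pre-smoothed, see
#'   [smooth_trace()]).
#' @param hr_min_hz,hr_max_hz plausible heart-rate band (Hz); `hr_max_hz`
#'   sets the separation constraint and `hr_min_hz` must be below it.
#' @param min_prominence_frac required prominence as a fraction of the
#'   global max-min range, in (0, 1).
#' @return An object of class `beat_markers`: integer `peaks` and
#'   `valleys` (1-based frame indices, strictly increasing, interleaved),
#'   per-beat `period_s` (inter-valley intervals), and `fps`.
#' @export
#' @examples
#' tr <- area_trace(c(2, 5, 2, 5, 2, 5, 2), fps = 5)
#' detect_beats(tr, hr_max_hz = 5, min_prominence_frac = 0.5)
detect_beats <- function(trace, hr_min_hz = 0.5, hr_max_hz = 8,
                         min_prominence_frac = 0.25) {
  stopifnot(inherits(trace, "area_trace"))
  if (!(hr_min_hz < hr_max_hz)) stopf("need hr_min_hz < hr_max_hz")
  if (min_prominence_frac <= 0 || min_prominence_frac >= 1)
    stopf("min_prominence_frac must lie in (0, 1)")
  x <- trace$area_um2
  fps <- attr(trace, "fps")
  rng <- max(x) - min(x)
  if (rng <= 0) stopf("constant trace: no extrema to detect")
  prom_min <- min_prominence_frac * rng
  min_sep <- fps / hr_max_hz
  peaks <- find_extrema(x, prom_min, min_sep)
  valleys <- find_extrema(-x, prom_min, min_sep)
  alt <- enforce_alternation(x, peaks, valleys)
  if (length(alt$valleys) < 2L)
    stopf("fewer than 2 valleys detected: no beat period measurable")
  beat_markers(alt$peaks, alt$valleys, fps)
}

#' @rdname detect_beats
#' @param peaks,valleys strictly increasing integer frame indices.
#' @param fps frame rate.
#' @export
beat_markers <- function(peaks, valleys, fps) {
  peaks <- as.integer(peaks); valleys <- as.integer(valleys)
  if (is.unsorted(peaks, strictly = TRUE) ||
      is.unsorted(valleys, strictly = TRUE))
    stopf("marker indices must be strictly increasing")
  period_s <- diff(valleys) / fps
  if (length(period_s) && any(period_s <= 0)) stopf("periods must be > 0")
  structure(list(peaks = peaks, valleys = valleys, period_s = period_s,
                 fps = fps),
            class = "beat_markers")
}

#' @export
print.beat_markers <- function(x, ...) {
  cat(sprintf("<beat_markers> %d peaks, %d valleys (%d periods) at %g fps\n",
              length(x$peaks), length(x$valleys), length(x$period_s), x$fps))
  invisible(x)
}

# local maxima of x with plateau collapse (leftmost frame), boundary
# discard, topographic prominence filter, and greedy separation filter
# (taller first, leftmost on ties)
find_extrema <- function(x, prom_min, min_sep) {
  n <- length(x)
  r <- rle(x)
  m <- length(r$values)
  if (m < 3L) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-m]))
  ends <- starts + r$lengths - 1L
  # interior runs higher than both neighbouring runs
  cand_run <- which(r$values[-c(1L, m)] > r$values[-c(m - 1L, m)] &
                    r$values[-c(1L, m)] > r$values[-(1:2)]) + 1L
  cand <- starts[cand_run]                       # leftmost frame of plateau
  cand <- cand[starts[cand_run] > 1L & ends[cand_run] < n]
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) prominence_at(x, i), numeric(1))
  cand <- cand[prom >= prom_min]
  if (!length(cand)) return(integer(0))
  # greedy separation: taller candidates claim their neighbourhood first
  ord <- order(-x[cand], cand)
  keep <- integer(0)
  for (i in cand[ord]) {
    if (!length(keep) || all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
  }
  sort(keep)
}

# topographic prominence of a local maximum at index i: height above the
# higher of the two lowest saddles toward the nearest strictly higher
# ground (or the series edge)
prominence_at <- function(x, i) {
  n <- length(x)
  left_higher <- which(x[seq_len(i - 1L)] > x[i])
  lo_l <- if (length(left_higher)) max(left_higher) + 1L else 1L
  right_higher <- which(x[seq.int(i + 1L, n)] > x[i])
  hi_r <- if (length(right_higher)) i + min(right_higher) - 1L else n
  x[i] - max(min(x[lo_l:i]), min(x[i:hi_r]))
}

# keep the more extreme of adjacent same-type extrema (leftmost on ties)
enforce_alternation <- function(x, peaks, valleys) {
  idx <- c(peaks, valleys)
  typ <- rep(c(1L, -1L), c(length(peaks), length(valleys)))
  o <- order(idx)
  idx <- idx[o]; typ <- typ[o]
  repeat {
    same <- which(diff(typ) == 0L)
    if (!length(same)) break
    j <- same[1L]
    a <- idx[j]; b <- idx[j + 1L]
    # for peaks keep the higher, for valleys the lower; ties -> leftmost
    drop <- if (typ[j] == 1L) {
      if (x[b] > x[a]) j else j + 1L
    } else {
      if (x[b] < x[a]) j else j + 1L
    }
    idx <- idx[-drop]; typ <- typ[-drop]
  }
  list(peaks = idx[typ == 1L], valleys = idx[typ == -1L])
}

#' Heart rate from beat markers
#'
#' Per-beat rate is the inverse of the inter-valley interval,
#' `fps / (valley[i+1] - valley[i])` in Hz; the recording-level heart rate
#' is the mean of per-beat rates.
#'
#' @param markers a [beat_markers()] object with >= 2 valleys.
#' @param fps frame rate; defaults to the markers' own.
#' @return A list: `per_beat_hz`, `mean_hz`, `sd_hz`, `mean_bpm`, `n_beats`.
#' @export
#' @examples
#' heart_rate(beat_markers(integer(0), c(1, 126, 251), fps = 125))
heart_rate <- function(markers, fps = markers$fps) {
  stopifnot(inherits(markers, "beat_markers"))
  if (length(markers$valleys) < 2L) stopf("need >= 2 valleys for a rate")
  per_beat <- fps / diff(markers$valleys)
  list(per_beat_hz = per_beat, mean_hz = mean(per_beat),
       sd_hz = if (length(per_beat) > 1L) sd(per_beat) else NA_real_,
       mean_bpm = 60 * mean(per_beat), n_beats = length(per_beat))
}

#' End-diastolic and end-systolic area
#'
#' Mean trace value at the detected diastolic peaks (`eda`) or systolic
#' valleys (`esa`), in um^2.
#'
#' @param trace an [area_trace()].
#' @param markers a [beat_markers()] object.
#' @return Mean area in um^2.
#' @export
eda <- function(trace, markers) {
  stopifnot(inherits(trace, "area_trace"), inherits(markers, "beat_markers"))
  if (!length(markers$peaks)) stopf("no peaks: EDA undefined")
  mean(trace$area_um2[markers$peaks])
}

#' @rdname eda
#' @export
esa <- function(trace, markers) {
  stopifnot(inherits(trace, "area_trace"), inherits(markers, "beat_markers"))
  if (!length(markers$valleys)) stopf("no valleys: ESA undefined")
  mean(trace$area_um2[markers$valleys])
}

#' Fractional shortening
#'
#' `FS(%) = 100 * (EDA - ESA) / EDA`, the percent contractility of the
#' vessel.
#'
#' @param eda_um2 end-diastolic area (> 0).
#' @param esa_um2 end-systolic area (<= `eda_um2`).
#' @return FS in percent, in `[0, 100)`.
#' @export
#' @examples
#' fractional_shortening(8000, 4000)  # 50
fractional_shortening <- function(eda_um2, esa_um2) {
  if (!is_num1(eda_um2) || eda_um2 <= 0) stopf("eda_um2 must be > 0")
  if (!is_num1(esa_um2) || esa_um2 > eda_um2)
    stopf("esa_um2 must not exceed eda_um2")
  100 * (eda_um2 - esa_um2) / eda_um2
}

#' Arrhythmicity index
#'
#' Dispersion of the beat rhythm: the standard deviation of per-beat
#' (inter-valley) periods divided by their median. 0 for a perfectly
#' regular rhythm.
#'
#' @param markers a [beat_markers()] object with >= 3 valleys (>= 2
#'   periods).
#' @param fps frame rate; defaults to the markers' own.
#' @return Dimensionless AI >= 0.
#' @export
#' @examples
#' arrhythmicity_index(beat_markers(integer(0), c(1, 63, 125, 187), 125))
arrhythmicity_index <- function(markers, fps = markers$fps) {
  stopifnot(inherits(markers, "beat_markers"))
  if (length(markers$valleys) < 3L)
    stopf("need >= 2 beat periods (3 valleys) for AI")
  periods <- diff(markers$valleys) / fps
  sd(periods) / median(periods)
}

#' Full cardiac report for one recording
#'
#' Runs the quantification chain: smoothing, beat detection on the smoothed
#' trace, then HR, EDA, ESA, FS and AI. EDA/ESA are measured on the
#' *unsmoothed* trace at the detected marker frames, so the moving average
#' cannot bias the systolic minimum upward.
#'
#' @param trace an [area_trace()].
#' @param smooth_window_s detection smoothing window (s).
#' @param hr_min_hz,hr_max_hz,min_prominence_frac passed to
#'   [detect_beats()].
#' @return An object of class `cardiac_report`: `hr_hz`, `hr_bpm`,
#'   `eda_um2`, `esa_um2`, `fs_percent`, `ai`, `n_beats`, `duration_s`,
#'   `markers`, and a `per_beat` data.frame (valley frame, period, rate).
#' @export
cardiac_report <- function(trace, smooth_window_s = 0.04,
                           hr_min_hz = 0.5, hr_max_hz = 8,
                           min_prominence_frac = 0.25) {
  stopifnot(inherits(trace, "area_trace"))
  sm <- smooth_trace(trace, smooth_window_s)
  markers <- detect_beats(sm, hr_min_hz, hr_max_hz, min_prominence_frac)
  hr <- heart_rate(markers)
  eda_v <- eda(trace, markers)
  esa_v <- esa(trace, markers)
  fps <- attr(trace, "fps")
  per_beat <- data.frame(
    valley_frame = head(markers$valleys, -1L),
    next_valley_frame = tail(markers$valleys, -1L),
    period_s = markers$period_s,
    rate_hz = hr$per_beat_hz)
  structure(list(hr_hz = hr$mean_hz, hr_bpm = hr$mean_bpm,
                 hr_sd_hz = hr$sd_hz,
                 eda_um2 = eda_v, esa_um2 = esa_v,
                 fs_percent = fractional_shortening(eda_v, esa_v),
                 ai = if (length(markers$valleys) >= 3L)
                   arrhythmicity_index(markers) else NA_real_,
                 n_beats = hr$n_beats,
                 duration_s = nrow(trace) / fps,
                 markers = markers, per_beat = per_beat),
            class = "cardiac_report")
}

#' @export
print.cardiac_report <- function(x, ...) {
  cat("<cardiac_report>\n")
  cat(sprintf("  HR  %.3f Hz (%.1f bpm) over %d beats in %.3g s\n",
              x$hr_hz, x$hr_bpm, x$n_beats, x$duration_s))
  cat(sprintf("  EDA %.0f um2, ESA %.0f um2, FS %.1f%%, AI %.3f\n",
              x$eda_um2, x$esa_um2, x$fs_percent, x$ai))
  invisible(x)
}

#' Write a cardiac report to JSON (and per-beat CSV)
#'
#' @param report a `cardiac_report`.
#' @param path_json JSON output path.
#' @param path_csv optional per-beat CSV path.
#' @export
write_cardiac_report <- function(report, path_json, path_csv = NULL) {
  stopifnot(inherits(report, "cardiac_report"))
  out <- report[c("hr_hz", "hr_bpm", "hr_sd_hz", "eda_um2", "esa_um2",
                  "fs_percent", "ai", "n_beats", "duration_s")]
  out$peak_frames <- report$markers$peaks
  out$valley_frames <- report$markers$valleys
  jsonlite::write_json(out, path_json, auto_unbox = TRUE, digits = NA)
  if (!is.null(path_csv))
    write.csv(report$per_beat, path_csv, row.names = FALSE)
  invisible(path_json)
}
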