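#' Ground-truth lumen-area waveform
#'
#' Generates the per-frame true lumen area of a beating vessel. Each beat is
#' a raised-cosine contraction pulse dipping from `eda_um2` down to `esa_um2`
#' and back over `systole_fraction` of the beat period, followed by a
#' diastolic plateau at `eda_um2`. Per-beat periods are
#' `rate_hz^-1 * (1 + jitter_cv * Z)` with `Z` standard normal truncated at
#' plus/minus 2 SD, drawn from the stream seeded by `kin$seed`. Contraction
#' pulses are centered on integer frames, so the trace equals `esa_um2`
#' exactly at every recorded valley frame and `eda_um2` exactly at every
#' recorded peak frame.
#'
#' @param kin a [vessel_kinematics()] object.
#' @param reset_seed if `TRUE` (default) the RNG is seeded from `kin$seed`
#'   before drawing beat periods; [render_mmode()] passes `FALSE` because it
#'   manages the recording-level stream itself.
#' @return An object of class `ground_truth`: a list with `area_um2`
#'   (length `round(duration_s * fps)`), integer `peak_frames` and
#'   `valley_frames` (1-based, strictly increasing), per-beat `period_s`
#'   (intervals between consecutive recorded valleys), `fps`, `n_frames`,
#'   and the `kinematics` used.
#' @export
#' @examples
#' gt <- area_waveform(vessel_kinematics(jitter_cv = 0, seed = 1))
#' range(gt$area_um2)              # exactly c(esa, eda)
#' length(gt$valley_frames)        # ~ duration_s * rate_hz beats
area_waveform <- function(kin, reset_seed = TRUE) {
  stopifnot(inherits(kin, "vessel_kinematics"))
  n <- round(kin$duration_s * kin$fps)
  p0 <- kin$fps / kin$rate_hz                     # nominal period, frames
  sf <- kin$systole_fraction
  if (reset_seed) set.seed(kin$seed)

  # draw enough beats to overfill the recording
  n_beats <- ceiling(n / (p0 * (1 - 2 * kin$jitter_cv))) + 2L
  z <- if (kin$jitter_cv > 0) rnorm_trunc2(n_beats) else numeric(n_beats)
  periods <- p0 * (1 + kin$jitter_cv * z)         # frames

  # valley centers: first beat led in by half a diastolic plateau, so the
  # recording opens near end-diastole
  centers <- (1 - sf) * periods[1] / 2 + sf * periods[1] / 2 +
    c(0, cumsum(periods[-n_beats]))
  half_w <- sf * periods / 2                      # contraction half-width
  if (n < centers[1] + half_w[1])
    stopf("recording too short for one full beat (%d frames, need >= %.0f)",
          n, ceiling(centers[1] + half_w[1]))

  keep <- which(round(centers) >= 1 & round(centers) <= n)
  valleys <- round(centers[keep])
  half_w <- half_w[keep]

  amp <- kin$eda_um2 - kin$esa_um2
  area <- rep(kin$eda_um2, n)
  for (i in seq_along(valleys)) {
    w <- half_w[i]
    f <- max(1L, valleys[i] - floor(w)):min(n, valleys[i] + floor(w))
    area[f] <- kin$eda_um2 - amp * 0.5 * (1 + cos(pi * (f - valleys[i]) / w))
  }

  # diastolic peaks: plateau midpoints between consecutive valleys
  peaks <- integer(0)
  if (length(valleys) >= 2L) {
    lo <- head(valleys, -1) + ceiling(head(half_w, -1))
    hi <- tail(valleys, -1) - ceiling(tail(half_w, -1))
    peaks <- as.integer(round((lo + hi) / 2))
    peaks <- peaks[peaks >= 1 & peaks <= n]
  }

  structure(list(area_um2 = area,
                 peak_frames = peaks,
                 valley_frames = as.integer(valleys),
                 period_s = diff(valleys) / kin$fps,
                 fps = kin$fps, n_frames = n, kinematics = kin),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  cat(sprintf("  %d frames at %g fps; %d valleys, %d peaks\n",
              x$n_frames, x$fps, length(x$valley_frames),
              length(x$peak_frames)))
  cat(sprintf("  area range [%.3g, %.3g] um2\n",
              min(x$area_um2), max(x$area_um2)))
  invisible(x)
}

#' Write / read a ground-truth JSON sidecar
#'
#' @param truth a `ground_truth` object.
#' @param path JSON file path.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` returns a `ground_truth` object.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  out <- truth
  out$kinematics <- unclass(out$kinematics)
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$kinematics <- do.call(vessel_kinematics, x$kinematics)
  x$peak_frames <- as.integer(x$peak_frames)
  x$valley_frames <- as.integer(x$valley_frames)
  structure(x, class = "ground_truth")
}
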