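#' Ground-truth vessel kinematics
#'
#' Describes the beating state of the dorsal vessel used to drive the
#' simulator: the end-diastolic and end-systolic lumen cross-sectional
#' areas between which each beat contracts, the mean beat rate, the
#' beat-period jitter (an arrhythmia surrogate), and the recording geometry
#' (duration and frame rate).
#'
#' @param eda_um2 end-diastolic (maximum) lumen area, in square microns.
#' @param esa_um2 end-systolic (minimum) lumen area, in square microns; must
#'   be strictly smaller than `eda_um2`.
#' @param rate_hz mean beat rate in beats per second.
#' @param jitter_cv coefficient of variation of the per-beat period
#'   (dimensionless, in `[0, 0.5)`); each beat period is drawn as
#'   `rate_hz^-1 * (1 + jitter_cv * Z)` with `Z` standard normal truncated
#'   to plus/minus 2 SD.
#' @param systole_fraction fraction of each beat period spent in the
#'   contraction-relaxation pulse (strictly between 0 and 1).
#' @param duration_s recording duration in seconds.
#' @param fps frame rate in frames per second; must exceed `2 * rate_hz`
#'   so beats are countable (Nyquist).
#' @param seed integer seed; all randomness of a simulated recording
#'   (beat-period jitter first, then per-frame speckle in frame order) is
#'   consumed from the stream this seed initializes.
#'
#' @return An object of class `vessel_kinematics`.
#' @seealso [kinematics_preset()] for named presets, [area_waveform()] for
#'   the ground-truth trace the kinematics generate.
#' @export
#' @examples
#' vessel_kinematics(eda_um2 = 7700, esa_um2 = 2900, rate_hz = 2)
vessel_kinematics <- function(eda_um2 = 7.7e3, esa_um2 = 2.9e3,
                              rate_hz = 2, jitter_cv = 0.05,
                              systole_fraction = 0.4,
                              duration_s = 16, fps = 125, seed = 1L) {
  if (!is_num1(eda_um2) || !is_num1(esa_um2) || !(eda_um2 > esa_um2) ||
      esa_um2 <= 0)
    stopf("need eda_um2 > esa_um2 > 0 (got %s, %s)", eda_um2, esa_um2)
  if (!is_num1(rate_hz) || rate_hz <= 0) stopf("rate_hz must be > 0")
  if (!is_num1(jitter_cv) || jitter_cv < 0 || jitter_cv >= 0.5)
    stopf("jitter_cv must lie in [0, 0.5)")
  if (!is_num1(systole_fraction) || systole_fraction <= 0 ||
      systole_fraction >= 1)
    stopf("systole_fraction must lie in (0, 1)")
  if (!is_num1(duration_s) || duration_s <= 0) stopf("duration_s must be > 0")
  if (!is_num1(fps) || fps <= 2 * rate_hz)
    stopf("fps must exceed 2 * rate_hz (Nyquist for beat counting)")
  structure(list(eda_um2 = eda_um2, esa_um2 = esa_um2, rate_hz = rate_hz,
                 jitter_cv = jitter_cv, systole_fraction = systole_fraction,
                 duration_s = duration_s, fps = fps,
                 seed = as.integer(seed)),
            class = "vessel_kinematics")
}

#' @export
print.vessel_kinematics <- function(x, ...) {
  cat("<vessel_kinematics>\n")
  cat(sprintf("  EDA %.3g um2, ESA %.3g um2, rate %.3g Hz, jitter CV %.3g\n",
              x$eda_um2, x$esa_um2, x$rate_hz, x$jitter_cv))
  cat(sprintf("  %.3g s at %g fps (%d frames), systole fraction %.2f, seed %d\n",
              x$duration_s, x$fps, round(x$duration_s * x$fps),
              x$systole_fraction, x$seed))
  invisible(x)
}

.kinematics_presets <- list(
  # EDA/ESA are the 1-week-old group means reported for this model system;
  # rate and jitter are simulator defaults (no printed heart-rate values)
  "WT-1wk-male"    = list(eda_um2 = 7.7e3, esa_um2 = 2.9e3),
  "WT-1wk-female"  = list(eda_um2 = 8.8e3, esa_um2 = 4.0e3),
  "KO-1wk-male"    = list(eda_um2 = 5.5e3, esa_um2 = 2.8e3),
  "KO-1wk-female"  = list(eda_um2 = 6.3e3, esa_um2 = 2.7e3)
)

#' Named kinematics presets
#'
#' Presets anchored to the reported group-mean end-diastolic and
#' end-systolic areas of 1-week-old flies (`WT`/`KO`, male/female); beat
#' rate 2 Hz and period jitter CV 0.05 are simulator defaults shared by all
#' presets.
#'
#' @param name preset name; one of `"WT-1wk-male"`, `"WT-1wk-female"`,
#'   `"KO-1wk-male"`, `"KO-1wk-female"`.
#' @param ... overrides passed to [vessel_kinematics()] (e.g. `seed`,
#'   `duration_s`, `jitter_cv`).
#' @return A `vessel_kinematics` object.
#' @export
#' @examples
#' kinematics_preset("WT-1wk-male", seed = 7)
kinematics_preset <- function(name = "WT-1wk-male", ...) {
  if (!name %in% names(.kinematics_presets))
    stopf("unknown preset '%s' (available: %s)", name,
          paste(names(.kinematics_presets), collapse = ", "))
  args <- utils::modifyList(.kinematics_presets[[name]], list(...))
  do.call(vessel_kinematics, args)
}

#' SD-OCM system description
#'
#' Optical and sampling parameters of the simulated spectral-domain optical
#' coherence microscope. Defaults follow the imaging system used for fly
#' dorsal-vessel recordings: an 850 nm center wavelength, 165 nm bandwidth
#' source, a 2048-pixel line-scan spectrometer camera, 128 A-scans per
#' B-scan at 125 frames/s, ~2.8 um lateral and ~3.3 um axial resolution.
#'
#' `pixel_size_um` is the native (pre-calibration) pixel pitch of rendered
#' or reconstructed images, `c(axial, lateral)`. The default lateral pitch
#' is `lateral_fov_um / ascans_per_frame` (2 um) and the axial pitch matches
#' the spectral depth-pixel size `pi / (k_max - k_min)` (~2.2 um), so the
#' image-level and spectral simulation paths share one geometry. Masks are
#' later resampled to 1 um/pixel by [calibrate_resize()].
#'
#' @param center_wavelength_nm source center wavelength (nm).
#' @param bandwidth_nm full source bandwidth (nm).
#' @param spectral_samples spectrometer pixels per A-scan (>= 2; powers of
#'   two keep the FFT fast).
#' @param ascans_per_frame A-scans per B-scan frame.
#' @param fps frame rate (frames/s).
#' @param lateral_resolution_um,axial_resolution_um FWHM optical resolutions
#'   (um) used as the rendering point-spread function.
#' @param lateral_fov_um lateral field of view (um).
#' @param pixel_size_um named numeric `c(axial =, lateral =)` pixel pitch in
#'   um of rendered images.
#' @return An object of class `ocm_system`.
#' @export
ocm_system <- function(center_wavelength_nm = 850, bandwidth_nm = 165,
                       spectral_samples = 2048, ascans_per_frame = 128,
                       fps = 125, lateral_resolution_um = 2.8,
                       axial_resolution_um = 3.3, lateral_fov_um = 256,
                       pixel_size_um = c(
                         axial = 2.2,
                         lateral = lateral_fov_um / ascans_per_frame)) {
  vals <- c(center_wavelength_nm, bandwidth_nm, spectral_samples,
            ascans_per_frame, fps, lateral_resolution_um, axial_resolution_um,
            lateral_fov_um, pixel_size_um)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stopf("all ocm_system quantities must be finite and > 0")
  if (spectral_samples < 2 || spectral_samples != round(spectral_samples))
    stopf("spectral_samples must be an integer >= 2")
  if (bandwidth_nm >= 2 * center_wavelength_nm)
    stopf("bandwidth_nm too large for center_wavelength_nm")
  pixel_size_um <- setNames(as.numeric(pixel_size_um)[1:2],
                            c("axial", "lateral"))
  structure(list(center_wavelength_nm = center_wavelength_nm,
                 bandwidth_nm = bandwidth_nm,
                 spectral_samples = as.integer(spectral_samples),
                 ascans_per_frame = as.integer(ascans_per_frame),
                 fps = fps,
                 lateral_resolution_um = lateral_resolution_um,
                 axial_resolution_um = axial_resolution_um,
                 lateral_fov_um = lateral_fov_um,
                 pixel_size_um = pixel_size_um),
            class = "ocm_system")
}

#' @export
print.ocm_system <- function(x, ...) {
  cat("<ocm_system>\n")
  cat(sprintf("  source %g nm +/- %g/2 nm, %d spectral samples\n",
              x$center_wavelength_nm, x$bandwidth_nm, x$spectral_samples))
  cat(sprintf("  %d A-scans/frame at %g fps, FOV %g um\n",
              x$ascans_per_frame, x$fps, x$lateral_fov_um))
  cat(sprintf("  resolution %g um lateral / %g um axial; pixels %g x %g um\n",
              x$lateral_resolution_um, x$axial_resolution_um,
              x$pixel_size_um[["axial"]], x$pixel_size_um[["lateral"]]))
  invisible(x)
}

#' Vessel cross-section geometry for rendering
#'
#' The lumen is modeled as an ellipse of fixed lateral:axial aspect ratio
#' (wider than deep) surrounded by a bright wall on a darker background;
#' the aspect ratio is fixed so that every requested area maps to a unique
#' analytic ellipse, which makes rendered areas testable in closed form.
#'
#' @param aspect lateral-to-axial semi-axis ratio `a / b` of the lumen
#'   ellipse (> 0).
#' @param wall_um wall thickness in um.
#' @param margin_um clear margin between the outer wall and the image border
#'   used when deriving a field of view from an area.
#' @param lumen_level,wall_level,background_level relative linear
#'   reflectivity/intensity levels of the three compartments.
#' @return An object of class `vessel_geometry`.
#' @export
vessel_geometry <- function(aspect = 2, wall_um = 12, margin_um = 24,
                            lumen_level = 0.05, wall_level = 1,
                            background_level = 0.15) {
  if (!is_num1(aspect) || aspect <= 0) stopf("aspect must be > 0")
  if (!is_num1(wall_um) || wall_um <= 0) stopf("wall_um must be > 0")
  structure(list(aspect = aspect, wall_um = wall_um, margin_um = margin_um,
                 lumen_level = lumen_level, wall_level = wall_level,
                 background_level = background_level),
            class = "vessel_geometry")
}

# lumen semi-axes (um) of an ellipse of given area under the fixed aspect
lumen_semiaxes <- function(area_um2, aspect) {
  b <- sqrt(area_um2 / (pi * aspect))
  c(a = aspect * b, b = b)
}
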