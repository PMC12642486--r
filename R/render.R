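# Image-level forward model: hollow elliptical vessel cross-sections with
# anti-aliased edges, Gaussian PSF blur, and fully developed multiplicative
# speckle (unit-mean exponential intensity noise).

# coverage in [0,1] of an ellipse (semi-axes a, b in um) on the pixel grid;
# soft edge ~1 pixel wide removes pixelation bias in rendered areas
ellipse_coverage <- function(x2_over, z2_over, a, b, px_eff) {
  rho <- sqrt(x2_over / a^2 + z2_over / b^2)
  # approximate signed distance to the ellipse boundary (um)
  d <- (rho - 1) * b
  pmin(pmax(0.5 - d / px_eff, 0), 1)   # argument order keeps dim()
}

# derive a field of view c(axial, lateral) um that fits the outer wall of
# the largest expected lumen plus a clear margin
fov_for_area <- function(area_um2, geometry) {
  ax <- lumen_semiaxes(area_um2, geometry$aspect)
  c(axial = 2 * (ax[["b"]] + geometry$wall_um + geometry$margin_um),
    lateral = 2 * (ax[["a"]] + geometry$wall_um + geometry$margin_um))
}

#' Render one vessel B-scan cross-section
#'
#' Renders a hollow vessel: a bright elliptical wall around a dark lumen of
#' the requested area on a darker background, blurred by a Gaussian PSF with
#' sigmas derived from the system's lateral/axial resolutions (FWHM =
#' 2.355 sigma), then optionally corrupted by multiplicative unit-mean
#' exponential speckle.
#'
#' @param area_um2 requested lumen area in square microns (> 0 and at least
#'   one pixel).
#' @param system an [ocm_system()].
#' @param geometry a [vessel_geometry()].
#' @param fov_um optional field of view `c(axial, lateral)` in um; defaults
#'   to a field derived from `area_um2`. The outer wall must fit inside it.
#' @param speckle apply speckle noise? (`TRUE` by default).
#' @param seed optional integer; when given, the RNG is seeded before noise
#'   is drawn (identical inputs + seed give bit-identical images).
#' @param frame_index,time_s bookkeeping carried on the returned object.
#' @return An object of class `bscan_image`: list with non-negative
#'   `intensity` matrix (axial rows x lateral columns), `pixel_size_um`
#'   (`c(axial, lateral)`), `frame_index`, `time_s`.
#' @export
#' @examples
#' b <- render_bscan(3927, ocm_system(), speckle = FALSE)
#' dim(b$intensity)
render_bscan <- function(area_um2, system = ocm_system(),
                         geometry = vessel_geometry(), fov_um = NULL,
                         speckle = TRUE, seed = NULL,
                         frame_index = 1L, time_s = 0) {
  if (!is_num1(area_um2) || area_um2 <= 0) stopf("area_um2 must be > 0")
  px <- system$pixel_size_um
  if (area_um2 < prod(px))
    stopf("requested lumen area (%.3g um2) is below one pixel", area_um2)
  if (is.null(fov_um)) fov_um <- fov_for_area(area_um2, geometry)
  ax <- lumen_semiaxes(area_um2, geometry$aspect)
  if (2 * (ax[["a"]] + geometry$wall_um) > fov_um[["lateral"]] ||
      2 * (ax[["b"]] + geometry$wall_um) > fov_um[["axial"]])
    stopf("vessel (outer wall %.0f x %.0f um) does not fit the %.0f x %.0f um field of view",
          2 * (ax[["a"]] + geometry$wall_um), 2 * (ax[["b"]] + geometry$wall_um),
          fov_um[["lateral"]], fov_um[["axial"]])

  nr <- max(2L, round(fov_um[["axial"]] / px[["axial"]]))
  nc <- max(2L, round(fov_um[["lateral"]] / px[["lateral"]]))
  g <- render_grid(nr, nc, px)
  img <- render_vessel_frame(area_um2, g, geometry)
  img <- conv_sep(img,
                  system$axial_resolution_um / 2.355 / px[["axial"]],
                  system$lateral_resolution_um / 2.355 / px[["lateral"]])
  if (speckle) {
    if (!is.null(seed)) set.seed(seed)
    img <- img * matrix(rexp(nr * nc), nr, nc)
  }
  structure(list(intensity = img, pixel_size_um = px,
                 frame_index = as.integer(frame_index), time_s = time_s),
            class = "bscan_image")
}

# precomputed squared pixel coordinates (um^2) about the image center
render_grid <- function(nr, nc, px) {
  z <- (seq_len(nr) - (nr + 1) / 2) * px[["axial"]]
  x <- (seq_len(nc) - (nc + 1) / 2) * px[["lateral"]]
  list(z2 = matrix(z^2, nr, nc), x2 = matrix(x^2, nr, nc, byrow = TRUE),
       px_eff = sqrt(prod(px)), nr = nr, nc = nc)
}

# noise-free, unblurred compartment image on a precomputed grid
render_vessel_frame <- function(area_um2, g, geometry) {
  ax <- lumen_semiaxes(area_um2, geometry$aspect)
  outer_cov <- ellipse_coverage(g$x2, g$z2, ax[["a"]] + geometry$wall_um,
                                ax[["b"]] + geometry$wall_um, g$px_eff)
  lumen_cov <- ellipse_coverage(g$x2, g$z2, ax[["a"]], ax[["b"]], g$px_eff)
  geometry$background_level +
    (geometry$wall_level - geometry$background_level) * outer_cov +
    (geometry$lumen_level - geometry$wall_level) * lumen_cov
}

#' Render a full M-mode recording
#'
#' Generates the ground-truth area waveform for `kin` and renders one
#' B-scan per frame into an M-mode series. All randomness (beat jitter,
#' then per-frame speckle in frame order) is consumed from the stream
#' seeded by `kin$seed`, so a recording is fully reproducible. The field of
#' view is fixed across frames (derived from `eda_um2` with 5% headroom).
#'
#' @param kin a [vessel_kinematics()] object.
#' @param system an [ocm_system()] (its `fps` is taken from `kin`).
#' @param geometry a [vessel_geometry()].
#' @param speckle apply speckle noise?
#' @param out_dir optional directory; when given, the stack is written as a
#'   16-bit multi-page TIFF (`mmode.tif` + `mmode.json` metadata sidecar)
#'   and the ground truth as `truth.json`.
#' @return A list with `mmode` (an `mmode_series`: 3-D `frames` array
#'   `[axial, lateral, frame]`, `pixel_size_um`, `fps`, `timestamps`) and
#'   `truth` (the [area_waveform()] ground truth).
#' @export
render_mmode <- function(kin, system = ocm_system(),
                         geometry = vessel_geometry(), speckle = TRUE,
                         out_dir = NULL) {
  stopifnot(inherits(kin, "vessel_kinematics"),
            inherits(system, "ocm_system"))
  system$fps <- kin$fps
  set.seed(kin$seed)
  truth <- area_waveform(kin, reset_seed = FALSE)
  n <- truth$n_frames
  px <- system$pixel_size_um
  fov <- fov_for_area(kin$eda_um2 * 1.05, geometry)
  fov[["lateral"]] <- max(fov[["lateral"]], system$lateral_fov_um)
  nr <- max(2L, round(fov[["axial"]] / px[["axial"]]))
  nc <- max(2L, round(fov[["lateral"]] / px[["lateral"]]))
  g <- render_grid(nr, nc, px)
  sig_ax <- system$axial_resolution_um / 2.355 / px[["axial"]]
  sig_lat <- system$lateral_resolution_um / 2.355 / px[["lateral"]]

  frames <- array(0, dim = c(nr, nc, n))
  for (i in seq_len(n)) {
    img <- render_vessel_frame(truth$area_um2[i], g, geometry)
    img <- conv_sep(img, sig_ax, sig_lat)
    if (speckle) img <- img * matrix(rexp(nr * nc), nr, nc)
    frames[, , i] <- img
  }
  mm <- mmode_series(frames, px, kin$fps)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_mmode(mm, file.path(out_dir, "mmode.tif"))
    write_ground_truth(truth, file.path(out_dir, "truth.json"))
  }
  list(mmode = mm, truth = truth)
}

#' M-mode image series container
#'
#' @param frames 3-D numeric array `[axial, lateral, frame]` of non-negative
#'   linear intensities (a single matrix is promoted to one frame).
#' @param pixel_size_um `c(axial, lateral)` pixel pitch in um.
#' @param fps frame rate; timestamps are `(0:(n-1)) / fps`.
#' @return An object of class `mmode_series`.
#' @export
mmode_series <- function(frames, pixel_size_um, fps) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(length(dim(frames)) == 3L, all(frames >= 0), fps > 0)
  pixel_size_um <- setNames(as.numeric(pixel_size_um)[1:2],
                            c("axial", "lateral"))
  n <- dim(frames)[3]
  structure(list(frames = frames, pixel_size_um = pixel_size_um, fps = fps,
                 timestamps = (seq_len(n) - 1) / fps),
            class = "mmode_series")
}

#' @export
print.mmode_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<mmode_series> %d frames of %d x %d px (%g x %g um/px) at %g fps, %.3g s\n",
              d[3], d[1], d[2], x$pixel_size_um[["axial"]],
              x$pixel_size_um[["lateral"]], x$fps, d[3] / x$fps))
  invisible(x)
}

#' Write / read an M-mode series as 16-bit multi-page TIFF
#'
#' Intensities are scaled by the stack maximum into `[0, 1]` for storage;
#' the scale, pixel pitch and frame rate go to a JSON sidecar
#' (`<path>.json`) so `read_mmode()` restores the calibrated series.
#'
#' @param series an `mmode_series`.
#' @param path TIFF file path.
#' @return `write_mmode()` returns `path` invisibly; `read_mmode()` returns
#'   an `mmode_series`.
#' @export
write_mmode <- function(series, path) {
  stopifnot(inherits(series, "mmode_series"))
  mx <- max(series$frames, 1e-12)
  pages <- lapply(seq_len(dim(series$frames)[3]),
                  function(i) series$frames[, , i] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(pixel_size_um = as.list(series$pixel_size_um),
                            fps = series$fps, intensity_scale = mx),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mmode
#' @export
read_mmode <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]] * meta$intensity_scale
  mmode_series(frames, unlist(meta$pixel_size_um), meta$fps)
}
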