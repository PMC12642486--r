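# Spectral-domain forward model: wavelength-sampled interferograms for a
# set of discrete reflectors per A-scan,
#   I(k) = S(k) * (1 + sum_j r_j * cos(2 k z_j)),
# with a Gaussian source envelope S(k). Dispersion, sensitivity fall-off and
# autocorrelation terms are deliberately omitted (documented limitation).

# uniform-in-wavelength detector grid (nm, strictly increasing)
wavelength_grid <- function(system) {
  seq(system$center_wavelength_nm - system$bandwidth_nm / 2,
      system$center_wavelength_nm + system$bandwidth_nm / 2,
      length.out = system$spectral_samples)
}

# Gaussian source spectral envelope evaluated at wavenumbers k (nm^-1)
source_envelope <- function(k, system, amplitude = 1000) {
  lam <- wavelength_grid(system)
  kmin <- 2 * pi / max(lam); kmax <- 2 * pi / min(lam)
  k0 <- (kmin + kmax) / 2
  sigma <- (kmax - kmin) / 6
  amplitude * exp(-(k - k0)^2 / (2 * sigma^2))
}

#' Axial depth-pixel size of the spectral sampling
#'
#' `delta_z = pi / (k_max - k_min)` in um, the depth increment per FFT bin
#' after resampling the spectrum to a uniform wavenumber grid. Depends only
#' on the spectral span (bandwidth), not on the number of samples; the
#' unambiguous depth range is `spectral_samples / 2 * depth_pixel_um()`.
#'
#' @param system an [ocm_system()].
#' @return Depth pixel size in um.
#' @export
depth_pixel_um <- function(system) {
  lam <- wavelength_grid(system)
  dk <- 2 * pi / min(lam) - 2 * pi / max(lam)   # nm^-1
  pi / dk / 1000                                 # nm -> um
}

#' Synthesize spectral interferograms from a reflectivity profile
#'
#' Computes, per A-scan, the interferogram
#' `I(k) = S(k) * (1 + sum_j r_j cos(2 k z_j))` sampled on the system's
#' uniform-in-wavelength grid, with a Gaussian source envelope `S(k)`.
#' Deterministic (no noise term).
#'
#' @param reflectivity numeric matrix, depths x A-scans: reflectivity
#'   `r_j >= 0` of the reflector at `depths_um[j]` for each lateral
#'   position. A vector is treated as a single A-scan.
#' @param depths_um reflector depths in um; all must lie strictly inside
#'   the unambiguous range `spectral_samples / 2 * depth_pixel_um(system)`.
#' @param system an [ocm_system()].
#' @return An object of class `spectral_frame`: list with `counts`
#'   (A-scans x spectral samples, non-negative), `wavelength_nm` (strictly
#'   increasing), `domain = "wavelength"` and `k_nm = NULL`.
#' @export
#' @examples
#' sp <- synthesize_spectra(1, depths_um = 100, ocm_system())
#' dim(sp$counts)
synthesize_spectra <- function(reflectivity, depths_um,
                               system = ocm_system()) {
  if (is.vector(reflectivity)) reflectivity <- matrix(reflectivity, ncol = 1)
  stopifnot(is.matrix(reflectivity), nrow(reflectivity) == length(depths_um))
  if (any(reflectivity < 0)) stopf("reflectivities must be non-negative")
  zmax <- system$spectral_samples / 2 * depth_pixel_um(system)
  if (length(depths_um) && (any(depths_um < 0) || any(depths_um >= zmax)))
    stopf("depths must lie in [0, %.0f) um (unambiguous range)", zmax)

  lam <- wavelength_grid(system)
  k <- 2 * pi / lam                               # nm^-1, decreasing
  S <- source_envelope(k, system)
  n_asc <- ncol(reflectivity)
  if (length(depths_um) == 0L || all(reflectivity == 0)) {
    counts <- matrix(S, n_asc, length(lam), byrow = TRUE)
  } else {
    # fringes: (ascans x samples) = t(R) %*% cos(2 z k)
    C <- cos(2 * outer(depths_um * 1000, k))      # depths x samples
    fr <- crossprod(reflectivity, C)              # ascans x samples
    counts <- sweep(1 + fr, 2, S, `*`)
  }
  spectral_frame(counts, lam)
}

#' Spectral frame container
#'
#' @param counts numeric matrix, A-scans x spectral samples, of real-valued
#'   detector counts.
#' @param wavelength_nm strictly monotone increasing wavelength grid.
#' @param k_nm uniform wavenumber grid (set by [resample_to_k()]).
#' @param domain `"wavelength"` or `"wavenumber"`.
#' @return An object of class `spectral_frame`.
#' @export
spectral_frame <- function(counts, wavelength_nm, k_nm = NULL,
                           domain = "wavelength") {
  stopifnot(is.matrix(counts), ncol(counts) == length(wavelength_nm))
  if (any(diff(wavelength_nm) <= 0))
    stopf("wavelength grid must be strictly increasing")
  structure(list(counts = counts, wavelength_nm = wavelength_nm,
                 k_nm = k_nm, domain = domain),
            class = "spectral_frame")
}

#' @export
print.spectral_frame <- function(x, ...) {
  cat(sprintf("<spectral_frame> %d A-scans x %d samples, %s domain, %.1f-%.1f nm\n",
              nrow(x$counts), ncol(x$counts), x$domain,
              min(x$wavelength_nm), max(x$wavelength_nm)))
  invisible(x)
}

# reflectivity phantom of the vessel cross-section on the reconstruction
# grid: axial pitch = depth_pixel_um(system), lateral pitch = FOV / A-scans.
# Lumen reflectivity 0, wall bright, faint background inside the rendered
# band; placed at depth_offset_um so the vessel sits away from DC.
vessel_reflectivity <- function(area_um2, system = ocm_system(),
                                geometry = vessel_geometry(),
                                fov_um = NULL, depth_offset_um = 120) {
  if (is.null(fov_um)) fov_um <- fov_for_area(area_um2, geometry)
  dz <- depth_pixel_um(system)
  px <- c(axial = dz, lateral = system$lateral_fov_um / system$ascans_per_frame)
  nr <- max(2L, round(fov_um[["axial"]] / dz))
  nc <- system$ascans_per_frame
  g <- render_grid(nr, nc, px)
  geometry$lumen_level <- 0
  geometry$background_level <- 0.05
  r <- render_vessel_frame(area_um2, g, geometry)
  depths <- depth_offset_um + (seq_len(nr) - 1) * dz
  list(reflectivity = r, depths_um = depths, pixel_size_um = px)
}

#' Simulate a spectral-domain M-mode recording
#'
#' Spectral counterpart of [render_mmode()]: generates the ground-truth
#' waveform, builds a per-frame vessel reflectivity phantom, and synthesizes
#' one [spectral_frame] per frame. Deterministic given `kin$seed`.
#'
#' @param kin a [vessel_kinematics()] object.
#' @param system an [ocm_system()].
#' @param geometry a [vessel_geometry()].
#' @param depth_offset_um depth of the vessel band below zero delay.
#' @return A list with `frames` (list of `spectral_frame`), `truth`
#'   (ground truth), and `background` (the source envelope sampled on the
#'   wavelength grid, for [preprocess_spectrum()]).
#' @export
simulate_spectral_mmode <- function(kin, system = ocm_system(),
                                    geometry = vessel_geometry(),
                                    depth_offset_um = 120) {
  stopifnot(inherits(kin, "vessel_kinematics"))
  system$fps <- kin$fps
  truth <- area_waveform(kin)
  fov <- fov_for_area(kin$eda_um2 * 1.05, geometry)
  frames <- lapply(truth$area_um2, function(a) {
    ref <- vessel_reflectivity(a, system, geometry, fov, depth_offset_um)
    synthesize_spectra(ref$reflectivity, ref$depths_um, system)
  })
  k <- 2 * pi / wavelength_grid(system)
  list(frames = frames, truth = truth,
       background = source_envelope(k, system))
}
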