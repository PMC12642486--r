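# Standard SD-OCT reconstruction chain: background subtraction ->
# resampling to uniform wavenumber -> windowed FFT -> magnitude A-scans.
# The lab-specific processing behind real recordings is unpublished; this
# module documents a conventional chain with the same contract.

#' Background-subtract a spectral frame
#'
#' Removes the (DC) source term: subtracts a background spectrum from every
#' A-scan, then removes each A-scan's residual mean so the DC FFT bin is
#' empty. The default background is the mean spectrum over the frame's
#' A-scans, the usual choice when no reference spectrum was recorded.
#'
#' @param frame a [spectral_frame()].
#' @param background optional numeric vector (length = spectral samples),
#'   e.g. the source envelope returned by [simulate_spectral_mmode()].
#' @return A `spectral_frame` with zero-mean rows.
#' @export
preprocess_spectrum <- function(frame, background = NULL) {
  stopifnot(inherits(frame, "spectral_frame"))
  m <- ncol(frame$counts)
  if (is.null(background)) background <- colMeans(frame$counts)
  if (length(background) != m)
    stopf("background length %d != spectral samples %d", length(background), m)
  counts <- sweep(frame$counts, 2, background, `-`)
  counts <- counts - rowMeans(counts)
  spectral_frame(counts, frame$wavelength_nm, frame$k_nm, frame$domain)
}

#' Resample spectra to a uniform wavenumber grid
#'
#' Detectors sample uniformly in wavelength; depth reconstruction by FFT
#' requires uniform sampling in wavenumber `k = 2 pi / lambda`. Spectra are
#' linearly interpolated onto a uniform k grid of the same length spanning
#' the same endpoints (cubic is deliberately not the default; linear is
#' standard and monotone).
#'
#' @param frame a [spectral_frame()] in the wavelength domain.
#' @return A `spectral_frame` with `domain = "wavenumber"` and `k_nm` set
#'   (increasing, uniform).
#' @export
resample_to_k <- function(frame) {
  stopifnot(inherits(frame, "spectral_frame"))
  if (any(diff(frame$wavelength_nm) <= 0))
    stopf("wavelength grid must be strictly monotone")
  k_orig <- rev(2 * pi / frame$wavelength_nm)          # increasing
  k_new <- seq(k_orig[1], k_orig[length(k_orig)], length.out = length(k_orig))
  counts <- t(apply(frame$counts, 1, function(row)
    approx(k_orig, rev(row), xout = k_new)$y))
  if (nrow(frame$counts) == 1L) counts <- matrix(counts, nrow = 1)
  spectral_frame(counts, frame$wavelength_nm, k_nm = k_new,
                 domain = "wavenumber")
}

#' Depth profile (A-scan) from a uniform-k spectrum
#'
#' Applies a window (Hann by default), FFTs, and keeps the magnitude of the
#' positive-frequency half. Bin `b` (1-based) corresponds to depth
#' `(b - 1) * delta_z` with `delta_z = pi / (k_max - k_min)`.
#'
#' @param spec_k numeric vector (one spectrum) or matrix (A-scans x samples)
#'   sampled on the uniform wavenumber grid `k_nm`, or a `spectral_frame`
#'   in the wavenumber domain.
#' @param k_nm the uniform wavenumber grid (nm^-1); taken from the frame if
#'   `spec_k` is a `spectral_frame`.
#' @param window `"hann"` or `"none"`.
#' @return An object of class `ascan_profile`: list with `intensity`
#'   (depth pixels x A-scans, non-negative linear magnitude) and
#'   `depth_pixel_um`.
#' @export
ascan <- function(spec_k, k_nm = NULL, window = c("hann", "none")) {
  window <- match.arg(window)
  if (inherits(spec_k, "spectral_frame")) {
    if (!identical(spec_k$domain, "wavenumber"))
      stopf("spectral_frame must be resampled to k first (see resample_to_k)")
    k_nm <- spec_k$k_nm
    spec_k <- spec_k$counts
  }
  if (is.vector(spec_k)) spec_k <- matrix(spec_k, nrow = 1)
  m <- ncol(spec_k)
  if (is.null(k_nm) || length(k_nm) != m)
    stopf("k_nm grid of length %d required", m)
  w <- if (window == "hann")
    0.5 - 0.5 * cos(2 * pi * (seq_len(m) - 1) / (m - 1)) else rep(1, m)
  x <- t(sweep(spec_k, 2, w, `*`))                 # samples x ascans
  X <- mvfft(x)
  half <- m %/% 2
  intensity <- Mod(X[seq_len(half), , drop = FALSE]) / m
  dz <- pi / (k_nm[m] - k_nm[1]) / 1000            # nm -> um
  structure(list(intensity = intensity, depth_pixel_um = dz),
            class = "ascan_profile")
}

# full frame: spectral_frame -> bscan_image (linear magnitude)
reconstruct_bscan <- function(frame, system, background = NULL,
                              frame_index = 1L, time_s = 0,
                              window = "hann") {
  fr <- preprocess_spectrum(frame, background)
  fr <- resample_to_k(fr)
  prof <- ascan(fr, window = window)
  px <- c(axial = prof$depth_pixel_um,
          lateral = system$lateral_fov_um / system$ascans_per_frame)
  structure(list(intensity = prof$intensity, pixel_size_um = px,
                 frame_index = as.integer(frame_index), time_s = time_s),
            class = "bscan_image")
}

#' Reconstruct an M-mode series from spectral frames
#'
#' Runs [preprocess_spectrum()], [resample_to_k()] and [ascan()] on each
#' frame and assembles the magnitude images into an `mmode_series` with
#' timestamps at `1/fps` spacing.
#'
#' @param frames list of [spectral_frame()] objects (>= 1), all of the same
#'   shape.
#' @param system an [ocm_system()].
#' @param background optional background spectrum applied to every frame.
#' @param crop_depth_um optional `c(min, max)` depth window (um) to crop the
#'   reconstructed images to, e.g. around a phantom at a known offset.
#' @return An `mmode_series` of linear-intensity images (display
#'   log-compression is presentation-only and never applied here).
#' @export
reconstruct_mmode <- function(frames, system = ocm_system(),
                              background = NULL, crop_depth_um = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  shapes <- vapply(frames, function(f) dim(f$counts), integer(2))
  if (any(shapes != shapes[, 1]))
    stopf("inconsistent spectral frame shapes")
  imgs <- lapply(seq_along(frames), function(i)
    reconstruct_bscan(frames[[i]], system, background, i, (i - 1) / system$fps))
  px <- imgs[[1]]$pixel_size_um
  keep <- seq_len(nrow(imgs[[1]]$intensity))
  if (!is.null(crop_depth_um)) {
    depths <- (keep - 1) * px[["axial"]]
    keep <- which(depths >= crop_depth_um[1] & depths <= crop_depth_um[2])
  }
  arr <- array(0, dim = c(length(keep), ncol(imgs[[1]]$intensity),
                          length(imgs)))
  for (i in seq_along(imgs)) arr[, , i] <- imgs[[i]]$intensity[keep, ]
  mmode_series(arr, px, system$fps)
}
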