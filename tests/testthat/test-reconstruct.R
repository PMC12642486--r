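# spectral forward model and the SD-OCT reconstruction chain

small_sys <- function(samples = 512)
  ocm_system(spectral_samples = samples, ascans_per_frame = 16,
             lateral_fov_um = 64)

test_that("empty reflectivity gives the bare source envelope", {
  sys <- small_sys()
  sp <- synthesize_spectra(matrix(0, 3, 4), depths_um = c(50, 100, 150), sys)
  k <- 2 * pi / sp$wavelength_nm
  expect_equal(sp$counts[1, ], flycardia:::source_envelope(k, sys))
  expect_equal(sp$counts[1, ], sp$counts[4, ])
})

test_that("forward model is linear in the reflectors", {
  sys <- small_sys()
  d <- c(80, 140)
  ra <- matrix(c(0.6, 0), 2, 1); rb <- matrix(c(0, 0.4), 2, 1)
  sa <- synthesize_spectra(ra, d, sys)$counts
  sb <- synthesize_spectra(rb, d, sys)$counts
  sab <- synthesize_spectra(ra + rb, d, sys)$counts
  S <- synthesize_spectra(matrix(0, 2, 1), d, sys)$counts
  expect_equal(sa + sb - S, sab, tolerance = 1e-12)
})

test_that("depths beyond the unambiguous range are rejected", {
  sys <- small_sys()
  zmax <- sys$spectral_samples / 2 * depth_pixel_um(sys)
  expect_error(synthesize_spectra(matrix(1, 1, 1), zmax * 1.01, sys),
               "unambiguous")
  expect_silent(synthesize_spectra(matrix(1, 1, 1), zmax * 0.9, sys))
})

test_that("synthesis is deterministic", {
  sys <- small_sys()
  r <- matrix(runif(6), 3, 2)
  expect_identical(synthesize_spectra(r, c(40, 90, 130), sys),
                   synthesize_spectra(r, c(40, 90, 130), sys))
})

test_that("preprocessing zeroes a pure-background frame and isolates fringes", {
  sys <- small_sys()
  S <- flycardia:::source_envelope(2 * pi / flycardia:::wavelength_grid(sys),
                                   sys)
  raw <- spectral_frame(matrix(S, 4, length(S), byrow = TRUE),
                        flycardia:::wavelength_grid(sys))
  pp <- preprocess_spectrum(raw)
  expect_equal(max(abs(pp$counts)), 0)

  # single reflector minus envelope leaves S(k) * r * cos(2 k z)
  z <- 100; r <- 0.5
  sp <- synthesize_spectra(matrix(r, 1, 1), z, sys)
  pp2 <- preprocess_spectrum(sp, background = S)
  k <- 2 * pi / sp$wavelength_nm
  fringe <- S * r * cos(2 * k * z * 1000)
  expect_equal(pp2$counts[1, ], fringe - mean(fringe), tolerance = 1e-9)

  expect_error(preprocess_spectrum(sp, background = S[-1]), "length")
})

test_that("k-resampling: constants pass through, non-monotone grids error", {
  sys <- small_sys()
  lam <- flycardia:::wavelength_grid(sys)
  const <- spectral_frame(matrix(3, 2, length(lam)), lam)
  expect_equal(resample_to_k(const)$counts, const$counts, tolerance = 1e-12)
  rk <- resample_to_k(const)
  expect_equal(diff(rk$k_nm), rep(diff(rk$k_nm)[1], length(lam) - 1),
               tolerance = 1e-12)
  bad <- const
  bad$wavelength_nm[5] <- bad$wavelength_nm[3]
  expect_error(resample_to_k(bad), "monotone")
})

test_that("a spectrum already uniform in k is unchanged by resampling", {
  sys <- small_sys()
  lam <- flycardia:::wavelength_grid(sys)
  k_uniform <- seq(2 * pi / max(lam), 2 * pi / min(lam),
                   length.out = length(lam))
  x <- sin(seq(0, 6, length.out = length(lam)))
  # wavelength grid that maps to the uniform k grid
  fr <- spectral_frame(matrix(rev(x), 1, length(lam)),
                       sort(2 * pi / k_uniform))
  out <- resample_to_k(fr)
  expect_equal(out$counts[1, ], x, tolerance = 1e-9)
})

test_that("point reflectors are localized within one depth pixel", {
  sys <- small_sys()
  dz <- depth_pixel_um(sys)
  zmax <- sys$spectral_samples / 2 * dz
  depths <- seq(0.05, 0.95, length.out = 20) * zmax
  S <- flycardia:::source_envelope(2 * pi / flycardia:::wavelength_grid(sys),
                                   sys)
  for (z in depths) {
    sp <- synthesize_spectra(matrix(1, 1, 1), z, sys)
    prof <- ascan(resample_to_k(preprocess_spectrum(sp, S)))
    peak_bin <- which.max(prof$intensity[, 1])
    expect_lte(abs((peak_bin - 1) - z / dz), 1)
  }
})

test_that("zero spectra give zero profiles; two reflectors resolve", {
  sys <- small_sys()
  lam <- flycardia:::wavelength_grid(sys)
  zero <- resample_to_k(spectral_frame(matrix(0, 1, length(lam)), lam))
  expect_equal(max(ascan(zero)$intensity), 0)

  dz <- depth_pixel_um(sys)
  sep <- 2 * sys$axial_resolution_um + 4 * dz
  S <- flycardia:::source_envelope(2 * pi / lam, sys)
  sp <- synthesize_spectra(matrix(c(1, 1), 2, 1), c(120, 120 + sep), sys)
  prof <- ascan(resample_to_k(preprocess_spectrum(sp, S)))$intensity[, 1]
  pk <- order(prof, decreasing = TRUE)[1:8]
  groups <- cutree(hclust(dist(pk)), h = 3)
  expect_gte(length(unique(groups)), 2)
})

test_that("reconstruct_mmode shapes, timestamps and error handling", {
  sys <- small_sys()
  lam <- flycardia:::wavelength_grid(sys)
  one <- synthesize_spectra(matrix(0.5, 1, sys$ascans_per_frame), 100, sys)
  mm <- reconstruct_mmode(list(one), sys)
  expect_equal(dim(mm$frames)[3], 1L)
  expect_equal(dim(mm$frames)[1], sys$spectral_samples / 2)
  expect_equal(mm$pixel_size_um[["axial"]], depth_pixel_um(sys))

  mm3 <- reconstruct_mmode(list(one, one, one), sys)
  expect_equal(mm3$timestamps, (0:2) / sys$fps)

  short <- spectral_frame(one$counts[, 1:100, drop = FALSE], lam[1:100])
  expect_error(reconstruct_mmode(list(one, short), sys), "inconsistent")
})

test_that("synthesize -> reconstruct -> segment recovers the area trace", {
  sys <- ocm_system(spectral_samples = 512)
  kin <- vessel_kinematics(duration_s = 1.0, jitter_cv = 0, seed = 4)
  sp <- simulate_spectral_mmode(kin, sys)
  fov_ax <- flycardia:::fov_for_area(kin$eda_um2 * 1.05,
                                     vessel_geometry())[["axial"]]
  mm <- reconstruct_mmode(sp$frames, sys, sp$background,
                          crop_depth_um = 120 + c(-10, fov_ax + 10))
  tr <- extract_area_trace(calibrate_resize(segment_mmode(mm), 1))
  err <- abs(tr$area_um2 - sp$truth$area_um2) / sp$truth$area_um2
  expect_lte(mean(err), 0.05)
})
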