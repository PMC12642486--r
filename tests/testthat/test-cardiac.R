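# beat detection and the five cardiac read-outs

test_that("smooth_trace: identity cases, denoising, and window errors", {
  tr <- area_trace(c(5, 7, 6, 8, 5, 7), fps = 10)
  expect_equal(smooth_trace(tr, 0), tr)
  const <- area_trace(rep(4, 50), fps = 10)
  expect_equal(smooth_trace(const, 0.5)$area_um2, rep(4, 50))
  expect_error(smooth_trace(tr, 10), "longer than trace")

  set.seed(2)
  t_s <- seq(0, 8, by = 1 / 125)
  clean <- 5000 + 2000 * sin(2 * pi * 2 * t_s)
  noisy <- area_trace(pmax(clean + rnorm(length(t_s), 0, 300), 0), fps = 125)
  sm <- smooth_trace(noisy, 0.05)             # period / 10
  rmse <- function(x) sqrt(mean((x - clean)^2))
  expect_lt(rmse(sm$area_um2), rmse(noisy$area_um2))
})

test_that("detector resolves the 7-sample alternating example", {
  tr <- area_trace(c(2, 5, 2, 5, 2, 5, 2), fps = 5)
  m <- detect_beats(tr, hr_max_hz = 5, min_prominence_frac = 0.5)
  expect_identical(m$peaks, c(2L, 4L, 6L))
  expect_identical(m$valleys, c(3L, 5L))
  expect_equal(m$period_s, 2 / 5)
})

test_that("detector rejects constant and beatless traces", {
  expect_error(detect_beats(area_trace(rep(5, 100), fps = 10)), "constant")
  one_dip <- area_trace(c(rep(10, 20), 5, rep(10, 20)), fps = 10)
  expect_error(detect_beats(one_dip, min_prominence_frac = 0.25),
               "fewer than 2 valleys")
})

test_that("detector matches the brute-force oracle on random traces", {
  for (seed in 1:25) {
    n <- sample(50:400, 1)
    x <- random_trace(n, seed)
    x <- x - min(x)               # both paths must see the same vector
    fps <- 125
    hr_max <- sample(c(4, 8, 12), 1)
    frac <- sample(c(0.1, 0.25, 0.4), 1)
    ref <- oracle_detect(x, fps, hr_max, frac)
    got <- tryCatch(
      detect_beats(area_trace(x, fps), hr_max_hz = hr_max,
                   min_prominence_frac = frac),
      error = function(e) NULL)
    if (is.null(got)) {
      expect_lt(length(ref$valleys), 2)
    } else {
      expect_identical(as.integer(got$peaks), as.integer(ref$peaks))
      expect_identical(as.integer(got$valleys), as.integer(ref$valleys))
    }
  }
})

test_that("detector recovers ground-truth beats on a noise-free simulation", {
  kin <- vessel_kinematics(rate_hz = 2, jitter_cv = 0, duration_s = 16,
                           fps = 125)
  gt <- area_waveform(kin)
  m <- detect_beats(area_trace(gt$area_um2, 125))
  expect_gte(length(m$valleys), floor(16 * 2) - 1)
  expect_lte(length(m$valleys), floor(16 * 2) + 1)
  matched <- vapply(m$valleys, function(v)
    min(abs(gt$valley_frames - v)), numeric(1))
  expect_lte(max(matched), 1)
})

test_that("heart rate from valley spacing", {
  hr <- heart_rate(beat_markers(integer(0), c(1, 126, 251), fps = 125))
  expect_equal(hr$per_beat_hz, c(1, 1))
  expect_equal(hr$mean_bpm, 60)
  hr2 <- heart_rate(beat_markers(integer(0), c(1, 51, 101), fps = 125))
  expect_equal(hr2$mean_hz, 2.5)
  expect_error(heart_rate(beat_markers(integer(0), 5L, fps = 125)),
               ">= 2 valleys")
})

test_that("EDA/ESA are marker means; single-marker case; errors", {
  tr <- area_trace(c(1000, 7000, 2000, 9000, 4000), fps = 10)
  m <- beat_markers(peaks = c(2L, 4L), valleys = c(3L, 5L), fps = 10)
  expect_equal(eda(tr, m), 8000)
  expect_equal(esa(tr, m), 3000)
  m1 <- beat_markers(peaks = 2L, valleys = c(3L, 5L), fps = 10)
  expect_equal(eda(tr, m1), 7000)
  m0 <- beat_markers(integer(0), c(3L, 5L), fps = 10)
  expect_error(eda(tr, m0), "no peaks")
})

test_that("fractional shortening formula and its algebra", {
  expect_equal(fractional_shortening(8000, 4000), 50)
  expect_equal(fractional_shortening(5000, 5000), 0)
  expect_equal(fractional_shortening(7700, 2900), 100 * 4800 / 7700)
  expect_error(fractional_shortening(4000, 5000), "exceed")
  expect_error(fractional_shortening(0, 0), "> 0")
  set.seed(3)
  for (i in 1:200) {
    e <- runif(1, 1e3, 1e4); s <- runif(1, 0, e); c0 <- runif(1, 0.1, 10)
    expect_equal(fractional_shortening(c0 * e, c0 * s),
                 fractional_shortening(e, s))
  }
  fs <- vapply(seq(1000, 5000, by = 500), fractional_shortening,
               numeric(1), eda_um2 = 5000)
  expect_true(all(diff(fs) < 0))              # strictly decreasing in ESA
})

test_that("arrhythmicity index: regular rhythm, hand example, invariances", {
  expect_equal(arrhythmicity_index(
    beat_markers(integer(0), c(1, 63, 125, 187), fps = 125)), 0)
  # periods 0.5, 0.5, 1.0 s -> SD / median = 0.2887 / 0.5
  m <- beat_markers(integer(0), c(1, 6, 11, 21), fps = 10)
  expect_equal(arrhythmicity_index(m), sd(c(0.5, 0.5, 1)) / 0.5)
  # uniform time rescaling: double fps, double spacing
  m2 <- beat_markers(integer(0), c(1, 11, 21, 41), fps = 20)
  expect_equal(arrhythmicity_index(m2), arrhythmicity_index(m))
  expect_error(arrhythmicity_index(beat_markers(integer(0), c(1L, 5L), 10)),
               ">= 2 beat periods")
})

test_that("cardiac_report on the noise-free default preset", {
  kin <- kinematics_preset("WT-1wk-male", jitter_cv = 0)
  gt <- area_waveform(kin)
  tr <- area_trace(gt$area_um2, kin$fps)
  rep <- cardiac_report(tr)
  expect_lt(abs(rep$fs_percent - 100 * 4800 / 7700), 2)
  expect_lt(abs(rep$eda_um2 - 7700) / 7700, 0.03)
  expect_lt(abs(rep$esa_um2 - 2900) / 2900, 0.03)
  expect_lt(abs(rep$hr_hz - 2) / 2, 0.02)
  # jitter-free periods alternate 62/63 frames, so AI reflects only the
  # frame-quantization floor ~ 0.5 / (fps / rate)
  expect_lt(rep$ai, 0.01)
  # determinism: identical input gives identical report
  expect_identical(rep, cardiac_report(tr))
  # structured failure surfaces from the detector
  expect_error(cardiac_report(area_trace(rep(5, 200), fps = 125)), "constant")
})

test_that("report JSON carries the five read-outs", {
  kin <- test_kin()
  gt <- area_waveform(kin)
  rep <- cardiac_report(area_trace(gt$area_um2, kin$fps))
  path <- tempfile(fileext = ".json")
  write_cardiac_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$fs_percent, rep$fs_percent)
  expect_equal(back$eda_um2, rep$eda_um2)
  expect_equal(length(back$valley_frames), length(rep$markers$valleys))
})
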