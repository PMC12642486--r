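# Intensity-based lumen segmentation. The lumen is the dark region enclosed
# by the bright wall: Gaussian pre-smoothing, global threshold, a mild
# morphological opening (removes speckle-induced dark bridges across the
# wall) followed by closing, selection of the largest dark component that
# does not touch the image border, hole filling. Frames without an adequate
# interior component are flagged invalid, never raised as errors.

#' Segment the vessel lumen in one frame
#'
#' @param image a `bscan_image` (from [render_bscan()] or reconstruction)
#'   or a plain numeric matrix of linear intensities, in which case
#'   `pixel_size_um` must be supplied.
#' @param pixel_size_um `c(axial, lateral)` um/pixel; taken from the image
#'   object when available.
#' @param smooth_sigma_um Gaussian pre-smoothing sigma in um (tames
#'   speckle; the default trades a little edge blur for robust thresholds).
#' @param min_area_um2 smallest credible lumen; frames whose best component
#'   is smaller are flagged invalid.
#' @param threshold `"midlevel"` (default) starts from Otsu's threshold on
#'   the smoothed frame, then re-thresholds once at the midpoint between
#'   the lumen and wall intensity levels estimated from the Otsu mask,
#'   which centres the boundary on the wall-lumen edge; `"otsu"` stops
#'   after the first pass.
#' @return A list: logical `mask`, logical `valid`, `area_um2` (0 when
#'   invalid), and the `threshold` used.
#' @export
#' @examples
#' b <- render_bscan(3927, speckle = FALSE)
#' s <- segment_lumen(b)
#' s$valid; s$area_um2
segment_lumen <- function(image, pixel_size_um = NULL,
                          smooth_sigma_um = 3, min_area_um2 = 400,
                          threshold = c("midlevel", "otsu")) {
  threshold <- match.arg(threshold)
  if (inherits(image, "bscan_image")) {
    pixel_size_um <- image$pixel_size_um
    image <- image$intensity
  }
  stopifnot(is.matrix(image))
  if (is.null(pixel_size_um)) stopf("pixel_size_um calibration is required")
  px <- setNames(as.numeric(pixel_size_um)[1:2], c("axial", "lateral"))
  sm <- conv_sep(image, smooth_sigma_um / px[["axial"]],
                 smooth_sigma_um / px[["lateral"]])
  res <- segment_core(sm, px, min_area_um2, threshold)
  res
}

# shared per-frame segmentation on an already-smoothed image
segment_core <- function(sm, px, min_area_um2, threshold) {
  mx <- max(sm)
  invalid <- list(mask = matrix(FALSE, nrow(sm), ncol(sm)), valid = FALSE,
                  area_um2 = 0, threshold = NA_real_)
  if (mx <= 0 || min(sm) == mx) return(invalid)
  thr <- EBImage::otsu(sm / mx, range = c(0, 1)) * mx
  mask <- threshold_component(sm, thr, px, min_area_um2)
  if (threshold == "midlevel" && !is.null(mask)) {
    # work in a window around the first-pass component: cheaper, and
    # distant dark regions cannot displace the lumen
    rr <- range(which(rowSums(mask) > 0))
    cc <- range(which(colSums(mask) > 0))
    rr <- max(1L, rr[1] - 8L):min(nrow(sm), rr[2] + 8L)
    cc <- max(1L, cc[1] - 8L):min(ncol(sm), cc[2] + 8L)
    smw <- sm[rr, cc, drop = FALSE]
    mw <- mask[rr, cc, drop = FALSE]
    lumen_lvl <- median(smw[mw])
    # wall level from the upper quantile of the surrounding ring; threshold
    # slightly above midlevel compensates the inward crossing shift that
    # smoothing a thin bright band produces
    ring <- EBImage::dilate(mw, EBImage::makeBrush(9, "box")) & !mw
    wall_lvl <- quantile(smw[ring], 0.85, names = FALSE)
    thr2 <- lumen_lvl + 0.55 * (wall_lvl - lumen_lvl)
    m2 <- threshold_component(smw, thr2, px, min_area_um2)
    if (!is.null(m2)) {
      mask[] <- FALSE
      mask[rr, cc] <- m2
      thr <- thr2
    }
  }
  if (is.null(mask)) return(invalid)
  list(mask = mask, valid = TRUE, area_um2 = sum(mask) * prod(px),
       threshold = thr)
}

# dark-region components below thr; opening removes thin speckle bridges
# across the wall, closing fills pinholes; drop border-touching components,
# keep the largest one >= min area, fill holes; NULL if none
threshold_component <- function(sm, thr, px, min_area_um2) {
  dark <- sm < thr
  if (!any(dark)) return(NULL)
  dark <- EBImage::opening(dark, EBImage::makeBrush(3, "box")) > 0
  dark <- EBImage::closing(dark, EBImage::makeBrush(3, "box")) > 0
  lab <- EBImage::bwlabel(dark)
  if (max(lab) == 0) return(NULL)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab, nbins = max(lab))
  sizes[intersect(border, seq_along(sizes))] <- 0
  if (all(sizes * prod(px) < min_area_um2)) return(NULL)
  best <- which.max(sizes)
  mask <- lab == best
  EBImage::fillHull(mask) > 0
}

#' Segment every frame of an M-mode series
#'
#' @param series an `mmode_series`.
#' @inheritParams segment_lumen
#' @return An object of class `mask_stack`: list with logical 3-D `masks`
#'   array, `pixel_size_um`, `fps`, `timestamps`, logical `valid` per
#'   frame.
#' @export
segment_mmode <- function(series, smooth_sigma_um = 3, min_area_um2 = 400,
                          threshold = c("midlevel", "otsu")) {
  stopifnot(inherits(series, "mmode_series"))
  threshold <- match.arg(threshold)
  px <- series$pixel_size_um
  d <- dim(series$frames)
  sig_ax <- smooth_sigma_um / px[["axial"]]
  sig_lat <- smooth_sigma_um / px[["lateral"]]
  masks <- array(FALSE, dim = d)
  valid <- logical(d[3])
  for (i in seq_len(d[3])) {
    sm <- conv_sep(series$frames[, , i], sig_ax, sig_lat)
    r <- segment_core(sm, px, min_area_um2, threshold)
    masks[, , i] <- r$mask
    valid[i] <- r$valid
  }
  mask_stack(masks, px, series$fps, valid)
}

#' Binary mask stack container
#'
#' @param masks logical 3-D array `[axial, lateral, frame]` (a matrix is
#'   promoted to one frame).
#' @param pixel_size_um `c(axial, lateral)` um/pixel.
#' @param fps frame rate.
#' @param valid logical per-frame validity flags (default all `TRUE`).
#' @return An object of class `mask_stack`.
#' @export
mask_stack <- function(masks, pixel_size_um, fps,
                       valid = rep(TRUE, dim(masks)[3])) {
  if (is.matrix(masks)) masks <- array(masks, dim = c(dim(masks), 1L))
  stopifnot(length(dim(masks)) == 3L, is.logical(masks),
            length(valid) == dim(masks)[3])
  pixel_size_um <- setNames(as.numeric(pixel_size_um)[1:2],
                            c("axial", "lateral"))
  structure(list(masks = masks, pixel_size_um = pixel_size_um, fps = fps,
                 timestamps = (seq_len(dim(masks)[3]) - 1) / fps,
                 valid = valid),
            class = "mask_stack")
}

#' @export
print.mask_stack <- function(x, ...) {
  d <- dim(x$masks)
  cat(sprintf("<mask_stack> %d frames of %d x %d px at %g x %g um/px; %d valid\n",
              d[3], d[1], d[2], x$pixel_size_um[["axial"]],
              x$pixel_size_um[["lateral"]], sum(x$valid)))
  invisible(x)
}

#' Resample masks to 1 micron per pixel
#'
#' Nearest-neighbour rescaling of every mask to an isotropic target pitch
#' (1 um/pixel by convention), after which lumen area equals pixel count.
#'
#' @param stack a `mask_stack`.
#' @param target_um target isotropic pixel pitch in um.
#' @return A `mask_stack` at `target_um` per pixel.
#' @export
calibrate_resize <- function(stack, target_um = 1) {
  stopifnot(inherits(stack, "mask_stack"))
  px <- stack$pixel_size_um
  if (is.null(px) || any(!is.finite(px)) || any(px <= 0))
    stopf("mask stack lacks a valid pixel_size_um calibration")
  if (all(abs(px - target_um) < 1e-12)) return(stack)
  d <- dim(stack$masks)
  nr <- max(1L, round(d[1] * px[["axial"]] / target_um))
  nc <- max(1L, round(d[2] * px[["lateral"]] / target_um))
  # nearest-neighbour index maps (EBImage::resize pixel-centre convention)
  ri <- pmin(pmax(ceiling((seq_len(nr) - 0.5) * d[1] / nr), 1L), d[1])
  ci <- pmin(pmax(ceiling((seq_len(nc) - 0.5) * d[2] / nc), 1L), d[2])
  out <- stack$masks[ri, ci, , drop = FALSE]
  mask_stack(out, c(axial = target_um, lateral = target_um), stack$fps,
             stack$valid)
}

#' Extract the lumen-area trace from a mask stack
#'
#' Converts per-frame mask pixel counts into areas (um^2). Invalid frames
#' are linearly interpolated from their valid neighbours (nearest valid
#' value at the ends) and stay flagged. A recording with more than
#' `max_invalid_frac` invalid frames is unusable and raises an error.
#'
#' @param stack a `mask_stack` (calibrated or not; areas use its pixel
#'   pitch).
#' @param max_invalid_frac maximum tolerated fraction of invalid frames.
#' @return An `area_trace`: a data.frame with columns `frame`, `time_s`,
#'   `area_um2`, `valid`, carrying the frame rate in `attr(, "fps")`.
#' @export
extract_area_trace <- function(stack, max_invalid_frac = 0.2) {
  stopifnot(inherits(stack, "mask_stack"))
  d <- dim(stack$masks)
  n <- d[3]
  px_area <- prod(stack$pixel_size_um)
  flat <- stack$masks
  dim(flat) <- c(d[1] * d[2], n)
  area <- colSums(flat) * px_area
  valid <- stack$valid
  bad <- !valid
  if (mean(bad) > max_invalid_frac)
    stopf("%.0f%% of frames invalid (> %.0f%% allowed): recording unusable",
          100 * mean(bad), 100 * max_invalid_frac)
  if (any(bad)) {
    area[bad] <- approx(which(valid), area[valid], xout = which(bad),
                        rule = 2)$y
  }
  area_trace(area, stack$fps, valid)
}

#' Area-trace container
#'
#' @param area_um2 per-frame lumen area (um^2, >= 0).
#' @param fps frame rate.
#' @param valid per-frame validity flags.
#' @return A data.frame of class `area_trace` with columns `frame`,
#'   `time_s`, `area_um2`, `valid` and attribute `fps`.
#' @export
area_trace <- function(area_um2, fps, valid = rep(TRUE, length(area_um2))) {
  stopifnot(all(area_um2 >= 0), fps > 0, length(valid) == length(area_um2))
  n <- length(area_um2)
  out <- data.frame(frame = seq_len(n), time_s = (seq_len(n) - 1) / fps,
                    area_um2 = as.numeric(area_um2), valid = valid)
  attr(out, "fps") <- fps
  class(out) <- c("area_trace", "data.frame")
  out
}

#' Write / read an area trace as CSV
#'
#' Columns `frame,time_s,area_um2,valid`; the frame rate is recoverable
#' from the `time_s` spacing.
#'
#' @param trace an `area_trace`.
#' @param path CSV path.
#' @export
write_area_trace <- function(trace, path) {
  stopifnot(inherits(trace, "area_trace"))
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_area_trace
#' @export
read_area_trace <- function(path) {
  df <- read.csv(path)
  need <- c("frame", "time_s", "area_um2", "valid")
  if (!all(need %in% names(df)))
    stopf("trace CSV must have columns %s", paste(need, collapse = ","))
  fps <- 1 / median(diff(df$time_s))
  area_trace(df$area_um2, fps, as.logical(df$valid))
}
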