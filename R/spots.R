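# Spot detection on filtered images and the annulus-based SNR measure.

#' Band-pass filter an image for diffraction-limited spots
#'
#' Difference-of-Gaussians: the image smoothed at `low_sigma` minus the
#' image smoothed at `high_sigma`, with negative values clipped to zero.
#' Removes both pixel noise and slowly varying background so local maxima
#' correspond to spots.
#'
#' @param img numeric matrix.
#' @param low_sigma,high_sigma Gaussian sigmas in pixels (low < high).
#' @return filtered matrix, same dimensions.
#' @export
filter_image <- function(img, low_sigma = 1, high_sigma = 5) {
  if (low_sigma >= high_sigma)
    stop("low_sigma must be smaller than high_sigma")
  img <- matrix(as.numeric(img), nrow(img), ncol(img))
  lo <- EBImage::gblur(img, sigma = low_sigma)
  hi <- EBImage::gblur(img, sigma = high_sigma)
  out <- lo - hi
  out[out < 0] <- 0
  out
}

#' Detect spots as thresholded local maxima
#'
#' Pixels that are strict local maxima in their 3x3 neighbourhood and
#' exceed `median + threshold_sd * robust sd` (robust sd = 1.4826 x MAD, so
#' bright spots do not inflate the threshold) are candidate spots;
#' non-maximum suppression keeps the brightest detection within
#' `min_separation_px`. Positions are refined to subpixel accuracy over
#' the 3x3 window (Gaussian interpolation, intensity-weighted centroid as
#' fallback) and converted to microns.
#'
#' @param filtered filtered image from [filter_image()].
#' @param threshold_sd detection threshold in robust sds above the median.
#' @param min_separation_px non-maximum suppression radius (pixels).
#' @param pixel_size microns per pixel.
#' @param round round index stored in the output.
#' @param is_bead logical flag stored in the output.
#' @return spot table: data.frame round, x_um, y_um, intensity, is_bead.
#' @export
detect_spots <- function(filtered, threshold_sd = 5, min_separation_px = 3,
                         pixel_size = 0.18, round = 0L, is_bead = FALSE) {
  stopifnot(threshold_sd > 0)
  med <- stats::median(filtered)
  # clipping at zero shrinks (or zeroes) the MAD when a large share of the
  # pixels are 0; the upper quartile of the half-normal recovers the noise
  # scale in that regime, so take the larger of the two robust estimates
  s <- max(stats::mad(filtered),
           (stats::quantile(filtered, 0.75, names = FALSE) - med) / 0.6745)
  if (s == 0) s <- stats::sd(filtered)
  thr <- med + threshold_sd * s
  ny <- nrow(filtered); nx <- ncol(filtered)
  if (ny < 3L || nx < 3L || !any(filtered > thr))
    return(data.frame(round = integer(0), x_um = numeric(0),
                      y_um = numeric(0), intensity = numeric(0),
                      is_bead = logical(0)))
  core <- filtered[2:(ny - 1L), 2:(nx - 1L)]
  is_max <- core > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    nb <- filtered[(2:(ny - 1L)) + dy, (2:(nx - 1L)) + dx]
    is_max <- is_max & (core >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(round = integer(0), x_um = numeric(0),
                      y_um = numeric(0), intensity = numeric(0),
                      is_bead = logical(0)))
  ry <- idx[, 1L] + 1L; cx <- idx[, 2L] + 1L    # matrix indices of maxima
  inten <- filtered[cbind(ry, cx)]

  # non-maximum suppression, brightest first
  ord <- order(inten, decreasing = TRUE)
  keep <- logical(length(ord))
  ky <- numeric(0); kx <- numeric(0)
  for (i in ord) {
    if (length(ky) == 0L ||
        min((ky - ry[i])^2 + (kx - cx[i])^2) >= min_separation_px^2) {
      keep[i] <- TRUE
      ky <- c(ky, ry[i]); kx <- c(kx, cx[i])
    }
  }
  ry <- ry[keep]; cx <- cx[keep]; inten <- inten[keep]

  # subpixel refinement over the 3x3 window: Gaussian interpolation
  # (parabola in log intensity, exact for a noiseless Gaussian peak) with
  # intensity-weighted centroid as fallback when a neighbour is not positive
  sub_x <- numeric(length(ry)); sub_y <- numeric(length(ry))
  gauss_off <- function(im, ip, i0) {
    den <- log(im) + log(ip) - 2 * log(i0)
    if (!is.finite(den) || den >= 0) return(NA_real_)
    max(-0.5, min(0.5, 0.5 * (log(im) - log(ip)) / den))
  }
  for (i in seq_along(ry)) {
    w <- filtered[(ry[i] - 1L):(ry[i] + 1L), (cx[i] - 1L):(cx[i] + 1L)]
    ox <- if (all(w[2L, ] > 0)) gauss_off(w[2L, 1L], w[2L, 3L], w[2L, 2L])
          else NA_real_
    oy <- if (all(w[, 2L] > 0)) gauss_off(w[1L, 2L], w[3L, 2L], w[2L, 2L])
          else NA_real_
    if (is.na(ox) || is.na(oy)) {
      w <- pmax(w, 0); s <- sum(w)
      if (s <= 0) { ox <- 0; oy <- 0 } else {
        if (is.na(ox)) ox <- sum(t(w) * (-1:1)) / s
        if (is.na(oy)) oy <- sum(w * (-1:1)) / s
      }
    }
    sub_x[i] <- ox; sub_y[i] <- oy
  }
  # pixel (col-1, row-1) is 0-based; its center sits at (index + 0.5) * ps
  data.frame(round = round,
             x_um = (cx - 1L + sub_x + 0.5) * pixel_size,
             y_um = (ry - 1L + sub_y + 0.5) * pixel_size,
             intensity = inten, is_bead = is_bead)
}

#' Signal-to-noise ratio of detected spots
#'
#' SNR = peak signal over the standard deviation of the background pixels
#' in an annulus around the spot (default radii 3 and 9 pixels). Pixels of
#' the annulus that fall within `r_in` of another detected spot are
#' excluded from the background so neighbouring signal does not inflate
#' the noise estimate. A zero background sd yields `Inf`.
#'
#' @param img image the spots were detected in (numeric matrix).
#' @param spots spot table with `x_um`, `y_um` (microns).
#' @param r_in,r_out annulus radii in pixels.
#' @param pixel_size microns per pixel.
#' @return numeric vector of per-spot SNR values (NA where the annulus
#'   leaves the image).
#' @export
compute_snr <- function(img, spots, r_in = 3, r_out = 9,
                        pixel_size = 0.18) {
  ny <- nrow(img); nx <- ncol(img)
  px <- floor(spots$x_um / pixel_size)   # 0-based pixel indices
  py <- floor(spots$y_um / pixel_size)
  n <- nrow(spots)
  snr <- rep(NA_real_, n)
  offs <- expand.grid(dx = -r_out:r_out, dy = -r_out:r_out)
  d <- sqrt(offs$dx^2 + offs$dy^2)
  ann <- offs[d > r_in & d <= r_out, ]
  for (i in seq_len(n)) {
    if (px[i] - r_out < 0L || px[i] + r_out >= nx ||
        py[i] - r_out < 0L || py[i] + r_out >= ny) next
    ax <- px[i] + ann$dx; ay <- py[i] + ann$dy
    # exclude annulus pixels near any other spot
    ok <- rep(TRUE, nrow(ann))
    for (j in seq_len(n)) {
      if (j == i) next
      dd <- (ax - px[j])^2 + (ay - py[j])^2
      ok <- ok & dd > r_in^2
    }
    bg <- img[cbind(ay[ok] + 1L, ax[ok] + 1L)]
    peak <- max(img[(py[i]:(py[i] + 2L)), (px[i]:(px[i] + 2L))])
    s <- stats::sd(bg)
    snr[i] <- if (is.na(s) || s == 0) Inf else peak / s
  }
  snr
}
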