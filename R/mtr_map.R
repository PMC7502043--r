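#' Voxel-wise MTR map
#'
#' `MTR = 100 * (1 - I_MT / I_REF)` in percent, computed where the
#' reference magnitude is above `floor` times its robust maximum (99th
#' percentile); elsewhere the map is invalid.  Values are clipped to
#' `[-100, 100]` and the number of clipped voxels recorded in provenance.
#'
#' @param vol_mt,vol_ref Co-registered volumes on the same grid (numeric or
#'   complex; magnitudes are used).
#' @param floor Validity floor as a fraction of the robust reference
#'   maximum; default 0.05.
#' @param voxel_size Voxel size (mm), length 3.
#' @return An `mtr_map`: list with `data` (percent, `NA` where invalid),
#'   `valid` (logical array), `voxel_size`, `provenance`.
#' @export
mtr_map <- function(vol_mt, vol_ref, floor = 0.05,
                    voxel_size = c(1, 1, 1)) {
  if (!all(dim(vol_mt) == dim(vol_ref)))
    stop("MT and REF volumes must share a grid")
  a_mt <- abs(vol_mt)
  a_ref <- abs(vol_ref)
  robmax <- as.numeric(quantile(a_ref, 0.99))
  valid <- a_ref > floor * robmax
  mtr <- array(NA_real_, dim(a_ref))
  mtr[valid] <- 100 * (1 - a_mt[valid] / a_ref[valid])
  n_clip <- sum(mtr < -100 | mtr > 100, na.rm = TRUE)
  mtr[!is.na(mtr)] <- pmin(pmax(mtr[!is.na(mtr)], -100), 100)
  structure(list(data = mtr, valid = valid,
                 voxel_size = as.numeric(voxel_size),
                 provenance = list(floor = floor, robust_max = robmax,
                                   n_clipped = n_clip)),
            class = "mtr_map")
}

#' @export
print.mtr_map <- function(x, ...) {
  cat(sprintf("<mtr_map> matrix %s, %.1f%% valid, median MTR %.1f%%\n",
              paste(dim(x$data), collapse = "x"),
              100 * mean(x$valid), median(x$data, na.rm = TRUE)))
  invisible(x)
}

#' @rdname mtr_map
#' @param object An `mtr_map`.
#' @param slice Slice index (third dimension) to draw; default middle.
#' @param ... Unused.
#' @export
autoplot.mtr_map <- function(object, slice = NULL, ...) {
  d <- dim(object$data)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$mtr <- as.vector(object$data[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$mtr)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20", name = "MTR (%)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("MTR map, slice %d", slice))
}

#' Per-slice Gaussian smoothing of an MTR map
#'
#' Applies a 2D truncated Gaussian filter to every short-axis slice
#' (default kernel 5 pixels, sigma 3 pixels).  The truncated kernel weights
#' are renormalized over the valid voxels contributing to each output
#' voxel, so invalid regions neither bleed in nor shrink the map.
#'
#' @param map An [mtr_map].
#' @param kernel Odd kernel size in pixels.
#' @param sigma Gaussian sigma in pixels.
#' @return The smoothed `mtr_map`.
#' @export
smooth_map <- function(map, kernel = 5, sigma = 3) {
  if (kernel %% 2 == 0) stop("kernel size must be odd")
  half <- (kernel - 1) / 2
  off <- -half:half
  w2 <- outer(exp(-off^2 / (2 * sigma^2)), exp(-off^2 / (2 * sigma^2)))
  w2 <- w2 / sum(w2)
  d <- dim(map$data)
  num <- array(0, d)
  den <- array(0, d)
  val <- ifelse(map$valid, map$data, 0)
  vmask <- map$valid * 1
  shift2d <- function(a, dx, dy) {
    out <- array(0, dim(a))
    xs <- seq_len(d[1]) - dx
    ys <- seq_len(d[2]) - dy
    okx <- xs >= 1 & xs <= d[1]
    oky <- ys >= 1 & ys <= d[2]
    out[okx, oky, ] <- a[xs[okx], ys[oky], , drop = FALSE]
    out
  }
  for (i in seq_along(off)) {
    for (j in seq_along(off)) {
      num <- num + w2[i, j] * shift2d(val, off[i], off[j])
      den <- den + w2[i, j] * shift2d(vmask, off[i], off[j])
    }
  }
  out <- map
  sm <- array(NA_real_, d)
  ok <- map$valid & den > 0
  sm[ok] <- num[ok] / den[ok]
  out$data <- sm
  out$provenance$smoothed <- c(kernel = kernel, sigma = sigma)
  out
}

#' Scar segmentation by remote-myocardium thresholding
#'
#' Computes the threshold `mean - 2 * SD` of the MTR over a remote
#' (healthy) myocardium region and selects as scar all valid myocardial
#' voxels with MTR strictly below it.
#'
#' @param map An [mtr_map].
#' @param myo Logical array: the full myocardium mask (m1).
#' @param remote Logical array: remote myocardium, subset of `myo`.
#' @return List with `scar` (logical array) and `threshold` (percent).
#' @export
scar_threshold_segmentation <- function(map, myo, remote) {
  stopifnot(all(dim(myo) == dim(map$data)),
            all(dim(remote) == dim(map$data)))
  if (!any(remote)) stop("remote ROI is empty")
  if (any(remote & !myo)) stop("remote ROI must lie within the myocardium mask")
  vals <- map$data[remote & map$valid]
  if (!length(vals)) stop("remote ROI contains no valid MTR voxels")
  thr <- mean(vals) - 2 * sd(vals)
  if (is.na(thr)) thr <- mean(vals)  # single-voxel remote
  scar <- map$valid & myo & !is.na(map$data) & map$data < thr
  list(scar = scar, threshold = thr)
}

#' Scar overlap with the LGE reference
#'
#' Percentage of LGE scar voxels also selected by the MTR segmentation:
#' `100 * |LGE_scar intersect MTR_scar| / |LGE_scar|`.
#'
#' @param scar_mtr,scar_lge Logical arrays on the same grid.
#' @return Overlap in percent.
#' @export
overlap_percent <- function(scar_mtr, scar_lge) {
  stopifnot(all(dim(scar_mtr) == dim(scar_lge)))
  if (!any(scar_lge)) stop("LGE scar mask is empty: overlap undefined")
  100 * sum(scar_lge & scar_mtr) / sum(scar_lge)
}

#' False-positive rate of the MTR scar segmentation
#'
#' Fraction of LGE remote (healthy) voxels wrongly selected as scar:
#' `100 * |LGE_remote intersect MTR_scar| / |LGE_remote|`.  With
#' `literal = TRUE` the complementary form `100 * (1 - ...)` is returned
#' instead.
#'
#' @param scar_mtr,remote_lge Logical arrays on the same grid.
#' @param literal Return the complementary form.
#' @return Percentage.
#' @export
false_positive_percent <- function(scar_mtr, remote_lge, literal = FALSE) {
  stopifnot(all(dim(scar_mtr) == dim(remote_lge)))
  if (!any(remote_lge)) stop("LGE remote mask is empty: rate undefined")
  frac <- sum(remote_lge & scar_mtr) / sum(remote_lge)
  if (literal) 100 * (1 - frac) else 100 * frac
}

#' In-plane binary erosion of a mask
#'
#' Erodes a 3-D mask with a 3x3 in-plane structuring element, repeated
#' `iterations` times.  Used to emulate a manually drawn region of
#' interest kept away from tissue boundaries.
#'
#' @param mask Logical 3-D array.
#' @param iterations Number of erosion passes.
#' @return The eroded logical array.
#' @export
erode_mask <- function(mask, iterations = 1) {
  d <- dim(mask)
  for (it in seq_len(iterations)) {
    out <- mask
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      shifted <- array(FALSE, d)
      xs <- seq_len(d[1]) - dx
      ys <- seq_len(d[2]) - dy
      okx <- xs >= 1 & xs <= d[1]
      oky <- ys >= 1 & ys <= d[2]
      shifted[okx, oky, ] <- mask[xs[okx], ys[oky], , drop = FALSE]
      out <- out & shifted
    }
    mask <- out
  }
  mask
}

#' Dice coefficient between two masks
#'
#' @param a,b Logical arrays on the same grid.
#' @return Dice similarity in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
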