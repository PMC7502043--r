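# Translation estimation by normalized cross-correlation.
#
# For global (circular) shifts the NCC denominator is shift-invariant, so
# the estimate reduces to the argmax of the circular cross-correlation of
# the zero-mean images, computed by FFT, refined to sub-pixel precision by
# a parabolic fit of the 3-point neighbourhood along each axis.

# shift s such that a(x) = b(x - s), circularly
xcorr_peak <- function(a, b) {
  a0 <- a - mean(a)
  b0 <- b - mean(b)
  if (sd(a0) == 0 || sd(b0) == 0)
    stop("cannot estimate a shift from a flat (zero-variance) image")
  cc <- Re(fft(fft(a0) * Conj(fft(b0)), inverse = TRUE)) / length(a0)
  d <- dim(cc)
  peak <- arrayInd(which.max(cc), d)
  shift <- numeric(length(d))
  for (ax in seq_along(d)) {
    m <- peak[ax]
    lo <- if (m == 1) d[ax] else m - 1
    hi <- if (m == d[ax]) 1 else m + 1
    at <- function(i) {
      p <- as.list(peak)
      p[[ax]] <- i
      do.call(`[`, c(list(cc), p))
    }
    y1 <- at(lo); y2 <- at(m); y3 <- at(hi)
    denom <- y1 - 2 * y2 + y3
    frac <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
    s <- (m - 1) + frac
    if (s > d[ax] / 2) s <- s - d[ax]  # wrap to signed shift
    shift[ax] <- s
  }
  shift
}

#' Estimate in-plane translation between two navigator images
#'
#' Returns the displacement `(d_LR, d_FH)` in mm of `inav` relative to
#' `reference_inav`, maximizing the normalized cross-correlation over
#' integer shifts and refined to sub-pixel precision by a parabolic fit of
#' the correlation peak's 3-point neighbourhood.
#'
#' @param inav,reference_inav 2-D images on the same grid.
#' @param pixel_size Pixel size (mm), length 2.
#' @return Named numeric vector `c(d_LR, d_FH)` in mm.
#' @export
estimate_translation <- function(inav, reference_inav, pixel_size = c(1, 1)) {
  stopifnot(all(dim(inav) == dim(reference_inav)))
  s <- xcorr_peak(inav, reference_inav)
  c(d_LR = s[1] * pixel_size[1], d_FH = s[2] * pixel_size[2])
}

# out(x) = vol(x - t), t in voxels (possibly fractional), circular
fourier_shift <- function(vol, shift_vox) {
  d <- dim(vol)
  k <- lapply(seq_along(d), function(ax) k_axis(d[ax], 1))
  ph <- outer(outer(k[[1]] * shift_vox[1],
                    if (length(d) >= 2) k[[2]] * shift_vox[2] else 0, `+`),
              if (length(d) >= 3) k[[3]] * shift_vox[3] else 0, `+`)
  dim(ph) <- d
  out <- ifft_c(fft_c(vol) * exp(-2i * pi * ph))
  if (is.complex(vol)) out else Re(out)
}

#' Co-register two volumes by 3D translation
#'
#' Estimates the 3D translation maximizing the normalized cross-correlation
#' between the magnitudes of two volumes (integer search plus parabolic
#' sub-voxel refinement) and applies it to the first volume by Fourier
#' shift.  Used to remove small residual misalignments between the
#' MT-prepared and reference reconstructions.  Deformable co-registration
#' is available through the `register_fn` plug-in, which must take
#' `(moving, fixed)` and return the aligned volume.
#'
#' @param vol_mt Moving volume (numeric or complex 3-D array).
#' @param vol_ref Fixed volume on the same grid.
#' @param voxel_size Voxel size (mm), length 3.
#' @param register_fn Optional plug-in replacing the rigid alignment.
#' @return List with `aligned` (shifted `vol_mt`), `shift_vox` (the
#'   displacement of `vol_mt` relative to `vol_ref`, voxels) and `shift_mm`.
#' @export
coregister_pair <- function(vol_mt, vol_ref, voxel_size = c(1, 1, 1),
                            register_fn = NULL) {
  stopifnot(all(dim(vol_mt) == dim(vol_ref)))
  if (!is.null(register_fn))
    return(list(aligned = register_fn(vol_mt, vol_ref),
                shift_vox = rep(NA_real_, 3), shift_mm = rep(NA_real_, 3)))
  s <- xcorr_peak(abs(vol_mt), abs(vol_ref))  # vol_mt(x) = vol_ref(x - s)
  list(aligned = fourier_shift(vol_mt, -s),
       shift_vox = s, shift_mm = s * voxel_size)
}
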