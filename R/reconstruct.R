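# Iterative SENSE and motion-compensated GMD reconstruction.
#
# Encoding model per coil c (and respiratory bin b for GMD):
#   y_{c,b} = M_b F S_c W_b x
# with W_b the trilinear warp taking the reference volume to bin b, S_c the
# coil sensitivity, F the centred orthonormal 3D FFT and M_b the sampling
# mask.  Both reconstructions solve the normal equations A x = E^H y by
# conjugate gradient, stopping at relative residual <= tol or max_iter.

cg_solve <- function(Aop, rhs, tol = 1e-6, max_iter = 30) {
  x <- array(0 + 0i, dim(rhs))
  r <- rhs
  p <- r
  rs <- sum(Mod(r)^2)
  rs0 <- rs
  hist <- numeric(0)
  energy <- numeric(0)  # quadratic objective, = ||Ex - k||^2 up to a constant
  it <- 0
  while (it < max_iter && sqrt(rs / rs0) > tol) {
    it <- it + 1
    Ap <- Aop(p)
    alpha <- rs / Re(sum(Conj(p) * Ap))
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(Mod(r)^2)
    hist <- c(hist, sqrt(rs_new / rs0))
    energy <- c(energy, -0.5 * Re(sum(Conj(x) * (rhs + r))))
    beta <- rs_new / rs
    p <- r + beta * p
    rs <- rs_new
  }
  list(x = x, iterations = it, residuals = hist, energy = energy)
}

recon_image <- function(data, voxel_size, method, iterations, residuals,
                        energy = numeric(0)) {
  structure(list(data = data, voxel_size = voxel_size, method = method,
                 iterations = iterations, residuals = residuals,
                 energy = energy),
            class = "recon_image")
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf("<recon_image> %s, matrix %s, %d CG iterations, final residual %.2e\n",
              x$method, paste(dim(x$data), collapse = "x"), x$iterations,
              if (length(x$residuals)) x$residuals[length(x$residuals)] else 0))
  invisible(x)
}

#' @rdname cg_sense
#' @param x A `recon_image`.
#' @param ... Unused.
#' @export
glance.recon_image <- function(x, ...) {
  tibble(method = x$method, iterations = x$iterations,
         final_residual = if (length(x$residuals))
           x$residuals[length(x$residuals)] else 0)
}

coil_check <- function(coils, dimv) {
  stopifnot(length(dim(coils)) == 4, all(dim(coils)[2:4] == dimv))
}

#' Iterative SENSE (CG-SENSE) reconstruction
#'
#' Conjugate-gradient solution of the SENSE normal equations for pooled
#' Cartesian data: coil weighting, centred orthonormal FFT, sampling mask.
#' Stops at relative residual `tol` (default 1e-6) or `max_iter` (30).
#'
#' @param kspace A [cartesian_kspace], or a pooled list as returned by
#'   [pool_kspace].
#' @param coils Complex coil sensitivities `(coil, nx, ny, nz)`.
#' @param beats Optional heartbeat subset to pool (e.g. one respiratory
#'   bin).
#' @param tol,max_iter CG stopping rule.
#' @return A `recon_image` with the complex volume and CG provenance.
#' @export
cg_sense <- function(kspace, coils, beats = NULL, tol = 1e-6,
                     max_iter = 30) {
  pooled <- if (inherits(kspace, "cartesian_kspace"))
    pool_kspace(kspace, beats) else kspace
  voxel <- if (inherits(kspace, "cartesian_kspace"))
    kspace$voxel_size else c(1, 1, 1)
  if (!any(pooled$mask)) stop("empty sampling mask")
  dimv <- dim(pooled$data)[2:4]
  coil_check(coils, dimv)
  nc <- dim(coils)[1]
  mask3 <- array(rep(pooled$mask, times = dimv[3]), dimv)
  Eh <- function(y) {  # y: (coil, nx, ny, nz)
    acc <- array(0 + 0i, dimv)
    for (cc in seq_len(nc)) {
      s <- array(coils[cc, , , ], dimv)
      acc <- acc + Conj(s) * ifft_c(array(y[cc, , , ], dimv) * mask3)
    }
    acc
  }
  Aop <- function(x) {
    acc <- array(0 + 0i, dimv)
    for (cc in seq_len(nc)) {
      s <- array(coils[cc, , , ], dimv)
      acc <- acc + Conj(s) * ifft_c(mask3 * fft_c(s * x))
    }
    acc
  }
  rhs <- Eh(pooled$data)
  sol <- cg_solve(Aop, rhs, tol, max_iter)
  recon_image(sol$x, voxel, "cg_sense", sol$iterations, sol$residuals,
              sol$energy)
}

#' Motion-compensated GMD reconstruction
#'
#' Generalized-matrix-description reconstruction: solves
#' `min_x sum_b || M_b F S W_b x - k_b ||^2` by conjugate gradient, where
#' `W_b` warps the reference-bin volume to respiratory bin `b` with the
#' bin's motion field (trilinear interpolation; the adjoint is the
#' transpose of the interpolation operator).
#'
#' @param kspace A [cartesian_kspace] (translationally corrected to each
#'   bin's centre).
#' @param bins A [assign_bins] result labelling every heartbeat.
#' @param fields Named list of motion fields, one `(nx, ny, nz, 3)` array
#'   (mm, pull-back convention) per bin; the reference bin's field must be
#'   identity (zero).
#' @param coils Complex coil sensitivities `(coil, nx, ny, nz)`.
#' @inheritParams cg_sense
#' @return A `recon_image`.
#' @export
gmd_reconstruct <- function(kspace, bins, fields, coils, tol = 1e-6,
                            max_iter = 30) {
  dimv <- dim(kspace$data)[3:5]
  coil_check(coils, dimv)
  nc <- dim(coils)[1]
  bin_ids <- sort(unique(bins$bin))
  if (!all(as.character(bin_ids) %in% names(fields)))
    stop("motion field missing for some bins")
  pooled <- lapply(bin_ids, function(b)
    pool_kspace(kspace, beats = bins$beat[bins$bin == b]))
  wis <- lapply(bin_ids, function(b)
    warp_indices(dimv, fields[[as.character(b)]], kspace$voxel_size))
  masks3 <- lapply(pooled, function(p)
    array(rep(p$mask, times = dimv[3]), dimv))
  Eh_all <- function() {
    acc <- array(0 + 0i, dimv)
    for (i in seq_along(bin_ids)) {
      binacc <- array(0 + 0i, dimv)
      for (cc in seq_len(nc)) {
        s <- array(coils[cc, , , ], dimv)
        binacc <- binacc +
          Conj(s) * ifft_c(array(pooled[[i]]$data[cc, , , ], dimv) *
                             masks3[[i]])
      }
      acc <- acc + apply_warp_adjoint(binacc, wis[[i]])
    }
    acc
  }
  Aop <- function(x) {
    acc <- array(0 + 0i, dimv)
    for (i in seq_along(bin_ids)) {
      xb <- apply_warp(x, wis[[i]])
      binacc <- array(0 + 0i, dimv)
      for (cc in seq_len(nc)) {
        s <- array(coils[cc, , , ], dimv)
        binacc <- binacc + Conj(s) * ifft_c(masks3[[i]] * fft_c(s * xb))
      }
      acc <- acc + apply_warp_adjoint(binacc, wis[[i]])
    }
    acc
  }
  sol <- cg_solve(Aop, Eh_all(), tol, max_iter)
  recon_image(sol$x, kspace$voxel_size, "gmd", sol$iterations,
              sol$residuals, sol$energy)
}
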