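# Trilinear warp operator and its exact transpose (splatting).
#
# A motion field is a 4-D array (nx, ny, nz, 3) of displacements in mm in
# the pull-back convention: the warped volume at voxel p samples the input
# at p + d(p)/voxel.  The adjoint scatters each output value back to the
# same eight neighbours with the same weights, which is the transpose of
# the interpolation matrix (not an inverse warp).

warp_indices <- function(dimv, field_mm, voxel_size) {
  n <- prod(dimv)
  gx <- rep(seq_len(dimv[1]), times = dimv[2] * dimv[3])
  gy <- rep(rep(seq_len(dimv[2]), each = dimv[1]), times = dimv[3])
  gz <- rep(seq_len(dimv[3]), each = dimv[1] * dimv[2])
  px <- gx + field_mm[, , , 1] / voxel_size[1]
  py <- gy + field_mm[, , , 2] / voxel_size[2]
  pz <- gz + field_mm[, , , 3] / voxel_size[3]
  x0 <- floor(px); y0 <- floor(py); z0 <- floor(pz)
  fx <- px - x0; fy <- py - y0; fz <- pz - z0
  idx <- vector("list", 8)
  wts <- vector("list", 8)
  corner <- 0L
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    corner <- corner + 1L
    cx <- x0 + dx; cy <- y0 + dy; cz <- z0 + dz
    w <- (if (dx == 1) fx else 1 - fx) *
         (if (dy == 1) fy else 1 - fy) *
         (if (dz == 1) fz else 1 - fz)
    inside <- cx >= 1 & cx <= dimv[1] & cy >= 1 & cy <= dimv[2] &
              cz >= 1 & cz <= dimv[3]
    lin <- ifelse(inside, cx + (cy - 1) * dimv[1] +
                    (cz - 1) * dimv[1] * dimv[2], 1L)
    idx[[corner]] <- as.integer(lin)
    wts[[corner]] <- as.numeric(w * inside)
  }
  list(idx = idx, wts = wts, n = n)
}

# forward warp (pull): out(p) = sum_c w_c(p) * vol(idx_c(p))
apply_warp <- function(vol, wi) {
  v <- as.vector(vol)
  out <- 0
  for (c in seq_len(8)) out <- out + wi$wts[[c]] * v[wi$idx[[c]]]
  array(out, dim(vol))
}

# transpose warp (push/splat): out(idx_c(p)) += w_c(p) * vol(p)
apply_warp_adjoint <- function(vol, wi) {
  v <- as.vector(vol)
  if (is.complex(v)) {
    re <- numeric(wi$n)
    im <- numeric(wi$n)
    for (c in seq_len(8)) {
      w <- wi$wts[[c]] * v
      re <- re + as.vector(tapply_sum(Re(w), wi$idx[[c]], wi$n))
      im <- im + as.vector(tapply_sum(Im(w), wi$idx[[c]], wi$n))
    }
    array(complex(real = re, imaginary = im), dim(vol))
  } else {
    out <- numeric(wi$n)
    for (c in seq_len(8))
      out <- out + tapply_sum(wi$wts[[c]] * v, wi$idx[[c]], wi$n)
    array(out, dim(vol))
  }
}

tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

# identity motion field for a grid
identity_field <- function(dimv) array(0, c(dimv, 3))

# uniform translation field (mm)
translation_field <- function(dimv, t_mm) {
  f <- array(0, c(dimv, 3))
  for (ax in 1:3) f[, , , ax] <- t_mm[ax]
  f
}
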