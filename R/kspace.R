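#' Per-heartbeat Cartesian k-space container
#'
#' Raw segmented Cartesian acquisition: complex samples indexed
#' `(coil, heartbeat, kx, ky, kz)` with the two phase-encode directions
#' `(kx, ky)` = (left-right, foot-head) and a fully sampled readout `kz`,
#' plus the per-heartbeat sampling mask over the phase-encode plane.
#'
#' @param data Complex 5-D array `(coil, beat, nx, ny, nz)`.
#' @param mask Logical 3-D array `(beat, nx, ny)`; `mask[b, , ]` marks the
#'   phase-encode points acquired in heartbeat `b`.
#' @param voxel_size Voxel size in mm, length 3.
#' @return A `cartesian_kspace` object.
#' @export
cartesian_kspace <- function(data, mask, voxel_size) {
  stopifnot(length(dim(data)) == 5, length(dim(mask)) == 3,
            dim(data)[2] == dim(mask)[1],
            all(dim(data)[3:4] == dim(mask)[2:3]),
            length(voxel_size) == 3)
  structure(list(data = data, mask = mask,
                 voxel_size = as.numeric(voxel_size)),
            class = "cartesian_kspace")
}

#' @export
print.cartesian_kspace <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<cartesian_kspace> %d coils, %d beats, matrix %d x %d x %d, voxel %s mm, %.1f%% sampled\n",
    d[1], d[2], d[3], d[4], d[5],
    paste(signif(x$voxel_size, 3), collapse = "x"),
    100 * sum(apply(x$mask, c(2, 3), any)) / prod(d[3:4])))
  invisible(x)
}

#' Beat-to-beat translational k-space correction
#'
#' Compensates a rigid in-plane displacement per heartbeat by the Fourier
#' shift theorem: `K_cor = K_acq * exp(2i pi k . d)` with `k` the
#' phase-encode trajectory in cycles/mm and `d = (d_LR, d_FH)` in mm.  The
#' readout dimension is untouched.  The sign convention moves the anatomy
#' back to the reference (end-expiration) position.
#'
#' @param kspace A [cartesian_kspace].
#' @param trace A data frame with columns `beat`, `d_LR`, `d_FH` (mm),
#'   covering every heartbeat that carries samples.
#' @return The corrected [cartesian_kspace].
#' @export
phase_shift_correct <- function(kspace, trace) {
  d <- dim(kspace$data)
  n_beats <- d[2]
  beats_with_data <- which(apply(kspace$mask, 1, any))
  if (!all(beats_with_data %in% trace$beat))
    stop("displacement trace missing entries for beats carrying samples")
  kx <- k_axis(d[3], kspace$voxel_size[1])
  ky <- k_axis(d[4], kspace$voxel_size[2])
  out <- kspace$data
  for (b in beats_with_data) {
    row <- match(b, trace$beat)
    ph <- exp(2i * pi * (outer(kx * trace$d_LR[row], ky * trace$d_FH[row],
                               `+`)))
    # broadcast over coil (dim 1) and readout (dim 5)
    for (cc in seq_len(d[1]))
      for (zz in seq_len(d[5]))
        out[cc, b, , , zz] <- out[cc, b, , , zz] * ph
  }
  kspace$data <- out
  kspace
}

#' Pool a set of heartbeats into a single-average k-space
#'
#' Averages duplicate samples and returns the combined k-space
#' `(coil, nx, ny, nz)` with its pooled sampling mask.  Used after
#' translational correction, before CG-SENSE.
#'
#' @param kspace A [cartesian_kspace].
#' @param beats Heartbeat indices to pool (default: all).
#' @return List with `data` (complex array `(coil, nx, ny, nz)`) and
#'   `mask` (logical `(nx, ny)`).
#' @export
pool_kspace <- function(kspace, beats = NULL) {
  d <- dim(kspace$data)
  if (is.null(beats)) beats <- seq_len(d[2])
  acc <- array(0 + 0i, d[c(1, 3, 4, 5)])
  cnt <- array(0, d[3:4])
  for (b in beats) {
    m <- array(kspace$mask[b, , , drop = FALSE], d[3:4])
    if (!any(m)) next
    cnt <- cnt + m
    mk <- array(rep(m, each = d[1]), c(d[1], d[3], d[4]))
    for (zz in seq_len(d[5])) {
      sl <- array(kspace$data[, b, , , zz, drop = FALSE],
                  c(d[1], d[3], d[4]))
      acc[, , , zz] <- array(acc[, , , zz, drop = FALSE],
                             c(d[1], d[3], d[4])) + mk * sl
    }
  }
  mask <- cnt > 0
  w <- ifelse(cnt > 0, 1 / pmax(cnt, 1), 0)
  wk <- array(rep(w, each = d[1]), c(d[1], d[3], d[4]))
  for (zz in seq_len(d[5]))
    acc[, , , zz] <- array(acc[, , , zz, drop = FALSE],
                           c(d[1], d[3], d[4])) * wk
  list(data = acc, mask = mask)
}
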