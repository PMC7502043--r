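# Synthetic acquisition: spiral-profile Cartesian ordering, analytic coil
# maps, respiratory motion model, and the full k-space simulation.

#' Spiral-profile Cartesian phase-encode ordering
#'
#' Orders the phase-encode points of the `(kx, ky)` plane centre-out along
#' an Archimedean spiral and deals consecutive runs of `profiles_per_beat`
#' points to successive heartbeats, rotating the within-beat angular start
#' by the golden angle per beat.  In full-sampling mode the beats partition
#' the grid exactly and the DC point is acquired in the first beat.  The
#' seed fixes the first-beat rotation, so masks are reproducible.
#'
#' @param matrix_size Phase-encode matrix `c(nx, ny)`.
#' @param profiles_per_beat Points acquired per heartbeat (default 30).
#' @param n_beats Number of heartbeats; full sampling requires
#'   `profiles_per_beat * n_beats >= nx * ny` and oversubscription beyond
#'   one pass is an error.
#' @param seed Integer seed for the initial spiral rotation.
#' @return Logical array `(beat, nx, ny)` of per-beat sampling masks.
#' @export
spiral_profile_ordering <- function(matrix_size, profiles_per_beat = 30,
                                    n_beats, seed = 1234) {
  nx <- matrix_size[1]; ny <- matrix_size[2]
  npts <- nx * ny
  if (profiles_per_beat * n_beats < npts)
    stop("not enough beats to cover the grid in full-sampling mode")
  if ((n_beats - 1) * profiles_per_beat >= npts)
    stop("oversubscription: more beats than needed for one full pass")
  cx <- floor(nx / 2) + 1; cy <- floor(ny / 2) + 1
  gx <- rep(seq_len(nx), times = ny)
  gy <- rep(seq_len(ny), each = nx)
  r <- sqrt((gx - cx)^2 + (gy - cy)^2)
  golden <- pi * (3 - sqrt(5))
  set.seed(seed)
  theta0 <- stats::runif(1, 0, 2 * pi)
  theta <- (atan2(gy - cy, gx - cx) - theta0) %% (2 * pi)
  ord <- order(r, theta)  # centre-out spiral-like global order, rotated
  masks <- array(FALSE, c(n_beats, nx, ny))
  for (b in seq_len(n_beats)) {
    lo <- (b - 1) * profiles_per_beat + 1
    hi <- min(b * profiles_per_beat, npts)
    if (lo > hi) break
    chunk <- ord[lo:hi]
    ang <- (theta[chunk] - theta0 - (b - 1) * golden) %% (2 * pi)
    chunk <- chunk[order(ang, r[chunk])]
    m <- masks[b, , ]
    m[chunk] <- TRUE
    masks[b, , ] <- m
  }
  masks
}

#' Analytic coil sensitivity maps
#'
#' Gaussian-magnitude, linear-phase coil sensitivities placed around the
#' volume, normalized so the per-voxel sum of squares is at most 1.
#'
#' @param dimv Matrix size, length 3.
#' @param n_coils Number of coils.
#' @return Complex array `(coil, nx, ny, nz)`.
#' @export
make_coil_maps <- function(dimv, n_coils = 8) {
  if (n_coils == 1)
    return(array(1 + 0i, c(1, dimv)))
  ang <- 2 * pi * (seq_len(n_coils) - 1) / n_coils
  ccx <- (dimv[1] + 1) / 2 + 0.6 * dimv[1] * cos(ang) / 2
  ccy <- (dimv[2] + 1) / 2 + 0.6 * dimv[2] * sin(ang) / 2
  gx <- rep(seq_len(dimv[1]), times = dimv[2] * dimv[3])
  gy <- rep(rep(seq_len(dimv[2]), each = dimv[1]), times = dimv[3])
  w <- 0.7 * max(dimv[1:2])
  maps <- array(0 + 0i, c(n_coils, dimv))
  for (cc in seq_len(n_coils)) {
    mag <- exp(-((gx - ccx[cc])^2 + (gy - ccy[cc])^2) / (2 * w^2))
    ph <- 0.1 * (gx - ccx[cc]) / dimv[1] + 0.07 * (gy - ccy[cc]) / dimv[2]
    maps[cc, , , ] <- array(complex(modulus = mag, argument = ph), dimv)
  }
  sos <- array(0, dimv)
  for (cc in seq_len(n_coils)) sos <- sos + Mod(maps[cc, , , ])^2
  scale <- sqrt(max(sos))
  maps / scale
}

#' Respiratory motion model
#'
#' Smooth pseudo-periodic breathing: foot-head and left-right translation
#' `amplitude * sin(pi * t / period)^2` plus a linear drift, and an
#' optional non-rigid component in which the translation is modulated by a
#' smooth spatial envelope (stronger motion towards the diaphragm), keeping
#' the deformation Jacobian positive for realistic amplitudes.
#'
#' @param period Breathing period (seconds), default 4.
#' @param amplitude_FH,amplitude_LR Peak displacement (mm), defaults 8 and
#'   2.
#' @param drift Slow drift (mm/min), default 0.
#' @param nonrigid_amplitude Amplitude of the spatially varying component
#'   (mm), default 0 (purely rigid).
#' @param nonrigid_scale Spatial scale of the envelope (mm), default 60.
#' @return A `motion_model` list.
#' @export
motion_model <- function(period = 4, amplitude_FH = 8, amplitude_LR = 2,
                         drift = 0, nonrigid_amplitude = 0,
                         nonrigid_scale = 60) {
  stopifnot(period > 0, amplitude_FH >= 0, amplitude_LR >= 0,
            nonrigid_amplitude >= 0, nonrigid_scale > 0)
  structure(list(period = period, amplitude_FH = amplitude_FH,
                 amplitude_LR = amplitude_LR, drift = drift,
                 nonrigid_amplitude = nonrigid_amplitude,
                 nonrigid_scale = nonrigid_scale),
            class = "motion_model")
}

# rigid displacement (mm) at time t (s)
motion_displacement <- function(motion, t) {
  s <- sin(pi * t / motion$period)^2
  c(d_LR = motion$amplitude_LR * s + motion$drift * t / 60 * 0.25,
    d_FH = motion$amplitude_FH * s + motion$drift * t / 60)
}

# Spatial envelope of the motion, 1 at the (heart-centred) grid centre and
# decaying with in-plane distance; the navigator trace therefore reports
# the heart's displacement exactly while the periphery moves less.
nonrigid_envelope <- function(dimv, voxel_size, scale_mm) {
  gx <- rep(seq_len(dimv[1]), times = dimv[2] * dimv[3])
  gy <- rep(rep(seq_len(dimv[2]), each = dimv[1]), times = dimv[3])
  dx <- (gx - (dimv[1] + 1) / 2) * voxel_size[1]
  dy <- (gy - (dimv[2] + 1) / 2) * voxel_size[2]
  array(exp(-(dx^2 + dy^2) / scale_mm^2), dimv)
}

# fraction of the motion that is spatially varying, in [0, 1]
nonrigid_kappa <- function(motion) {
  min(1, motion$nonrigid_amplitude / max(motion$amplitude_FH, 1e-9))
}

# dense pull-back acquisition field (mm) for rigid displacement d (mm):
# displacement at p is d * (1 - kappa * (1 - env(p)))
motion_field <- function(motion, dimv, voxel_size, d) {
  f <- array(0, c(dimv, 3))
  kap <- nonrigid_kappa(motion)
  scale <- if (kap > 0)
    1 - kap * (1 - nonrigid_envelope(dimv, voxel_size,
                                     motion$nonrigid_scale))
  else 1
  f[, , , 1] <- -d[1] * scale
  f[, , , 2] <- -d[2] * scale
  f
}


#' Acquisition specification
#'
#' @param profiles_per_beat Phase-encode profiles per heartbeat (30).
#' @param ordering `"spiral"` (spiral-profile Cartesian, full sampling) —
#'   the only mode currently generated.
#' @param n_coils Number of analytic coils.
#' @param noise_sd Complex Gaussian noise SD per k-space sample, in units
#'   of the image signal (orthonormal FFT), so the image-domain noise SD
#'   matches.
#' @param seed Seed for ordering and noise.
#' @return An `acquisition_spec` list.
#' @export
acquisition_spec <- function(profiles_per_beat = 30, ordering = "spiral",
                             n_coils = 4, noise_sd = 0, seed = 1234) {
  structure(list(profiles_per_beat = as.integer(profiles_per_beat),
                 ordering = ordering, n_coils = as.integer(n_coils),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "acquisition_spec")
}

#' Simulate a segmented Cartesian acquisition of a phantom
#'
#' Per heartbeat: the per-voxel signal is evaluated with the two-pool
#' simulator at each voxel's tissue parameters (cached over the phantom's
#' unique parameter sets), the signal volume is warped by the motion model
#' at that beat, multiplied by analytic coil maps, Fourier transformed, and
#' sampled on that beat's spiral-profile mask; complex Gaussian noise is
#' added to the acquired samples.  The exact displacement trace and dense
#' per-beat motion fields are emitted as ground truth.
#'
#' @param phantom A `digital_phantom`.
#' @param acq An [acquisition_spec].
#' @param prep An [mt_preparation] or `NULL` (REF acquisition).
#' @param imaging An [imaging_module].
#' @param protocol A [sim_protocol]; its heart rate also spaces the beats
#'   in time for the motion model.
#' @param motion A [motion_model], or `NULL` for a static acquisition.
#' @param noise_seed Seed for the measurement noise (defaults to
#'   `acq$seed + 1`), separate from the ordering seed so paired MT/REF
#'   acquisitions can share a trajectory with independent noise.
#' @return List: `kspace` ([cartesian_kspace]), `trace` (tibble of
#'   per-beat displacements, mm), `fields` (function
#'   `(beat, reference_d) -> dense pull-back motion field` of that beat's
#'   anatomy relative to the reference displacement — ground truth for
#'   [gmd_reconstruct] after the data are rigidly corrected to their bin
#'   centres), `coils`, `signal_volume` (the static, motion-free signal),
#'   `inavs` (low-resolution projection images, one per beat).
#' @export
simulate_acquisition <- function(phantom, acq, prep, imaging, protocol,
                                 motion = NULL, noise_seed = NULL) {
  dimv <- dim(phantom$labels)
  rr <- 60 / protocol$heart_rate
  # per-label signal via the Bloch core
  ids <- sort(unique(as.vector(phantom$labels)))
  ids <- ids[ids > 0]
  sig <- numeric(max(ids))
  for (id in ids)
    sig[id] <- simulate_sequence(phantom$tissues[[id]], prep, imaging,
                                 protocol) * phantom$rho[[id]]
  vol <- array(0, dimv)
  for (id in ids) vol[phantom$labels == id] <- sig[id]

  n_beats <- as.integer(ceiling(dimv[1] * dimv[2] / acq$profiles_per_beat))
  masks <- spiral_profile_ordering(dimv[1:2], acq$profiles_per_beat,
                                   n_beats, acq$seed)
  coils <- make_coil_maps(dimv, acq$n_coils)
  data <- array(0 + 0i, c(acq$n_coils, n_beats, dimv))
  trace <- tibble(beat = seq_len(n_beats), d_LR = 0, d_FH = 0)
  inavs <- vector("list", n_beats)
  set.seed(if (is.null(noise_seed)) acq$seed + 1L else as.integer(noise_seed))
  for (b in seq_len(n_beats)) {
    d <- c(0, 0)
    vol_b <- vol
    if (!is.null(motion)) {
      d <- motion_displacement(motion, (b - 1) * rr)
      if (nonrigid_kappa(motion) > 0) {
        f <- motion_field(motion, dimv, phantom$voxel_size, d)
        vol_b <- apply_warp(vol, warp_indices(dimv, f, phantom$voxel_size))
      } else {
        vol_b <- fourier_shift(vol, c(d[1] / phantom$voxel_size[1],
                                      d[2] / phantom$voxel_size[2], 0))
      }
      trace$d_LR[b] <- d[1]
      trace$d_FH[b] <- d[2]
    }
    inavs[[b]] <- apply(vol_b, c(1, 2), sum)
    m <- masks[b, , ]
    nm <- sum(m)
    for (cc in seq_len(acq$n_coils)) {
      k <- fft_c(array(coils[cc, , , ], dimv) * vol_b)
      for (zz in seq_len(dimv[3])) {
        kz <- k[, , zz]
        kz[!m] <- 0 + 0i
        if (acq$noise_sd > 0 && nm > 0)
          kz[m] <- kz[m] + complex(real = rnorm(nm, 0, acq$noise_sd /
                                                  sqrt(2)),
                                   imaginary = rnorm(nm, 0, acq$noise_sd /
                                                       sqrt(2)))
        data[cc, b, , , zz] <- kz
      }
    }
  }
  fields_fn <- function(beat, reference_d = c(0, 0)) {
    if (is.null(motion)) return(identity_field(dimv))
    d <- motion_displacement(motion, (beat - 1) * rr) - reference_d
    motion_field(motion, dimv, phantom$voxel_size, d)
  }
  list(kspace = cartesian_kspace(data, masks, phantom$voxel_size),
       trace = trace, fields = fields_fn, coils = coils,
       signal_volume = vol, inavs = inavs)
}
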