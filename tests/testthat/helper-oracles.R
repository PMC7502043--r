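# Independent oracles and small shared fixtures.

# brute-force midpoint Riemann sum for the super-Lorentzian lineshape
G_brute <- function(delta_f, T2_bound, n = 1e6) {
  th <- (seq_len(n) - 0.5) * (pi / 2) / n
  u <- 3 * cos(th)^2 - 1
  sum(sin(th) * sqrt(2 / pi) * (T2_bound / abs(u)) *
        exp(-2 * (2 * pi * delta_f * T2_bound / u)^2)) * (pi / 2) / n
}

# dense-step forward-Euler integration of the two-pool system, written
# directly from the coupled ODEs (independent of the package's
# matrix-exponential path); G is supplied by the caller (use G_brute)
euler_propagate <- function(M, tissue, omega1, delta_f, b0, dt, nsub,
                            G = NULL) {
  if (is.null(G))
    G <- if (Mod(omega1) > 0) G_brute(delta_f + b0, tissue$T2_bound) else 0
  h <- dt / nsub
  M0A <- 1 - tissue$psr
  M0B <- tissue$psr
  RA <- 1 / tissue$T1_free
  RB <- 1 / tissue$T1_bound
  R <- tissue$exchange_rate
  w <- 2 * pi * (delta_f + b0)
  rrfb <- pi * Mod(omega1)^2 * G
  wx <- Re(omega1)
  wy <- Im(omega1)
  for (i in seq_len(nsub)) {
    d1 <- -w * M[2] - M[1] / tissue$T2_free - wy * M[3]
    d2 <- w * M[1] - M[2] / tissue$T2_free + wx * M[3]
    d3 <- wy * M[1] - wx * M[2] + RA * (M0A - M[3]) - R * M0B * M[3] +
      R * M0A * M[4]
    d4 <- RB * (M0B - M[4]) - (rrfb + R * M0A) * M[4] + R * M0B * M[3]
    M <- M + h * c(d1, d2, d3, d4)
  }
  M
}

# fast protocols for unit tests (fewer pulses/profiles than the study
# protocol; the acceptance tests use the full settings)
quick_prep <- function(delta_f = 3000, mt_flip = 800, n_pulses = 5) {
  mt_preparation(make_sinc_pulse(mt_flip, 20.48e-3, 270,
                                 offset = delta_f),
                 n_pulses = n_pulses)
}

quick_spgr <- function() spgr_module(profiles_per_beat = 10)
quick_bssfp <- function() bssfp_module(profiles_per_beat = 10)
quick_protocol <- function(b0 = 0)
  sim_protocol(n_heartbeats = 3, measure_beat = 3, b0_offset = b0)

# single fully sampled single-beat k-space object from a volume
full_kspace <- function(vol, voxel_size = c(1, 1, 1), n_coils = 1,
                        coils = NULL) {
  dimv <- dim(vol)
  if (is.null(coils)) coils <- array(1 + 0i, c(n_coils, dimv))
  data <- array(0 + 0i, c(n_coils, 1, dimv))
  for (cc in seq_len(n_coils))
    data[cc, 1, , , ] <- fft_c_test(array(coils[cc, , , ], dimv) * vol)
  list(kspace = cartesian_kspace(data, array(TRUE, c(1, dimv[1], dimv[2])),
                                 voxel_size),
       coils = coils)
}

# local copy of the centred orthonormal FFT for fixture construction
fft_c_test <- function(x) {
  sh <- function(a, inv) {
    d <- dim(a)
    idx <- lapply(d, function(n) {
      h <- if (inv) ceiling(n / 2) else floor(n / 2)
      c((h + 1):n, seq_len(h))
    })
    do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  sh(fft(sh(x, TRUE)), FALSE) / sqrt(length(x))
}

rmse_to <- function(a, b) sqrt(mean((abs(a) - abs(b))^2))

# translational-only and ground-truth-field GMD reconstructions of a
# simulated moving acquisition (bin-centre rigid correction, per-bin
# ground-truth fields from the generator)
moco_pair <- function(sim, n_bins = 4) {
  rec_tr <- cg_sense(phase_shift_correct(sim$kspace, sim$trace),
                     sim$coils)
  bins <- assign_bins(sim$trace, n_bins)
  ref_bin <- attr(bins, "reference")
  centre_of <- function(b) {
    idx <- match(bins$beat[bins$bin == b], sim$trace$beat)
    c(median(sim$trace$d_LR[idx]), median(sim$trace$d_FH[idx]))
  }
  centres <- lapply(stats::setNames(nm = sort(unique(bins$bin))),
                    centre_of)
  tr <- sim$trace
  for (i in seq_len(nrow(tr))) {
    cb <- centres[[as.character(bins$bin[match(tr$beat[i], bins$beat)])]]
    tr$d_LR[i] <- tr$d_LR[i] - cb[1]
    tr$d_FH[i] <- tr$d_FH[i] - cb[2]
  }
  ks_bin <- phase_shift_correct(sim$kspace, tr)
  d_ref <- centres[[as.character(ref_bin)]]
  fields <- lapply(stats::setNames(nm = names(centres)), function(b) {
    members <- bins$beat[bins$bin == as.integer(b)]
    idx <- match(members, sim$trace$beat)
    near <- members[which.min(abs(sim$trace$d_FH[idx] -
                                    centres[[b]][2]))]
    sim$fields(near, reference_d = d_ref)
  })
  rec_gmd <- gmd_reconstruct(ks_bin, bins, fields, sim$coils)
  list(translational = rec_tr, gmd = rec_gmd)
}
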