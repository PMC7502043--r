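make_smooth_image <- function(n = 32) {
  g <- expand.grid(x = seq_len(n), y = seq_len(n))
  img <- matrix(exp(-((g$x - 13)^2 + (g$y - 19)^2) / 30) +
                  0.5 * exp(-((g$x - 22)^2 + (g$y - 9)^2) / 50), n, n)
  img
}

test_that("translation estimation recovers constructed shifts", {
  img <- make_smooth_image()
  expect_equal(unname(estimate_translation(img, img)), c(0, 0))
  sh <- img[c((32 - 2):32, 1:(32 - 3)), c(3:32, 1:2)]  # shift (3, -2)
  est <- estimate_translation(sh, img)
  expect_equal(unname(est), c(3, -2), tolerance = 0.1)
  # sub-pixel shift via Fourier phase ramp
  k <- fft(img)
  kx <- c(0:15, -16:-1) / 32
  ph <- exp(-2i * pi * outer(kx * 0.4, kx * 0, `+`))
  sub <- Re(fft(k * ph, inverse = TRUE)) / length(img)
  est2 <- estimate_translation(sub, img)
  expect_equal(unname(est2[1]), 0.4, tolerance = 0.15)
  expect_error(estimate_translation(matrix(1, 8, 8), matrix(1, 8, 8)),
               "flat")
})

test_that("k-space phase correction is exact and reversible", {
  set.seed(3)
  vol <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  fk <- full_kspace(vol)
  tr0 <- tibble::tibble(beat = 1, d_LR = 0, d_FH = 0)
  expect_identical(phase_shift_correct(fk$kspace, tr0)$data,
                   fk$kspace$data)
  tr <- tibble::tibble(beat = 1, d_LR = 2.3, d_FH = -1.1)
  tr_inv <- tibble::tibble(beat = 1, d_LR = -2.3, d_FH = 1.1)
  round_trip <- phase_shift_correct(phase_shift_correct(fk$kspace, tr),
                                    tr_inv)
  expect_lt(max(abs(round_trip$data - fk$kspace$data)), 1e-12)
  expect_error(phase_shift_correct(fk$kspace,
                                   tibble::tibble(beat = 2, d_LR = 0,
                                                  d_FH = 0)),
               "missing")
})

test_that("whole-voxel correction undoes a whole-voxel object shift", {
  set.seed(4)
  vol <- array(0, c(16, 16, 4))
  vol[5:12, 6:11, 2:3] <- 1
  shifted <- vol[c(14:16, 1:13), , ]  # anatomy moved by +3 voxels in x
  fk <- full_kspace(shifted)
  cor <- phase_shift_correct(fk$kspace,
                             tibble::tibble(beat = 1, d_LR = 3, d_FH = 0))
  rec <- cg_sense(cor, array(1 + 0i, c(1, 16, 16, 4)))
  expect_lt(max(abs(abs(rec$data) - vol)), 1e-10)
})

test_that("Eq-1 correction commutes with coil weighting", {
  set.seed(5)
  dimv <- c(12, 12, 2)
  data <- array(complex(real = rnorm(2 * prod(dimv)),
                        imaginary = rnorm(2 * prod(dimv))),
                c(2, 1, dimv))
  ks <- cartesian_kspace(data, array(TRUE, c(1, 12, 12)), c(1, 1, 1))
  tr <- tibble::tibble(beat = 1, d_LR = 1.7, d_FH = -0.4)
  whole <- phase_shift_correct(ks, tr)
  for (cc in 1:2) {
    single <- cartesian_kspace(data[cc, , , , , drop = FALSE],
                               ks$mask, c(1, 1, 1))
    expect_lt(max(abs(phase_shift_correct(single, tr)$data[1, , , , ] -
                        whole$data[cc, , , , ])), 1e-10)
  }
})

test_that("respiratory binning partitions beats with bounded bin width", {
  const <- tibble::tibble(beat = 1:20, d_LR = 0, d_FH = 2)
  b <- assign_bins(const, 3)
  expect_equal(length(unique(b$bin)), 1)
  expect_equal(unname(attr(b, "widths")), 0)
  unif <- tibble::tibble(beat = 1:60, d_LR = 0,
                         d_FH = seq(0, 10, length.out = 60))
  b2 <- assign_bins(unif, 3, max_width = 3.5)
  expect_true(all(attr(b2, "widths") <= 3.5))
  expect_setequal(b2$beat, unif$beat)
  expect_true(all(table(b2$beat) == 1))  # exactly one label per beat
  # reference bin is end-expiration (smallest displacement)
  expect_equal(unname(attr(b2, "reference")),
               as.integer(names(which.min(attr(b2, "centres")))))
  expect_error(assign_bins(unif, 2), "between 3 and 5")
})

test_that("CG-SENSE inverts the identity encoding and reduces residuals", {
  set.seed(6)
  vol <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  fk <- full_kspace(vol)
  rec <- cg_sense(fk$kspace, fk$coils)
  expect_lt(max(abs(rec$data - vol)), 1e-8)
  # undersampled multi-coil problem: energy is monotone non-increasing
  dimv <- c(24, 24, 4)
  obj <- array(0, dimv)
  obj[6:18, 8:20, 2:3] <- 2
  obj[10:14, 11:16, 2] <- 5
  coils <- make_coil_maps(dimv, 8)
  data <- array(0 + 0i, c(8, 1, dimv))
  for (cc in 1:8)
    data[cc, 1, , , ] <- fft_c_test(array(coils[cc, , , ], dimv) * obj)
  mask <- array(FALSE, c(1, dimv[1], dimv[2]))
  mask[1, seq(1, dimv[1], by = 2), ] <- TRUE  # 2x uniform undersampling
  ks <- cartesian_kspace(data, mask, c(1, 1, 1))
  rec2 <- cg_sense(ks, coils, max_iter = 30)
  expect_true(all(diff(rec2$energy) <= 1e-8))
  nrmse <- sqrt(mean((abs(rec2$data) - obj)^2)) / diff(range(obj))
  expect_lt(nrmse, 0.05)
  expect_error(cg_sense(cartesian_kspace(data * 0,
                                         array(FALSE, c(1, dimv[1:2])),
                                         c(1, 1, 1)), coils),
               "empty")
})

test_that("GMD with identity fields degenerates to pooled CG-SENSE", {
  set.seed(7)
  dimv <- c(16, 16, 4)
  vol <- array(rnorm(prod(dimv)), dimv)
  fk <- full_kspace(vol, n_coils = 2,
                    coils = make_coil_maps(dimv, 2))
  trace <- tibble::tibble(beat = 1, d_LR = 0, d_FH = 0)
  bins <- assign_bins(tibble::tibble(beat = 1, d_LR = 0, d_FH = 0), 3)
  fields <- list(`1` = array(0, c(dimv, 3)))
  g <- gmd_reconstruct(fk$kspace, bins, fields, fk$coils)
  s <- cg_sense(fk$kspace, fk$coils)
  expect_lt(max(abs(g$data - s$data)), 1e-6)
  expect_true(all(diff(g$energy) <= 1e-8))
  expect_error(gmd_reconstruct(fk$kspace, bins, list(), fk$coils),
               "missing")
})

test_that("ground-truth GMD beats translational-only recon under non-rigid motion", {
  ph <- make_cardiac_phantom(grid = c(32, 32, 8))
  pro <- sim_protocol()
  acq <- acquisition_spec(n_coils = 2, noise_sd = 0, seed = 21)
  mot <- motion_model(amplitude_FH = 8, amplitude_LR = 2,
                      nonrigid_amplitude = 6, nonrigid_scale = 40)
  sim <- simulate_acquisition(ph, acq, NULL, spgr_module(), pro, mot)
  recs <- moco_pair(sim)
  err_tr <- rmse_to(recs$translational$data, sim$signal_volume)
  err_gmd <- rmse_to(recs$gmd$data, sim$signal_volume)
  expect_lt(err_gmd, err_tr)
  # vessel sharpness improves with the motion-field reconstruction
  vs_tr <- vessel_sharpness(abs(recs$translational$data),
                            ph$centerlines$vein_1,
                            voxel_size = ph$voxel_size)
  vs_gmd <- vessel_sharpness(abs(recs$gmd$data), ph$centerlines$vein_1,
                             voxel_size = ph$voxel_size)
  expect_gt(vs_gmd, vs_tr)
})

test_that("binned reconstructions of a static phantom agree across bins", {
  set.seed(9)
  dimv <- c(16, 16, 4)
  vol <- array(0, dimv)
  vol[5:12, 5:12, 2:3] <- 1.5
  fk <- full_kspace(vol)
  # three identical fully sampled passes, one per bin
  data <- array(0 + 0i, c(1, 3, dimv))
  for (b in 1:3) data[1, b, , , ] <- fk$kspace$data[1, 1, , , ]
  ks <- cartesian_kspace(data, array(TRUE, c(3, dimv[1], dimv[2])),
                         c(1, 1, 1))
  recs <- lapply(1:3, function(b) cg_sense(ks, fk$coils, beats = b))
  expect_lt(max(abs(recs[[1]]$data - recs[[2]]$data)), 1e-6)
  expect_lt(max(abs(recs[[2]]$data - recs[[3]]$data)), 1e-6)
})

test_that("3D co-registration recovers translations and is inverse-consistent", {
  set.seed(10)
  dimv <- c(24, 24, 8)
  vol <- array(0, dimv)
  vol[8:16, 9:15, 3:6] <- outer(outer(sin(1:9), cos(1:7)), rep(1, 4)) + 2
  moved <- mtprep:::fourier_shift(vol, c(1.5, 0, -2))
  reg <- coregister_pair(moved, vol)
  expect_equal(reg$shift_vox, c(1.5, 0, -2), tolerance = 0.2)
  expect_lt(rmse_to(reg$aligned, vol), 0.05 * max(vol))
  reg_back <- coregister_pair(vol, moved)
  expect_equal(reg_back$shift_vox, -reg$shift_vox, tolerance = 0.2)
  expect_error(coregister_pair(array(1, dimv), vol), "flat")
  # plug-in hook replaces the rigid step
  reg_plug <- coregister_pair(moved, vol,
                              register_fn = function(m, f) f)
  expect_identical(reg_plug$aligned, vol)
})
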