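test_that("MTR map arithmetic, validity floor and clipping", {
  ref <- array(1, c(8, 8, 2))
  expect_true(all(mtr_map(ref, ref)$data == 0))
  expect_true(all(abs(mtr_map(0.6 * ref, ref)$data - 40) < 1e-12))
  # constructed low-signal voxels fall outside the validity mask
  ref2 <- ref
  ref2[1:3, 1, 1] <- 0.01
  m <- mtr_map(0.5 * ref2, ref2, floor = 0.05)
  expect_equal(sum(!m$valid), 3)
  expect_true(all(is.na(m$data[!m$valid])))
  # clipping is applied and counted
  mt <- ref
  mt[1, 1, 1] <- 5
  m2 <- mtr_map(mt, ref)
  expect_equal(min(m2$data), -100)
  expect_equal(m2$provenance$n_clipped, 1)
  expect_error(mtr_map(array(1, c(4, 4, 1)), ref), "grid")
})

test_that("Gaussian smoothing preserves constants and matches the kernel oracle", {
  const <- mtr_map(0.5 * array(1, c(16, 16, 2)), array(1, c(16, 16, 2)))
  expect_equal(smooth_map(const)$data, const$data, tolerance = 1e-12)
  # impulse response equals the truncated, renormalized kernel computed by
  # direct summation
  ref <- array(1, c(17, 17, 1))
  mt <- ref
  mt[9, 9, 1] <- 0  # MTR impulse of 100 at the centre
  m <- mtr_map(mt, ref)
  sm <- smooth_map(m, kernel = 5, sigma = 3)
  off <- -2:2
  w <- outer(exp(-off^2 / 18), exp(-off^2 / 18))
  w <- w / sum(w)
  expect_equal(sm$data[9, 9, 1], 100 * w[3, 3], tolerance = 1e-10)
  expect_equal(sm$data[9, 11, 1], 100 * w[3, 5], tolerance = 1e-10)
  expect_error(smooth_map(m, kernel = 4), "odd")
})

test_that("mean-minus-2-sigma thresholding selects the scar tail", {
  # homogeneous Gaussian map: the one-sided 2-sigma tail is ~2.3% of myo
  set.seed(123)
  d <- c(50, 50, 40)  # 1e5 voxels
  ref <- array(1, d)
  mtr_true <- 30
  noise <- array(rnorm(prod(d), 0, 2), d)
  mt <- (1 - (mtr_true + noise) / 100) * ref
  m <- mtr_map(mt, ref)
  myo <- array(TRUE, d)
  seg <- scar_threshold_segmentation(m, myo, myo)
  frac <- sum(seg$scar) / prod(d)
  expect_equal(frac, stats::pnorm(-2), tolerance = 3 * sqrt(0.023 / prod(d)) /
                 0.023)
  # a sector 8 points below with remote SD 1.9 is selected in full
  d2 <- c(40, 40, 4)
  ref2 <- array(1, d2)
  set.seed(124)
  base <- 25.1 + array(rnorm(prod(d2), 0, 1.9), d2)
  sector <- array(FALSE, d2)
  sector[1:10, , ] <- TRUE
  vals <- base
  vals[sector] <- vals[sector] - 8
  # keep remote statistics exact: threshold from the unshifted region
  mt2 <- (1 - vals / 100) * ref2
  m2 <- mtr_map(mt2, ref2)
  seg2 <- scar_threshold_segmentation(m2, array(TRUE, d2), !sector)
  expect_gte(sum(seg2$scar & sector) / sum(sector), 0.95)
  # zero-variance remote and uniform map give an empty scar
  u <- mtr_map(0.7 * ref2, ref2)
  seg3 <- scar_threshold_segmentation(u, array(TRUE, d2), array(TRUE, d2))
  expect_equal(sum(seg3$scar), 0)
  expect_error(scar_threshold_segmentation(u, array(TRUE, d2),
                                           array(FALSE, d2)), "empty")
})

test_that("thresholding is invariant to adding a constant to the map", {
  set.seed(17)
  d <- c(20, 20, 2)
  ref <- array(1, d)
  vals <- 30 + array(rnorm(prod(d), 0, 3), d)
  myo <- array(TRUE, d)
  remote <- array(FALSE, d)
  remote[5:15, 5:15, ] <- TRUE
  seg_a <- scar_threshold_segmentation(mtr_map((1 - vals / 100) * ref, ref),
                                       myo, remote)
  seg_b <- scar_threshold_segmentation(mtr_map((1 - (vals + 10) / 100) * ref,
                                               ref), myo, remote)
  expect_identical(seg_a$scar, seg_b$scar)
  expect_equal(seg_b$threshold, seg_a$threshold + 10, tolerance = 1e-10)
})

test_that("overlap and false-positive operators count exactly", {
  d <- c(10, 10, 2)
  a <- array(FALSE, d)
  a[1:5, , ] <- TRUE
  expect_equal(overlap_percent(a, a), 100)
  b <- array(FALSE, d)
  b[6:10, , ] <- TRUE
  expect_equal(overlap_percent(a, b), 0)
  half <- a
  half[1:5, 6:10, ] <- FALSE  # covers half of a's voxels
  expect_equal(overlap_percent(half, a), 50)
  expect_error(overlap_percent(a, array(FALSE, d)), "empty")
  # false positives, default and literal forms
  expect_equal(false_positive_percent(b, a), 0)
  expect_equal(false_positive_percent(b, a, literal = TRUE), 100)
  expect_equal(false_positive_percent(a, a), 100)
  expect_equal(false_positive_percent(a, a, literal = TRUE), 0)
  tenth <- array(FALSE, d)
  tenth[1, 1:10, 1] <- TRUE  # 10 of a's 100 voxels
  expect_equal(false_positive_percent(tenth, a), 10)
  # bounds and monotonicity under mask growth
  set.seed(31)
  scar <- array(runif(prod(d)) < 0.3, d)
  lge <- array(runif(prod(d)) < 0.4, d)
  if (!any(lge)) lge[1] <- TRUE
  o1 <- overlap_percent(scar, lge)
  bigger <- scar | (array(runif(prod(d)) < 0.2, d))
  expect_gte(overlap_percent(bigger, lge), o1)
  expect_true(o1 >= 0 && o1 <= 100)
})

test_that("short-axis reformatting is exact for identity and axis permutations", {
  set.seed(19)
  vol <- array(rnorm(12 * 12 * 12), c(12, 12, 12))
  id <- reformat_short_axis(vol, diag(3))
  expect_equal(id, vol, tolerance = 1e-10)
  # 90-degree rotation about z permutes the box dimensions exactly
  box <- array(0, c(13, 13, 5))
  box[5:9, 3:11, 2:4] <- 1  # 5 x 9 x 3 box
  rot <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  out <- reformat_short_axis(box, rot)
  expect_equal(sum(out, na.rm = TRUE), sum(box), tolerance = 1e-6)
  expect_equal(dim(out), dim(box))
  expect_equal(max(abs(out[3:11, 5:9, 2:4] - 1), na.rm = TRUE), 0,
               tolerance = 1e-10)
  expect_error(reformat_short_axis(vol, matrix(1, 3, 3)), "orthonormal")
})

test_that("reformatting a smooth analytic field is accurate at 30 degrees", {
  n <- 24
  centre <- (n + 1) / 2
  f <- function(x, y, z)
    sin(0.3 * (x - centre)) + cos(0.25 * (y - centre)) + 0.1 * z
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  vol <- array(f(g$x, g$y, g$z), c(n, n, n))
  th <- 30 * pi / 180
  axes <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1),
                 3, 3)
  out <- reformat_short_axis(vol, axes)
  # compare against direct analytic evaluation on the rotated grid
  inner <- 7:18  # stay inside the field of view
  expected <- array(NA_real_, dim(out))
  for (i in inner) for (j in inner) for (k in inner) {
    off <- axes %*% c(i - centre, j - centre, k - centre)
    expected[i, j, k] <- f(centre + off[1], centre + off[2],
                           centre + off[3])
  }
  err <- max(abs(out[inner, inner, inner] - expected[inner, inner, inner]))
  expect_lt(err, 0.02 * diff(range(vol)))
})

test_that("AHA labels partition the myocardium into the 16 standard sectors", {
  n <- 64
  myo <- array(FALSE, c(n, n, 6))
  centre <- c(32.5, 32.5)
  g <- expand.grid(x = 1:n, y = 1:n)
  r <- sqrt((g$x - centre[1])^2 + (g$y - centre[2])^2)
  ann <- matrix(r >= 12 & r <= 22, n, n)
  for (z in 1:6) myo[, , z] <- ann
  slabs <- c(1L, 1L, 2L, 2L, 3L, 3L)
  lab <- aha16_labels(myo, slabs, centre, centre + c(20, 0))
  # partition: every myocardial voxel labelled exactly once
  expect_true(all(!is.na(lab[myo])))
  expect_true(all(is.na(lab[!myo])))
  expect_setequal(sort(unique(as.vector(lab[myo]))), 1:16)
  # basal/mid have 6 sectors, apical 4
  expect_true(all(lab[, , 1:2][myo[, , 1:2]] %in% 1:6))
  expect_true(all(lab[, , 3:4][myo[, , 3:4]] %in% 7:12))
  expect_true(all(lab[, , 5:6][myo[, , 5:6]] %in% 13:16))
  # centred annulus: basal sector populations agree closely
  counts <- table(lab[, , 1][myo[, , 1]])
  expect_lt(diff(range(counts)) / mean(counts), 0.05)
  # rotating the RV insertion by 60 degrees permutes basal labels cyclically
  th <- 60 * pi / 180
  rot_pt <- centre + 20 * c(cos(th), sin(th))
  lab2 <- aha16_labels(myo, slabs, centre, rot_pt)
  m1 <- lab[, , 1][myo[, , 1]]
  m2 <- lab2[, , 1][myo[, , 1]]
  expect_equal(((m1 - 2) %% 6) + 1, m2)
  expect_error(aha16_labels(myo, slabs, c(200, 200), centre), "outside")
})

test_that("segment statistics recover constructed means and variations", {
  d <- c(30, 30, 6)
  ref <- array(1, d)
  myo <- array(FALSE, d)
  g <- expand.grid(x = 1:30, y = 1:30)
  r <- sqrt((g$x - 15.5)^2 + (g$y - 15.5)^2)
  ann <- matrix(r >= 6 & r <= 12, 30, 30)
  for (z in 1:6) myo[, , z] <- ann
  labels <- aha16_labels(myo, c(1L, 1L, 2L, 2L, 3L, 3L), c(15.5, 15.5),
                         c(27, 15.5))
  # constant map: zero spatial variation everywhere
  m_const <- mtr_map(0.6 * ref, ref)
  st <- segment_stats(m_const, labels)
  expect_true(all(abs(st$spatial_variation[st$n > 1]) < 1e-10))
  expect_equal(attr(st, "global_mean"), 40)
  # two-level construction: intersegment variation from the closed form
  vals <- array(30, d)
  sector1 <- !is.na(labels) & labels <= 6
  vals[sector1] <- 50
  m2 <- mtr_map((1 - vals / 100) * ref, ref)
  st2 <- segment_stats(m2, labels)
  means <- st2$mean[!is.na(st2$mean)]
  expect_equal(attr(st2, "intersegment_variation"),
               100 * sd(means) / mean(means))
  expect_equal(sort(unique(round(means, 6))), c(30, 50))
  # sampled Gaussian map recovers mu = 37, sigma = 5.8 (SV ~ 15.7%)
  set.seed(77)
  d3 <- c(120, 120, 6)
  ref3 <- array(1, d3)
  myo3 <- array(TRUE, d3)
  labels3 <- aha16_labels(myo3, c(1L, 1L, 2L, 2L, 3L, 3L), c(60.5, 60.5),
                          c(110, 60.5))
  vals3 <- array(rnorm(prod(d3), 37, 5.8), d3)
  st3 <- segment_stats(mtr_map((1 - vals3 / 100) * ref3, ref3), labels3)
  expect_equal(mean(st3$spatial_variation), 100 * 5.8 / 37,
               tolerance = 0.5 / 15.7)
  # spatial variation is scale-invariant and doubles with the SD
  vals4 <- array(rnorm(prod(d3), 37, 11.6), d3)
  st4 <- segment_stats(mtr_map((1 - vals4 / 100) * ref3, ref3), labels3)
  expect_equal(mean(st4$spatial_variation) / mean(st3$spatial_variation),
               2, tolerance = 0.05)
})

test_that("contrast ratio and CNR follow their definitions", {
  d <- c(10, 10, 2)
  ref <- array(1, d)
  vals <- array(15, d)
  myo <- array(FALSE, d)
  myo[1:5, , ] <- TRUE
  blood <- !myo
  vals[myo] <- 37.5
  m <- mtr_map((1 - vals / 100) * ref, ref)
  expect_equal(contrast_ratio(m, myo, blood), 2.5)
  # CR is invariant to a uniform scaling of the map values
  m_scaled <- m
  m_scaled$data <- m$data * 3
  expect_equal(contrast_ratio(m_scaled, myo, blood), 2.5)
  img <- array(4, d)
  img[1:5, , ] <- 10
  lungs <- array(FALSE, d)
  lungs[6:10, 1:5, 1] <- TRUE
  set.seed(5)
  img[lungs] <- rnorm(sum(lungs), 4, 0.75)
  img_blood <- array(FALSE, d)
  img_blood[1:5, , ] <- TRUE
  img_myo <- !img_blood & !lungs
  v <- cnr(img, img_blood, img_myo, lungs)
  expect_equal(v, (mean(img[img_blood]) - mean(img[img_myo])) /
                 sd(img[lungs]))
  expect_equal(cnr(2 * img, img_blood, img_myo, lungs), v)
  expect_equal(cnr(img, img_blood, img_blood, lungs), 0)
  expect_error(cnr(array(1, d), img_blood, img_myo, lungs), "zero lung SD")
})

test_that("vessel sharpness is 100 for an ideal tube and drops with blur", {
  d <- c(32, 32, 6)
  img <- array(0, d)
  img[15:17, , 3] <- 1  # 3-voxel tube along y, unit intensity, step edges
  pts <- cbind(15, seq(8, 24, by = 1), 2)  # mm with unit voxels (0-based)
  cl <- vessel_centerline(pts)
  vs <- vessel_sharpness(img, cl, vessel_diameter = 3)
  expect_equal(vs, 100, tolerance = 1e-6)
  expect_equal(vessel_sharpness(3 * img, cl, vessel_diameter = 3), vs,
               tolerance = 1e-6)
  blur <- img
  for (k in 1:2) {
    blur[2:31, , ] <- (blur[1:30, , ] + blur[2:31, , ] + blur[3:32, , ]) / 3
  }
  vs_blur <- vessel_sharpness(blur / max(blur), cl, vessel_diameter = 3)
  expect_lt(vs_blur, vs)
  expect_error(vessel_centerline(pts[1:3, ]), "5 points")
})
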