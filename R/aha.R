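# Short-axis reformatting and AHA 16-segment statistics.

# trilinear sample of vol at fractional voxel coordinates (n x 3 matrix);
# NA outside the grid
trilinear_sample <- function(vol, pts) {
  d <- dim(vol)
  x0 <- floor(pts[, 1]); y0 <- floor(pts[, 2]); z0 <- floor(pts[, 3])
  fx <- pts[, 1] - x0; fy <- pts[, 2] - y0; fz <- pts[, 3] - z0
  out <- rep(0, nrow(pts))
  valid <- pts[, 1] >= 1 & pts[, 1] <= d[1] &
           pts[, 2] >= 1 & pts[, 2] <= d[2] &
           pts[, 3] >= 1 & pts[, 3] <= d[3]
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    cx <- pmin(pmax(x0 + dx, 1), d[1])
    cy <- pmin(pmax(y0 + dy, 1), d[2])
    cz <- pmin(pmax(z0 + dz, 1), d[3])
    w <- (if (dx == 1) fx else 1 - fx) *
         (if (dy == 1) fy else 1 - fy) *
         (if (dz == 1) fz else 1 - fz)
    out <- out + w * vol[cbind(cx, cy, cz)]
  }
  out[!valid] <- NA_real_
  out
}

#' Reformat a volume onto a short-axis grid
#'
#' Trilinear resampling of a volume onto a new grid defined by an
#' orthonormal axis matrix and a centre point.  Output voxel `(i, j, k)`
#' (0-based, grid centred) samples the input at
#' `centre + axes %*% (offset * out_voxel)` in mm.  Voxels falling outside
#' the input field of view are `NA`.
#'
#' @param vol 3-D array.
#' @param axes 3x3 orthonormal matrix; columns are the output x/y/z
#'   directions expressed in input-volume mm coordinates.
#' @param centre Centre of the output grid in input voxel coordinates
#'   (1-based).
#' @param out_dim Output matrix size, length 3.
#' @param voxel_size Input voxel size (mm).
#' @param out_voxel Output voxel size (mm).
#' @return The resampled array (`NA` outside the input volume).
#' @export
reformat_short_axis <- function(vol, axes, centre = (dim(vol) + 1) / 2,
                                out_dim = dim(vol),
                                voxel_size = c(1, 1, 1),
                                out_voxel = voxel_size) {
  if (abs(abs(det(axes)) - 1) > 1e-6 ||
      max(abs(t(axes) %*% axes - diag(3))) > 1e-6)
    stop("axes must form an orthonormal matrix")
  g <- expand.grid(i = seq_len(out_dim[1]), j = seq_len(out_dim[2]),
                   k = seq_len(out_dim[3]))
  off <- cbind((g$i - (out_dim[1] + 1) / 2) * out_voxel[1],
               (g$j - (out_dim[2] + 1) / 2) * out_voxel[2],
               (g$k - (out_dim[3] + 1) / 2) * out_voxel[3])
  mm <- off %*% t(axes)
  pts <- cbind(centre[1] + mm[, 1] / voxel_size[1],
               centre[2] + mm[, 2] / voxel_size[2],
               centre[3] + mm[, 3] / voxel_size[3])
  array(trilinear_sample(vol, pts), out_dim)
}

#' AHA 16-segment labels for the left ventricle
#'
#' Assigns each myocardial voxel a segment id of the American Heart
#' Association 16-segment model: 6 basal (ids 1-6) and 6 mid-cavity
#' (7-12) sectors of 60 degrees, and 4 apical sectors (13-16) of
#' 90 degrees.  Angles are measured counterclockwise from the ray through
#' the anterior RV-insertion point, in the short-axis plane viewed from the
#' apex; boundary voxels go to the lower id.
#'
#' @param lv_myo Logical 3-D array: LV myocardium on a short-axis grid.
#' @param slabs Integer vector over slices (third dimension): 1 = basal,
#'   2 = mid, 3 = apical, `NA` = not used.
#' @param centre LV centre `(x, y)` in voxels.
#' @param rv_insertion Anterior RV insertion point `(x, y)` in voxels.
#' @return Integer array of segment ids (`NA` outside `lv_myo` or unused
#'   slices), class `aha_labels`.
#' @export
aha16_labels <- function(lv_myo, slabs, centre, rv_insertion) {
  d <- dim(lv_myo)
  stopifnot(length(slabs) == d[3])
  if (centre[1] < 1 || centre[1] > d[1] || centre[2] < 1 || centre[2] > d[2])
    stop("LV centre outside the mask bounding box")
  theta0 <- atan2(rv_insertion[2] - centre[2], rv_insertion[1] - centre[1])
  gx <- rep(seq_len(d[1]), times = d[2])
  gy <- rep(seq_len(d[2]), each = d[1])
  ang <- (atan2(gy - centre[2], gx - centre[1]) - theta0) * 180 / pi
  ang <- ang %% 360
  labels <- array(NA_integer_, d)
  sector_of <- function(theta, width) {
    s <- ceiling(theta / width)
    s[theta == 0] <- 1L
    as.integer(s)
  }
  for (z in seq_len(d[3])) {
    if (is.na(slabs[z])) next
    m <- lv_myo[, , z]
    if (!any(m)) next
    lab <- switch(slabs[z],
                  sector_of(ang, 60),            # basal: 1-6
                  sector_of(ang, 60) + 6L,       # mid: 7-12
                  sector_of(ang, 90) + 12L)      # apical: 13-16
    sl <- array(NA_integer_, d[1:2])
    sl[m] <- lab[as.vector(m)]
    labels[, , z] <- sl
  }
  structure(labels, class = c("aha_labels", "array"))
}

#' Per-segment MTR statistics
#'
#' Mean, SD and spatial variation (`100 * SD / mean`, percent) of the MTR
#' over each AHA segment, plus the global mean over all labelled valid
#' voxels and the intersegment variation
#' (`100 * SD(segment means) / mean(segment means)`).  Empty segments are
#' flagged and excluded from the aggregates.
#'
#' @param map An [mtr_map].
#' @param labels An [aha16_labels] array on the same grid.
#' @return A `segment_stats` tibble `(segment, n, mean, sd,
#'   spatial_variation)` with attributes `global_mean`,
#'   `intersegment_variation`.
#' @export
segment_stats <- function(map, labels) {
  stopifnot(all(dim(labels) == dim(map$data)))
  vals <- map$data
  vals[!map$valid] <- NA
  seg <- as.vector(unclass(labels))
  v <- as.vector(vals)
  keep <- !is.na(seg) & !is.na(v)
  rows <- lapply(1:16, function(s) {
    x <- v[keep & seg == s]
    tibble(segment = s, n = length(x),
           mean = if (length(x)) mean(x) else NA_real_,
           sd = if (length(x) > 1) sd(x) else NA_real_,
           spatial_variation = if (length(x) > 1 && mean(x) != 0)
             100 * sd(x) / mean(x) else NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  present <- !is.na(out$mean)
  gm <- mean(v[keep])
  iv <- if (sum(present) > 1)
    100 * sd(out$mean[present]) / mean(out$mean[present]) else NA_real_
  structure(out, class = c("segment_stats", class(out)),
            global_mean = gm, intersegment_variation = iv)
}

#' @rdname segment_stats
#' @param x A `segment_stats`.
#' @param ... Unused.
#' @export
tidy.segment_stats <- function(x, ...) as_tibble(x)

#' @rdname segment_stats
#' @export
glance.segment_stats <- function(x, ...) {
  tibble(global_mean = attr(x, "global_mean"),
         intersegment_variation = attr(x, "intersegment_variation"),
         n_segments = sum(!is.na(x$mean)))
}

#' @rdname segment_stats
#' @param object A `segment_stats`.
#' @export
autoplot.segment_stats <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$segment),
                                       y = .data$mean)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.3) +
    ggplot2::labs(x = "AHA segment", y = "MTR (%)")
}

#' Blood-myocardium contrast ratio of an MTR map
#'
#' Ratio of the mean myocardial MTR to the mean blood MTR.  Myocardial MTR
#' exceeds blood MTR, so values around 2-3 are typical.
#'
#' @param map An [mtr_map].
#' @param myo,blood Logical ROI arrays.
#' @return Dimensionless ratio.
#' @export
contrast_ratio <- function(map, myo, blood) {
  stopifnot(all(dim(myo) == dim(map$data)),
            all(dim(blood) == dim(map$data)))
  if (!any(myo) || !any(blood)) stop("ROIs must be non-empty")
  mb <- mean(map$data[blood & map$valid], na.rm = TRUE)
  mm <- mean(map$data[myo & map$valid], na.rm = TRUE)
  if (!is.finite(mb) || mb == 0) stop("blood MTR mean is zero: CR undefined")
  mm / mb
}

#' Contrast-to-noise ratio between blood and myocardium
#'
#' `CNR = (mean blood - mean myocardium) / SD(lungs)`, with the noise SD
#' taken over a signal-free lung region (n-1 normalization).
#'
#' @param image Intensity volume (e.g. the MT-prepared reconstruction
#'   magnitude).
#' @param blood,myo,lungs Logical ROI arrays.
#' @return Dimensionless CNR.
#' @export
cnr <- function(image, blood, myo, lungs) {
  stopifnot(all(dim(blood) == dim(image)), all(dim(myo) == dim(image)),
            all(dim(lungs) == dim(image)))
  if (sum(lungs) < 2) stop("lung ROI needs more than one voxel")
  s <- sd(image[lungs])
  if (s == 0) stop("zero lung SD: CNR undefined")
  (mean(image[blood]) - mean(image[myo])) / s
}
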