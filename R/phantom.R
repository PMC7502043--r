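# Digital phantoms with per-label tissue parameters and ground truth.

digital_phantom <- function(labels, label_names, tissues, rho, voxel_size,
                            centerlines = NULL, extras = list()) {
  structure(list(labels = labels, label_names = label_names,
                 tissues = tissues, rho = rho,
                 voxel_size = as.numeric(voxel_size),
                 centerlines = centerlines, extras = extras),
            class = "digital_phantom")
}

#' @export
print.digital_phantom <- function(x, ...) {
  cat(sprintf("<digital_phantom> matrix %s, labels: %s\n",
              paste(dim(x$labels), collapse = "x"),
              paste(x$label_names, collapse = ", ")))
  invisible(x)
}

#' Label mask of a phantom
#' @param phantom A `digital_phantom`.
#' @param name Label name.
#' @return Logical array.
#' @export
phantom_mask <- function(phantom, name) {
  id <- match(name, phantom$label_names)
  if (is.na(id)) stop("unknown label: ", name)
  phantom$labels == id
}

#' Digital agar vial phantom
#'
#' Cylindrical agar vials of the given concentrations on a common grid.
#' The concentration-to-parameter map is a documented heuristic chosen so
#' that the MT effect grows monotonically with agar content:
#' `psr = 0.012 * concentration`, `R = 50` Hz, `T1_free = 2.5` s and
#' `T2_free = 0.15 / (1 + 0.8 * concentration)` s, all overridable.
#'
#' @param concentrations Agar concentrations in percent, each in (0, 10].
#' @param grid Matrix size, length 3.
#' @param voxel_size Voxel size (mm).
#' @param vial_radius_mm Vial radius (mm).
#' @param param_map Function `concentration -> tissue_params` overriding
#'   the default map.
#' @return A `digital_phantom` with one label per vial plus background.
#' @export
make_agar_phantom <- function(concentrations = c(1, 2, 2.5, 5),
                              grid = c(48, 48, 8),
                              voxel_size = c(2, 2, 4),
                              vial_radius_mm = 8,
                              param_map = NULL) {
  stopifnot(all(concentrations > 0), all(concentrations <= 10))
  if (is.null(param_map)) {
    param_map <- function(conc)
      tissue_params(T1_free = 2.5,
                    T2_free = 0.15 / (1 + 0.8 * conc),
                    psr = 0.012 * conc, exchange_rate = 50)
  }
  nv <- length(concentrations)
  # vial centres on a ring
  ang <- 2 * pi * (seq_len(nv) - 1) / nv
  ring_r <- grid[1] * voxel_size[1] / 4
  cx <- (grid[1] + 1) / 2 + ring_r * cos(ang) / voxel_size[1]
  cy <- (grid[2] + 1) / 2 + ring_r * sin(ang) / voxel_size[2]
  if (nv > 1) {
    dists <- as.matrix(dist(cbind(cx * voxel_size[1], cy * voxel_size[2])))
    diag(dists) <- Inf
    if (min(dists) < 2 * vial_radius_mm)
      stop("vials overlap at the requested radius")
  }
  labels <- array(0L, grid)
  gx <- rep(seq_len(grid[1]), times = grid[2])
  gy <- rep(seq_len(grid[2]), each = grid[1])
  for (v in seq_len(nv)) {
    r2 <- ((gx - cx[v]) * voxel_size[1])^2 + ((gy - cy[v]) * voxel_size[2])^2
    inside <- r2 <= vial_radius_mm^2
    for (z in seq_len(grid[3])) {
      sl <- labels[, , z]
      sl[inside] <- v
      labels[, , z] <- sl
    }
  }
  tissues <- lapply(concentrations, param_map)
  names(tissues) <- paste0("agar_", concentrations)
  rho <- stats::setNames(rep(1, nv), names(tissues))
  digital_phantom(labels, names(tissues), tissues, rho, voxel_size)
}

#' Digital short-axis cardiac phantom
#'
#' A left-ventricular annulus with a reduced-PSR scar sector, a blood pool,
#' two tubular cardiac veins with exported centerlines, and lung, liver and
#' pectoral blocks.  All label masks are ground truth for the downstream
#' segmentation and metric operators.
#'
#' @param grid Matrix size, length 3.
#' @param voxel_size Voxel size (mm).
#' @param scar_sector Angular range of the scar sector in degrees,
#'   `c(from, to)` within `[0, 360)`, measured counterclockwise from the
#'   +x axis.
#' @param psr_remote,psr_scar Pool size ratios of healthy and scarred
#'   myocardium; `psr_scar < psr_remote`.
#' @param r_outer_mm,r_inner_mm Annulus radii (mm).
#' @return A `digital_phantom`; `extras$lv_centre` holds the LV centre.
#' @export
make_cardiac_phantom <- function(grid = c(48, 48, 10),
                                 voxel_size = c(2, 2, 4),
                                 scar_sector = c(0, 60),
                                 psr_remote = 0.15, psr_scar = 0.08,
                                 r_outer_mm = 30, r_inner_mm = 18) {
  if (any(scar_sector < 0) || any(scar_sector >= 360))
    stop("scar sector must lie within [0, 360)")
  if (psr_scar >= psr_remote)
    stop("psr_scar must be below psr_remote")
  label_names <- c("myocardium", "scar", "blood", "vein", "lungs", "liver",
                   "pectoral")
  tissues <- list(
    myocardium = tissue_params(1.1, 0.055, psr_remote, 50),
    scar = tissue_params(1.1, 0.055, psr_scar, 50),
    blood = tissue_params(1.6, 0.20, 0.03, 20),
    vein = tissue_params(1.6, 0.18, 0.03, 20),
    lungs = tissue_params(1.2, 0.04, 0.05, 30),
    liver = tissue_params(0.6, 0.045, 0.12, 45),
    pectoral = tissue_params(1.0, 0.04, 0.18, 55))
  rho <- c(myocardium = 1, scar = 1, blood = 1, vein = 1,
           lungs = 0.15, liver = 0.9, pectoral = 0.9)
  labels <- array(0L, grid)
  cx <- (grid[1] + 1) / 2
  cy <- (grid[2] + 1) / 2
  gx <- rep(seq_len(grid[1]), times = grid[2])
  gy <- rep(seq_len(grid[2]), each = grid[1])
  dx <- (gx - cx) * voxel_size[1]
  dy <- (gy - cy) * voxel_size[2]
  r <- sqrt(dx^2 + dy^2)
  theta <- (atan2(dy, dx) * 180 / pi) %% 360
  in_sector <- if (scar_sector[1] <= scar_sector[2])
    theta >= scar_sector[1] & theta < scar_sector[2]
  else theta >= scar_sector[1] | theta < scar_sector[2]
  annulus <- r <= r_outer_mm & r >= r_inner_mm
  bloodp <- r < r_inner_mm
  lv_slices <- 2:(grid[3] - 1)
  for (z in lv_slices) {
    sl <- labels[, , z]
    sl[annulus] <- 1L
    sl[annulus & in_sector] <- 2L
    sl[bloodp] <- 3L
    labels[, , z] <- sl
  }
  # two veins: tubes running in y at the epicardial border
  vein_r <- 1.2 * max(voxel_size[1:2])
  cl <- list()
  for (v in 1:2) {
    vx <- cx + (r_outer_mm + 2.5 * voxel_size[1]) *
      cos((if (v == 1) 210 else 330) * pi / 180) / voxel_size[1]
    vz <- if (v == 1) ceiling(grid[3] / 2) else ceiling(grid[3] / 2) + 1
    ys <- seq(ceiling(grid[2] * 0.25), floor(grid[2] * 0.75))
    for (y in ys) {
      near <- abs((gx - vx) * voxel_size[1]) <= vein_r & gy == y
      sl <- labels[, , vz]
      sl[near & sl == 0L] <- 4L
      labels[, , vz] <- sl
    }
    cl[[paste0("vein_", v)]] <- vessel_centerline(
      cbind((vx - 1) * voxel_size[1], (ys - 1) * voxel_size[2],
            (vz - 1) * voxel_size[3]),
      voxel_size = voxel_size)
  }
  # surrounding blocks
  lungs_x <- seq_len(max(1, floor(cx - r_outer_mm / voxel_size[1] - 4)))
  liver_y <- seq_len(max(1, floor(cy - r_outer_mm / voxel_size[2] - 4)))
  pect_y <- seq(min(grid[2], ceiling(cy + r_outer_mm / voxel_size[2] + 4)),
                grid[2])
  for (z in seq_len(grid[3])) {
    sl <- labels[, , z]
    sl[lungs_x, ] <- ifelse(sl[lungs_x, ] == 0L, 5L, sl[lungs_x, ])
    sl[, liver_y] <- ifelse(sl[, liver_y] == 0L, 6L, sl[, liver_y])
    sl[, pect_y] <- ifelse(sl[, pect_y] == 0L, 7L, sl[, pect_y])
    labels[, , z] <- sl
  }
  digital_phantom(labels, label_names, tissues, rho, voxel_size,
                  centerlines = cl,
                  extras = list(lv_centre = c(cx, cy),
                                lv_slices = lv_slices,
                                scar_sector = scar_sector))
}
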