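# Volume and raw-data I/O.  Volumes and masks travel as NIfTI-1 (mm units,
# RAS axis order as stored); a raw acquisition is a directory container
# with NIfTI payloads, a CSV displacement trace and a JSON manifest.

#' Read / write a volume as NIfTI-1
#'
#' @param vol 3-D (or higher) numeric array.
#' @param path Output `.nii` / `.nii.gz` path.
#' @param voxel_size Voxel size in mm.
#' @return `write_volume_nifti` returns the path; `read_volume_nifti` a
#'   list with `data` and `voxel_size`.
#' @export
write_volume_nifti <- function(vol, path, voxel_size = c(1, 1, 1)) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim(img)),
       voxel_size = RNifti::pixdim(img))
}

#' Write / read a raw acquisition container
#'
#' Directory layout: `kspace_real.nii` / `kspace_imag.nii` (5-D
#' coil x beat x kx x ky x kz), `mask.nii` (beat x kx x ky),
#' `coils_real.nii` / `coils_imag.nii`, `inav_trace.csv`
#' (beat, d_LR, d_FH in mm) and `manifest.json` (voxel size and protocol
#' metadata).
#'
#' @param acq Result of [simulate_acquisition] (or a compatible list with
#'   `kspace`, `trace`, `coils`).
#' @param dir Container directory (created if needed).
#' @param meta Extra metadata stored in the manifest.
#' @return The directory, invisibly.
#' @export
write_acquisition <- function(acq, dir, meta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ks <- acq$kspace
  write_volume_nifti(Re(ks$data), file.path(dir, "kspace_real.nii"))
  write_volume_nifti(Im(ks$data), file.path(dir, "kspace_imag.nii"))
  write_volume_nifti(ks$mask * 1, file.path(dir, "mask.nii"))
  write_volume_nifti(Re(acq$coils), file.path(dir, "coils_real.nii"))
  write_volume_nifti(Im(acq$coils), file.path(dir, "coils_imag.nii"))
  utils::write.csv(acq$trace, file.path(dir, "inav_trace.csv"),
                   row.names = FALSE)
  manifest <- c(list(voxel_size = ks$voxel_size,
                     matrix = dim(ks$data)[3:5],
                     n_coils = dim(ks$data)[1],
                     n_beats = dim(ks$data)[2]), meta)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_acquisition
#' @export
read_acquisition <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  re <- read_volume_nifti(file.path(dir, "kspace_real.nii"))$data
  im <- read_volume_nifti(file.path(dir, "kspace_imag.nii"))$data
  mask <- read_volume_nifti(file.path(dir, "mask.nii"))$data > 0.5
  cre <- read_volume_nifti(file.path(dir, "coils_real.nii"))$data
  cim <- read_volume_nifti(file.path(dir, "coils_imag.nii"))$data
  trace <- as_tibble(utils::read.csv(file.path(dir, "inav_trace.csv")))
  list(kspace = cartesian_kspace(complex(real = re, imaginary = im) |>
                                   array(dim(re)),
                                 mask, manifest$voxel_size),
       coils = array(complex(real = cre, imaginary = cim), dim(cre)),
       trace = trace, manifest = manifest)
}
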