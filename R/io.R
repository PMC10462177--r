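# File interfaces: NIfTI-1 volumes with JSON sidecars, protocol JSON,
# k-space serialization.

#' Write a volume as NIfTI-1
#'
#' @param vol 3D or 4D numeric array.
#' @param path output `.nii` or `.nii.gz` path.
#' @param voxel_mm voxel size (mm).
#' @return The path, invisibly.
#' @export
write_nifti_volume <- function(vol, path, voxel_mm = c(1, 1, 1)) {
  vox <- as_len3(voxel_mm, "voxel_mm")
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- if (length(dim(vol)) == 4) c(vox, 1) else vox
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` / `.nii.gz` path.
#' @return List with `data` (array), `voxel_mm`, `affine`.
#' @export
read_nifti_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file: ", path, call. = FALSE))
  list(data = array(as.numeric(img), dim(img)),
       voxel_mm = RNifti::pixdim(img)[1:3],
       affine = structure(RNifti::xform(img), class = NULL))
}

#' Persist a phantom as NIfTI volumes plus a JSON sidecar
#'
#' One file per map (`m0`, `r2s`, `chi`, `labels`, `mask`) and
#' `phantom.json` holding the voxel size, field strength, label dictionary
#' and seed.
#'
#' @param phantom an `epiqsm_phantom`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("m0", "r2s", "chi", "labels", "mask")) {
    write_nifti_volume(phantom[[nm]] + 0, file.path(dir, paste0(nm, ".nii.gz")),
                       phantom$voxel_mm)
  }
  meta <- list(voxel_mm = phantom$voxel_mm, b0_tesla = phantom$b0_tesla,
               labels = as.list(phantom$label_names), seed = phantom$seed)
  jsonlite::write_json(meta, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a phantom written by [write_phantom()]
#' @param dir directory containing the NIfTI maps and `phantom.json`.
#' @return An `epiqsm_phantom`.
#' @export
read_phantom <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "phantom.json"), simplifyVector = TRUE)
  vols <- lapply(c(m0 = "m0", r2s = "r2s", chi = "chi", labels = "labels", mask = "mask"),
                 function(nm) read_nifti_volume(file.path(dir, paste0(nm, ".nii.gz")))$data)
  structure(list(m0 = vols$m0, r2s = vols$r2s, chi = vols$chi,
                 labels = array(as.integer(round(vols$labels)), dim(vols$labels)),
                 mask = vols$mask > 0.5,
                 voxel_mm = meta$voxel_mm, b0_tesla = meta$b0_tesla,
                 label_names = unlist(meta$labels), seed = meta$seed),
            class = "epiqsm_phantom")
}

#' Persist a multi-echo image as magnitude/phase NIfTI pairs
#'
#' Writes `<prefix>_mag.nii.gz`, `<prefix>_phase.nii.gz` and
#' `<prefix>.json` (echo times, voxel size, provenance).
#'
#' @param image an `epiqsm_image`.
#' @param prefix path prefix.
#' @return The prefix, invisibly.
#' @export
write_multiecho <- function(image, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  write_nifti_volume(magnitude(image), paste0(prefix, "_mag.nii.gz"), image$voxel_mm)
  write_nifti_volume(phase(image), paste0(prefix, "_phase.nii.gz"), image$voxel_mm)
  jsonlite::write_json(list(te_s = image$te_s, voxel_mm = image$voxel_mm,
                            provenance = image$provenance),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(prefix)
}

#' Read a multi-echo image written by [write_multiecho()]
#' @param prefix path prefix used at write time.
#' @return An `epiqsm_image` (complex data rebuilt from magnitude and phase).
#' @export
read_multiecho <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  mag <- read_nifti_volume(paste0(prefix, "_mag.nii.gz"))$data
  ph <- read_nifti_volume(paste0(prefix, "_phase.nii.gz"))$data
  new_multiecho_image(mag * exp(1i * ph), meta$te_s, meta$voxel_mm,
                      as.list(meta$provenance))
}

#' Serialize a protocol to JSON
#' @param protocol an `epiqsm_protocol`.
#' @param path output path.
#' @export
write_protocol <- function(protocol, path) {
  jsonlite::write_json(unclass(protocol), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a protocol JSON written by [write_protocol()]
#' @param path input path.
#' @return An `epiqsm_protocol`.
#' @export
read_protocol <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(new_protocol, p[c("name", "matrix", "fov_mm", "te_s", "tr_s", "flip_deg",
                            "bw_hz_per_px", "epi_factor", "etl_s", "accel", "caipi",
                            "caipi_shift", "repetitions", "gmax_mt_per_m",
                            "slew_mt_per_m_per_ms")])
}

#' Persist simulated k-space
#'
#' Shot-resolved k-space is stored with R's native serialization (it is an
#' internal intermediate, not an exchange format).
#'
#' @param kdata an `epiqsm_kspace`.
#' @param path output `.rds` path.
#' @export
write_kspace <- function(kdata, path) {
  saveRDS(kdata, path)
  invisible(path)
}

#' Read k-space written by [write_kspace()]
#' @param path input path.
#' @export
read_kspace <- function(path) readRDS(path)
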