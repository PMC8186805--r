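#' Write a label volume to NIfTI
#'
#' Writes the integer tissue grid as a NIfTI volume (with the voxel size
#' in the header) plus an optional CSV sidecar mapping codes to tissue
#' names.  A write-then-read round trip reproduces dims, voxel size,
#' origin and labels exactly.
#'
#' @param volume a `labeled_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param sidecar if `TRUE` (default), also write `<path>.labels.csv`.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(volume, path, sidecar = TRUE) {
  stopifnot(inherits(volume, "labeled_volume"))
  arr <- volume$labels
  attr(arr, "pixdim") <- rep(volume$voxel_size, 3)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int16"), path)
  if (sidecar) {
    lc <- label_counts(volume)
    utils::write.csv(lc[, c("code", "name")],
                     paste0(path, ".labels.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a label volume from NIfTI
#'
#' @param path a NIfTI file containing an isotropic integer label volume.
#' @param origin mm offset of the grid corner (the NIfTI qform offset is
#'   not interpreted; phantoms written by this package use origin 0).
#' @return A `labeled_volume`.
#' @export
read_label_volume <- function(path, origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  pd <- pd[seq_len(3)]
  if (max(pd) - min(pd) > 1e-6 * max(pd)) {
    stop("anisotropic voxels (", paste(signif(pd, 6), collapse = " x "),
         " mm): isotropic label volumes are required")
  }
  arr <- as.array(img)
  if (length(dim(arr)) != 3) stop("expected a 3-D volume, got ", length(dim(arr)), " dims")
  if (max(abs(arr - round(arr))) > 1e-9) stop("volume contains non-integer data")
  arr <- array(as.integer(round(arr)), dim = dim(arr))
  known <- tissue_labels()$code
  bad <- setdiff(unique(as.vector(arr)), known)
  if (length(bad)) stop("unknown tissue code(s) in volume: ", paste(sort(bad), collapse = ", "))
  labeled_volume(arr, voxel_size = pd[1], origin = origin)
}

#' Write / read fiducials as CSV
#'
#' Plain CSV with columns `name, x, y, z` (mm).
#'
#' @param fiducials data frame with columns name, x, y, z.
#' @param path CSV path.
#' @return The fiducials data frame (read) or `path` invisibly (write).
#' @export
write_fiducials <- function(fiducials, path) {
  stopifnot(all(c("name", "x", "y", "z") %in% names(fiducials)))
  utils::write.csv(fiducials[, c("name", "x", "y", "z")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fiducials
#' @export
read_fiducials <- function(path) {
  fid <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("Nz", "Iz", "Vz", "LPA", "RPA", "LMa", "RMa")
  missing <- setdiff(need, fid$name)
  if (length(missing)) stop("fiducials file lacks: ", paste(missing, collapse = ", "))
  fid
}

#' Persist a continuous-wave fluence grid as NIfTI + JSON sidecar
#'
#' @param fluence a `fluence_volume` (see [simulate_fluence()]).
#' @param path output `.nii`/`.nii.gz` path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_fluence_volume <- function(fluence, path) {
  stopifnot(inherits(fluence, "fluence_volume"))
  cw <- sum_time_gates(fluence)
  attr(cw, "pixdim") <- rep(fluence$voxel_size, 3)
  RNifti::writeNifti(RNifti::asNifti(cw, datatype = "double"), path)
  meta <- list(n_photons = fluence$n_photons, seed = fluence$seed,
               t_max_ns = fluence$t_max_ns, n_gates = fluence$n_gates,
               launch_position = fluence$launch_position,
               launch_direction = fluence$launch_direction,
               normalisation = "per launched photon per mm^3 (track-length estimator)")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
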