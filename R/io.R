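#' Read and write volumes as NIfTI-1
#'
#' Volumes and label masks are exchanged as NIfTI-1 files (`.nii` /
#' `.nii.gz`).  The grid geometry is carried in the sform/qform affine: the
#' affine's 3x3 block factors as `direction %*% diag(spacing)` and its
#' fourth column is the origin, so a write/read round trip preserves data,
#' spacing, origin and direction to floating-point precision.
#'
#' @param path path to a NIfTI-1 file.
#' @param units optional units label attached to the returned volume.
#' @return `read_volume()` returns a [volume_image()]; `read_mask()` a
#'   [mask_volume()].
#' @export
read_volume <- function(path, units = "") {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3L)
    stop(sprintf("expected a 3D volume, got %dD payload in %s",
                 length(dim(a)), path), call. = FALSE)
  aff <- RNifti::xform(img)
  m <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(m^2))
  if (any(spacing <= 0) || any(!is.finite(spacing)))
    stop("malformed NIfTI header: nonpositive voxel spacing", call. = FALSE)
  direction <- sweep(m, 2, spacing, `/`)
  volume_image(array(as.numeric(a), dim = dim(a)), spacing = spacing,
               origin = aff[1:3, 4], direction = direction, units = units)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  vals <- v$data
  if (!all(vals %in% c(0, 1)))
    stop("mask file contains values other than 0/1", call. = FALSE)
  mask_volume(vals, v$spacing, v$origin, v$direction)
}

#' @rdname read_volume
#' @param volume a `volume_image` or `mask_volume`.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_image"))
  aff <- diag(4)
  aff[1:3, 1:3] <- volume$direction %*% diag(volume$spacing)
  aff[1:3, 4] <- volume$origin
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
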