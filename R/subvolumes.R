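#' Resample a binary mask through a rigid transform
#'
#' The mask is resampled with linear interpolation and re-binarised at 0.5,
#' which is unbiased for half-voxel shifts.  The transform follows the
#' resampling convention of [apply_rigid()].
#'
#' @param mask a [mask_volume()].
#' @param transform a [rigid_transform()].
#' @param target target grid (defaults to the mask's own grid).
#' @return A [mask_volume()] on the target grid.
#' @export
transform_mask <- function(mask, transform, target = vol_grid(mask)) {
  stopifnot(inherits(mask, "mask_volume"))
  v <- apply_rigid(mask, transform, target, mode = "linear", fill = 0)
  tg <- vol_grid(target)
  mask_volume(array(as.numeric(v$data >= 0.5), tg$dim), tg$spacing,
              tg$origin, tg$direction)
}

#' Partition pre-recurrence edema into recurrence sub-volumes
#'
#' After the recurrent tumor contour has been brought onto the
#' pre-recurrence grid, the pre-recurrence edema is split into
#' `subedema_rec` (edema overlapped by recurrent tumor) and
#' `subedema_no_rec` (the remainder).  The two sub-volumes are disjoint and
#' exactly exhaust the edema.  If the recurrent tumor misses the edema
#' entirely the labelling is flagged (`flagged_empty_rec = TRUE`), the
#' analogue of excluding cases whose recurrence does not fall within the
#' original edema.
#'
#' @param edema_pre pre-recurrence edema [mask_volume()].
#' @param tumor_rec_on_pre_grid recurrent tumor mask already resampled onto
#'   the same grid (see [transform_mask()]).
#' @param provenance optional identifier (case id, transform id) carried in
#'   the result.
#' @return A list of class `subvolume_labeling` with fields `subedema_rec`,
#'   `subedema_no_rec`, `edema`, `flagged_empty_rec`, `provenance`.
#' @export
define_subvolumes <- function(edema_pre, tumor_rec_on_pre_grid,
                              provenance = NULL) {
  stopifnot(inherits(edema_pre, "mask_volume"),
            inherits(tumor_rec_on_pre_grid, "mask_volume"))
  stop_if_grid_mismatch(edema_pre, tumor_rec_on_pre_grid, "the two masks")
  e <- edema_pre$data > 0
  t <- tumor_rec_on_pre_grid$data > 0
  if (!any(e)) stop("edema mask is empty", call. = FALSE)
  g <- vol_grid(edema_pre)
  rec <- e & t
  norec <- e & !t
  mk <- function(m) mask_volume(array(as.numeric(m), g$dim), g$spacing,
                                g$origin, g$direction)
  structure(list(subedema_rec = mk(rec), subedema_no_rec = mk(norec),
                 edema = edema_pre, flagged_empty_rec = !any(rec),
                 provenance = provenance),
            class = "subvolume_labeling")
}

#' @export
print.subvolume_labeling <- function(x, ...) {
  cat(sprintf("<subvolume_labeling> edema %d vox = rec %d + no_rec %d%s\n",
              sum(x$edema$data), sum(x$subedema_rec$data),
              sum(x$subedema_no_rec$data),
              if (x$flagged_empty_rec) " [flagged: empty subedema_rec]" else ""))
  invisible(x)
}

#' Physical volume of a mask in cubic millimetres
#'
#' @param mask a [mask_volume()].
#' @return voxel count times voxel volume, in mm^3.
#' @export
volume_mm3 <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  sum(mask$data) * prod(mask$spacing)
}

#' Dice overlap coefficient between two masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b [mask_volume()] objects on the same grid, or plain
#'   logical/0-1 arrays of equal dimension.
#' @return scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  if (inherits(a, "mask_volume") && inherits(b, "mask_volume")) {
    stop_if_grid_mismatch(a, b, "masks")
    a <- a$data; b <- b$data
  }
  a <- a > 0; b <- b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Write a sub-volume labelling as an integer-coded NIfTI labelmap
#'
#' Codes: 1 = subedema_rec, 2 = subedema_no_rec, 0 = elsewhere.
#'
#' @param labeling a [define_subvolumes()] result.
#' @param path output NIfTI path.
#' @export
write_subvolumes <- function(labeling, path) {
  g <- vol_grid(labeling$edema)
  lab <- array(0, g$dim)
  lab[labeling$subedema_rec$data > 0] <- 1
  lab[labeling$subedema_no_rec$data > 0] <- 2
  write_volume(volume_image(lab, g$spacing, g$origin, g$direction,
                            units = "label"), path)
}
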