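#' Rigid (6 degree-of-freedom) spatial transforms
#'
#' A `rigid_transform` maps physical points as
#' `T(x) = R (x - center) + center + translation`, with `R` a proper
#' rotation.  In resampling ([apply_rigid()], [transform_mask()]) the
#' transform maps points of the *target* (fixed) grid into the space of the
#' *input* (moving) volume, the usual resampling convention: the output at
#' target point `x` is the input sampled at `T(x)`.
#'
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1).
#' @param translation length-3 translation in mm.
#' @param center length-3 centre of rotation in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation); center <- as.numeric(center)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("`rotation` must be orthonormal with determinant +1", call. = FALSE)
  structure(list(rotation = rotation, translation = translation,
                 center = center), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- euler_zyx_angles(x$rotation)
  cat(sprintf("<rigid_transform> angles ZYX (%.3f, %.3f, %.3f) deg, translation (%s) mm\n",
              ang[1], ang[2], ang[3],
              paste(signif(x$translation, 4), collapse = ", ")))
  invisible(x)
}

#' Build a rigid transform from Euler angles
#'
#' Angles are applied in ZYX order: `R = Rz(az) %*% Ry(ay) %*% Rx(ax)`.
#'
#' @param angles_deg length-3 rotation angles (degrees) about the x, y and z
#'   axes, given in the order `(ax, ay, az)`.
#' @param translation length-3 translation (mm).
#' @param center length-3 centre of rotation (mm).
#' @return A [rigid_transform()].
#' @export
rigid_from_euler <- function(angles_deg = c(0, 0, 0), translation = c(0, 0, 0),
                             center = c(0, 0, 0)) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  rigid_transform(rz %*% ry %*% rx, translation, center)
}

# ZYX Euler angles (degrees) of a rotation matrix; inverse of rigid_from_euler
euler_zyx_angles <- function(R) {
  ay <- asin(pmin(1, pmax(-1, -R[3, 1])))
  if (abs(cos(ay)) > 1e-8) {
    ax <- atan2(R[3, 2], R[3, 3])
    az <- atan2(R[2, 1], R[1, 1])
  } else {  # gimbal lock
    ax <- atan2(-R[2, 3], R[2, 2])
    az <- 0
  }
  c(ax, ay, az) * 180 / pi
}

#' Apply a rigid transform to physical points
#'
#' @param transform a [rigid_transform()].
#' @param pts N x 3 matrix of physical points (mm).
#' @return N x 3 matrix of transformed points.
#' @export
transform_points <- function(transform, pts) {
  pts <- matrix(pts, ncol = 3)
  sweep(sweep(pts, 2, transform$center, `-`) %*% t(transform$rotation),
        2, transform$center + transform$translation, `+`)
}

#' Invert or compose rigid transforms
#'
#' `invert_rigid(T)` returns the transform with
#' `invert_rigid(T)(T(x)) = x`; `compose_rigid(A, B)` returns the transform
#' applying `B` first: `compose_rigid(A, B)(x) = A(B(x))`.
#'
#' @param transform,a,b [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
invert_rigid <- function(transform) {
  R <- t(transform$rotation)
  # forward: y = R0 (x - c) + c + t  =>  x = R0^T (y - c - t) + c
  # express as rotation about the same center:
  # x = R (y - c) + c + t' with t' = -R t
  rigid_transform(R, -R %*% transform$translation, transform$center)
}

#' @rdname invert_rigid
#' @export
compose_rigid <- function(a, b) {
  # (a o b)(x) = Ra(Rb(x - cb) + cb + tb - ca) + ca + ta
  # choose center cb for the composite:
  # = Ra Rb (x - cb) + cb + [Ra(cb + tb - ca) + ca + ta - cb]
  R <- a$rotation %*% b$rotation
  t_new <- as.numeric(a$rotation %*% (b$center + b$translation - a$center)) +
    a$center + a$translation - b$center
  rigid_transform(R, t_new, b$center)
}

#' Resample a volume through a rigid transform
#'
#' The output on `target` at physical point `x` equals `volume` sampled at
#' `transform(x)` (see [rigid_transform()] for the convention).  Linear
#' interpolation is the default for intensity images; masks go through
#' [transform_mask()], which re-binarises at 0.5.
#'
#' @param volume a `volume_image`.
#' @param transform a [rigid_transform()].
#' @param target target grid; defaults to the volume's own grid.
#' @param mode `"linear"` or `"nearest"`.
#' @param fill fill value outside the source extent.
#' @return A `volume_image` on the target grid.
#' @export
apply_rigid <- function(volume, transform, target = vol_grid(volume),
                        mode = c("linear", "nearest"), fill = 0) {
  mode <- match.arg(mode)
  tg <- vol_grid(target)
  if (is_identity_rigid(transform) && same_grid(volume, tg))
    return(volume)
  pts <- voxel_to_world(tg, all_grid_indices(tg))
  pts <- transform_points(transform, pts)
  vals <- sample_volume(volume, pts, mode = mode, fill = fill)
  volume_image(array(vals, dim = tg$dim), spacing = tg$spacing,
               origin = tg$origin, direction = tg$direction,
               units = volume$units)
}

is_identity_rigid <- function(transform, tol = 1e-12) {
  max(abs(transform$rotation - diag(3))) < tol &&
    max(abs(transform$translation)) < tol
}

#' Serialize a rigid transform as a homogeneous matrix
#'
#' The transform is written as a plain-text 4x4 homogeneous matrix `A` with
#' `A[1:3,1:3] = R` and `A[1:3,4] = t + c - R c`, i.e. the centre of
#' rotation folded into the offset (the layout used by ITK transform
#' files).  `read_rigid()` restores a transform with centre 0.
#'
#' @param transform a [rigid_transform()].
#' @param path output file path.
#' @export
write_rigid <- function(transform, path) {
  A <- diag(4)
  A[1:3, 1:3] <- transform$rotation
  A[1:3, 4] <- transform$translation + transform$center -
    as.numeric(transform$rotation %*% transform$center)
  utils::write.table(format(A, digits = 17), path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_rigid
#' @export
read_rigid <- function(path) {
  A <- as.matrix(utils::read.table(path))
  if (!all(dim(A) == c(4, 4)))
    stop("transform file must contain a 4x4 matrix", call. = FALSE)
  rigid_transform(A[1:3, 1:3], A[1:3, 4], center = c(0, 0, 0))
}
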