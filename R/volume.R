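#' 3D scalar volumes on a physical grid
#'
#' A `volume_image` is a 3D array of scalar values together with its grid
#' geometry: voxel spacing (mm per axis), the physical position of voxel
#' `(0,0,0)` (mm), and a 3x3 matrix of direction cosines mapping voxel axes
#' to physical axes.  Voxel indices are 0-based in all physical-coordinate
#' computations; the physical position of voxel index `i` (0-based) is
#' `direction %*% (spacing * i) + origin`, the convention used by the NIfTI
#' affine.
#'
#' @param data numeric 3D array of voxel values.
#' @param spacing positive numeric length-3, mm per voxel along each axis.
#' @param origin numeric length-3, physical position (mm) of voxel (0,0,0).
#' @param direction 3x3 orthonormal matrix of direction cosines.
#' @param units free-text label for the voxel values, e.g.
#'   `"ADC 1e-6 mm^2/s"`.
#' @return An object of class `volume_image`.
#' @seealso [mask_volume()], [read_volume()], [resample_to_grid()]
#' @export
volume_image <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         direction = diag(3), units = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  direction <- matrix(as.numeric(direction), 3, 3)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be strictly positive on all three axes", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be a finite length-3 vector", call. = FALSE)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("`direction` must be orthonormal", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin,
                 direction = direction, units = units),
            class = "volume_image")
}

#' Binary label masks on a volume grid
#'
#' A `mask_volume` shares the grid fields of [volume_image()] but constrains
#' voxel values to 0/1.  Values are stored as a numeric array of 0s and 1s.
#'
#' @param data 3D array coercible to 0/1 (logical or numeric).
#' @inheritParams volume_image
#' @return An object of class `mask_volume` (which also inherits the grid
#'   accessors of `volume_image`).
#' @export
mask_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        direction = diag(3)) {
  if (is.logical(data)) data <- array(as.numeric(data), dim = dim(data))
  if (!all(data %in% c(0, 1)))
    stop("mask values must all be 0 or 1", call. = FALSE)
  v <- volume_image(data, spacing, origin, direction, units = "binary")
  class(v) <- c("mask_volume", "volume_image")
  v
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm%s\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              if (nzchar(x$units)) paste0(", units: ", x$units) else ""))
  invisible(x)
}

#' Grid geometry of a volume
#'
#' Extracts (or constructs) the grid geometry used by the resampling and
#' registration functions: dimensions, spacing, origin and direction.
#'
#' @param x a `volume_image`/`mask_volume`, or a list with fields `dim`,
#'   `spacing`, `origin`, `direction`.
#' @return A list of class `vol_grid`.
#' @export
vol_grid <- function(x) {
  if (inherits(x, "vol_grid")) return(x)
  if (inherits(x, "volume_image"))
    g <- list(dim = dim(x$data), spacing = x$spacing, origin = x$origin,
              direction = x$direction)
  else if (is.list(x) && all(c("dim", "spacing", "origin", "direction") %in% names(x)))
    g <- x[c("dim", "spacing", "origin", "direction")]
  else stop("cannot extract a grid from this object", call. = FALSE)
  structure(g, class = "vol_grid")
}

same_grid <- function(a, b, tol = 1e-6) {
  a <- vol_grid(a); b <- vol_grid(b)
  identical(as.integer(a$dim), as.integer(b$dim)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$direction - b$direction)) < tol
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!same_grid(a, b))
    stop(sprintf("%s must share the same grid geometry", what), call. = FALSE)
  invisible(TRUE)
}

#' Convert 0-based voxel indices to physical coordinates
#'
#' @param grid a grid (anything accepted by [vol_grid()]).
#' @param idx0 N x 3 matrix of 0-based (possibly fractional) voxel indices.
#' @return N x 3 matrix of physical coordinates in mm.
#' @export
voxel_to_world <- function(grid, idx0) {
  g <- vol_grid(grid)
  idx0 <- matrix(idx0, ncol = 3)
  sweep(idx0 %*% diag(g$spacing) %*% t(g$direction), 2, g$origin, `+`)
}

#' Convert physical coordinates to 0-based continuous voxel indices
#'
#' @inheritParams voxel_to_world
#' @param pts N x 3 matrix of physical coordinates (mm).
#' @return N x 3 matrix of continuous 0-based voxel indices.
#' @export
world_to_voxel <- function(grid, pts) {
  g <- vol_grid(grid)
  pts <- matrix(pts, ncol = 3)
  # direction orthonormal: inverse is the transpose
  sweep(pts, 2, g$origin, `-`) %*% g$direction %*% diag(1 / g$spacing)
}

#' Sample a volume at arbitrary physical points
#'
#' Trilinear or nearest-neighbour interpolation at physical coordinates.
#' Points falling outside the volume (beyond half a voxel of the outermost
#' voxel centres for nearest, beyond the outermost centres for linear)
#' receive `fill`.
#'
#' @param volume a `volume_image`.
#' @param pts N x 3 matrix of physical coordinates (mm).
#' @param mode `"linear"` or `"nearest"`.
#' @param fill value used outside the volume's extent (default 0).
#' @return numeric vector of length N.
#' @export
sample_volume <- function(volume, pts, mode = c("linear", "nearest"), fill = 0) {
  mode <- match.arg(mode)
  idx <- world_to_voxel(volume, pts)
  d <- dim(volume$data)
  arr <- volume$data
  n <- nrow(idx)
  out <- rep(as.numeric(fill), n)
  if (mode == "nearest") {
    i <- round(idx)
    ok <- i[, 1] >= 0 & i[, 1] <= d[1] - 1 &
          i[, 2] >= 0 & i[, 2] <= d[2] - 1 &
          i[, 3] >= 0 & i[, 3] <= d[3] - 1
    if (any(ok)) {
      lin <- 1 + i[ok, 1] + d[1] * (i[ok, 2] + d[2] * i[ok, 3])
      out[ok] <- arr[lin]
    }
    return(out)
  }
  f <- floor(idx)
  w <- idx - f
  ok <- f[, 1] >= -1 & f[, 1] <= d[1] - 1 &
        f[, 2] >= -1 & f[, 2] <= d[2] - 1 &
        f[, 3] >= -1 & f[, 3] <= d[3] - 1
  # strictly interior points interpolate among 8 corners; boundary-straddling
  # points use fill for out-of-range corners
  if (!any(ok)) return(out)
  fo <- f[ok, , drop = FALSE]; wo <- w[ok, , drop = FALSE]
  acc <- numeric(sum(ok))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    cx <- fo[, 1] + dx; cy <- fo[, 2] + dy; cz <- fo[, 3] + dz
    wt <- (if (dx == 1) wo[, 1] else 1 - wo[, 1]) *
          (if (dy == 1) wo[, 2] else 1 - wo[, 2]) *
          (if (dz == 1) wo[, 3] else 1 - wo[, 3])
    inside <- cx >= 0 & cx <= d[1] - 1 & cy >= 0 & cy <= d[2] - 1 &
              cz >= 0 & cz <= d[3] - 1
    val <- rep(as.numeric(fill), length(cx))
    if (any(inside))
      val[inside] <- arr[1 + cx[inside] + d[1] * (cy[inside] + d[2] * cz[inside])]
    acc <- acc + wt * val
  }
  out[ok] <- acc
  out
}

grid_world_corners <- function(grid) {
  g <- vol_grid(grid)
  corners <- as.matrix(expand.grid(c(0, g$dim[1] - 1), c(0, g$dim[2] - 1),
                                   c(0, g$dim[3] - 1)))
  voxel_to_world(g, corners)
}

grids_overlap <- function(a, b) {
  # conservative bounding-box test in physical space
  ca <- grid_world_corners(a); cb <- grid_world_corners(b)
  all(apply(ca, 2, min) <= apply(cb, 2, max) + 1e-9) &&
    all(apply(cb, 2, min) <= apply(ca, 2, max) + 1e-9)
}

all_grid_indices <- function(grid) {
  g <- vol_grid(grid)
  d <- g$dim
  cbind(rep(0:(d[1] - 1), times = d[2] * d[3]),
        rep(rep(0:(d[2] - 1), each = d[1]), times = d[3]),
        rep(0:(d[3] - 1), each = d[1] * d[2]))
}

#' Resample a volume onto a target grid
#'
#' Interpolates the volume at the voxel centres of `target`.  Linear
#' interpolation is used for intensity images; masks should use
#' `"nearest"`, or be resampled linearly and re-binarised at 0.5 as done by
#' [transform_mask()].  Voxels of the target grid that map outside the
#' source volume receive `fill` (default 0); regions of interest are
#' expected to lie inside the valid field of view.
#'
#' @param volume a `volume_image`.
#' @param target target grid (a `vol_grid`, `volume_image` or list).
#' @param mode `"linear"` or `"nearest"`.
#' @param fill fill value outside the source extent.
#' @return A `volume_image` on the target grid.
#' @export
resample_to_grid <- function(volume, target, mode = c("linear", "nearest"),
                             fill = 0) {
  mode <- match.arg(mode)
  tg <- vol_grid(target)
  if (!grids_overlap(volume, tg))
    stop("source and target grids have disjoint physical extents", call. = FALSE)
  if (same_grid(volume, tg)) {
    out <- volume
    return(out)
  }
  pts <- voxel_to_world(tg, all_grid_indices(tg))
  vals <- sample_volume(volume, pts, mode = mode, fill = fill)
  volume_image(array(vals, dim = tg$dim), spacing = tg$spacing,
               origin = tg$origin, direction = tg$direction,
               units = volume$units)
}
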