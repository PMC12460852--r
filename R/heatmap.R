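#' Choose the analysis slice for location prediction
#'
#' Returns the axial slice (third-axis index, 1-based) with the largest
#' tumor cross-sectional area among slices where edema is present.
#' Ties break toward the lowest index.
#'
#' @param tumor_pre,edema_pre nonempty [mask_volume()] objects on the same
#'   grid.
#' @return integer slice index.
#' @export
select_slice <- function(tumor_pre, edema_pre) {
  stop_if_grid_mismatch(tumor_pre, edema_pre, "tumor and edema masks")
  tarea <- apply(tumor_pre$data, 3, sum)
  earea <- apply(edema_pre$data, 3, sum)
  eligible <- earea > 0 & tarea > 0
  if (!any(eligible))
    stop("no slice contains both tumor and edema", call. = FALSE)
  cand <- which(eligible)
  cand[which.max(tarea[cand])]
}

# bilinear 2x upsampling of a matrix; fine cell i (0-based) samples the
# original at continuous index (i + 0.5)/2 - 0.5, borders replicated
upsample2_bilinear <- function(m) {
  up1 <- function(n) {
    s <- (seq_len(2 * n) - 1 + 0.5) / 2 - 0.5
    f <- pmin(pmax(floor(s), 0), n - 1)
    w <- s - f
    hi <- pmin(f + 1, n - 1)
    list(lo = f + 1, hi = hi + 1, w = w)
  }
  ix <- up1(nrow(m)); iy <- up1(ncol(m))
  a <- m[ix$lo, iy$lo]; b <- m[ix$hi, iy$lo]
  c_ <- m[ix$lo, iy$hi]; d <- m[ix$hi, iy$hi]
  wx <- matrix(ix$w, 2 * nrow(m), 2 * ncol(m))
  wy <- matrix(iy$w, 2 * nrow(m), 2 * ncol(m), byrow = TRUE)
  (1 - wx) * (1 - wy) * a + wx * (1 - wy) * b + (1 - wx) * wy * c_ + wx * wy * d
}

#' Tile-based max/mean ADC ratio map of the edema on one slice
#'
#' Partitions the selected slice into non-overlapping square tiles of
#' `tile_size` voxels per side, anchored at the corner of the edema
#' bounding box.  Fractional tile sizes (2.5) are realised exactly on a 2x
#' bilinearly upsampled grid (2.5 voxels -> 5 fine cells).  A tile is
#' evaluated iff at least 50% of its area lies inside the edema; its value
#' is the maximum ADC over its edema voxels divided by the mean ADC over
#' all edema voxels on the slice (the whole-ROI mean, under which the
#' published decision threshold is operative).  With the default
#' `below_positive` direction, tiles with value strictly below `threshold`
#' are predicted recurrence-prone.
#'
#' @param adc ADC `volume_image`.
#' @param edema_pre edema [mask_volume()] on the same grid.
#' @param slice_index 1-based axial slice, e.g. from [select_slice()].
#' @param tile_size tile side in voxels; 2, 2.5 and 3 are the standard
#'   units (others are accepted with a warning; fractional sizes must be
#'   multiples of 0.5).
#' @param threshold decision threshold on the tile ratio (default 2.408,
#'   the published ROC cutpoint).
#' @param direction `"below_positive"` (default) or `"above_positive"`.
#' @return An object of class `tile_heatmap`.
#' @export
tile_ratio_map <- function(adc, edema_pre, slice_index, tile_size = 2,
                           threshold = 2.408,
                           direction = c("below_positive", "above_positive")) {
  direction <- match.arg(direction)
  stop_if_grid_mismatch(adc, edema_pre, "ADC and edema mask")
  d <- dim(adc$data)
  stopifnot(slice_index >= 1, slice_index <= d[3])
  frac <- abs(tile_size - round(tile_size)) > 1e-9
  if (frac && abs(tile_size * 2 - round(tile_size * 2)) > 1e-9)
    stop("fractional tile sizes must be multiples of 0.5 voxels", call. = FALSE)
  if (!tile_size %in% c(2, 2.5, 3))
    warning(sprintf("non-standard tile size %.2f voxels", tile_size),
            call. = FALSE)
  sl_adc <- adc$data[, , slice_index]
  sl_ed <- edema_pre$data[, , slice_index] > 0
  if (!any(sl_ed)) stop("edema is empty on the selected slice", call. = FALSE)
  factor <- if (frac) 2L else 1L
  if (factor == 2L) {
    wa <- upsample2_bilinear(sl_adc)
    we <- upsample2_bilinear(sl_ed + 0) >= 0.5
  } else {
    wa <- sl_adc
    we <- sl_ed
  }
  k <- as.integer(round(tile_size * factor))

  idx <- which(we, arr.ind = TRUE)
  x0 <- min(idx[, 1]); x1 <- max(idx[, 1])
  y0 <- min(idx[, 2]); y1 <- max(idx[, 2])
  roi_mean <- mean(wa[we])

  tiles <- list()
  value_map <- matrix(NA_real_, nrow(wa), ncol(wa))
  pred_work <- matrix(FALSE, nrow(wa), ncol(wa))
  for (tx in seq(x0, x1, by = k)) for (ty in seq(y0, y1, by = k)) {
    xr <- tx:min(tx + k - 1L, nrow(wa))
    yr <- ty:min(ty + k - 1L, ncol(wa))
    em <- we[xr, yr, drop = FALSE]
    if (sum(em) / (k * k) < 0.5) next
    val <- max(wa[xr, yr][em]) / roi_mean
    pos <- if (direction == "below_positive") val < threshold else val > threshold
    value_map[xr, yr] <- val
    if (pos) pred_work[xr, yr] <- TRUE
    tiles[[length(tiles) + 1L]] <-
      data.frame(x = tx, y = ty, value = val, positive = pos)
  }
  if (!length(tiles))
    stop("no tile has at least half its area inside the edema", call. = FALSE)
  tiles <- do.call(rbind, tiles)

  # project the working-grid prediction back to original voxels (majority)
  if (factor == 2L) {
    fold <- function(m) {
      (m[seq(1, nrow(m), 2), seq(1, ncol(m), 2)] +
       m[seq(2, nrow(m), 2), seq(1, ncol(m), 2)] +
       m[seq(1, nrow(m), 2), seq(2, ncol(m), 2)] +
       m[seq(2, nrow(m), 2), seq(2, ncol(m), 2)]) / 4
    }
    pred_orig <- fold(pred_work + 0) >= 0.5
  } else {
    pred_orig <- pred_work
  }

  structure(list(slice_index = slice_index, tile_size = tile_size,
                 factor = factor, threshold = threshold,
                 direction = direction, tiles = tiles,
                 roi_mean = roi_mean, value_map = value_map,
                 predicted_work = pred_work, predicted_mask = pred_orig,
                 edema_slice = sl_ed, grid = vol_grid(adc)),
            class = "tile_heatmap")
}

#' @export
print.tile_heatmap <- function(x, ...) {
  cat(sprintf("<tile_heatmap> slice %d, %.1f-voxel tiles: %d evaluated, %d predicted positive (threshold %.3f, %s)\n",
              x$slice_index, x$tile_size, nrow(x$tiles), sum(x$tiles$positive),
              x$threshold, x$direction))
  invisible(x)
}

#' Score a tile prediction against the true recurrence region
#'
#' Restricted to edema voxels on the heatmap's slice:
#' `voxel_accuracy = (TP + TN) / total` and
#' `dice = 2 TP / (2 TP + FP + FN)`, with recurrence as the positive
#' class.  Edema voxels in non-evaluated tiles count as predicted
#' negative.
#'
#' @param heatmap a [tile_ratio_map()] result.
#' @param truth_rec ground-truth recurrence [mask_volume()] on the
#'   heatmap's grid (e.g. a phantom's `truth_infiltration`).
#' @param edema_pre edema mask on the same grid.
#' @return list with `voxel_accuracy`, `dice`, `tp`, `fp`, `fn`, `tn`.
#' @export
evaluate_prediction <- function(heatmap, truth_rec, edema_pre) {
  stopifnot(inherits(heatmap, "tile_heatmap"))
  if (!same_grid(vol_grid(truth_rec), heatmap$grid) ||
      !same_grid(vol_grid(edema_pre), heatmap$grid))
    stop("masks are not on the heatmap's grid", call. = FALSE)
  ed <- edema_pre$data[, , heatmap$slice_index] > 0
  tr <- truth_rec$data[, , heatmap$slice_index] > 0
  pred <- heatmap$predicted_mask
  p <- pred[ed]; t <- tr[ed]
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  list(voxel_accuracy = (tp + tn) / length(p),
       dice = if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn),
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Render a tile heatmap over the anatomical slice
#'
#' Writes a deterministic PNG: the grayscale background slice with tile
#' ratio values colour-mapped (viridis) and alpha-blended on top.
#' Rendering the same heatmap twice yields byte-identical files.
#'
#' @param heatmap a [tile_ratio_map()] result.
#' @param background `volume_image` supplying the background slice
#'   (typically the ADC map itself).
#' @param path output PNG path.
#' @param alpha overlay opacity in `[0, 1]`.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(heatmap, background, path, alpha = 0.45) {
  stopifnot(inherits(heatmap, "tile_heatmap"))
  bg <- background$data[, , heatmap$slice_index]
  rng <- range(bg)
  bgn <- if (diff(rng) > 0) (bg - rng[1]) / diff(rng) else bg * 0
  if (heatmap$factor == 2L) bgn <- upsample2_bilinear(bgn)

  vm <- heatmap$value_map
  img <- array(rep(bgn, 3), dim = c(nrow(bgn), ncol(bgn), 3))
  ev <- !is.na(vm)
  if (any(ev)) {
    v <- vm[ev]
    vr <- range(v)
    vn <- if (diff(vr) > 0) (v - vr[1]) / diff(vr) else v * 0
    pal <- grDevices::hcl.colors(256, "viridis")
    cols <- grDevices::col2rgb(pal[pmin(255, floor(vn * 255)) + 1]) / 255
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[ev] <- (1 - alpha) * plane[ev] + alpha * cols[ch, ]
      img[, , ch] <- plane
    }
  }
  # image rows run top-to-bottom; flip the y axis for display orientation
  png::writePNG(aperm(img[, ncol(bgn):1, , drop = FALSE], c(2, 1, 3)), path)
  invisible(path)
}

#' Predicted-mask NIfTI export of a tile heatmap
#'
#' Returns (and optionally writes) the predicted recurrence-prone mask as
#' a full-volume labelmap that is zero outside the heatmap's slice.
#'
#' @param heatmap a [tile_ratio_map()] result.
#' @param path optional NIfTI output path.
#' @return A [mask_volume()].
#' @export
heatmap_mask <- function(heatmap, path = NULL) {
  g <- heatmap$grid
  m <- array(0, g$dim)
  m[, , heatmap$slice_index] <- heatmap$predicted_mask + 0
  mv <- mask_volume(m, g$spacing, g$origin, g$direction)
  if (!is.null(path)) write_volume(mv, path)
  mv
}
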