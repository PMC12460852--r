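#' Names of the per-region ADC histogram features
#'
#' The eight first-order statistics computed for each region of interest:
#' mean, standard deviation, maximum, minimum, median, skewness, kurtosis,
#' and the max/mean ratio (`ratio_maxi_mean`), the discriminative statistic
#' of the recurrence-location model.
#'
#' @return character vector of length 8.
#' @export
adc_feature_names <- function() {
  c("meanADC", "stdmeanADC", "maxiADC", "miniADC", "medianADC",
    "skewnessADC", "kurtosisADC", "ratio_maxi_mean")
}

#' First-order histogram features of a region of interest
#'
#' Computes the eight ADC histogram parameters over the voxels of `volume`
#' selected by `mask`:
#' * `meanADC`: arithmetic mean;
#' * `stdmeanADC`: sample standard deviation (n-1 denominator);
#' * `maxiADC` / `miniADC`: extremes;
#' * `medianADC`: median (average of the middle order statistics for even n);
#' * `skewnessADC`: `g1 = m3 / m2^(3/2)` with central sample moments `m_k`;
#' * `kurtosisADC`: `m4 / m2^2` (non-excess by default; subtract 3 via
#'   `excess_kurtosis = TRUE`);
#' * `ratio_maxi_mean`: `maxiADC / meanADC`.
#'
#' Skewness and kurtosis are reported as `NA` (missing, not 0) when fewer
#' than 3 voxels are available or when `m2 = 0`.
#'
#' @param volume a `volume_image` (typically the ADC map on the analysis
#'   grid).
#' @param mask a nonempty [mask_volume()] on the same grid.
#' @param excess_kurtosis if `TRUE`, report kurtosis minus 3.
#' @return A named list of class `histogram_features`.
#' @export
extract_features <- function(volume, mask, excess_kurtosis = FALSE) {
  stopifnot(inherits(volume, "volume_image"), inherits(mask, "mask_volume"))
  stop_if_grid_mismatch(volume, mask, "volume and mask")
  x <- volume$data[mask$data > 0]
  if (length(x) == 0) stop("mask selects no voxels", call. = FALSE)
  if (any(!is.finite(x))) stop("masked values must all be finite", call. = FALSE)
  n <- length(x)
  if (n < 2) stop("standard deviation undefined for fewer than 2 voxels",
                  call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  skew <- kurt <- NA_real_
  if (n >= 3 && m2 > 0) {
    skew <- mean((x - m)^3) / m2^1.5
    kurt <- mean((x - m)^4) / m2^2 - if (excess_kurtosis) 3 else 0
  }
  if (m == 0) stop("ROI mean is zero; max/mean ratio undefined", call. = FALSE)
  structure(list(meanADC = m, stdmeanADC = stats::sd(x), maxiADC = max(x),
                 miniADC = min(x), medianADC = stats::median(x),
                 skewnessADC = skew, kurtosisADC = kurt,
                 ratio_maxi_mean = max(x) / m, n_voxels = n),
            class = "histogram_features")
}

#' @export
print.histogram_features <- function(x, ...) {
  cat(sprintf("<histogram_features> n=%d mean=%.1f sd=%.1f max=%.1f min=%.1f ratio=%.3f\n",
              x$n_voxels, x$meanADC, x$stdmeanADC, x$maxiADC, x$miniADC,
              x$ratio_maxi_mean))
  invisible(x)
}

#' @export
as.data.frame.histogram_features <- function(x, ...) {
  as.data.frame(unclass(x)[adc_feature_names()])
}

#' Build the paired cohort feature table from phantom cases
#'
#' For each case the recurrent tumor mask is brought from the post grid
#' onto the pre grid (using the supplied or true registration transform),
#' the edema is partitioned with [define_subvolumes()], and the histogram
#' features of both sub-volumes are extracted from the pre-recurrence ADC
#' map.  Each case contributes one `rec` and one `no_rec` row.  Cases whose
#' recurrence misses the edema are skipped with a message (mirroring the
#' inclusion criterion that recurrence must fall at least partly within the
#' edema).
#'
#' @param cases list of [generate_phantom()] cases (or equivalent lists
#'   with the same fields).
#' @param transforms optional list of registration transforms mapping
#'   pre-grid points into each case's post space; by default the inverse of
#'   each case's true misalignment is used.
#' @param excess_kurtosis passed to [extract_features()].
#' @return A data.frame with columns `case_id`, `label`
#'   (`"rec"`/`"no_rec"`), `volume_mm3` and the eight feature columns.
#' @export
cohort_feature_table <- function(cases, transforms = NULL,
                                 excess_kurtosis = FALSE) {
  rows <- list()
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    tr <- if (is.null(transforms)) invert_rigid(cs$misalignment) else transforms[[i]]
    rec_on_pre <- transform_mask(cs$tumor_rec_native, tr, vol_grid(cs$edema_pre))
    lab <- define_subvolumes(cs$edema_pre, rec_on_pre, provenance = cs$case_id)
    if (lab$flagged_empty_rec) {
      message(sprintf("case %s: recurrence does not overlap edema; skipped",
                      cs$case_id))
      next
    }
    case_rows <- list()
    for (side in c("rec", "no_rec")) {
      m <- if (side == "rec") lab$subedema_rec else lab$subedema_no_rec
      if (sum(m$data) < 3) {
        message(sprintf("case %s: sub-volume %s too small; case skipped",
                        cs$case_id, side))
        case_rows <- NULL
        break
      }
      f <- extract_features(cs$adc_pre, m, excess_kurtosis)
      case_rows[[side]] <-
        cbind(data.frame(case_id = cs$case_id, label = side,
                         volume_mm3 = volume_mm3(m)),
              as.data.frame(f))
    }
    if (!is.null(case_rows)) rows <- c(rows, case_rows)
  }
  if (!length(rows)) stop("no usable cases in cohort", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a cohort feature table as CSV
#'
#' @param table a [cohort_feature_table()] data.frame.
#' @param path output CSV path.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
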