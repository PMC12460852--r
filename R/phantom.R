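#' Specification of a synthetic ADC phantom case
#'
#' Describes one synthetic glioblastoma case: a brain-like background, a
#' low-ADC spherical tumor core, a surrounding vasogenic edema shell, and an
#' infiltrated sub-region of that shell (one or more angular lobes) whose
#' intensity composition differs from the rest of the shell.  All ADC
#' values are in 10^-6 mm^2/s.
#'
#' The shell is a two-component mixture.  Under
#' `effect_direction = "rec_lower_ratio"` (default) the *non-infiltrated*
#' shell carries a free-water-like high-ADC admixture
#' (`edema_freewater_fraction` of voxels at `adc_freewater_mean`), while the
#' infiltrated lobes carry a small admixture of low-ADC cellular foci
#' (`infil_outlier_fraction` of voxels at
#' `infil_outlier_scale * adc_infil_mean`).  The infiltrated region then has
#' a max/mean ADC ratio *below* that of its complement, and below-threshold
#' tiles mark the recurrence-prone region.  `"rec_higher_ratio"` swaps the
#' two admixtures between regions.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing numeric length-3, mm per voxel.
#' @param adc_background_mean,adc_background_sd brain background component.
#' @param adc_tumor_mean,adc_tumor_sd tumor core component (also used for
#'   recurrent tumor at the post timepoint).
#' @param adc_edema_mean,adc_edema_sd base vasogenic edema component.
#' @param adc_infil_mean,adc_infil_sd base infiltrated-edema component.
#' @param adc_freewater_mean mean of the free-water-like high-ADC admixture.
#' @param edema_freewater_fraction proportion in `[0,1)` of shell voxels
#'   drawn from the high-ADC admixture.
#' @param infil_outlier_fraction proportion in `[0,1)` of infiltrated voxels
#'   drawn from the outlier (cellular-focus) component.
#' @param infil_outlier_scale multiplicative factor (> 0) applied to
#'   `adc_infil_mean` for the outlier component; values below 1 give
#'   restricted-diffusion foci.
#' @param effect_direction `"rec_lower_ratio"` or `"rec_higher_ratio"`.
#' @param tumor_radius_mm,edema_thickness_mm sphere radius and shell
#'   thickness in mm.
#' @param infil_angular_fraction fraction in `[0,1]` of the shell's azimuth
#'   occupied by infiltration, split equally over `infil_lobes` lobes.
#' @param infil_lobes number of angular infiltration lobes.
#' @param wedge_rotation_deg azimuthal orientation of the lobes (degrees).
#' @param center_offset_mm length-3 offset of the lesion centre from the
#'   grid centre (mm).
#' @param misalignment a [rigid_transform()] mapping post-timepoint points
#'   into pre-timepoint space (the simulated inter-scan misalignment), or
#'   `NULL` for the default 3 degrees about z plus 2 mm translation.
#' @param seed integer RNG seed; identical (spec, seed) pairs give
#'   bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 32L), spacing = c(2, 2, 2),
                         adc_background_mean = 750, adc_background_sd = 50,
                         adc_tumor_mean = 600, adc_tumor_sd = 80,
                         adc_edema_mean = 1500, adc_edema_sd = 150,
                         adc_infil_mean = 1250, adc_infil_sd = 200,
                         adc_freewater_mean = 8400,
                         edema_freewater_fraction = 0.55,
                         infil_outlier_fraction = 0.10,
                         infil_outlier_scale = 0.5,
                         effect_direction = c("rec_lower_ratio",
                                              "rec_higher_ratio"),
                         tumor_radius_mm = 16, edema_thickness_mm = 12,
                         infil_angular_fraction = 0.5, infil_lobes = 2L,
                         wedge_rotation_deg = 0, center_offset_mm = c(0, 0, 0),
                         misalignment = NULL, seed = 1L) {
  effect_direction <- match.arg(effect_direction)
  spec <- list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
               adc_background_mean = adc_background_mean,
               adc_background_sd = adc_background_sd,
               adc_tumor_mean = adc_tumor_mean, adc_tumor_sd = adc_tumor_sd,
               adc_edema_mean = adc_edema_mean, adc_edema_sd = adc_edema_sd,
               adc_infil_mean = adc_infil_mean, adc_infil_sd = adc_infil_sd,
               adc_freewater_mean = adc_freewater_mean,
               edema_freewater_fraction = edema_freewater_fraction,
               infil_outlier_fraction = infil_outlier_fraction,
               infil_outlier_scale = infil_outlier_scale,
               effect_direction = effect_direction,
               tumor_radius_mm = tumor_radius_mm,
               edema_thickness_mm = edema_thickness_mm,
               infil_angular_fraction = infil_angular_fraction,
               infil_lobes = as.integer(infil_lobes),
               wedge_rotation_deg = wedge_rotation_deg,
               center_offset_mm = as.numeric(center_offset_mm),
               misalignment = misalignment, seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  means <- c(s$adc_background_mean, s$adc_tumor_mean, s$adc_edema_mean,
             s$adc_infil_mean, s$adc_freewater_mean)
  sds <- c(s$adc_background_sd, s$adc_tumor_sd, s$adc_edema_sd, s$adc_infil_sd)
  if (any(means <= 0)) stop("all ADC means must be > 0", call. = FALSE)
  if (any(sds < 0)) stop("all ADC sds must be >= 0", call. = FALSE)
  if (s$infil_angular_fraction < 0 || s$infil_angular_fraction > 1)
    stop("infil_angular_fraction must lie in [0, 1]", call. = FALSE)
  for (f in c(s$infil_outlier_fraction, s$edema_freewater_fraction))
    if (f < 0 || f >= 1)
      stop("admixture fractions must lie in [0, 1)", call. = FALSE)
  if (s$infil_outlier_scale <= 0)
    stop("infil_outlier_scale must be > 0", call. = FALSE)
  if (s$infil_lobes < 1) stop("infil_lobes must be >= 1", call. = FALSE)
  if (length(s$grid_shape) != 3L || any(s$grid_shape < 8L))
    stop("grid_shape must be three axes of at least 8 voxels", call. = FALSE)
  invisible(TRUE)
}

# component draw helper: normal with exact mean when sd = 0
draw_component <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) rep(mean, n) else stats::rnorm(n, mean, sd)
}

#' Generate one synthetic phantom case
#'
#' Builds the pre-recurrence ADC and T1 volumes, the tumor and edema masks,
#' the ground-truth infiltrated sub-region, and the post-recurrence ADC
#' volume with its recurrent tumor mask on a deliberately misaligned grid.
#' The recurrent tumor equals the pre-recurrence tumor united with the
#' infiltrated sub-region, moved onto the post grid by the spec's
#' misalignment transform.
#'
#' @param spec a [phantom_spec()].
#' @param case_id identifier stored in the case.
#' @return An object of class `phantom_case` with fields `adc_pre`,
#'   `t1_pre`, `adc_post`, `tumor_pre`, `edema_pre`, `tumor_rec_native`,
#'   `truth_infiltration`, `case_id`, `misalignment` and `spec`.
#' @export
generate_phantom <- function(spec, case_id = "case_01") {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- vol_grid(list(dim = spec$grid_shape, spacing = spec$spacing,
                     origin = c(0, 0, 0), direction = diag(3)))
  half_extent <- (g$dim - 1) * g$spacing / 2
  outer_r <- spec$tumor_radius_mm + spec$edema_thickness_mm
  if (any(outer_r + abs(spec$center_offset_mm) > half_extent))
    stop(sprintf(paste0("phantom geometry does not fit inside the grid: ",
                        "outer radius %.1f mm + offset exceeds half-extent ",
                        "(%s) mm"),
                 outer_r, paste(signif(half_extent, 4), collapse = ", ")),
         call. = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  ctr <- as.numeric(voxel_to_world(g, matrix((g$dim - 1) / 2, 1))) +
    spec$center_offset_mm
  pts <- voxel_to_world(g, all_grid_indices(g))
  dx <- pts[, 1] - ctr[1]; dy <- pts[, 2] - ctr[2]; dz <- pts[, 3] - ctr[3]
  r <- sqrt(dx^2 + dy^2 + dz^2)

  tumor <- r <= spec$tumor_radius_mm
  edema <- r > spec$tumor_radius_mm & r <= outer_r
  ang <- (atan2(dy, dx) - spec$wedge_rotation_deg * pi / 180) %% (2 * pi)
  lobe_width <- 2 * pi / spec$infil_lobes
  infil <- edema & (spec$infil_angular_fraction > 0) &
    (ang %% lobe_width) < lobe_width * spec$infil_angular_fraction
  vaso <- edema & !infil

  # admixture placement by effect direction
  if (spec$effect_direction == "rec_lower_ratio") {
    vaso_mix <- list(fraction = spec$edema_freewater_fraction,
                     mean = spec$adc_freewater_mean, sd = spec$adc_edema_sd)
    infil_mix <- list(fraction = spec$infil_outlier_fraction,
                      mean = spec$infil_outlier_scale * spec$adc_infil_mean,
                      sd = spec$adc_infil_sd)
  } else {
    infil_mix <- list(fraction = spec$edema_freewater_fraction,
                      mean = spec$adc_freewater_mean, sd = spec$adc_infil_sd)
    vaso_mix <- list(fraction = spec$infil_outlier_fraction,
                     mean = spec$infil_outlier_scale * spec$adc_edema_mean,
                     sd = spec$adc_edema_sd)
  }

  mixture_draw <- function(n, base_mean, base_sd, mix) {
    vals <- draw_component(n, base_mean, base_sd)
    if (mix$fraction > 0 && n > 0) {
      hit <- stats::runif(n) < mix$fraction
      vals[hit] <- draw_component(sum(hit), mix$mean, mix$sd)
    }
    vals
  }

  nvox <- prod(g$dim)
  adc <- draw_component(nvox, spec$adc_background_mean, spec$adc_background_sd)
  adc[tumor] <- draw_component(sum(tumor), spec$adc_tumor_mean, spec$adc_tumor_sd)
  adc[vaso] <- mixture_draw(sum(vaso), spec$adc_edema_mean, spec$adc_edema_sd,
                            vaso_mix)
  adc[infil] <- mixture_draw(sum(infil), spec$adc_infil_mean, spec$adc_infil_sd,
                             infil_mix)

  t1 <- draw_component(nvox, 400, 40)
  t1[edema] <- draw_component(sum(edema), 250, 30)
  t1[tumor] <- draw_component(sum(tumor), 900, 60)

  mk_vol <- function(v, units) volume_image(array(v, g$dim), g$spacing,
                                            g$origin, g$direction, units)
  mk_mask <- function(m) mask_volume(array(as.numeric(m), g$dim), g$spacing,
                                     g$origin, g$direction)

  adc_pre <- mk_vol(adc, "ADC 1e-6 mm^2/s")
  t1_pre <- mk_vol(t1, "T1 a.u.")
  tumor_pre <- mk_mask(tumor)
  edema_pre <- mk_mask(edema)
  truth_infiltration <- mk_mask(infil)

  mis <- spec$misalignment
  if (is.null(mis))
    mis <- rigid_from_euler(c(0, 0, 3), c(2, 0, 0), center = ctr)

  # post-timepoint scene built in pre space, then moved onto the post grid
  rec_mask_pre <- tumor | infil
  adc_post_pre <- adc
  adc_post_pre[rec_mask_pre] <- draw_component(sum(rec_mask_pre),
                                               spec$adc_tumor_mean,
                                               spec$adc_tumor_sd)
  adc_post <- apply_rigid(mk_vol(adc_post_pre, "ADC 1e-6 mm^2/s"), mis, g,
                          fill = spec$adc_background_mean)
  tumor_rec_native <- transform_mask(mk_mask(rec_mask_pre), mis, g)

  structure(list(adc_pre = adc_pre, t1_pre = t1_pre, adc_post = adc_post,
                 tumor_pre = tumor_pre, edema_pre = edema_pre,
                 tumor_rec_native = tumor_rec_native,
                 truth_infiltration = truth_infiltration,
                 case_id = case_id, misalignment = mis, spec = spec),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s: %s voxels, tumor %d vox, edema %d vox (infiltrated %d)\n",
              x$case_id, paste(dim(x$adc_pre$data), collapse = "x"),
              sum(x$tumor_pre$data), sum(x$edema_pre$data),
              sum(x$truth_infiltration$data)))
  invisible(x)
}

#' Generate a seeded cohort of phantom cases
#'
#' Per-case seeds are derived deterministically from the master seed, and
#' each case receives geometric jitter: tumor radius scaled by
#' U(0.85, 1.15), lobe orientation U(0, 360) degrees, and an in-plane
#' centre offset U(-4, 4) mm per axis.
#'
#' @param n_cases number of cases (default 32, a typical single-centre
#'   recurrent-glioblastoma cohort size).
#' @param spec template [phantom_spec()]; per-case specs modify its
#'   geometry fields.
#' @param seed master seed for the cohort.
#' @return A list of [generate_phantom()] cases.
#' @export
generate_cohort <- function(n_cases = 32L, spec = phantom_spec(), seed = 1L) {
  stopifnot(n_cases >= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  case_seeds <- sample.int(.Machine$integer.max - 1L, n_cases)
  radius_jit <- stats::runif(n_cases, 0.85, 1.15)
  rot_jit <- stats::runif(n_cases, 0, 360)
  off_jit <- matrix(stats::runif(2 * n_cases, -4, 4), ncol = 2)
  lapply(seq_len(n_cases), function(i) {
    s <- unclass(spec)
    s$tumor_radius_mm <- spec$tumor_radius_mm * radius_jit[i]
    s$wedge_rotation_deg <- rot_jit[i]
    s$center_offset_mm <- c(off_jit[i, ], 0)
    s$seed <- case_seeds[i]
    s <- structure(s, class = "phantom_spec")
    validate_phantom_spec(s)
    generate_phantom(s, case_id = sprintf("case_%02d", i))
  })
}

#' Serialize a phantom spec to JSON
#'
#' The spec (including any misalignment transform, stored as its 4x4
#' homogeneous matrix plus centre) is written as plain-text JSON so that
#' phantom cohorts are reproducible from a config file.
#'
#' @param spec a [phantom_spec()].
#' @param path output JSON path.
#' @export
write_phantom_spec <- function(spec, path) {
  s <- unclass(spec)
  if (!is.null(s$misalignment)) {
    m <- s$misalignment
    s$misalignment <- list(rotation = as.numeric(m$rotation),
                           translation = m$translation, center = m$center)
  }
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  mis <- NULL
  if (!is.null(s$misalignment) && !is.null(s$misalignment$rotation))
    mis <- rigid_transform(matrix(s$misalignment$rotation, 3, 3),
                           s$misalignment$translation, s$misalignment$center)
  s$misalignment <- NULL
  args <- s[intersect(names(s), names(formals(phantom_spec)))]
  args$misalignment <- mis
  do.call(phantom_spec, args)
}
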