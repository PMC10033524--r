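#' Synthetic bladder phantom configuration
#'
#' Describes one synthetic T2-like bladder case: an ellipsoidal organ with a
#' bright fluid-filled lumen, a darker closed wall shell of a few voxels'
#' thickness, and an intermediate-intensity tumor blob attached to the inner
#' wall surface, embedded in a dark background with additive Gaussian noise.
#' Contrast ordering mimics T2-weighted MRI, where urine is hyperintense.
#'
#' `bladder_radii` are the OUTER ellipsoid semi-axes; the lumen is the outer
#' ellipsoid shrunk by `wall_thickness` on every axis. The tumor is a sphere
#' centred on the inner wall surface at in-plane angle `tumor_angle`,
#' clipped to the organ (lumen plus wall).
#'
#' For grids at least 400 voxels in-plane the whole outer ellipsoid must sit
#' inside the fixed region-of-interest window rows/cols `[100, 400)` used by
#' [extract_roi()]; smaller grids (already ROI- or network-sized) only
#' require the ellipsoid to fit inside the grid.
#'
#' @param grid_shape integer triple `(rows, cols, slices)`.
#' @param bladder_center voxel triple (0-based) of the ellipsoid centre;
#'   default just above the grid centre (the organ sits upper-central).
#' @param bladder_radii outer ellipsoid semi-axes in voxels; the default
#'   scales with the grid (about 1/6 of the in-plane extent, reproducing the
#'   usual bladder-to-field proportion on a 512-voxel matrix).
#' @param wall_thickness wall shell thickness in voxels (>= 1); default a
#'   few voxels, scaled down for small grids.
#' @param tumor_radius tumor sphere radius in voxels (>= 1).
#' @param tumor_angle in-plane angle (radians) locating the tumor on the wall.
#' @param intensity_lumen,intensity_wall,intensity_tumor,intensity_background
#'   mean region intensities (arbitrary units).
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed integer seed; generation is a pure function of (config, seed).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(512, 512, 32),
                           bladder_center = NULL,
                           bladder_radii = NULL,
                           wall_thickness = NULL,
                           tumor_radius = NULL,
                           tumor_angle = pi / 4,
                           intensity_lumen = 1000,
                           intensity_wall = 300,
                           intensity_tumor = 600,
                           intensity_background = 100,
                           noise_sd = 30,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  # geometry defaults scale with the grid; on the 512 x 512 x 32 default
  # grid they give centre (245, 245, 15) and radii (85, 95, 12)
  if (is.null(bladder_center))
    bladder_center <- round(grid_shape * c(0.4785, 0.4785, 0.4688))
  if (is.null(bladder_radii))
    bladder_radii <- pmax(round(grid_shape * c(0.166, 0.1855, 0.375)), 3)
  if (is.null(wall_thickness))
    wall_thickness <- max(2, round(grid_shape[1] / 128))
  if (is.null(tumor_radius))
    tumor_radius <- max(wall_thickness + 2, round(grid_shape[1] * 0.0234))
  cfg <- list(grid_shape = grid_shape,
              bladder_center = as.numeric(bladder_center),
              bladder_radii = as.numeric(bladder_radii),
              wall_thickness = as.numeric(wall_thickness),
              tumor_radius = as.numeric(tumor_radius),
              tumor_angle = as.numeric(tumor_angle),
              intensity_lumen = intensity_lumen,
              intensity_wall = intensity_wall,
              intensity_tumor = intensity_tumor,
              intensity_background = intensity_background,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  with(cfg, {
    if (length(grid_shape) != 3L || any(grid_shape < 1L))
      stop("grid_shape must be three positive integers")
    if (wall_thickness < 1) stop("wall_thickness must be >= 1 voxel")
    if (tumor_radius < 1) stop("tumor_radius must be >= 1 voxel")
    if (any(bladder_radii <= wall_thickness))
      stop("bladder_radii must exceed wall_thickness on every axis")
    lo <- bladder_center - bladder_radii
    hi <- bladder_center + bladder_radii
    if (any(lo < 0) || any(hi > grid_shape - 1))
      stop("outer ellipsoid does not fit inside grid_shape")
    # the fixed ROI crop must capture the organ on ROI-capable grids
    if (all(grid_shape[1:2] >= 400L)) {
      if (any(lo[1:2] < 100) || any(hi[1:2] >= 400))
        stop("bladder must lie inside the in-plane window [100, 400) so the fixed ROI crop captures it")
    }
  })
  invisible(cfg)
}

ellipsoid_mask <- function(grid_shape, center, radii) {
  r <- (seq_len(grid_shape[1]) - 1 - center[1]) / radii[1]
  c_ <- (seq_len(grid_shape[2]) - 1 - center[2]) / radii[2]
  s <- (seq_len(grid_shape[3]) - 1 - center[3]) / radii[3]
  d2 <- outer(outer(r^2, c_^2, `+`), s^2, `+`)
  array(d2 <= 1, grid_shape)
}

sphere_mask <- function(grid_shape, center, radius) {
  ellipsoid_mask(grid_shape, center, rep(radius, 3))
}

#' Generate one synthetic bladder case
#'
#' Builds the intensity volume and the two binary masks from a
#' [phantom_config()]. The wall mask is the closed ellipsoidal shell (outer
#' minus inner ellipsoid), the tumor mask a wall-attached sphere clipped to
#' the organ; tumor voxels are removed from the wall mask so the two are
#' disjoint. With `noise_sd = 0` the intensity volume is piecewise constant
#' over the four regions.
#'
#' @param config a [phantom_config()].
#' @return A list with `image` ([mri_volume]) and `masks` ([mask_pair]).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  validate_phantom_config(config)
  gs <- config$grid_shape
  outer_e <- ellipsoid_mask(gs, config$bladder_center, config$bladder_radii)
  inner_r <- config$bladder_radii - config$wall_thickness
  inner_e <- ellipsoid_mask(gs, config$bladder_center, inner_r)
  wall <- outer_e & !inner_e

  # tumor centred on the inner wall surface, in the central axial plane
  tc <- config$bladder_center +
    c(inner_r[1] * cos(config$tumor_angle), inner_r[2] * sin(config$tumor_angle), 0)
  tumor <- sphere_mask(gs, tc, config$tumor_radius) & outer_e
  if (!any(tumor & wall))
    stop("tumor does not intersect the wall shell: detached tumor configuration")
  wall <- wall & !tumor

  img <- array(config$intensity_background, gs)
  img[inner_e] <- config$intensity_lumen
  img[wall] <- config$intensity_wall
  img[tumor] <- config$intensity_tumor
  if (config$noise_sd > 0) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(config$seed)
    img <- img + array(stats::rnorm(prod(gs), 0, config$noise_sd), gs)
  }
  id <- sprintf("phantom_seed%d", config$seed)
  list(image = mri_volume(img, c(1, 1, 1), id),
       masks = mask_pair(array(as.numeric(wall), gs),
                         array(as.numeric(tumor), gs), id))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a cohort of phantom cases on disk
#'
#' Writes `n_cases` case directories (`case_001`, ...), each holding
#' `image.nrrd`, `wall.nrrd` and `tumor.nrrd`, plus a `manifest.csv` listing
#' per-case generation parameters. Geometry (radii, centre, tumor angle and
#' radius) is jittered uniformly within +/- `jitter` of the template; the
#' whole cohort is a pure function of `(config_template, seed)`.
#'
#' @param n_cases number of cases (>= 1).
#' @param config_template a [phantom_config()] used as the jitter template.
#' @param seed integer master seed for the cohort.
#' @param out_dir output directory (created if needed).
#' @param jitter relative geometry jitter (default 0.2 = +/- 20 percent).
#' @return Character vector of case directory paths, invisibly; the manifest
#'   data frame is attached as attribute `"manifest"`.
#' @export
generate_cohort <- function(n_cases, config_template = phantom_config(),
                            seed = 1L, out_dir, jitter = 0.2) {
  stopifnot(n_cases >= 1, inherits(config_template, "phantom_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create output dir '%s'", out_dir))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  rows <- vector("list", n_cases)
  dirs <- character(n_cases)
  for (i in seq_len(n_cases)) {
    cfg <- config_template
    # draw jitters in a fixed order so the manifest is reproducible
    jr <- stats::runif(3, 1 - jitter, 1 + jitter)
    jc <- stats::runif(2, -jitter, jitter)
    ang <- stats::runif(1, 0, 2 * pi)
    jt <- stats::runif(1, 1 - jitter, 1 + jitter)
    case_seed <- sample.int(.Machine$integer.max - 1L, 1)
    cfg$bladder_radii <- cfg$bladder_radii * jr
    cfg$bladder_center[1:2] <- cfg$bladder_center[1:2] +
      jc * cfg$bladder_radii[1:2]
    # clamp the jittered geometry into the legal box (grid, and the ROI
    # window on ROI-capable grids) so every drawn case is valid
    lo <- c(0, 0, 0)
    hi <- cfg$grid_shape - 1
    if (all(cfg$grid_shape[1:2] >= 400L)) {
      lo[1:2] <- 100
      hi[1:2] <- 399
    }
    cfg$bladder_radii <- pmax(
      pmin(cfg$bladder_radii, cfg$bladder_center - lo, hi - cfg$bladder_center),
      cfg$wall_thickness + 1)
    cfg$tumor_angle <- ang
    cfg$tumor_radius <- max(cfg$tumor_radius * jt, cfg$wall_thickness + 1)
    cfg$seed <- case_seed
    validate_phantom_config(cfg)
    case <- generate_phantom(cfg)
    id <- sprintf("case_%03d", i)
    case$image$case_id <- id
    case$masks$case_id <- id
    dirs[i] <- file.path(out_dir, id)
    write_case(dirs[i], case$image, case$masks)
    rows[[i]] <- data.frame(
      case_id = id, seed = case_seed,
      radius_r = cfg$bladder_radii[1], radius_c = cfg$bladder_radii[2],
      radius_s = cfg$bladder_radii[3],
      center_r = cfg$bladder_center[1], center_c = cfg$bladder_center[2],
      center_s = cfg$bladder_center[3],
      wall_thickness = cfg$wall_thickness,
      tumor_radius = cfg$tumor_radius, tumor_angle = cfg$tumor_angle,
      noise_sd = cfg$noise_sd)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  attr(dirs, "manifest") <- manifest
  invisible(dirs)
}
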