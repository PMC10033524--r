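#' Augmentation scenario
#'
#' Holds the data-multiplication parameter `na` (augmented volumes emitted
#' per original training volume) together with the transform composition.
#' The two study scenarios are:
#'
#' * `na = 10`: 3 positive rotations + 3 negative rotations (rotations 2, 4
#'   and 6 horizontally flipped) + 4 elastic volumes (2 random fields, each
#'   applied to the original and its horizontal flip);
#' * `na = 5`: 2 positive + 1 negative rotation (rotation 3 flipped) + 2
#'   elastic volumes (1 field on original and flip).
#'
#' Rotation angles are drawn fresh per original volume, uniformly from
#' `pos_angle_range` / `neg_angle_range` degrees.
#'
#' @param na augmented volumes per original; 5 and 10 are the study values.
#' @param pos_angle_range,neg_angle_range rotation ranges in degrees.
#' @param n_pos_rot,n_neg_rot,n_elastic composition counts; must sum to `na`
#'   and `n_elastic` must be even (fields apply to original + flip).
#' @param flip_assignment indices (within the `n_pos_rot + n_neg_rot`
#'   rotations, positives first) that are horizontally flipped.
#' @param elastic_alpha maximum elastic displacement in voxels.
#' @param elastic_sigma smoothness (Gaussian sigma, voxels) of the field.
#' @param seed integer seed used by [build_training_set()].
#' @return An object of class `augmentation_scenario`.
#' @export
augmentation_scenario <- function(na = 10,
                                  pos_angle_range = c(5, 10),
                                  neg_angle_range = c(-10, -5),
                                  n_pos_rot = NULL, n_neg_rot = NULL,
                                  n_elastic = NULL, flip_assignment = NULL,
                                  elastic_alpha = 3, elastic_sigma = 8,
                                  seed = 1L) {
  na <- as.integer(na)
  if (is.null(n_pos_rot)) {
    if (na == 10L) {
      n_pos_rot <- 3L; n_neg_rot <- 3L; n_elastic <- 4L
      if (is.null(flip_assignment)) flip_assignment <- c(2L, 4L, 6L)
    } else if (na == 5L) {
      n_pos_rot <- 2L; n_neg_rot <- 1L; n_elastic <- 2L
      if (is.null(flip_assignment)) flip_assignment <- 3L
    } else {
      stop(sprintf(paste0("no default composition for na = %d; give n_pos_rot, ",
                          "n_neg_rot and n_elastic explicitly"), na))
    }
  }
  if (is.null(flip_assignment)) flip_assignment <- integer(0)
  sc <- list(na = na, pos_angle_range = pos_angle_range,
             neg_angle_range = neg_angle_range,
             n_pos_rot = as.integer(n_pos_rot), n_neg_rot = as.integer(n_neg_rot),
             n_elastic = as.integer(n_elastic),
             flip_assignment = as.integer(flip_assignment),
             elastic_alpha = elastic_alpha, elastic_sigma = elastic_sigma,
             seed = as.integer(seed))
  if (sc$n_pos_rot + sc$n_neg_rot + sc$n_elastic != na)
    stop("n_pos_rot + n_neg_rot + n_elastic must equal na")
  if (sc$n_elastic %% 2L != 0L)
    stop("n_elastic must be even (each field is applied to original and flip)")
  if (length(sc$flip_assignment) &&
      any(sc$flip_assignment < 1L | sc$flip_assignment > sc$n_pos_rot + sc$n_neg_rot))
    stop("flip_assignment indices must address the rotated copies")
  class(sc) <- "augmentation_scenario"
  sc
}

flip_horizontal <- function(vol) {
  vol[, rev(seq_len(dim(vol)[2])), , drop = FALSE]
}

#' Rotate a case in-plane (optionally flipped)
#'
#' Rotates image and labels about the slice axis by `angle_deg` around the
#' in-plane centre, the image with trilinear interpolation and the labels
#' with nearest-neighbour (label set preserved). The optional horizontal
#' flip (mirror along the column axis) is applied after the rotation. The
#' same geometric transform is used for both arrays.
#'
#' @param image numeric 3D array.
#' @param labels label 3D array aligned with `image`.
#' @param angle_deg rotation angle in degrees (0 gives the identity).
#' @param flip logical, horizontal flip after rotation.
#' @return List with rotated `image` and `labels`.
#' @export
rotate_case <- function(image, labels, angle_deg, flip = FALSE) {
  d <- dim(image)
  if (!identical(d, dim(labels))) stop("image and labels shapes disagree")
  theta <- angle_deg * pi / 180
  r0 <- (d[1] - 1) / 2
  c0 <- (d[2] - 1) / 2
  rr <- seq_len(d[1]) - 1 - r0
  cc <- seq_len(d[2]) - 1 - c0
  if (flip) cc <- rev(cc)
  # inverse mapping: target voxel looks up its source location
  sr <- r0 + outer(rr, cc, function(a, b) cos(theta) * a + sin(theta) * b)
  sc <- c0 + outer(rr, cc, function(a, b) -sin(theta) * a + cos(theta) * b)
  cr <- array(sr, d)
  cgc <- array(sc, d)
  cs <- array(rep(seq_len(d[3]) - 1, each = d[1] * d[2]), d)
  img <- array(warp_cpp(as.double(image), as.integer(d),
                        as.double(cr), as.double(cgc), as.double(cs), FALSE), d)
  lab <- array(warp_cpp(as.double(labels), as.integer(d),
                        as.double(cr), as.double(cgc), as.double(cs), TRUE), d)
  list(image = img, labels = lab)
}

#' Elastic deformation of a case
#'
#' Warps image and labels with one smooth random in-plane displacement
#' field: uniform noise, Gaussian-smoothed in 3D with `sigma`, normalised to
#' unit maximum and scaled by `alpha` (so `alpha` is the maximum displacement
#' in voxels; `alpha = 0` is the identity). The same field warps image
#' (trilinear) and labels (nearest-neighbour). Displacements are drawn from
#' the current RNG state unless a precomputed `field` is given.
#'
#' @param image,labels aligned 3D arrays.
#' @param alpha maximum displacement in voxels.
#' @param sigma field smoothness (Gaussian sigma in voxels).
#' @param field optional list `(dr, dc)` of displacement arrays to reuse.
#' @return List with `image`, `labels` and the `field` used.
#' @export
elastic_case <- function(image, labels, alpha = 3, sigma = 8, field = NULL) {
  d <- dim(image)
  if (!identical(d, dim(labels))) stop("image and labels shapes disagree")
  if (alpha < 0 || sigma <= 0) stop("elastic parameters must be positive")
  if (is.null(field)) field <- elastic_field(d, alpha, sigma)
  base_r <- array(rep(seq_len(d[1]) - 1, times = d[2] * d[3]), d)
  base_c <- array(rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]), d)
  base_s <- array(rep(seq_len(d[3]) - 1, each = d[1] * d[2]), d)
  cr <- base_r + field$dr
  cc <- base_c + field$dc
  img <- array(warp_cpp(as.double(image), as.integer(d),
                        as.double(cr), as.double(cc), as.double(base_s), FALSE), d)
  lab <- array(warp_cpp(as.double(labels), as.integer(d),
                        as.double(cr), as.double(cc), as.double(base_s), TRUE), d)
  list(image = img, labels = lab, field = field)
}

elastic_field <- function(d, alpha, sigma) {
  draw <- function() {
    noise <- array(stats::runif(prod(d), -1, 1), d)
    sm <- array(gauss_smooth3_cpp(as.double(noise), as.integer(d), sigma), d)
    m <- max(abs(sm))
    if (m == 0 || alpha == 0) array(0, d) else sm / m * alpha
  }
  list(dr = draw(), dc = draw())
}

#' Generate the `na` augmented copies of one case
#'
#' Applies the scenario's composition: rotations with angles drawn fresh
#' from the configured ranges (flips per `flip_assignment`), then the
#' elastic fields, each applied to the original and its horizontal flip.
#' Angles and fields are drawn from the current RNG state, so seed the RNG
#' (or use [build_training_set()]) for reproducibility.
#'
#' @param image,labels one preprocessed case.
#' @param scenario an [augmentation_scenario()].
#' @return List of `na` elements, each `list(image, labels, transform)`.
#' @export
augment_case <- function(image, labels, scenario) {
  stopifnot(inherits(scenario, "augmentation_scenario"))
  out <- vector("list", scenario$na)
  k <- 0L
  angles <- c(
    stats::runif(scenario$n_pos_rot, scenario$pos_angle_range[1],
                 scenario$pos_angle_range[2]),
    stats::runif(scenario$n_neg_rot, scenario$neg_angle_range[1],
                 scenario$neg_angle_range[2]))
  for (i in seq_along(angles)) {
    flip <- i %in% scenario$flip_assignment
    rc <- rotate_case(image, labels, angles[i], flip)
    k <- k + 1L
    out[[k]] <- list(image = rc$image, labels = rc$labels,
                     transform = sprintf("rotate%+.2f%s", angles[i],
                                         if (flip) "+flip" else ""))
  }
  n_fields <- scenario$n_elastic %/% 2L
  for (f in seq_len(n_fields)) {
    field <- elastic_field(dim(image), scenario$elastic_alpha,
                           scenario$elastic_sigma)
    ec <- elastic_case(image, labels, scenario$elastic_alpha,
                       scenario$elastic_sigma, field = field)
    k <- k + 1L
    out[[k]] <- list(image = ec$image, labels = ec$labels,
                     transform = sprintf("elastic%d", f))
    fi <- flip_horizontal(image)
    fl <- flip_horizontal(labels)
    ec2 <- elastic_case(fi, fl, scenario$elastic_alpha,
                        scenario$elastic_sigma, field = field)
    k <- k + 1L
    out[[k]] <- list(image = ec2$image, labels = ec2$labels,
                     transform = sprintf("elastic%d+flip", f))
  }
  out
}

#' Build the augmented training and validation sets
#'
#' Training set = the originals plus `na` augmentations per case (so `x`
#' originals yield `x + x * na` training volumes); validation set = one
#' additional, independently drawn augmentation per case (a fresh random
#' rotation). Train and validation share no augmented volume. The whole
#' output is a pure function of `(cases, scenario$seed)`.
#'
#' @param cases list of preprocessed cases, each `list(image, labels)` with
#'   an optional `case_id`.
#' @param scenario an [augmentation_scenario()].
#' @return List with `train` and `val` (lists of `list(image, labels,
#'   case_id, transform)`) and a `manifest` data frame.
#' @export
build_training_set <- function(cases, scenario) {
  if (length(cases) < 1L) stop("at least one case is required")
  stopifnot(inherits(scenario, "augmentation_scenario"))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(scenario$seed)
  train <- list()
  val <- list()
  rows <- list()
  for (ci in seq_along(cases)) {
    case <- cases[[ci]]
    id <- case$case_id %||% sprintf("case_%03d", ci)
    train[[length(train) + 1L]] <-
      list(image = case$image, labels = case$labels, case_id = id,
           transform = "original")
    rows[[length(rows) + 1L]] <- data.frame(set = "train", case_id = id,
                                            transform = "original")
    aug <- augment_case(case$image, case$labels, scenario)
    for (a in aug) {
      train[[length(train) + 1L]] <-
        list(image = a$image, labels = a$labels, case_id = id,
             transform = a$transform)
      rows[[length(rows) + 1L]] <- data.frame(set = "train", case_id = id,
                                              transform = a$transform)
    }
    # one fresh augmentation per case for validation
    sign_pos <- stats::runif(1) < 0.5
    ang <- if (sign_pos)
      stats::runif(1, scenario$pos_angle_range[1], scenario$pos_angle_range[2])
    else
      stats::runif(1, scenario$neg_angle_range[1], scenario$neg_angle_range[2])
    vc <- rotate_case(case$image, case$labels, ang, flip = FALSE)
    val[[length(val) + 1L]] <-
      list(image = vc$image, labels = vc$labels, case_id = id,
           transform = sprintf("val_rotate%+.2f", ang))
    rows[[length(rows) + 1L]] <- data.frame(set = "val", case_id = id,
                                            transform = sprintf("val_rotate%+.2f", ang))
  }
  list(train = train, val = val, manifest = do.call(rbind, rows))
}
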