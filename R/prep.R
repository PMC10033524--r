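#' Extract the fixed bladder region of interest
#'
#' Crops the fixed in-plane window rows/cols `[100, 400)` (0-based,
#' half-open), where the bladder sits in this acquisition protocol, and
#' brings the slice axis to `target_slices`: deeper volumes are
#' centre-cropped, shallower ones zero-padded symmetrically (extra voxel at
#' the end when the difference is odd).
#'
#' @param volume numeric 3D array with at least 400 rows and 400 cols.
#' @param roi in-plane window as `(row_start, row_end, col_start, col_end)`,
#'   0-based half-open; default `c(100, 400, 100, 400)`.
#' @param target_slices output slice count (default 32).
#' @return A `300 x 300 x target_slices` array (for the default window).
#' @export
extract_roi <- function(volume, roi = c(100, 400, 100, 400),
                        target_slices = 32L) {
  d <- dim(volume)
  if (length(d) != 3L) stop("`volume` must be a 3D array")
  if (d[1] < roi[2] || d[2] < roi[4])
    stop(sprintf(paste0(
      "in-plane size %dx%d is smaller than the %dx%d ROI window; ",
      "resize or pad the volume upstream before ROI extraction"),
      d[1], d[2], roi[2], roi[4]))
  out <- volume[(roi[1] + 1):roi[2], (roi[3] + 1):roi[4], , drop = FALSE]
  s <- d[3]
  if (s > target_slices) {
    lo <- (s - target_slices) %/% 2
    out <- out[, , (lo + 1):(lo + target_slices), drop = FALSE]
  } else if (s < target_slices) {
    pad <- target_slices - s
    lo <- pad %/% 2
    padded <- array(0, c(dim(out)[1:2], target_slices))
    padded[, , (lo + 1):(lo + s)] <- out
    out <- padded
  }
  out
}

#' Resize a volume by interpolation
#'
#' Trilinear interpolation for intensity volumes; nearest-neighbour for masks
#' and label volumes so the label set is preserved. Used to bring the
#' `300 x 300 x 32` ROI down to the network input size `128 x 128 x 32`.
#'
#' @param volume numeric 3D array.
#' @param target integer triple, output shape (default `c(128, 128, 32)`).
#' @param is_mask logical; `TRUE` selects nearest-neighbour interpolation.
#' @return Array of shape `target`.
#' @export
resize_volume <- function(volume, target = c(128, 128, 32), is_mask = FALSE) {
  d <- dim(volume)
  if (length(d) != 3L) stop("`volume` must be a 3D array")
  target <- as.integer(target)
  if (length(target) != 3L || any(target < 1L)) stop("`target` must be three positive integers")
  if (identical(as.integer(d), target)) return(volume)
  # pixel-centre mapping: src = (t + 0.5) * in/out - 0.5
  coord <- function(axis) (seq_len(target[axis]) - 0.5) * d[axis] / target[axis] - 0.5
  cr <- array(coord(1), target)
  cc <- array(rep(coord(2), each = target[1]), target)
  cs <- array(rep(coord(3), each = target[1] * target[2]), target)
  y <- warp_cpp(as.double(volume), as.integer(d),
                as.double(cr), as.double(cc), as.double(cs), isTRUE(is_mask))
  array(y, target)
}

#' Normalize a volume to zero mean and unit standard deviation
#'
#' Per-volume standardization over all voxels. A constant volume maps to all
#' zeros (the zero standard deviation is guarded by an epsilon).
#'
#' @param volume numeric array with more than one voxel.
#' @param eps standard-deviation floor below which the volume is treated as
#'   constant.
#' @return Array of the same shape with mean ~0 and sd ~1.
#' @export
normalize_volume <- function(volume, eps = 1e-12) {
  if (length(volume) < 2L) stop("`volume` must have more than one voxel")
  mu <- mean(volume)
  sigma <- sqrt(mean((volume - mu)^2))
  if (sigma < eps) return(array(0, dim(volume)))
  (volume - mu) / sigma
}

#' Merge the wall/tumor masks into one label volume
#'
#' Produces the three-class integer label convention: 0 background, 255
#' bladder wall, 125 tumor. Voxels claimed by both masks resolve to tumor.
#'
#' @param masks a [mask_pair] (or a list with binary `wall`/`tumor` arrays).
#' @return Integer-valued array with values in `{0, 255, 125}`.
#' @export
encode_masks <- function(masks) {
  wall <- masks$wall
  tumor <- masks$tumor
  if (!identical(dim(wall), dim(tumor)))
    stop(sprintf("mask shapes disagree: wall %s vs tumor %s",
                 paste(dim(wall), collapse = "x"),
                 paste(dim(tumor), collapse = "x")))
  labels <- array(0, dim(wall))
  labels[wall != 0] <- 255
  labels[tumor != 0] <- 125  # tumor takes precedence over wall
  labels
}

label_values <- c(background = 0, wall = 255, tumor = 125)

#' One-hot encode / decode the three-class label volume
#'
#' Channel order is fixed as (background, wall, tumor); the two functions are
#' exact inverses on valid label volumes.
#'
#' @param labels array with values in `{0, 255, 125}`.
#' @return `to_onehot`: a 4D binary array `(rows, cols, slices, 3)` whose
#'   channels sum to 1 at every voxel. `from_onehot`: the label array.
#' @export
to_onehot <- function(labels) {
  bad <- !(labels %in% label_values)
  if (any(bad))
    stop(sprintf("label volume contains value(s) outside {0, 255, 125}: %s",
                 paste(unique(labels[bad])[1:min(3, sum(bad))], collapse = ", ")))
  d <- dim(labels)
  oh <- array(0, c(d, 3L))
  oh[, , , 1] <- labels == 0
  oh[, , , 2] <- labels == 255
  oh[, , , 3] <- labels == 125
  oh
}

#' @rdname to_onehot
#' @param channels 4D array `(rows, cols, slices, 3)`; per-voxel argmax is
#'   taken, so soft probability maps are also accepted.
#' @export
from_onehot <- function(channels) {
  d <- dim(channels)
  if (length(d) != 4L || d[4] != 3L)
    stop("`channels` must be a (rows, cols, slices, 3) array")
  p1 <- channels[, , , 1]; p2 <- channels[, , , 2]; p3 <- channels[, , , 3]
  m <- pmax(p1, p2, p3)
  labels <- array(125, d[1:3])
  labels[p2 >= m] <- 255
  labels[p1 >= m] <- 0  # ties break toward the lower class index
  labels
}

#' Preprocess one case to the network input contract
#'
#' Full chain: fixed ROI extraction, resize to the network input shape,
#' intensity normalization; masks follow the same geometry (nearest
#' neighbour) and are merged into the `{0, 255, 125}` label volume.
#'
#' @param case list with `image` ([mri_volume]) and `masks` ([mask_pair]),
#'   as returned by [load_case()] or [generate_phantom()].
#' @param target network input shape (default `c(128, 128, 32)`).
#' @param roi in-plane ROI window passed to [extract_roi()]; set to `NULL`
#'   to skip ROI extraction for volumes already at ROI scale.
#' @return List with `image` (normalized array of shape `target`), `labels`
#'   (`{0,255,125}` array of shape `target`), `onehot` and `case_id`.
#' @export
preprocess_case <- function(case, target = c(128, 128, 32),
                            roi = c(100, 400, 100, 400)) {
  img <- case$image$voxels
  labels <- encode_masks(case$masks)
  if (!is.null(roi)) {
    img <- extract_roi(img, roi, target[3])
    labels <- extract_roi(labels, roi, target[3])
  }
  img <- resize_volume(img, target, is_mask = FALSE)
  labels <- resize_volume(labels, target, is_mask = TRUE)
  img <- normalize_volume(img)
  list(image = img, labels = labels, onehot = to_onehot(labels),
       case_id = case$image$case_id)
}
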