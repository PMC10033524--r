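#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` between two aligned binary masks
#' (ground truth A, prediction B), in `[0, 1]`. Two empty masks score 1
#' (perfect agreement on absence); empty versus non-empty scores 0.
#'
#' @param a,b binary (or logical) 3D masks of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("mask shapes disagree: %s vs %s",
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  a <- a != 0
  b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Bilateral filtering of a class-probability map
#'
#' Edge-preserving smoothing applied slice-wise (2D) to each class channel:
#' neighbours are weighted by spatial proximity and by probability
#' similarity, so isolated spurious responses are suppressed while large
#' coherent high-probability regions keep their interior values. Channels
#' are renormalized to sum to 1 per voxel afterwards.
#'
#' @param probs probability array `(rows, cols, slices, classes)`.
#' @param sigma_spatial spatial kernel sigma in voxels (> 0).
#' @param sigma_intensity probability-similarity sigma (> 0); wide enough by
#'   default that an isolated single-voxel response is suppressed while
#'   region boundaries (probability steps) remain sharp.
#' @return Filtered probability array of the same shape.
#' @export
bilateral_filter_probs <- function(probs, sigma_spatial = 3,
                                   sigma_intensity = 0.4) {
  if (sigma_spatial <= 0 || sigma_intensity <= 0)
    stop("bilateral filter sigmas must be positive")
  d <- dim(probs)
  if (length(d) != 4L) stop("`probs` must be a 4D (rows, cols, slices, classes) array")
  out <- probs
  for (ch in seq_len(d[4]))
    out[, , , ch] <- array(
      bilateral2d_cpp(as.double(probs[, , , ch]), d[1:3],
                      sigma_spatial, sigma_intensity), d[1:3])
  n <- prod(d[1:3])
  m <- matrix(out, n, d[4])
  m <- m / rowSums(m)
  array(m, d)
}

#' Binarize a probability map into the label convention
#'
#' Per-voxel argmax over the three class channels, ties broken toward the
#' lower class index (background < wall < tumor), emitted as the
#' `{0, 255, 125}` label convention.
#'
#' @param probs probability array `(rows, cols, slices, 3)`.
#' @return Label array with values in `{0, 255, 125}`.
#' @export
binarize_probs <- function(probs) {
  from_onehot(probs)
}

#' Post-process and segment one probability map
#'
#' The test-time chain: bilateral filter, then threshold to hard labels.
#'
#' @param model a trained [build_model()] network.
#' @param image preprocessed intensity volume matching the model input.
#' @param post apply the bilateral filter before binarization.
#' @param sigma_spatial,sigma_intensity bilateral filter parameters.
#' @return Label array with values in `{0, 255, 125}`.
#' @export
predict_case <- function(model, image, post = TRUE, sigma_spatial = 3,
                         sigma_intensity = 0.4) {
  probs <- predict(model, image)
  if (post) probs <- bilateral_filter_probs(probs, sigma_spatial, sigma_intensity)
  binarize_probs(probs)
}

#' Dice report row for one case
#'
#' Computes wall, tumor and background Dice from the per-class masks of the
#' predicted and ground-truth label volumes; the overall Dice is the
#' unweighted mean of the three.
#'
#' @param pred,truth label arrays with values in `{0, 255, 125}`.
#' @param case_id identifier for the report row.
#' @return One-row data frame: `case_id`, `wall_dice`, `tumor_dice`,
#'   `background_dice`, `overall_dice`.
#' @export
evaluate_case <- function(pred, truth, case_id = "case") {
  for (x in list(pred, truth))
    if (!all(x %in% c(0, 255, 125)))
      stop("label volume contains values outside {0, 255, 125}")
  if (!identical(dim(pred), dim(truth)))
    stop("prediction and ground truth shapes disagree")
  wall <- dice(truth == 255, pred == 255)
  tumor <- dice(truth == 125, pred == 125)
  bg <- dice(truth == 0, pred == 0)
  data.frame(case_id = case_id, wall_dice = wall, tumor_dice = tumor,
             background_dice = bg, overall_dice = mean(c(bg, wall, tumor)))
}

#' Run the architecture / augmentation experiment grid
#'
#' Trains one model per cell of `architectures x na_values x train_sizes`
#' with a fixed seed, evaluates on held-out cases, and returns per-case rows
#' plus cell-level aggregate means (the layout of the study's comparison
#' tables). The train/test split is seeded and recorded in the output.
#'
#' @param case_dirs character vector of case directories (see [load_case()]).
#' @param architectures block counts to compare (study: 4, 5, 6).
#' @param na_values augmentation scenarios to compare (study: 5, 10).
#' @param train_sizes numbers of original training volumes per cell;
#'   `NULL` uses all non-test cases.
#' @param n_test held-out test cases.
#' @param seed master seed (split, scenarios, weights, training).
#' @param target network input shape.
#' @param roi ROI window for [preprocess_case()] (`NULL` to skip).
#' @param base_filters,filter_growth model width settings.
#' @param train_cfg a [train_config()] applied to every cell.
#' @param post post-process predictions with the bilateral filter.
#' @return A list of class `experiment_result`: `results` (per-case data
#'   frame with model/na/train_size columns), `summary` (cell means),
#'   `split` (train pool and test case ids).
#' @export
run_experiment <- function(case_dirs, architectures = c(4, 5, 6),
                           na_values = c(5, 10), train_sizes = NULL,
                           n_test = 2L, seed = 1L,
                           target = c(128, 128, 32),
                           roi = c(100, 400, 100, 400),
                           base_filters = 16L, filter_growth = 2,
                           train_cfg = train_config(), post = TRUE) {
  n <- length(case_dirs)
  if (is.null(train_sizes)) train_sizes <- n - n_test
  if (max(train_sizes) + n_test > n)
    stop(sprintf(
      "insufficient cases: %d available, need %d training + %d test",
      n, max(train_sizes), n_test))
  cases <- lapply(case_dirs, function(d) {
    case <- load_case(d)
    pp <- preprocess_case(case, target = target, roi = roi)
    pp
  })
  ids <- vapply(cases, function(x) x$case_id, "")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  perm <- sample.int(n)
  test_idx <- perm[seq_len(n_test)]
  pool_idx <- perm[-seq_len(n_test)]

  rows <- list()
  cell <- 0L
  for (blocks in architectures) {
    for (na in na_values) {
      for (ts in train_sizes) {
        cell <- cell + 1L
        scen <- augmentation_scenario(na = na, seed = seed * 101L + cell)
        sets <- build_training_set(cases[pool_idx[seq_len(ts)]], scen)
        spec <- model_spec(num_blocks = blocks, base_filters = base_filters,
                           filter_growth = filter_growth,
                           input_shape = target)
        model <- build_model(spec, seed = seed * 211L + cell)
        cfg <- train_cfg
        cfg$seed <- seed * 307L + cell
        fit <- train(model, sets$train, sets$val, cfg)
        for (ti in test_idx) {
          pred <- predict_case(fit$model, cases[[ti]]$image, post = post)
          ev <- evaluate_case(pred, cases[[ti]]$labels, ids[ti])
          rows[[length(rows) + 1L]] <- cbind(
            data.frame(model = sprintf("U-Net-%d", blocks), na = na,
                       train_size = ts), ev)
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(
    results[c("overall_dice", "wall_dice", "tumor_dice", "background_dice")],
    by = results[c("model", "na", "train_size")], FUN = mean)
  structure(list(results = results, summary = summary,
                 split = list(train_pool = ids[pool_idx], test = ids[test_idx])),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
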