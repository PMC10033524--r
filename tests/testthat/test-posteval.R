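# Brute-force voxel-loop Dice used as the independent oracle.
dice_loop <- function(a, b) {
  inter <- 0L; na <- 0L; nb <- 0L
  for (i in seq_along(a)) {
    ai <- a[i] != 0
    bi <- b[i] != 0
    if (ai) na <- na + 1L
    if (bi) nb <- nb + 1L
    if (ai && bi) inter <- inter + 1L
  }
  if (na + nb == 0L) return(1)
  2 * inter / (na + nb)
}

test_that("dice matches hand counts and edge conventions", {
  # |A| = 4, |B| = 6, overlap 3 -> 0.6
  a <- array(0, c(4, 4, 1)); a[1:4, 1, 1] <- 1
  b <- array(0, c(4, 4, 1)); b[2:4, 1, 1] <- 1; b[1:3, 2, 1] <- 1
  expect_equal(dice(a, b), 2 * 3 / (4 + 6))
  # identity and disjointness
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, 1 - a), 0)
  # both empty -> 1; empty vs non-empty -> 0
  z <- array(0, c(2, 2, 2))
  expect_equal(dice(z, z), 1)
  o <- z; o[1] <- 1
  expect_equal(dice(z, o), 0)
  expect_error(dice(a, z), "disagree")
})

test_that("dice agrees with the brute-force voxel loop on random masks", {
  withr::local_seed(1)
  for (rep in 1:50) {
    a <- random_mask(c(8, 8, 4), p = stats::runif(1, 0.05, 0.6))
    b <- random_mask(c(8, 8, 4), p = stats::runif(1, 0.05, 0.6))
    expect_equal(dice(a, b), dice_loop(a, b))
  }
})

test_that("bilateral filter preserves constants and plateaus, kills spikes", {
  dims <- c(24L, 24L, 4L)
  # constant probability map is unchanged up to renormalization noise
  pc <- array(1 / 3, c(dims, 3L))
  out <- bilateral_filter_probs(pc)
  expect_lt(max(abs(out - 1 / 3)), 1e-6)

  # isolated single-voxel spike is attenuated below 0.5
  p <- array(0, c(dims, 3L))
  p[, , , 1] <- 1
  p[12, 12, 2, 1] <- 0
  p[12, 12, 2, 3] <- 1
  out <- bilateral_filter_probs(p)
  expect_lt(out[12, 12, 2, 3], 0.5)

  # a large homogeneous plateau keeps its interior
  p2 <- array(0, c(dims, 3L))
  p2[, , , 1] <- 1
  p2[6:19, 6:19, , 1] <- 0
  p2[6:19, 6:19, , 2] <- 1
  out2 <- bilateral_filter_probs(p2)
  expect_gte(min(out2[10:15, 10:15, , 2]), 0.9)

  expect_error(bilateral_filter_probs(pc, sigma_spatial = 0), "positive")
})

test_that("binarization applies argmax with ties toward the lower class", {
  p <- array(0, c(1, 1, 1, 3))
  p[1, 1, 1, ] <- c(0.1, 0.7, 0.2)
  expect_equal(as.vector(binarize_probs(p)), 255)
  p[1, 1, 1, ] <- c(1, 1, 1) / 3
  expect_equal(as.vector(binarize_probs(p)), 0)
  p[1, 1, 1, ] <- c(0.2, 0.4, 0.4)
  expect_equal(as.vector(binarize_probs(p)), 255)
  # idempotent on hard one-hot maps
  withr::local_seed(2)
  lab <- random_labels(c(6, 5, 4))
  expect_identical(binarize_probs(to_onehot(lab)), lab)
})

test_that("post-processing preserves shape and the label alphabet", {
  withr::local_seed(3)
  dims <- c(16L, 16L, 8L)
  z <- array(rnorm(prod(dims) * 3), c(dims, 3L))
  probs <- bladderseg:::softmax4(z)
  lab <- binarize_probs(bilateral_filter_probs(probs))
  expect_identical(dim(lab), dims)
  expect_true(all(lab %in% c(0, 255, 125)))
})

test_that("evaluate_case computes per-class Dice and their unweighted mean", {
  s <- small_phantom_sample(seed = 4, grid = c(32L, 32L, 8L))
  r <- evaluate_case(s$labels, s$labels, "self")
  expect_equal(unlist(r[c("wall_dice", "tumor_dice", "background_dice",
                          "overall_dice")], use.names = FALSE),
               c(1, 1, 1, 1))
  expect_identical(names(r), c("case_id", "wall_dice", "tumor_dice",
                               "background_dice", "overall_dice"))

  # all-background prediction: foreground Dice 0, overall = background/3
  pred0 <- array(0, dim(s$labels))
  r0 <- evaluate_case(pred0, s$labels)
  expect_equal(r0$wall_dice, 0)
  expect_equal(r0$tumor_dice, 0)
  expect_equal(r0$overall_dice, r0$background_dice / 3)
  expect_equal(r0$background_dice,
               dice(s$labels == 0, array(TRUE, dim(pred0))))

  expect_error(evaluate_case(pred0 + 7, s$labels), "outside")
})

test_that("run_experiment produces the grid rows and a reproducible split", {
  tmp <- withr::local_tempdir()
  tmpl <- cohort_phantom_config(grid = c(64L, 64L, 16L))
  dirs <- generate_cohort(4, tmpl, seed = 2L, out_dir = tmp)
  cfg <- train_config(max_epochs = 1, patience = 5, seed = 1)
  ex <- run_experiment(dirs, architectures = c(2, 3), na_values = 5,
                       n_test = 1, seed = 9, target = c(32, 32, 8),
                       roi = NULL, base_filters = 2, train_cfg = cfg)
  expect_equal(nrow(ex$summary), 2)  # 2 architectures x 1 scenario
  expect_equal(nrow(ex$results), 2)  # 1 test case per cell
  expect_true(all(ex$results$overall_dice >= 0 & ex$results$overall_dice <= 1))
  ex2 <- run_experiment(dirs, architectures = c(2, 3), na_values = 5,
                        n_test = 1, seed = 9, target = c(32, 32, 8),
                        roi = NULL, base_filters = 2, train_cfg = cfg)
  expect_identical(ex$split, ex2$split)
  expect_identical(ex$results, ex2$results)
  expect_error(run_experiment(dirs, architectures = 2, na_values = 5,
                              train_sizes = 10, n_test = 1, seed = 1,
                              target = c(32, 32, 8), roi = NULL,
                              base_filters = 2, train_cfg = cfg),
               "insufficient")
})
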