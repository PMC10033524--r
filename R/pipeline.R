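#' End-to-end pipeline configuration
#'
#' Bundles every stage's parameters into one serializable list: phantom
#' cohort generation, preprocessing, augmentation, model, training and
#' post-processing. One global `seed` fans out to per-stage seeds by fixed
#' offsets so stages are individually reproducible. The resolved
#' configuration is frozen (as YAML) inside every run directory, and
#' re-running a frozen configuration reproduces all manifests.
#'
#' @param out_dir parent directory for run directories.
#' @param seed global integer seed.
#' @param n_cases phantom cohort size.
#' @param n_test held-out test cases.
#' @param grid_shape phantom grid shape.
#' @param target network input shape.
#' @param roi ROI window (`NULL` to skip ROI extraction).
#' @param na augmentation scenario parameter (5 or 10).
#' @param num_blocks,base_filters,filter_growth model settings.
#' @param max_epochs,patience,learning_rate,batch_size training settings.
#' @param sigma_spatial,sigma_intensity bilateral post-processing sigmas.
#' @param stages stages to execute, in order; a run with `"train"` removed
#'   needs `checkpoint` to point at a saved model.
#' @param checkpoint optional path to a saved model (RDS) used when the
#'   train stage is skipped.
#' @param run_name optional fixed run-directory name (default: timestamped).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 42L, n_cases = 3L, n_test = 1L,
                            grid_shape = c(512L, 512L, 32L),
                            target = c(128L, 128L, 32L),
                            roi = c(100L, 400L, 100L, 400L),
                            na = 5L, num_blocks = 5L, base_filters = 16L,
                            filter_growth = 2, max_epochs = 50L,
                            patience = 15L, learning_rate = 5e-4,
                            batch_size = 1L, sigma_spatial = 3,
                            sigma_intensity = 0.4,
                            stages = c("phantom", "prep", "augment", "train",
                                       "predict", "evaluate"),
                            checkpoint = NULL, run_name = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the segmentation pipeline end to end
#'
#' Executes the configured stages in order -- phantom cohort generation,
#' preprocessing, augmentation, training, prediction and evaluation --
#' logging stage timings, and writes every artifact (cohort, manifests,
#' checkpoints, training history, Dice report, predicted label volumes)
#' under one run directory along with the frozen configuration.
#'
#' @param config a [pipeline_config()].
#' @return The run directory path, invisibly, with attribute `"results"`
#'   holding the in-memory stage outputs (dice report, history, split).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  run_name <- config$run_name %||%
    format(Sys.time(), "run_%Y%m%d_%H%M%S")
  run_dir <- file.path(config$out_dir, run_name)
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_frozen <- config
  cfg_frozen$run_name <- run_name
  yaml::write_yaml(unclass(cfg_frozen), file.path(run_dir, "config.yaml"))

  results <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    message(sprintf("[%s] starting", name))
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }

  data_dir <- file.path(run_dir, "data")
  if ("phantom" %in% config$stages) {
    dirs <- stage("phantom", {
      tmpl <- phantom_config(grid_shape = config$grid_shape)
      generate_cohort(config$n_cases, tmpl, seed = config$seed + 1L,
                      out_dir = data_dir)
    })
  } else {
    dirs <- list.dirs(data_dir, recursive = FALSE)
  }

  cases <- stage("prep", {
    pp <- lapply(dirs, function(d)
      preprocess_case(load_case(d), target = config$target, roi = config$roi))
    jsonlite::write_json(
      list(target = config$target, roi = config$roi,
           n_cases = length(pp)),
      file.path(run_dir, "prep_params.json"), auto_unbox = TRUE)
    pp
  })

  ids <- vapply(cases, function(x) x$case_id, "")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config$seed + 2L)
  perm <- sample.int(length(cases))
  test_idx <- perm[seq_len(config$n_test)]
  train_idx <- perm[-seq_len(config$n_test)]
  split <- data.frame(case_id = ids[perm],
                      set = rep(c("test", "train"),
                                c(config$n_test, length(train_idx))))
  utils::write.csv(split, file.path(run_dir, "split.csv"), row.names = FALSE)
  results$split <- split

  fit <- NULL
  if ("train" %in% config$stages) {
    sets <- stage("augment", {
      scen <- augmentation_scenario(na = config$na, seed = config$seed + 3L)
      s <- build_training_set(cases[train_idx], scen)
      utils::write.csv(s$manifest, file.path(run_dir, "augment_manifest.csv"),
                       row.names = FALSE)
      s
    })
    fit <- stage("train", {
      spec <- model_spec(num_blocks = config$num_blocks,
                         base_filters = config$base_filters,
                         filter_growth = config$filter_growth,
                         input_shape = config$target)
      model <- build_model(spec, seed = config$seed + 4L)
      cfg <- train_config(learning_rate = config$learning_rate,
                          max_epochs = config$max_epochs,
                          patience = config$patience,
                          batch_size = config$batch_size,
                          seed = config$seed + 5L,
                          checkpoint_dir = file.path(run_dir, "checkpoints"))
      f <- train(model, sets$train, sets$val, cfg)
      utils::write.csv(f$history, file.path(run_dir, "history.csv"),
                       row.names = FALSE)
      f
    })
    results$history <- fit$history
    model <- fit$model
  } else {
    if (is.null(config$checkpoint))
      stop("stage 'train' skipped but no `checkpoint` given")
    model <- readRDS(config$checkpoint)
  }

  if (any(c("predict", "evaluate") %in% config$stages)) {
    report <- stage("predict", {
      rows <- list()
      pred_dir <- file.path(run_dir, "predictions")
      dir.create(pred_dir, showWarnings = FALSE)
      for (ti in test_idx) {
        pred <- predict_case(model, cases[[ti]]$image,
                             sigma_spatial = config$sigma_spatial,
                             sigma_intensity = config$sigma_intensity)
        write_nrrd(pred, file.path(pred_dir, paste0(ids[ti], "_pred.nrrd")),
                   type = "int")
        rows[[length(rows) + 1L]] <- evaluate_case(pred, cases[[ti]]$labels,
                                                   ids[ti])
      }
      do.call(rbind, rows)
    })
    if ("evaluate" %in% config$stages) {
      utils::write.csv(report, file.path(run_dir, "dice_report.csv"),
                       row.names = FALSE)
      results$dice_report <- report
    }
  }
  attr(run_dir, "results") <- results
  invisible(run_dir)
}
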