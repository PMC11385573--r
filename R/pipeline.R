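# Two-iteration workflow driver: simulate -> plan -> train -> predict ->
# evaluate, with a structured run configuration and plain-text reports.
#
# On phantom data the ground-truth masks stand in for the human annotator:
# iteration-1 annotation masks are taken from truth at the planned indices,
# and refinement masks likewise (in production those come from manually
# correcting the model's predicted stack).

#' Resolve a run configuration
#'
#' Merges user settings (a named list, or a YAML file path) over the desk
#' defaults: phantom parameters, training configuration, annotation stride,
#' inference options, and paths.
#'
#' @param config Named list or path to a YAML file; `NULL` for defaults.
#' @param ... Named overrides applied last (e.g. `seed = 7`).
#' @return A list of class `run_config` with elements `phantom`
#'   ([phantom_params()]), `train` ([train_config()]), `step`, `holdout_policy`,
#'   `use_tta`, `out_dir`, `stack_dir`, `mask_dir`, `seed`.
#' @export
run_config <- function(config = NULL, ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  dots <- list(...)
  config[names(dots)] <- dots
  seed <- as.integer(config$seed %||% 1L)
  phantom_over <- config$phantom %||% list()
  if (is.null(phantom_over$seed)) phantom_over$seed <- seed
  train_over <- config$train %||% list()
  if (is.null(train_over$seed)) train_over$seed <- seed
  out <- list(
    phantom = do.call(phantom_params, phantom_over),
    train = do.call(train_config, train_over),
    step = as.integer(config$step %||% 10L),
    holdout_policy = config$holdout_policy %||% "simplest",
    use_tta = config$use_tta %||% TRUE,
    out_dir = config$out_dir %||% "paleoseg_run",
    stack_dir = config$stack_dir %||% NULL,
    mask_dir = config$mask_dir %||% NULL,
    seed = seed
  )
  structure(out, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

archive_config <- function(config, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ps_assert(ok, "paleoseg_io_error", "cannot create run directory %s", dir)
  serializable <- list(
    phantom = unclass(config$phantom),
    train = unclass(config$train),
    step = config$step, holdout_policy = config$holdout_policy,
    use_tta = config$use_tta, seed = config$seed
  )
  yaml::write_yaml(serializable, file.path(dir, "run_config.yaml"))
}

#' Simulate a phantom run: write stack, truth masks and negative ranges
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the generated `stack`, `masks`, the
#'   derived `negative_ranges`, and the output directory.
#' @export
cmd_simulate <- function(config = run_config()) {
  dir <- config$out_dir
  archive_config(config, dir)
  ph <- generate_phantom(config$phantom)
  write_slice_stack(ph$stack, file.path(dir, "stack"))
  write_mask_stack(ph$masks, file.path(dir, "truth"), format = "png",
                   prefix = "truth")
  neg <- derive_negative_ranges(ph$masks, config$phantom$n_slices)
  yaml::write_yaml(list(negative_ranges = lapply(neg, as.integer)),
                   file.path(dir, "negative_ranges.yaml"))
  invisible(list(stack = ph$stack, masks = ph$masks, negative_ranges = neg,
                 out_dir = dir))
}

#' Run one training iteration of the sparse-annotation workflow (in memory)
#'
#' Iteration 1 selects every `step`-th slice across the fossil-bearing
#' extent, takes annotation masks at those indices from `truth` (the phantom
#' ground truth plays the human annotator), holds out one slice by the
#' complexity policy, and trains. Iteration 2 first refines the iteration-1
#' plan by midpoint insertion (halving the stride), pulls masks for the new
#' indices from `truth` (standing in for manual correction of the predicted
#' stack), keeps the same validation slice, and retrains from scratch.
#'
#' @param stack A [slice_stack()].
#' @param truth A [mask_stack()] with full coverage (phantom ground truth).
#' @param extent `c(first, last)` fossil-bearing slice range.
#' @param step Iteration-1 annotation stride.
#' @param config A [train_config()].
#' @param iteration 1 or 2.
#' @param plan For iteration 2, the iteration-1 plan (required).
#' @param holdout_policy Validation-slice policy, see
#'   [choose_validation_slice()].
#' @return List: `plan`, `annotations`, `model`.
#' @export
pipeline_iterate <- function(stack, truth, extent, step, config,
                             iteration = 1L, plan = NULL,
                             holdout_policy = "simplest") {
  n <- n_slices(stack)
  neg <- derive_negative_ranges(truth, n)
  if (iteration == 1L) {
    idx <- select_initial_slices(extent[1], extent[2], step)
    ann <- mask_stack(stats::setNames(
      lapply(idx, function(i) get_mask(truth, i)), as.character(idx)))
    val <- choose_validation_slice(ann, holdout_policy)
    plan <- annotation_plan(idx, step = step, validation_index = val,
                            negative_ranges = neg, iteration = 1L)
  } else {
    ps_assert(!is.null(plan) && inherits(plan, "annotation_plan"),
              "paleoseg_pipeline_state_error",
              "iteration 2 requires the iteration-1 plan (missing stage: iteration 1)")
    plan <- refine_plan(plan, extent[2])
    ann <- mask_stack(stats::setNames(
      lapply(plan$annotated_indices, function(i) get_mask(truth, i)),
      as.character(plan$annotated_indices)))
  }
  model <- train(stack, ann, plan, config)
  list(plan = plan, annotations = ann, model = model)
}

#' Run a full workflow iteration and write its artifacts
#'
#' Drives plan -> train -> predict for the phantom-backed demo: generates
#' (or reuses) the phantom, runs [pipeline_iterate()], predicts the full
#' stack with the configured inference options, and writes the plan, the
#' predicted mask stack, a per-slice Dice report (CSV) and a JSON summary
#' into the run directory.
#'
#' @param config A [run_config()].
#' @param iteration 1 or 2. Iteration 2 requires the iteration-1 plan file
#'   in the run directory.
#' @return Invisibly: `plan`, `model`, `predicted`, `report` (data.frame),
#'   `summary` (list).
#' @export
cmd_iterate <- function(config = run_config(), iteration = 1L) {
  dir <- config$out_dir
  archive_config(config, dir)
  ph <- generate_phantom(config$phantom)
  ext <- phantom_extent(config$phantom)
  plan1 <- NULL
  if (iteration == 2L) {
    plan_file <- file.path(dir, "plan_iter1.yaml")
    ps_assert(file.exists(plan_file), "paleoseg_pipeline_state_error",
              "missing %s: run iteration 1 first", plan_file)
    plan1 <- read_annotation_plan(plan_file)
  }
  res <- pipeline_iterate(ph$stack, ph$masks, ext, config$step, config$train,
                          iteration = iteration, plan = plan1,
                          holdout_policy = config$holdout_policy)
  write_annotation_plan(res$plan, file.path(dir, sprintf("plan_iter%d.yaml", iteration)))
  saveRDS(res$model, file.path(dir, sprintf("model_iter%d.rds", iteration)))
  utils::write.csv(res$model$history,
                   file.path(dir, sprintf("training_log_iter%d.csv", iteration)),
                   row.names = FALSE)
  predicted <- predict_stack(res$model, ph$stack, use_tta = config$use_tta)
  write_mask_stack(predicted, file.path(dir, sprintf("predicted_iter%d", iteration)),
                   format = "png", prefix = "pred")
  report <- dice_report(predicted, ph$masks)
  utils::write.csv(report$per_slice,
                   file.path(dir, sprintf("dice_report_iter%d.csv", iteration)),
                   row.names = FALSE)
  summary <- list(iteration = iteration,
                  best_val_dice = res$model$best_val_dice,
                  best_epoch = res$model$best_epoch,
                  mean_dice = report$mean_dice,
                  pooled_dice = report$pooled_dice,
                  n_annotated = length(res$plan$annotated_indices),
                  validation_index = res$plan$validation_index,
                  seed = config$seed)
  jsonlite::write_json(summary, file.path(dir, sprintf("summary_iter%d.json", iteration)),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(plan = res$plan, model = res$model, predicted = predicted,
                 report = report$per_slice, summary = summary))
}

# Per-slice Dice table plus the two aggregates, over shared indices.
dice_report <- function(predicted, truth) {
  shared <- intersect(mask_indices(predicted), mask_indices(truth))
  ps_assert(length(shared) > 0L, "paleoseg_coverage_error",
            "predicted and reference stacks share no slice indices")
  rows <- lapply(shared, function(i) {
    d <- dice(get_mask(predicted, i), get_mask(truth, i))
    data.frame(slice = i, dice = d$value, n_intersection = d$n_intersection,
               n_pred = d$n_pred, n_ref = d$n_ref)
  })
  per_slice <- do.call(rbind, rows)
  pooled <- dice(predicted, truth)
  list(per_slice = per_slice, mean_dice = mean(per_slice$dice),
       pooled_dice = pooled$value)
}

#' Score a predicted mask stack against reference masks on disk
#'
#' Reads both stacks, scores every shared slice index, and writes a
#' per-slice CSV plus the mean and pooled aggregates.
#'
#' @param predicted_dir Directory of predicted mask images.
#' @param truth_dir Directory of reference mask images.
#' @param out_csv Optional output CSV path.
#' @return List: `per_slice` data.frame, `mean_dice`, `pooled_dice`.
#' @export
cmd_evaluate <- function(predicted_dir, truth_dir, out_csv = NULL) {
  predicted <- read_mask_stack(predicted_dir)
  truth <- read_mask_stack(truth_dir)
  rep <- dice_report(predicted, truth)
  if (!is.null(out_csv)) {
    utils::write.csv(rep$per_slice, out_csv, row.names = FALSE)
  }
  rep
}
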