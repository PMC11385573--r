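# Training: optimizer heuristics, schedule, Dice metric, BCE loss, the
# epoch loop with Dice-monitored checkpointing, and evaluation.

#' Build a training configuration
#'
#' Defaults are the desk-scale study conditions: 64-pixel crops, batches of
#' 8, 200 epochs, a two-level decoder ladder, and the production heuristics
#' unchanged — weight decay 0.01, AdamW, initial learning rate
#' `0.01 * batch_size / 256`, encoder rates reduced tenfold, a 10-epoch
#' linear warmup from zero, then cosine annealing to zero. The full-scale
#' settings (512-pixel crops, 5000 epochs, decoder channels
#' `c(512, 256, 128, 64, 32)`) are expressed through the same fields.
#'
#' @param crop_size Square training crop edge in pixels.
#' @param batch_size Crops per optimizer step.
#' @param epochs Total epochs; an epoch is one pass through the epoch
#'   schedule (one positive crop per training slice plus the negative ratio).
#' @param weight_decay Decoupled weight decay coefficient.
#' @param base_lr_coefficient,lr_divisor The learning-rate heuristic
#'   `base_lr_coefficient * batch_size / lr_divisor`.
#' @param encoder_lr_factor Multiplier on the schedule for encoder layers.
#' @param warmup_epochs Linear warmup length (must be < `epochs`).
#' @param decoder_channels Strictly decreasing integer ladder; its length is
#'   the network depth.
#' @param encoder_name Encoder identifier. `"tiny"` (the built-in compact
#'   encoder) is provided; the field exists so alternative backbones can be
#'   plugged in.
#' @param channel_mode `"1ch"` (single slice) or `"2.5d"` (slice plus both
#'   axial neighbours as three channels).
#' @param neg_crops_per_epoch Negative crops per epoch (default 2).
#' @param mixed_precision Accepted for configuration compatibility; the CPU
#'   engine computes in double precision, so this switch has no numerical
#'   effect here.
#' @param threshold Probability cutoff for binarizing predictions.
#' @param augment_fill Image fill for rotation corners; `NULL` uses each
#'   crop's median intensity (the matrix level, in practice).
#' @param seed Integer seed; every random draw in training derives from it.
#' @return A validated list of class `train_config`.
#' @export
train_config <- function(crop_size = 64L, batch_size = 8L, epochs = 200L,
                         weight_decay = 0.01, base_lr_coefficient = 0.01,
                         lr_divisor = 256, encoder_lr_factor = 0.1,
                         warmup_epochs = 10L,
                         decoder_channels = c(16L, 8L),
                         encoder_name = "tiny",
                         channel_mode = c("1ch", "2.5d"),
                         neg_crops_per_epoch = 2L,
                         mixed_precision = FALSE, threshold = 0.5,
                         augment_fill = NULL, seed = 1L) {
  channel_mode <- match.arg(channel_mode)
  cfg <- list(crop_size = as.integer(crop_size), batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), weight_decay = weight_decay,
              base_lr_coefficient = base_lr_coefficient, lr_divisor = lr_divisor,
              encoder_lr_factor = encoder_lr_factor,
              warmup_epochs = as.integer(warmup_epochs),
              decoder_channels = as.integer(decoder_channels),
              encoder_name = encoder_name, channel_mode = channel_mode,
              neg_crops_per_epoch = as.integer(neg_crops_per_epoch),
              mixed_precision = isTRUE(mixed_precision), threshold = threshold,
              augment_fill = augment_fill, seed = as.integer(seed))
  ps_assert(cfg$warmup_epochs < cfg$epochs, "paleoseg_config_error",
            "warmup_epochs must be smaller than epochs")
  ps_assert(cfg$threshold > 0 && cfg$threshold < 1, "paleoseg_config_error",
            "threshold must lie strictly inside (0, 1)")
  ps_assert(length(cfg$decoder_channels) == 1L || all(diff(cfg$decoder_channels) < 0),
            "paleoseg_config_error", "decoder_channels must be strictly decreasing")
  ps_assert(identical(cfg$encoder_name, "tiny"), "paleoseg_config_error",
            "unknown encoder '%s' (available: 'tiny')", encoder_name)
  ps_assert(cfg$batch_size >= 1L, "paleoseg_argument_error",
            "batch_size must be >= 1")
  cfg
}

#' The linear-scaling initial learning rate heuristic
#'
#' `0.01 * batch_size / 256`: e.g. batch size 8 gives 0.0003125.
#'
#' @param batch_size Crops per optimizer step.
#' @param base_lr_coefficient,lr_divisor Heuristic constants.
#' @return The initial learning rate.
#' @export
initial_learning_rate <- function(batch_size, base_lr_coefficient = 0.01,
                                  lr_divisor = 256) {
  ps_assert(is.numeric(batch_size) && length(batch_size) == 1L && batch_size >= 1,
            "paleoseg_argument_error", "batch_size must be a positive number")
  base_lr_coefficient * batch_size / lr_divisor
}

#' Learning rate at a given epoch under warmup + cosine annealing
#'
#' For epoch `e < W` (warmup): `lr0 * e / W`, starting at exactly zero. For
#' `e >= W`: `lr0 * (1 + cos(pi * (e - W) / (E - W))) / 2`, decaying along a
#' half cosine to zero. The schedule is continuous at `e = W`. Encoder
#' parameter groups receive this value times `encoder_lr_factor`.
#'
#' @param epoch 0-based epoch index in `[0, epochs)`.
#' @param config A [train_config()].
#' @return The decoder-group learning rate at that epoch.
#' @export
learning_rate_at <- function(epoch, config) {
  E <- config$epochs; W <- config$warmup_epochs
  ps_assert(is_count(epoch) && epoch >= 0 && epoch < E,
            "paleoseg_argument_error", "epoch must lie in [0, %d)", E)
  lr0 <- initial_learning_rate(config$batch_size, config$base_lr_coefficient,
                               config$lr_divisor)
  if (epoch < W) lr0 * epoch / W
  else lr0 * 0.5 * (1 + cos(pi * (epoch - W) / (E - W)))
}

#' Soerensen-Dice overlap between binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`: 1 for exact overlap, 0 for disjoint
#' non-empty masks. When both masks are entirely empty the score is defined
#' as 1 (an empty prediction of an empty slice is perfect — needed so
#' fossil-free slices can be scored). Symmetric in its arguments. Given two
#' mask stacks, counts are pooled over their shared slice indices.
#'
#' @param pred,ref 0/1 matrices of identical geometry, or two
#'   [mask_stack()]s.
#' @return A `dice_score` object: fields `value`, `n_intersection`,
#'   `n_pred`, `n_ref`.
#' @export
dice <- function(pred, ref) {
  if (inherits(pred, "mask_stack") && inherits(ref, "mask_stack")) {
    shared <- intersect(mask_indices(pred), mask_indices(ref))
    ps_assert(length(shared) > 0L, "paleoseg_coverage_error",
              "the two mask stacks share no slice indices")
    ni <- np <- nr <- 0
    for (i in shared) {
      a <- get_mask(pred, i); b <- get_mask(ref, i)
      ps_assert(all(dim(a) == dim(b)), "paleoseg_geometry_error",
                "mask geometry mismatch at slice %d", i)
      ni <- ni + sum(a & b); np <- np + sum(a); nr <- nr + sum(b)
    }
  } else {
    ps_assert(all(dim(pred) == dim(ref)), "paleoseg_geometry_error",
              "mask geometry mismatch")
    ni <- sum(pred == 1L & ref == 1L)
    np <- sum(pred == 1L); nr <- sum(ref == 1L)
  }
  value <- if (np + nr == 0) 1 else 2 * ni / (np + nr)
  structure(list(value = value, n_intersection = ni, n_pred = np, n_ref = nr),
            class = "dice_score")
}

#' @export
print.dice_score <- function(x, ...) {
  cat(sprintf("Dice %.4f (intersection %d, pred %d, ref %d)\n",
              x$value, x$n_intersection, x$n_pred, x$n_ref))
  invisible(x)
}

#' Mean binary cross-entropy of predicted probabilities
#'
#' Probabilities are clamped to `[eps, 1 - eps]` before the logarithms, so
#' confident mistakes give a large but finite loss.
#'
#' @param probabilities Numeric grid in `[0, 1]`.
#' @param targets 0/1 grid of the same geometry.
#' @param eps Clamping epsilon.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(probabilities, targets, eps = 1e-7) {
  ps_assert(all(dim(probabilities) == dim(targets)), "paleoseg_geometry_error",
            "probability/target geometry mismatch")
  p <- pmin(pmax(probabilities, eps), 1 - eps)
  -mean(targets * log(p) + (1 - targets) * log(1 - p))
}

# Extract a crop of all channels of an assembled input at a 0-based origin.
crop_channels <- function(input, origin, crop_size) {
  rows <- (origin[1] + 1L):(origin[1] + crop_size)
  cols <- (origin[2] + 1L):(origin[2] + crop_size)
  if (length(dim(input)) == 3L) input[rows, cols, , drop = FALSE]
  else input[rows, cols, drop = FALSE]
}

as_input_array <- function(x) {
  if (length(dim(x)) == 2L) array(x, c(dim(x), 1L, 1L))
  else array(x, c(dim(x)[1:2], dim(x)[3], 1L))
}

# Forward a single assembled input through a trained model (or any function
# input -> probability matrix) and return the probability matrix.
predict_prob <- function(model, input) {
  if (is.function(model)) return(model(input))
  ps_assert(inherits(model, "trained_model"), "paleoseg_argument_error",
            "model must be a trained_model or a function")
  x <- as_input_array(input)
  in_ch <- dim(x)[3]
  ps_assert(in_ch == model$net$in_channels, "paleoseg_configuration_error",
            "input has %d channel(s) but the model expects %d",
            in_ch, model$net$in_channels)
  D <- model$net$depth
  H <- dim(x)[1]; W <- dim(x)[2]
  padH <- (2^D - H %% 2^D) %% 2^D
  padW <- (2^D - W %% 2^D) %% 2^D
  if (padH > 0 || padW > 0) {
    xp <- array(0, c(H + padH, W + padW, in_ch, 1L))
    xp[seq_len(H), seq_len(W), , ] <- x
    x <- xp
  }
  z <- unet_forward(model$net, x)$logits
  p <- sigmoid(z[, , 1L, 1L])
  p[seq_len(H), seq_len(W), drop = FALSE]
}

#' Train the UNet on sparse annotations
#'
#' Runs `config$epochs` epochs. Each epoch builds a fresh schedule (one
#' positive, fossil-pixel-guaranteed crop per training slice plus
#' `neg_crops_per_epoch` negative crops from the plan's fossil-free ranges),
#' augments every crop with a random rotation and flips, and consumes the
#' shuffled schedule in batches of `batch_size`. The optimizer is AdamW with
#' decoupled weight decay and two learning-rate groups (encoder rates scaled
#' by `encoder_lr_factor`) under the warmup-plus-cosine schedule. After each
#' epoch the full held-out slice is predicted (no test-time augmentation
#' during training-time validation) and its Dice against the held-out
#' annotation is monitored; the weights achieving the best validation Dice
#' are the ones returned. Every random draw derives from `config$seed`, so
#' two runs with the same inputs and seed are bitwise identical.
#'
#' @param stack A [slice_stack()].
#' @param annotations A [mask_stack()] covering every plan index.
#' @param plan An [annotation_plan()].
#' @param config A [train_config()].
#' @return A `trained_model`: fields `net` (weights), `best_val_dice`,
#'   `best_epoch` (0-based), `config`, and `history` (a data.frame with
#'   epoch, learning rate, training loss and validation Dice).
#' @export
train <- function(stack, annotations, plan, config = train_config()) {
  ps_assert(inherits(plan, "annotation_plan"), "paleoseg_argument_error",
            "plan must be an annotation_plan")
  missing <- setdiff(plan$annotated_indices, mask_indices(annotations))
  ps_assert(length(missing) == 0L, "paleoseg_coverage_error",
            "plan indices without masks: %s", paste(missing, collapse = ", "))
  train_idx <- training_indices(plan)
  ps_assert(length(train_idx) >= 1L, "paleoseg_schedule_error",
            "plan has no training slices")
  in_ch <- if (config$channel_mode == "2.5d") 3L else 1L
  cs <- config$crop_size
  ps_assert(cs <= stack$height && cs <= stack$width, "paleoseg_geometry_error",
            "crop_size exceeds slice dimensions")

  with_seed(config$seed, {
    net <- unet_init(in_ch, config$decoder_channels)
    opt <- adamw_init(net)
    # Pre-assemble per-slice inputs once (they are reused every epoch).
    inputs <- lapply(stats::setNames(train_idx, train_idx), function(i) {
      assemble_input(stack, i, config$channel_mode)
    })
    val_input <- assemble_input(stack, plan$validation_index, config$channel_mode)
    val_mask <- get_mask(annotations, plan$validation_index)
    has_negatives <- length(plan$negative_ranges) > 0L
    if (!has_negatives && config$neg_crops_per_epoch > 0L) {
      message("no negative ranges declared; training with positive crops only")
    }
    neg_per_epoch <- if (has_negatives) config$neg_crops_per_epoch else 0L

    best_dice <- -Inf; best_epoch <- NA_integer_; best_net <- net
    history <- data.frame(epoch = integer(0), lr = numeric(0),
                          train_loss = numeric(0), val_dice = numeric(0))
    for (epoch in seq_len(config$epochs) - 1L) {
      lr <- learning_rate_at(epoch, config)
      lr_groups <- list(decoder = lr, encoder = lr * config$encoder_lr_factor)
      sched <- build_epoch(plan, neg_per_epoch)
      epoch_loss <- 0; n_batches <- 0L
      starts <- seq.int(1L, nrow(sched), by = config$batch_size)
      for (s in starts) {
        rows <- s:min(s + config$batch_size - 1L, nrow(sched))
        nb <- length(rows)
        xb <- array(0, c(cs, cs, in_ch, nb))
        yb <- array(0, c(cs, cs, 1L, nb))
        for (j in seq_len(nb)) {
          it <- sched[rows[j], ]
          if (it$kind == "positive") {
            src <- it$slice
            pair <- sample_positive_crop(get_slice(stack, src),
                                         get_mask(annotations, src), cs)
            img <- crop_channels(inputs[[as.character(src)]], pair$origin, cs)
            pair <- new_crop_pair(img, pair$mask, src, pair$origin)
          } else {
            pair <- sample_negative_crop(stack, plan$negative_ranges, cs)
            if (config$channel_mode == "2.5d") {
              img <- crop_channels(assemble_input(stack, pair$source_index, "2.5d"),
                                   pair$origin, cs)
              pair <- new_crop_pair(img, pair$mask, pair$source_index, pair$origin)
            }
          }
          pair <- augment(pair, fill = config$augment_fill)
          xb[, , , j] <- pair$image
          yb[, , 1L, j] <- pair$mask
        }
        fw <- unet_forward(net, xb, keep_cache = TRUE)
        loss <- bce_with_logits(fw$logits, yb)
        if (!is.finite(loss)) {
          ps_error("paleoseg_training_divergence_error",
                   "non-finite loss at epoch %d", epoch)
        }
        dz <- (sigmoid(fw$logits) - yb) / length(yb)
        grads <- unet_backward(net, fw$cache, dz)
        upd <- adamw_step(net, grads, opt, lr_groups, config$weight_decay)
        net <- upd$net; opt <- upd$state
        epoch_loss <- epoch_loss + loss; n_batches <- n_batches + 1L
      }
      model_now <- structure(list(net = net, config = config), class = "trained_model")
      vp <- predict_prob(model_now, val_input)
      vd <- dice(binarize(vp, config$threshold), val_mask)$value
      history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                           train_loss = epoch_loss / n_batches,
                                           val_dice = vd))
      if (vd > best_dice) {
        best_dice <- vd; best_epoch <- epoch; best_net <- net
      }
    }
    structure(
      list(net = best_net, best_val_dice = best_dice, best_epoch = best_epoch,
           config = config, history = history),
      class = "trained_model"
    )
  })
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s encoder, depth %d, best validation Dice %.4f at epoch %d/%d\n",
              x$config$encoder_name, x$net$depth, x$best_val_dice,
              x$best_epoch, x$config$epochs))
  invisible(x)
}

#' Evaluate a model against reference masks
#'
#' Predicts each requested slice at full resolution, binarizes at the
#' model's threshold, and scores it against the reference. The aggregate is
#' reported two ways: the mean of per-slice Dice values and the
#' pooled-counts Dice over all evaluated pixels.
#'
#' @param model A `trained_model` (or a function mapping an assembled input
#'   to a probability matrix, useful as an oracle).
#' @param stack A [slice_stack()].
#' @param reference A [mask_stack()] covering `indices`.
#' @param indices 0-based slice indices to evaluate.
#' @param use_tta Apply 8-fold dihedral test-time augmentation.
#' @param channel_mode Input assembly mode; defaults to the model's.
#' @param threshold Binarization cutoff; defaults to the model's.
#' @return List with `per_slice` (data.frame: slice, dice, n_intersection,
#'   n_pred, n_ref), `mean_dice`, and `pooled_dice`.
#' @export
evaluate <- function(model, stack, reference, indices, use_tta = FALSE,
                     channel_mode = NULL, threshold = NULL) {
  if (is.null(channel_mode)) {
    channel_mode <- if (is.function(model)) "1ch" else model$config$channel_mode
  }
  if (is.null(threshold)) {
    threshold <- if (is.function(model)) 0.5 else model$config$threshold
  }
  missing <- setdiff(indices, mask_indices(reference))
  ps_assert(length(missing) == 0L, "paleoseg_coverage_error",
            "no reference mask for indices: %s", paste(missing, collapse = ", "))
  rows <- vector("list", length(indices))
  ni <- np <- nr <- 0
  for (k in seq_along(indices)) {
    i <- indices[k]
    input <- assemble_input(stack, i, channel_mode)
    prob <- if (use_tta) tta_predict(model, input, slice_index = i)$probability_map
    else predict_prob(model, input)
    d <- dice(binarize(prob, threshold), get_mask(reference, i))
    rows[[k]] <- data.frame(slice = i, dice = d$value,
                            n_intersection = d$n_intersection,
                            n_pred = d$n_pred, n_ref = d$n_ref)
    ni <- ni + d$n_intersection; np <- np + d$n_pred; nr <- nr + d$n_ref
  }
  per_slice <- do.call(rbind, rows)
  list(per_slice = per_slice,
       mean_dice = mean(per_slice$dice),
       pooled_dice = if (np + nr == 0) 1 else 2 * ni / (np + nr))
}
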