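# Full-slice inference with 8-fold dihedral test-time augmentation.
#
# The eight symmetries of the square (four rotations and four reflections)
# are implemented as exact index permutations — no interpolation — so the
# realigned probability maps average without resampling blur. Variant ids:
# 0..3 are counter-clockwise rotations by 0/90/180/270 degrees; 4..7 apply a
# horizontal flip first and then the same rotations. Ids 4..7 are
# reflections, hence involutions (each is its own inverse).

apply_variant <- function(m, variant_id) {
  ps_assert(is_count(variant_id) && variant_id >= 0 && variant_id <= 7,
            "paleoseg_argument_error", "variant_id must be in 0..7")
  if (variant_id >= 4L) m <- m[, ncol(m):1, drop = FALSE]
  rot90k(m, -(variant_id %% 4L))
}

#' All eight dihedral variants of a square grid
#'
#' Returns the orbit of the input under the dihedral group of the square:
#' the four 90-degree rotations and each composed with a flip, as exact
#' index permutations. Variant 0 is the identity. A generic asymmetric grid
#' yields eight pairwise-distinct variants; a fully symmetric grid yields
#' eight identical ones.
#'
#' @param image Square numeric matrix.
#' @return List with `grids` (list of 8 matrices) and `variant_ids` (0:7).
#' @export
dihedral_variants <- function(image) {
  ps_assert(nrow(image) == ncol(image), "paleoseg_geometry_error",
            "dihedral variants require a square grid")
  list(grids = lapply(0:7, function(v) apply_variant(image, v)),
       variant_ids = 0:7)
}

#' Invert one dihedral variant
#'
#' Exact inverse permutation: `inverse_dihedral(apply variant v, v)` is the
#' identity for every v. Rotations invert to the opposite rotation; the
#' flip-composed variants are reflections and invert to themselves.
#'
#' @param grid Square numeric matrix (a transformed grid).
#' @param variant_id Integer 0..7.
#' @return The realigned matrix.
#' @export
inverse_dihedral <- function(grid, variant_id) {
  ps_assert(is_count(variant_id) && variant_id >= 0 && variant_id <= 7,
            "paleoseg_argument_error", "variant_id must be in 0..7")
  if (variant_id < 4L) {
    rot90k(grid, variant_id %% 4L)
  } else {
    apply_variant(grid, variant_id)
  }
}

#' Predict one slice with dihedral test-time augmentation
#'
#' Transforms the input by each of the 8 dihedral variants, runs the model
#' on each, inverse-transforms the probability maps back into register, and
#' averages them in probability space (averaging before thresholding). The
#' output is a convex combination of model outputs, so probabilities stay in
#' `[0, 1]` and a constant-output model is unchanged by TTA.
#'
#' @param model A `trained_model`, or a function mapping an assembled input
#'   to a probability matrix.
#' @param input Square slice input (matrix, or H x W x 3 array for 2.5D).
#' @param slice_index Optional 0-based index recorded on the result.
#' @return A `tta_prediction`: `probability_map`, `n_variants = 8`,
#'   `slice_index`.
#' @export
tta_predict <- function(model, input, slice_index = NA_integer_) {
  dims <- dim(input)
  ps_assert(dims[1] == dims[2], "paleoseg_geometry_error",
            "test-time augmentation requires a square input")
  maps <- vector("list", 8L)
  for (v in 0:7) {
    if (length(dims) == 3L) {
      xt <- input
      for (ch in seq_len(dims[3])) xt[, , ch] <- apply_variant(input[, , ch], v)
    } else {
      xt <- apply_variant(input, v)
    }
    p <- predict_prob(model, xt)
    maps[[v + 1L]] <- inverse_dihedral(p, v)
  }
  # pairwise tree sum: exact (8 * p) / 8 = p when all maps agree, so a
  # symmetry-invariant model passes through TTA bit-exactly
  avg <- (((maps[[1]] + maps[[2]]) + (maps[[3]] + maps[[4]])) +
            ((maps[[5]] + maps[[6]]) + (maps[[7]] + maps[[8]]))) / 8
  structure(list(probability_map = avg, n_variants = 8L,
                 slice_index = as.integer(slice_index)),
            class = "tta_prediction")
}

#' Threshold a probability map into a binary mask
#'
#' A pixel becomes 1 iff its probability is greater than or equal to the
#' threshold, so the positive-pixel count is non-increasing in the
#' threshold.
#'
#' @param prob_map Numeric grid in `[0, 1]`.
#' @param threshold Cutoff strictly inside `(0, 1)`.
#' @return 0/1 integer matrix.
#' @export
binarize <- function(prob_map, threshold = 0.5) {
  ps_assert(is.numeric(threshold) && length(threshold) == 1L &&
              threshold > 0 && threshold < 1,
            "paleoseg_argument_error", "threshold must lie strictly inside (0, 1)")
  matrix(as.integer(prob_map >= threshold), nrow(prob_map), ncol(prob_map))
}

#' Predict a full mask stack
#'
#' Every slice is processed at full resolution (no tiling). With TTA on,
#' slices must be square; non-square slices are handled by symmetric
#' zero-padding to a square when `pad_to_square = TRUE`, otherwise they
#' raise a geometry error.
#'
#' @param model A `trained_model` or a probability-function oracle.
#' @param stack A [slice_stack()].
#' @param channel_mode Input assembly mode; defaults to the model's
#'   configuration (`"1ch"` for function models).
#' @param threshold Binarization cutoff; defaults to the model's.
#' @param use_tta Average the 8 dihedral variants before thresholding.
#' @param pad_to_square Permit TTA on non-square slices via zero padding.
#' @param indices 0-based slice indices to predict (default: all).
#' @param prob_dir Optional directory; when given, each slice's probability
#'   map is persisted there as a 16-bit TIFF for audit.
#' @return A complete predicted [mask_stack()] over `indices`.
#' @export
predict_stack <- function(model, stack, channel_mode = NULL, threshold = NULL,
                          use_tta = TRUE, pad_to_square = FALSE,
                          indices = seq_len(n_slices(stack)) - 1L,
                          prob_dir = NULL) {
  if (!is.null(prob_dir)) {
    dir.create(prob_dir, recursive = TRUE, showWarnings = FALSE)
  }
  if (is.null(channel_mode)) {
    channel_mode <- if (is.function(model)) "1ch" else model$config$channel_mode
  }
  if (is.null(threshold)) {
    threshold <- if (is.function(model)) 0.5 else model$config$threshold
  }
  h <- stack$height; w <- stack$width
  square <- h == w
  if (use_tta && !square && !pad_to_square) {
    ps_error("paleoseg_geometry_error",
             "TTA requires square slices (%d x %d); set pad_to_square = TRUE", h, w)
  }
  masks <- stats::setNames(vector("list", length(indices)), as.character(indices))
  for (k in seq_along(indices)) {
    i <- indices[k]
    input <- assemble_input(stack, i, channel_mode)
    if (use_tta) {
      if (!square) {
        side <- max(h, w)
        top <- (side - h) %/% 2L; left <- (side - w) %/% 2L
        if (channel_mode == "2.5d") {
          padded <- array(0, c(side, side, 3L))
          padded[top + seq_len(h), left + seq_len(w), ] <- input
        } else {
          padded <- matrix(0, side, side)
          padded[top + seq_len(h), left + seq_len(w)] <- input
        }
        prob <- tta_predict(model, padded, slice_index = i)$probability_map
        prob <- prob[top + seq_len(h), left + seq_len(w), drop = FALSE]
      } else {
        prob <- tta_predict(model, input, slice_index = i)$probability_map
      }
    } else {
      prob <- predict_prob(model, input)
    }
    if (!is.null(prob_dir)) {
      tiff::writeTIFF(prob, file.path(prob_dir, sprintf("prob_%05d.tif", i)),
                      bits.per.sample = 16L)
    }
    masks[[k]] <- binarize(prob, threshold)
  }
  mask_stack(masks, height = h, width = w)
}
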