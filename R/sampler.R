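# Epoch construction: positive crops guaranteed to contain fossil pixels,
# negative crops from documented fossil-free ranges at a fixed ratio,
# geometric augmentation, and 1-channel / 2.5D input assembly.
#
# All randomness flows from R's global RNG; callers seed it once per run.

new_crop_pair <- function(image, mask, source_index, origin) {
  structure(list(image = image, mask = mask,
                 source_index = as.integer(source_index),
                 origin = as.integer(origin)),
            class = "crop_pair")
}

#' Sample a crop guaranteed to contain fossil pixels
#'
#' Picks a positive mask pixel uniformly at random, then a crop origin
#' uniformly among all origins that keep that pixel inside the crop and the
#' crop inside the slice. Every returned crop therefore contains at least one
#' positive pixel, and every fossil pixel has non-zero sampling mass. If the
#' mask is empty the crop falls back to an unconstrained uniform origin
#' (mirroring the "if available in that slice" clause of the protocol).
#'
#' @param slice Numeric matrix (one CT slice).
#' @param mask Aligned 0/1 integer matrix.
#' @param crop_size Square crop edge in pixels; must not exceed either slice
#'   dimension.
#' @return A `crop_pair` with fields `image`, `mask`, `source_index` (NA
#'   here; the trainer fills it), and 0-based `origin = c(row, col)`.
#' @export
sample_positive_crop <- function(slice, mask, crop_size) {
  h <- nrow(slice); w <- ncol(slice)
  ps_assert(crop_size >= 1 && crop_size <= h && crop_size <= w,
            "paleoseg_geometry_error",
            "crop_size %d exceeds slice dimensions %d x %d", crop_size, h, w)
  pos <- which(mask == 1L)
  if (length(pos) == 0L) {
    orow <- runif_int(1, 0L, h - crop_size)
    ocol <- runif_int(1, 0L, w - crop_size)
  } else {
    pick <- pos[runif_int(1, 1L, length(pos))]
    pr <- ((pick - 1L) %% h) + 1L       # 1-based row of the chosen pixel
    pc <- ((pick - 1L) %/% h) + 1L
    orow <- runif_int(1, max(0L, pr - crop_size), min(h - crop_size, pr - 1L))
    ocol <- runif_int(1, max(0L, pc - crop_size), min(w - crop_size, pc - 1L))
  }
  rows <- (orow + 1L):(orow + crop_size)
  cols <- (ocol + 1L):(ocol + crop_size)
  new_crop_pair(slice[rows, cols, drop = FALSE],
                mask[rows, cols, drop = FALSE],
                NA_integer_, c(orow, ocol))
}

#' Sample a crop from documented fossil-free slices
#'
#' The source slice is drawn uniformly over the union of the negative
#' ranges; the crop origin is uniform; the target mask is all zeros by
#' construction.
#'
#' @param stack A [slice_stack()].
#' @param negative_ranges Non-empty list of `[start, end)` index pairs.
#' @param crop_size Square crop edge.
#' @return A `crop_pair` with an all-zero mask.
#' @export
sample_negative_crop <- function(stack, negative_ranges, crop_size) {
  ps_assert(length(negative_ranges) > 0L, "paleoseg_sampling_error",
            "no negative ranges available")
  lens <- vapply(negative_ranges, function(r) r[2] - r[1], numeric(1))
  total <- sum(lens)
  # uniform over the union: position k in [0, total) maps through the ranges
  k <- runif_int(1, 0L, as.integer(total) - 1L)
  cum <- cumsum(lens)
  ri <- which(k < cum)[1]
  offset <- k - c(0, cum)[ri]
  src <- as.integer(negative_ranges[[ri]][1] + offset)
  slice <- get_slice(stack, src)
  h <- nrow(slice); w <- ncol(slice)
  ps_assert(crop_size <= h && crop_size <= w, "paleoseg_geometry_error",
            "crop_size %d exceeds slice dimensions", crop_size)
  orow <- runif_int(1, 0L, h - crop_size)
  ocol <- runif_int(1, 0L, w - crop_size)
  rows <- (orow + 1L):(orow + crop_size)
  cols <- (ocol + 1L):(ocol + crop_size)
  new_crop_pair(slice[rows, cols, drop = FALSE],
                matrix(0L, crop_size, crop_size),
                src, c(orow, ocol))
}

#' Build the sample schedule for one epoch
#'
#' One positive crop request per training slice (annotated minus validation)
#' plus a fixed count of negative crop requests — the negative count is a
#' constant ratio (default 2), independent of how many positive slices there
#' are — interleaved in shuffled order. An epoch is one complete pass
#' through this schedule.
#'
#' @param plan An [annotation_plan()].
#' @param neg_crops_per_epoch Number of negative crops per epoch (default 2).
#' @return A data.frame with columns `kind` (`"positive"`/`"negative"`) and
#'   `slice` (source slice for positive items, NA for negative items, whose
#'   source is drawn at sampling time).
#' @export
build_epoch <- function(plan, neg_crops_per_epoch = 2L) {
  train_idx <- training_indices(plan)
  ps_assert(length(train_idx) >= 1L, "paleoseg_schedule_error",
            "plan has no training slices (all annotated slices held out?)")
  ps_assert(is_count(neg_crops_per_epoch) && neg_crops_per_epoch >= 0,
            "paleoseg_argument_error", "neg_crops_per_epoch must be >= 0")
  sched <- data.frame(
    kind = c(rep("positive", length(train_idx)), rep("negative", neg_crops_per_epoch)),
    slice = c(train_idx, rep(NA_integer_, neg_crops_per_epoch)),
    stringsAsFactors = FALSE
  )
  sched[sample.int(nrow(sched)), , drop = FALSE]
}

#' Assemble a 1-channel or 2.5D model input for one slice
#'
#' `"1ch"` returns the slice itself; `"2.5d"` stacks the previous, current
#' and next slice as three channels, replicating the edge slice where a
#' neighbour is missing.
#'
#' @param stack A [slice_stack()].
#' @param index 0-based slice index.
#' @param channel_mode `"1ch"` or `"2.5d"`.
#' @return A matrix (`"1ch"`) or an `height x width x 3` array (`"2.5d"`).
#' @export
assemble_input <- function(stack, index, channel_mode = c("1ch", "2.5d")) {
  channel_mode <- match.arg(channel_mode)
  mid <- get_slice(stack, index)
  if (channel_mode == "1ch") return(mid)
  n <- n_slices(stack)
  prev <- if (index > 0L) get_slice(stack, index - 1L) else mid
  nxt <- if (index < n - 1L) get_slice(stack, index + 1L) else mid
  arr <- array(0, c(nrow(mid), ncol(mid), 3L))
  arr[, , 1] <- prev; arr[, , 2] <- mid; arr[, , 3] <- nxt
  arr
}

# --- geometric transforms ----------------------------------------------

# Exact quarter-turn (index permutation); k clockwise 90-degree turns.
rot90k <- function(m, k) {
  k <- ((k %% 4) + 4) %% 4
  for (i in seq_len(k)) m <- t(m[nrow(m):1, , drop = FALSE])
  m
}

# Rotate a square matrix about its centre by `angle` degrees (counter-
# clockwise in image content). Multiples of 90 use exact index permutations;
# other angles resample: bilinear for images, nearest-neighbour for masks
# (so masks stay binary). Out-of-frame samples take `fill`.
rotate_square <- function(m, angle, fill = 0, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  angle <- angle %% 360
  if (angle %% 90 == 0) return(rot90k(m, -angle / 90))
  n <- nrow(m)
  c0 <- (n + 1) / 2
  th <- angle * pi / 180
  # inverse mapping: output pixel (r, c) samples input at rotation by -angle
  rc <- expand.grid(r = seq_len(n), c = seq_len(n))
  dy <- rc$r - c0; dx <- rc$c - c0
  sr <- c0 + cos(th) * dy + sin(th) * dx
  sc <- c0 - sin(th) * dy + cos(th) * dx
  if (interp == "nearest") {
    ir <- round(sr); ic <- round(sc)
    inside <- ir >= 1 & ir <= n & ic >= 1 & ic <= n
    out <- rep(fill, n * n)
    out[inside] <- m[cbind(ir[inside], ic[inside])]
  } else {
    r0 <- floor(sr); c0i <- floor(sc)
    fr <- sr - r0; fc <- sc - c0i
    gv <- function(rr, cc) {
      inside <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
      v <- rep(fill, length(rr))
      v[inside] <- m[cbind(rr[inside], cc[inside])]
      v
    }
    out <- gv(r0, c0i) * (1 - fr) * (1 - fc) + gv(r0 + 1, c0i) * fr * (1 - fc) +
      gv(r0, c0i + 1) * (1 - fr) * fc + gv(r0 + 1, c0i + 1) * fr * fc
  }
  matrix(out, n, n)
}

apply_geom <- function(m, angle, flip_h, flip_v, fill, interp) {
  if (flip_h) m <- m[, ncol(m):1, drop = FALSE]
  if (flip_v) m <- m[nrow(m):1, , drop = FALSE]
  if (angle %% 360 != 0) m <- rotate_square(m, angle, fill = fill, interp = interp)
  m
}

#' Randomly rotate and flip a training crop
#'
#' Applies one geometric transform — a uniform rotation in `[0, 360)` degrees
#' plus independent horizontal/vertical flips — identically to the image and
#' its mask. The image is resampled bilinearly, the mask by nearest
#' neighbour so it stays binary. Regions rotated in from outside the frame
#' are filled with `fill` (defaults to the crop median, i.e. the matrix
#' level, avoiding black corners the scanner never produces). Augmentation
#' is a training-time operation only; validation and inference inputs are
#' never augmented.
#'
#' @param pair A `crop_pair` with square crops.
#' @param fill Image fill value for out-of-frame regions; `NULL` uses the
#'   median of the image crop.
#' @param angle,flip_h,flip_v Optional fixed draws (mainly for testing);
#'   `NULL` draws them from the RNG.
#' @return The transformed `crop_pair`.
#' @export
augment <- function(pair, fill = NULL, angle = NULL, flip_h = NULL, flip_v = NULL) {
  img <- pair$image
  sq_dim <- if (length(dim(img)) == 3L) dim(img)[1:2] else dim(img)
  ps_assert(sq_dim[1] == sq_dim[2], "paleoseg_geometry_error",
            "augmentation requires square crops")
  if (is.null(angle)) angle <- stats::runif(1, 0, 360)
  if (is.null(flip_h)) flip_h <- stats::runif(1) < 0.5
  if (is.null(flip_v)) flip_v <- stats::runif(1) < 0.5
  if (angle == 0 && !flip_h && !flip_v) return(pair)
  if (is.null(fill)) {
    fill <- stats::median(if (length(dim(img)) == 3L) img[, , 2] else img)
  }
  if (length(dim(img)) == 3L) {
    out <- img
    for (ch in seq_len(dim(img)[3])) {
      out[, , ch] <- apply_geom(img[, , ch], angle, flip_h, flip_v, fill, "bilinear")
    }
    img <- out
  } else {
    img <- apply_geom(img, angle, flip_h, flip_v, fill, "bilinear")
  }
  msk <- apply_geom(pair$mask, angle, flip_h, flip_v, 0L, "nearest")
  storage.mode(msk) <- "integer"
  new_crop_pair(img, msk, pair$source_index, pair$origin)
}
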