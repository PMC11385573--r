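# Sparse-annotation protocol: every-Nth-slice selection, midpoint refinement,
# validation holdout policy, and bookkeeping of fossil-free slice ranges.

#' Construct an annotation plan
#'
#' Records which slice indices carry manual masks, the current annotation
#' stride, which annotated slice is held out for validation, and which index
#' ranges are documented fossil-free (the source of negative samples).
#'
#' @param annotated_indices Integer vector of 0-based annotated slice indices.
#' @param step Current annotation stride.
#' @param validation_index Held-out slice; must be one of `annotated_indices`.
#' @param negative_ranges List of `c(start, end)` half-open `[start, end)`
#'   intervals known to contain no fossil; must be disjoint.
#' @param iteration 1 (initial) or 2 (after midpoint refinement).
#' @return An object of class `annotation_plan`.
#' @export
annotation_plan <- function(annotated_indices, step, validation_index,
                            negative_ranges = list(), iteration = 1L) {
  idx <- sort(unique(as.integer(annotated_indices)))
  ps_assert(length(idx) >= 1L, "paleoseg_argument_error",
            "a plan needs at least one annotated index")
  ps_assert(is_count(step) && step >= 1, "paleoseg_argument_error",
            "step must be a positive integer")
  validation_index <- as.integer(validation_index)
  ps_assert(validation_index %in% idx, "paleoseg_argument_error",
            "validation_index must be one of the annotated indices")
  ps_assert(iteration %in% c(1L, 2L), "paleoseg_argument_error",
            "iteration must be 1 or 2")
  if (length(negative_ranges) > 0L) {
    rr <- do.call(rbind, lapply(negative_ranges, as.integer))
    ps_assert(ncol(rr) == 2L && all(rr[, 1] < rr[, 2]),
              "paleoseg_argument_error", "negative ranges must be [start, end) with start < end")
    o <- order(rr[, 1])
    rr <- rr[o, , drop = FALSE]
    if (nrow(rr) > 1L) {
      ps_assert(all(rr[-1, 1] >= rr[-nrow(rr), 2]), "paleoseg_argument_error",
                "negative ranges must be disjoint")
    }
    negative_ranges <- lapply(seq_len(nrow(rr)), function(i) rr[i, ])
  }
  structure(
    list(annotated_indices = idx, step = as.integer(step),
         validation_index = validation_index,
         negative_ranges = negative_ranges, iteration = as.integer(iteration)),
    class = "annotation_plan"
  )
}

#' @export
print.annotation_plan <- function(x, ...) {
  cat(sprintf("<annotation_plan> iteration %d, step %d, %d annotated slices, validation slice %d, %d negative ranges\n",
              x$iteration, x$step, length(x$annotated_indices),
              x$validation_index, length(x$negative_ranges)))
  invisible(x)
}

#' Training slice indices of a plan
#' @param plan An [annotation_plan()].
#' @return Annotated indices minus the validation slice.
#' @export
training_indices <- function(plan) {
  setdiff(plan$annotated_indices, plan$validation_index)
}

#' Select the initial every-Nth annotation slices
#'
#' Returns `extent_start, extent_start + step, ...` up to `extent_end`
#' (inclusive), i.e. `floor((extent_end - extent_start) / step) + 1` indices.
#'
#' @param extent_start,extent_end First and last (inclusive) slice index of
#'   the visible fossil-bearing extent. The extent is an explicit input — in
#'   practice it comes from human inspection of the stack.
#' @param step Annotation stride (e.g. 200 for "every 200th slice").
#' @return Ordered integer vector of slice indices.
#' @export
select_initial_slices <- function(extent_start, extent_end, step) {
  ps_assert(is_count(extent_start) && is_count(extent_end) &&
              extent_start <= extent_end,
            "paleoseg_argument_error", "need extent_start <= extent_end")
  ps_assert(is_count(step) && step >= 1, "paleoseg_argument_error",
            "step must be a positive integer")
  seq.int(as.integer(extent_start), as.integer(extent_end), by = as.integer(step))
}

#' Refine a plan by midpoint insertion
#'
#' Inserts the midpoints of consecutive annotated pairs and extends the
#' halved-stride grid up to `extent_end`, so the refined set equals
#' `select_initial_slices(start, extent_end, step / 2)`. Refinement is
#' additive (all iteration-1 indices are retained) and the validation slice
#' is preserved.
#'
#' @param plan An iteration-1 [annotation_plan()].
#' @param extent_end Last slice index (inclusive) of the visible extent; must
#'   be at least the largest annotated index.
#' @return An iteration-2 [annotation_plan()] with the stride halved.
#' @export
refine_plan <- function(plan, extent_end) {
  ps_assert(inherits(plan, "annotation_plan"), "paleoseg_argument_error",
            "plan must be an annotation_plan")
  ps_assert(plan$iteration == 1L, "paleoseg_refinement_error",
            "only an iteration-1 plan can be refined")
  ps_assert(plan$step %% 2L == 0L, "paleoseg_refinement_error",
            "step %d is odd: midpoints would not be integral", plan$step)
  ps_assert(is_count(extent_end) && extent_end >= max(plan$annotated_indices),
            "paleoseg_argument_error",
            "extent_end must cover the existing annotated indices")
  half <- plan$step %/% 2L
  refined <- select_initial_slices(min(plan$annotated_indices), extent_end, half)
  ps_assert(all(plan$annotated_indices %in% refined), "paleoseg_refinement_error",
            "existing indices do not sit on the halved-stride grid")
  annotation_plan(refined, step = half,
                  validation_index = plan$validation_index,
                  negative_ranges = plan$negative_ranges, iteration = 2L)
}

#' Choose the validation slice by mask complexity
#'
#' The positive-pixel count of each mask is the proxy for region-of-interest
#' complexity: `"simplest"` holds out the mask with the fewest positive
#' pixels, `"most_complex"` the most. Ties break to the lowest slice index.
#'
#' @param masks A [mask_stack()] restricted to the annotated indices
#'   (at least two masks).
#' @param policy `"simplest"` or `"most_complex"`.
#' @return The chosen 0-based slice index.
#' @export
choose_validation_slice <- function(masks, policy = c("simplest", "most_complex")) {
  policy <- match.arg(policy)
  idx <- mask_indices(masks)
  ps_assert(length(idx) >= 2L, "paleoseg_insufficient_annotation_error",
            "need at least two annotated masks to hold one out")
  counts <- vapply(idx, function(i) sum(get_mask(masks, i)), numeric(1))
  pick <- if (policy == "simplest") which(counts == min(counts)) else
    which(counts == max(counts))
  idx[min(pick)] # indices are sorted, so min(pick) is the lowest slice index
}

#' Derive fossil-free slice ranges from available masks
#'
#' Returns maximal half-open `[start, end)` intervals of contiguous slices
#' known to be fossil-free. With full mask coverage (e.g. phantom ground
#' truth) this is exact. With sparse annotation it is conservative: an
#' interval is only emitted around runs of annotated-empty slices not
#' interrupted by an annotated non-empty slice, and never extends past the
#' outermost empty annotation of a run.
#'
#' @param masks A [mask_stack()] (coverage may be partial).
#' @param n_slices Total slice count of the stack.
#' @return List of `c(start, end)` integer pairs (possibly empty).
#' @export
derive_negative_ranges <- function(masks, n_slices) {
  idx <- mask_indices(masks)
  if (length(idx) == 0L) return(list())
  empty <- vapply(idx, function(i) sum(get_mask(masks, i)) == 0L, logical(1))
  ranges <- list()
  if (!any(empty)) return(ranges)
  e_idx <- idx[empty]
  p_idx <- idx[!empty]
  # Group empty-annotated slices into blocks not interrupted by a positive
  # one; each block becomes the half-open interval [first, last + 1).
  block_start <- e_idx[1]; block_end <- e_idx[1]
  for (i in e_idx[-1]) {
    interrupted <- any(p_idx > block_end & p_idx < i)
    if (!interrupted) {
      block_end <- i
    } else {
      ranges[[length(ranges) + 1L]] <- c(block_start, block_end + 1L)
      block_start <- i; block_end <- i
    }
  }
  ranges[[length(ranges) + 1L]] <- c(block_start, block_end + 1L)
  ranges
}

#' Serialize an annotation plan to a YAML file
#' @param plan An [annotation_plan()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_plan <- function(plan, path) {
  obj <- list(
    annotated_indices = as.integer(plan$annotated_indices),
    step = plan$step,
    validation_index = plan$validation_index,
    negative_ranges = lapply(plan$negative_ranges, as.integer),
    iteration = plan$iteration
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read an annotation plan from a YAML file
#' @param path File written by [write_annotation_plan()].
#' @return An [annotation_plan()].
#' @export
read_annotation_plan <- function(path) {
  obj <- yaml::read_yaml(path)
  annotation_plan(obj$annotated_indices, step = obj$step,
                  validation_index = obj$validation_index,
                  negative_ranges = obj$negative_ranges,
                  iteration = obj$iteration)
}
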