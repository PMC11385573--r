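# Reading and writing CT slice stacks and binary mask stacks.
#
# A stack on disk is a directory of numbered single-channel images, one file
# per slice (e.g. slice_0001.tif). Slice indices are 0-based throughout the
# package; file numbering may start anywhere and is mapped to 0-based rank
# order for image stacks, while mask filenames carry the slice index itself.

#' Construct a slice stack
#'
#' An ordered set of grayscale CT slices sharing one geometry, with
#' intensities normalized to `[0, 1]`.
#'
#' @param slices List of numeric matrices (rows x cols), all the same size,
#'   values in `[0, 1]`.
#' @param voxel_size_um Edge length of a voxel in micrometres (metadata only).
#' @return An object of class `slice_stack` with fields `slices`, `height`,
#'   `width`, `voxel_size_um`.
#' @export
slice_stack <- function(slices, voxel_size_um = NA_real_) {
  ps_assert(is.list(slices) && length(slices) >= 1L,
            "paleoseg_missing_input_error", "a slice stack needs at least one slice")
  dims <- vapply(slices, dim, integer(2))
  ps_assert(all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1]),
            "paleoseg_geometry_error", "all slices must share the same height and width")
  rng <- range(vapply(slices, function(s) range(s), numeric(2)))
  ps_assert(rng[1] >= 0 && rng[2] <= 1,
            "paleoseg_format_error", "slice intensities must lie in [0, 1]")
  structure(
    list(slices = slices, height = dims[1, 1], width = dims[2, 1],
         voxel_size_um = voxel_size_um),
    class = "slice_stack"
  )
}

#' Number of slices in a stack
#' @param x A `slice_stack` or `mask_stack`.
#' @return Integer count.
#' @export
n_slices <- function(x) UseMethod("n_slices")

#' @export
n_slices.slice_stack <- function(x) length(x$slices)

#' @export
n_slices.mask_stack <- function(x) length(x$masks)

#' Get one slice by 0-based index
#' @param stack A `slice_stack`.
#' @param index 0-based slice index.
#' @return Numeric matrix.
#' @export
get_slice <- function(stack, index) {
  ps_assert(is_count(index) && index >= 0 && index < n_slices(stack),
            "paleoseg_bounds_error", "slice index %s out of range [0, %d)",
            format(index), n_slices(stack))
  stack$slices[[index + 1L]]
}

#' @export
print.slice_stack <- function(x, ...) {
  cat(sprintf("<slice_stack> %d slices of %d x %d, voxel %s um\n",
              n_slices(x), x$height, x$width, format(x$voxel_size_um)))
  invisible(x)
}

#' Construct a mask stack
#'
#' Binary masks keyed by 0-based slice index; 1 marks fossil, 0 air/matrix.
#' Coverage may be sparse (any subset of slice indices, including none).
#'
#' @param masks Named list of 0/1 integer matrices; names are slice indices.
#' @param height,width Expected mask geometry; inferred from the first mask
#'   when omitted and masks are present.
#' @return An object of class `mask_stack`.
#' @export
mask_stack <- function(masks = list(), height = NA_integer_, width = NA_integer_) {
  ps_assert(is.list(masks), "paleoseg_format_error", "masks must be a list")
  if (length(masks) > 0L) {
    idx <- suppressWarnings(as.integer(names(masks)))
    ps_assert(!anyNA(idx), "paleoseg_format_error",
              "mask list names must be integer slice indices")
    if (is.na(height)) height <- nrow(masks[[1]])
    if (is.na(width)) width <- ncol(masks[[1]])
    for (m in masks) {
      ps_assert(nrow(m) == height && ncol(m) == width,
                "paleoseg_geometry_error", "mask geometry does not match %d x %d",
                height, width)
      ps_assert(all(m == 0L | m == 1L), "paleoseg_not_binary_error",
                "mask values must be exactly 0 or 1")
    }
    masks <- masks[order(idx)]
  }
  structure(list(masks = masks, height = as.integer(height), width = as.integer(width)),
            class = "mask_stack")
}

#' Slice indices covered by a mask stack
#' @param masks A `mask_stack`.
#' @return Sorted integer vector of 0-based indices.
#' @export
mask_indices <- function(masks) {
  if (length(masks$masks) == 0L) return(integer(0))
  sort(as.integer(names(masks$masks)))
}

#' Get one mask by 0-based slice index
#' @param masks A `mask_stack`.
#' @param index 0-based slice index.
#' @return 0/1 integer matrix.
#' @export
get_mask <- function(masks, index) {
  key <- as.character(as.integer(index))
  ps_assert(key %in% names(masks$masks), "paleoseg_coverage_error",
            "no mask for slice index %s", key)
  masks$masks[[key]]
}

#' @export
print.mask_stack <- function(x, ...) {
  cat(sprintf("<mask_stack> %d masks of %s x %s\n",
              n_slices(x), format(x$height), format(x$width)))
  invisible(x)
}

# --- file discovery -----------------------------------------------------

ps_list_images <- function(path) {
  if (length(path) == 1L && dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE,
                        full.names = TRUE)
  } else {
    files <- Sys.glob(path)
  }
  sort(files) # stable pre-sort so numeric ordering ties are deterministic
}

# Last run of digits in the file name, used as the numeric sort key / index.
filename_number <- function(files) {
  base <- sub("\\.[A-Za-z]+$", "", basename(files))
  m <- regmatches(base, gregexpr("[0-9]+", base))
  vapply(m, function(g) {
    if (length(g) == 0L) NA_real_ else as.numeric(g[[length(g)]])
  }, numeric(1))
}

read_gray_image <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(file, as.is = TRUE)
    if (length(dim(img)) == 3L && dim(img)[3] > 1L)
      ps_error("paleoseg_format_error", "multi-channel image: %s", file)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    bits <- attr(img, "bits.per.sample")
    if (is.null(bits)) bits <- if (max(img) > 255) 16L else 8L
    normalize_intensities(img, bits)
  } else if (ext == "png") {
    img <- png::readPNG(file) # already scaled by the dtype maximum
    if (length(dim(img)) == 3L && dim(img)[3] > 1L)
      ps_error("paleoseg_format_error", "multi-channel image: %s", file)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  } else {
    ps_error("paleoseg_format_error", "unsupported image format: %s", file)
  }
}

#' Read a CT slice stack from numbered image files
#'
#' Slices are ordered by the numeric component of their file names (numeric,
#' not lexicographic, so `s2` sorts before `s10`) and assigned 0-based indices
#' in that order. 8-bit and 16-bit single-channel TIFF and PNG are accepted;
#' intensities are normalized by the dtype maximum so values span `[0, 1]`.
#' If the directory holds a `stack_meta.yaml` sidecar, the voxel size is
#' taken from it unless given explicitly.
#'
#' @param path Directory containing the images, or a glob pattern.
#' @param voxel_size_um Optional voxel size metadata.
#' @return A [slice_stack()].
#' @export
read_slice_stack <- function(path, voxel_size_um = NA_real_) {
  if (is.na(voxel_size_um) && length(path) == 1L && dir.exists(path)) {
    sidecar <- file.path(path, "stack_meta.yaml")
    if (file.exists(sidecar)) {
      meta <- yaml::read_yaml(sidecar)
      voxel_size_um <- meta$voxel_size_um %||% NA_real_
    }
  }
  files <- ps_list_images(path)
  ps_assert(length(files) >= 1L, "paleoseg_missing_input_error",
            "no image files found at %s", paste(path, collapse = ", "))
  key <- filename_number(files)
  ord <- order(key, files, na.last = TRUE)
  slices <- lapply(files[ord], read_gray_image)
  dims <- vapply(slices, dim, integer(2))
  ps_assert(all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1]),
            "paleoseg_geometry_error", "images have mixed dimensions")
  slice_stack(slices, voxel_size_um = voxel_size_um)
}

#' Normalize integer intensities to the unit interval
#'
#' Fixed per-dtype scaling `v / (2^bit_depth - 1)`: monotone, maps the dtype
#' extremes to exactly 0 and 1, and keeps intensity semantics stationary
#' across the stack (unlike per-slice min-max scaling, which would make
#' fossil-to-matrix contrast drift along the axis).
#'
#' @param raw Numeric matrix of integer sample values.
#' @param bit_depth 8 or 16.
#' @return Numeric matrix in `[0, 1]`.
#' @export
normalize_intensities <- function(raw, bit_depth) {
  ps_assert(is_count(bit_depth) && bit_depth %in% c(8, 16),
            "paleoseg_format_error", "unsupported bit depth: %s", format(bit_depth))
  dmax <- 2^bit_depth - 1
  ps_assert(min(raw) >= 0 && max(raw) <= dmax, "paleoseg_format_error",
            "sample values outside the %d-bit range", bit_depth)
  raw / dmax
}

#' Read a binary mask stack
#'
#' Mask file names carry the 0-based slice index they annotate (last digit
#' group in the name). Files must be two-level images; any strictly positive
#' pixel becomes 1.
#'
#' @param path Directory or glob of mask images.
#' @param expected_geometry Optional `c(height, width)` to validate against.
#' @return A [mask_stack()]; empty when no files match (plans may start
#'   unannotated).
#' @export
read_mask_stack <- function(path, expected_geometry = NULL) {
  files <- ps_list_images(path)
  if (length(files) == 0L) {
    hw <- if (is.null(expected_geometry)) c(NA_integer_, NA_integer_) else expected_geometry
    return(mask_stack(list(), height = hw[1], width = hw[2]))
  }
  key <- filename_number(files)
  ps_assert(!anyNA(key), "paleoseg_format_error",
            "mask file names must carry a numeric slice index")
  masks <- stats::setNames(vector("list", length(files)), as.character(as.integer(key)))
  for (i in seq_along(files)) {
    img <- read_gray_image(files[i])
    vals <- unique(as.vector(img))
    ps_assert(length(vals) <= 2L, "paleoseg_not_binary_error",
              "mask %s has %d distinct values (expected at most 2)",
              basename(files[i]), length(vals))
    m <- matrix(as.integer(img > 0), nrow(img), ncol(img))
    if (!is.null(expected_geometry)) {
      ps_assert(nrow(m) == expected_geometry[1] && ncol(m) == expected_geometry[2],
                "paleoseg_geometry_error", "mask %s does not match expected geometry",
                basename(files[i]))
    }
    masks[[i]] <- m
  }
  mask_stack(masks)
}

#' Write a mask stack as 8-bit images
#'
#' One file per mask, named `<prefix>_<index 0-padded>.<ext>`, with 0 written
#' as black and 1 as white (255), matching the annotation convention.
#' Reading the output back with [read_mask_stack()] reproduces the input
#' bit-exactly.
#'
#' @param masks A [mask_stack()].
#' @param out_dir Output directory (created if needed).
#' @param format `"png"` or `"tiff"`.
#' @param prefix File-name prefix.
#' @return Invisibly, a data.frame manifest with columns `index`, `file`.
#' @export
write_mask_stack <- function(masks, out_dir, format = c("png", "tiff"),
                             prefix = "mask") {
  format <- match.arg(format)
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ps_assert(ok && file.access(out_dir, mode = 2) == 0,
            "paleoseg_io_error", "cannot write to directory %s", out_dir)
  idx <- mask_indices(masks)
  ext <- if (format == "png") "png" else "tif"
  files <- file.path(out_dir, sprintf("%s_%05d.%s", prefix, idx, ext))
  for (i in seq_along(idx)) {
    img <- masks$masks[[as.character(idx[i])]] * 1.0 # writers scale [0,1] -> 0/255
    if (format == "png") {
      png::writePNG(img, files[i])
    } else {
      tiff::writeTIFF(img, files[i], bits.per.sample = 8L)
    }
  }
  invisible(data.frame(index = idx, file = files, stringsAsFactors = FALSE))
}

#' Write a slice stack as 16-bit TIFF files
#'
#' Intensities in `[0, 1]` are quantized to 16 bits (the inverse of the
#' read-time normalization, up to quantization).
#'
#' @param stack A [slice_stack()].
#' @param out_dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, a manifest data.frame (`index`, `file`).
#' @export
write_slice_stack <- function(stack, out_dir, prefix = "slice") {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ps_assert(ok && file.access(out_dir, mode = 2) == 0,
            "paleoseg_io_error", "cannot write to directory %s", out_dir)
  n <- n_slices(stack)
  files <- file.path(out_dir, sprintf("%s_%05d.tif", prefix, seq_len(n) - 1L))
  for (i in seq_len(n)) {
    tiff::writeTIFF(stack$slices[[i]], files[i], bits.per.sample = 16L)
  }
  if (!is.na(stack$voxel_size_um)) {
    yaml::write_yaml(list(voxel_size_um = stack$voxel_size_um, n_slices = n,
                          height = stack$height, width = stack$width),
                     file.path(out_dir, "stack_meta.yaml"))
  }
  invisible(data.frame(index = seq_len(n) - 1L, file = files, stringsAsFactors = FALSE))
}
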