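# Shared fixtures, all generated in code.

# A miniature phantom for fast unit tests: 24 slices of 64 x 64.
tiny_phantom_params <- function(seed = 7L, ...) {
  phantom_params(n_slices = 24L, height = 64L, width = 64L,
                 n_tubes = 1L, n_plates = 1L, foramen_width_vox = 5L,
                 empty_margin = 4L, seed = seed, ...)
}

tiny_train_config <- function(epochs = 3L, seed = 7L, warmup_epochs = 2L, ...) {
  train_config(crop_size = 32L, epochs = epochs, warmup_epochs = warmup_epochs,
               decoder_channels = c(8L, 4L), seed = seed, ...)
}

# The desk-scale study conditions (defaults of phantom_params/train_config).
desk_phantom_params <- function(seed) phantom_params(seed = seed)
desk_train_config <- function(seed) train_config(seed = seed)

# An asymmetric probe grid: all entries distinct, no dihedral symmetry.
asymmetric_probe <- function(n = 3L) matrix(seq_len(n * n), n, n)

# A random sparse binary mask with at least one positive pixel.
random_sparse_mask <- function(h, w, frac = 0.02) {
  m <- matrix(as.integer(stats::runif(h * w) < frac), h, w)
  if (sum(m) == 0L) m[sample(h * w, 1L)] <- 1L
  m
}

expect_error_class <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}
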