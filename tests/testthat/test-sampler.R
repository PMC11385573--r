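# Crop sampling guarantees, epoch composition, input assembly, augmentation.

test_that("positive crops always contain the single positive pixel", {
  set.seed(101)
  slice <- matrix(runif(64 * 64), 64, 64)
  mask <- matrix(0L, 64, 64)
  mask[37, 22] <- 1L
  for (i in 1:1000) {
    pair <- sample_positive_crop(slice, mask, 16)
    expect_equal(sum(pair$mask), 1L)
  }
})

test_that("degenerate crop geometry forces the origin and oversize crops error", {
  set.seed(5)
  slice <- matrix(runif(64 * 64), 64, 64)
  mask <- random_sparse_mask(64, 64)
  pair <- sample_positive_crop(slice, mask, 64)
  expect_equal(pair$origin, c(0L, 0L))
  expect_identical(pair$image, slice)
  expect_error_class(sample_positive_crop(slice, mask, 65), "paleoseg_geometry_error")
})

test_that("an empty mask falls back to an unconstrained crop", {
  set.seed(6)
  slice <- matrix(runif(32 * 32), 32, 32)
  pair <- sample_positive_crop(slice, matrix(0L, 32, 32), 8)
  expect_equal(sum(pair$mask), 0L)
  expect_equal(dim(pair$image), c(8L, 8L))
})

test_that("negative crops come uniformly from the union of negative ranges", {
  set.seed(11)
  st <- slice_stack(lapply(1:100, function(i) matrix(i / 100, 8, 8)))
  ranges <- list(c(0L, 10L), c(90L, 100L))
  src <- replicate(10000, sample_negative_crop(st, ranges, 4)$source_index)
  expect_true(all(src %in% c(0:9, 90:99)))
  first <- mean(src < 50)
  expect_lt(abs(first - 0.5), 0.05) # binomial check at n = 10^4
  # crops from a constant slice are constant, masks all zero
  one <- sample_negative_crop(st, list(c(0L, 1L)), 4)
  expect_equal(one$source_index, 0L)
  expect_true(all(one$image == st$slices[[1]][1, 1]))
  expect_true(all(one$mask == 0L))
  expect_error_class(sample_negative_crop(st, list(), 4), "paleoseg_sampling_error")
})

test_that("epoch schedules pair every training slice with the fixed negative ratio", {
  plan8 <- annotation_plan(seq(0, 1600, 200), step = 200, validation_index = 0)
  set.seed(3)
  sched <- build_epoch(plan8, 2L)
  expect_equal(nrow(sched), 10L) # 8 training + 2 negative
  expect_equal(sum(sched$kind == "positive"), 8L)
  expect_equal(sum(sched$kind == "negative"), 2L)
  expect_setequal(sched$slice[sched$kind == "positive"], seq(200, 1600, 200))

  plan17 <- annotation_plan(seq(0, 1700, 100), step = 100, validation_index = 0)
  expect_equal(nrow(build_epoch(plan17, 2L)), 19L)

  plan1 <- annotation_plan(c(0, 10), step = 10, validation_index = 10)
  expect_equal(nrow(build_epoch(plan1, 0L)), 1L)

  solo <- annotation_plan(0L, step = 10, validation_index = 0L)
  expect_error_class(build_epoch(solo, 2L), "paleoseg_schedule_error")

  # reproducible under a seed
  a <- local({ set.seed(9); build_epoch(plan8, 2L) })
  b <- local({ set.seed(9); build_epoch(plan8, 2L) })
  expect_identical(a, b)
})

test_that("2.5D assembly stacks neighbours with edge replication", {
  st <- slice_stack(lapply(1:5, function(i) matrix(i / 10, 6, 6)))
  expect_identical(assemble_input(st, 2, "1ch"), get_slice(st, 2))
  mid <- assemble_input(st, 2, "2.5d")
  expect_equal(dim(mid), c(6L, 6L, 3L))
  expect_identical(mid[, , 2], assemble_input(st, 2, "1ch"))
  expect_identical(mid[, , 1], get_slice(st, 1))
  expect_identical(mid[, , 3], get_slice(st, 3))
  lo <- assemble_input(st, 0, "2.5d")
  expect_identical(lo[, , 1], get_slice(st, 0)) # replicated edge
  expect_identical(lo[, , 3], get_slice(st, 1))
  hi <- assemble_input(st, 4, "2.5d")
  expect_identical(hi[, , 3], get_slice(st, 4))
  expect_error_class(assemble_input(st, 5, "1ch"), "paleoseg_bounds_error")
})

test_that("the identity augmentation draw returns the crop unchanged", {
  set.seed(2)
  pair <- sample_positive_crop(matrix(runif(64^2), 64, 64),
                               random_sparse_mask(64, 64), 32)
  out <- augment(pair, angle = 0, flip_h = FALSE, flip_v = FALSE)
  expect_identical(out$image, pair$image)
  expect_identical(out$mask, pair$mask)
})

test_that("quarter-turn augmentation equals the exact index-permutation rotation", {
  set.seed(3)
  img <- matrix(runif(16), 4, 4)
  msk <- matrix(as.integer(runif(16) > 0.5), 4, 4)
  pair <- paleoseg:::new_crop_pair(img, msk, 0L, c(0L, 0L))
  out <- augment(pair, angle = 90, flip_h = FALSE, flip_v = FALSE)
  # independent quarter-turn oracle: out[r, c] = in[c, n + 1 - r]
  n <- 4L
  oracle_img <- matrix(0, n, n)
  oracle_msk <- matrix(0L, n, n)
  for (r in 1:n) for (c in 1:n) {
    oracle_img[r, c] <- img[c, n + 1 - r]
    oracle_msk[r, c] <- msk[c, n + 1 - r]
  }
  expect_equal(out$image, oracle_img)
  expect_identical(out$mask, oracle_msk)
})

test_that("flips and quarter-turns preserve the positive-pixel count", {
  set.seed(4)
  for (i in 1:20) {
    msk <- random_sparse_mask(32, 32, 0.05)
    pair <- paleoseg:::new_crop_pair(matrix(runif(32^2), 32, 32), msk, 0L, c(0L, 0L))
    ang <- sample(c(0, 90, 180, 270), 1)
    out <- augment(pair, angle = ang, flip_h = runif(1) < 0.5, flip_v = runif(1) < 0.5)
    expect_equal(sum(out$mask), sum(msk))
  }
})

test_that("image and mask receive the same geometric operator", {
  # a delta test pattern: the mask pixel must stay on the bright image blob
  img <- matrix(0, 33, 33); msk <- matrix(0L, 33, 33)
  img[11, 21] <- 1; msk[11, 21] <- 1L
  pair <- paleoseg:::new_crop_pair(img, msk, 0L, c(0L, 0L))
  set.seed(8)
  for (i in 1:10) {
    out <- augment(pair, fill = 0)
    pos <- which(out$mask == 1L, arr.ind = TRUE)
    if (nrow(pos) == 0) next # rotated out of frame
    # the image mass near the transformed mask pixel dominates
    r <- pos[1, 1]; c <- pos[1, 2]
    nb <- out$image[max(1, r - 1):min(33, r + 1), max(1, c - 1):min(33, c + 1)]
    expect_gt(sum(nb), 0.5 * sum(out$image))
  }
})
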