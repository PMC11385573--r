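# Every-Nth selection, midpoint refinement, holdout policy, negative ranges.

test_that("every-Nth selection matches the closed-form count", {
  expect_equal(select_initial_slices(0, 1700, 200), seq(0, 1600, 200))
  expect_length(select_initial_slices(0, 1700, 200), 9L)
  expect_equal(select_initial_slices(0, 0, 200), 0L)
  expect_equal(select_initial_slices(0, 1700, 100), seq(0, 1700, 100))
  expect_length(select_initial_slices(0, 1700, 100), 18L)
  expect_error_class(select_initial_slices(10, 5, 1), "paleoseg_argument_error")
})

test_that("midpoint refinement is additive and lands on the halved-stride grid", {
  idx <- select_initial_slices(0, 1700, 200)
  plan <- annotation_plan(idx, step = 200, validation_index = 0)
  ref <- refine_plan(plan, 1700)
  expect_equal(ref$iteration, 2L)
  expect_equal(ref$step, 100L)
  expect_equal(ref$annotated_indices, seq(0, 1700, 100))
  expect_length(setdiff(ref$annotated_indices, idx), 9L)  # 9 new slices
  expect_length(ref$annotated_indices, 18L)
  expect_true(all(idx %in% ref$annotated_indices))
  expect_equal(ref$validation_index, plan$validation_index)

  p2 <- annotation_plan(c(0, 200, 400), step = 200, validation_index = 0)
  r2 <- refine_plan(p2, 400)
  expect_equal(setdiff(r2$annotated_indices, p2$annotated_indices), c(100, 300))

  single <- annotation_plan(0L, step = 200, validation_index = 0)
  expect_equal(setdiff(refine_plan(single, 0)$annotated_indices, 0L), integer(0))

  odd <- annotation_plan(c(0, 5), step = 5, validation_index = 0)
  expect_error_class(refine_plan(odd, 10), "paleoseg_refinement_error")
  expect_error_class(refine_plan(ref, 1700), "paleoseg_refinement_error") # already iter 2
})

test_that("refinement equals direct halved-stride selection over small extents", {
  for (start in c(0L, 3L)) {
    for (step in c(2L, 4L, 10L)) {
      for (k in 1:4) {
        end <- start + k * step
        plan <- annotation_plan(select_initial_slices(start, end, step),
                                step = step, validation_index = start)
        ref <- refine_plan(plan, end)
        expect_equal(ref$annotated_indices,
                     select_initial_slices(start, end, step %/% 2L))
      }
    }
  }
})

test_that("validation slice choice follows mask complexity with lowest-index ties", {
  mk <- function(n) {
    m <- matrix(0L, 8, 8); if (n > 0) m[seq_len(n)] <- 1L; m
  }
  ms <- mask_stack(list("5" = mk(10), "9" = mk(50), "7" = mk(20)))
  expect_equal(choose_validation_slice(ms, "simplest"), 5L)
  expect_equal(choose_validation_slice(ms, "most_complex"), 9L)
  tie <- mask_stack(list("3" = mk(10), "8" = mk(10)))
  expect_equal(choose_validation_slice(tie, "simplest"), 3L)
  one <- mask_stack(list("3" = mk(10)))
  expect_error_class(choose_validation_slice(one, "simplest"),
                     "paleoseg_insufficient_annotation_error")
})

test_that("negative ranges are exact under full coverage and conservative when sparse", {
  p <- phantom_params(n_slices = 100L, height = 96L, width = 96L,
                      empty_margin = 10L, seed = 6)
  ph <- generate_phantom(p)
  rr <- derive_negative_ranges(ph$masks, 100L)
  expect_true(any(vapply(rr, function(r) all(r == c(0L, 10L)), logical(1))))
  expect_true(any(vapply(rr, function(r) all(r == c(90L, 100L)), logical(1))))

  full <- mask_stack(stats::setNames(replicate(6, matrix(1L, 4, 4), simplify = FALSE),
                                     as.character(0:5)))
  expect_length(derive_negative_ranges(full, 6L), 0L)

  none <- mask_stack(stats::setNames(replicate(6, matrix(0L, 4, 4), simplify = FALSE),
                                     as.character(0:5)))
  expect_equal(derive_negative_ranges(none, 6L), list(c(0L, 6L)))

  # sparse: empty at 0 and 4, positive at 2 -> two conservative blocks
  sparse <- mask_stack(list("0" = matrix(0L, 4, 4),
                            "2" = matrix(1L, 4, 4),
                            "4" = matrix(0L, 4, 4)))
  expect_equal(derive_negative_ranges(sparse, 6L), list(c(0L, 1L), c(4L, 5L)))
})

test_that("plans serialize to YAML and back unchanged", {
  plan <- annotation_plan(seq(0, 80, 10), step = 10, validation_index = 40,
                          negative_ranges = list(c(0L, 5L), c(90L, 96L)),
                          iteration = 1L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_annotation_plan(plan, path)
  back <- read_annotation_plan(path)
  expect_equal(back$annotated_indices, plan$annotated_indices)
  expect_equal(back$validation_index, plan$validation_index)
  expect_equal(back$negative_ranges, plan$negative_ranges)
  expect_equal(back$step, plan$step)
})

test_that("plan invariants are enforced", {
  expect_error_class(annotation_plan(c(0, 10), step = 10, validation_index = 5),
                     "paleoseg_argument_error")
  expect_error_class(
    annotation_plan(c(0, 10), step = 10, validation_index = 0,
                    negative_ranges = list(c(0, 5), c(3, 8))),
    "paleoseg_argument_error")
})
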