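test_that("minmax_normalize maps endpoints, degenerates to zero, errors on NaN", {
  expect_equal(minmax_normalize(array(c(10, 15, 20), c(3, 1, 1)))[, 1, 1],
               c(0, 0.5, 1))
  expect_equal(minmax_normalize(array(7, c(2, 2, 2))), array(0, c(2, 2, 2)))
  v <- array(runif(27), c(3, 3, 3)); v[1] <- 0; v[27] <- 1
  expect_equal(minmax_normalize(v), v)
  v[2] <- NaN
  expect_error(minmax_normalize(v), "non-finite")
})

test_that("normalization is idempotent", {
  set.seed(1)
  for (i in 1:5) {
    v <- array(rnorm(64, sd = 10 * i), c(4, 4, 4))
    n1 <- minmax_normalize(v)
    expect_equal(minmax_normalize(n1), n1, tolerance = 1e-12)
  }
})

test_that("resize_volume honors shape, identity, and label value sets", {
  img <- array(runif(24 * 24 * 16), c(24, 24, 16))
  out <- resize_volume(img, c(12, 12, 12), "image")
  expect_identical(dim(out), c(12L, 12L, 12L))
  expect_identical(resize_volume(img, dim(img), "image"), img)

  seg <- random_seg(c(10, 10, 10))
  segr <- resize_volume(seg, c(6, 7, 8), "label")
  expect_true(all(unique(as.vector(segr)) %in% unique(as.vector(seg))))
  expect_identical(resize_volume(seg, dim(seg), "label"), seg)
  expect_error(resize_volume(matrix(1, 2, 2), c(2, 2, 2)), "3D")
})

test_that("resizing a constant volume yields a constant volume in both modes", {
  v <- array(3.5, c(9, 7, 5))
  expect_equal(resize_volume(v, c(5, 6, 7), "image"), array(3.5, c(5, 6, 7)))
  expect_equal(resize_volume(v, c(5, 6, 7), "label"), array(3.5, c(5, 6, 7)))
  # upsizing too
  expect_equal(resize_volume(v, c(12, 13, 14), "image"),
               array(3.5, c(12, 13, 14)))
})

test_that("derive_masks implements the label algebra", {
  seg <- array(0, c(2, 2, 2))
  seg[1, 1, 1] <- 4; seg[2, 1, 1] <- 2; seg[1, 2, 1] <- 1
  m <- derive_masks(seg)$data
  expect_equal(m[, 1, 1, 1], c(1, 1, 1))  # ET voxel
  expect_equal(m[, 2, 1, 1], c(1, 0, 0))  # edema voxel
  expect_equal(m[, 1, 2, 1], c(1, 1, 0))  # NET voxel
  expect_equal(m[, 2, 2, 2], c(0, 0, 0))  # background

  z <- derive_masks(array(0, c(3, 3, 3)))
  expect_true(all(z$data == 0))
  expect_error(derive_masks(array(5, c(2, 2, 2))), "outside")
  expect_warning(derive_masks(array(c(3, 0), c(2, 1, 1))), "missing label")
})

test_that("mask nesting and voxel counts match the brute-force oracle", {
  set.seed(7)
  for (i in 1:20) {
    seg <- random_seg(c(6, 6, 6))
    m <- derive_masks(seg)
    expect_nested(m)
    counts <- oracle_mask_counts(seg)
    expect_identical(sum(m$data[1, , , ]), as.double(counts[["wt"]]))
    expect_identical(sum(m$data[2, , , ]), as.double(counts[["tc"]]))
    expect_identical(sum(m$data[3, , , ]), as.double(counts[["et"]]))
  }
})

test_that("stack_case produces paired normalized stacks", {
  pp <- phantom_pair(seed = 21)
  expect_s3_class(pp$stack, "modality_stack")
  expect_s3_class(pp$masks, "mask_stack")
  expect_identical(dim(pp$stack$data), c(4L, 32L, 32L, 32L))
  expect_identical(dim(pp$masks$data), c(3L, 32L, 32L, 32L))
  expect_true(min(pp$stack$data) >= 0 && max(pp$stack$data) <= 1)
  expect_nested(pp$masks)

  # identity grid: stack values equal the normalized inputs
  case <- generate_phantom(phantom_spec(shape = c(16, 16, 16), seed = 4))
  pp16 <- stack_case(case, c(16, 16, 16))
  expect_equal(pp16$stack$data[1, , , ], minmax_normalize(case$flair))
  expect_equal(pp16$stack$data[3, , , ], minmax_normalize(case$t1ce))

  # unlabeled case: masks absent, not an error
  case$seg <- NULL
  class(case) <- "mri_case"
  expect_null(stack_case(case, c(16, 16, 16))$masks)
})

test_that("stack constructors validate their invariants", {
  expect_error(modality_stack(array(2, c(4, 4, 4, 4))), "\\[0, 1\\]")
  expect_error(modality_stack(array(0.5, c(3, 4, 4, 4))), "dim")
  bad <- array(0, c(3, 2, 2, 2)); bad[3, 1, 1, 1] <- 1  # ET outside TC
  expect_error(mask_stack(bad), "nesting")
  expect_error(mask_stack(array(0.5, c(3, 2, 2, 2))), "binary")
})
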