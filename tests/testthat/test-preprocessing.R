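test_that("reference point equals the rendered origin without jitter", {
  img <- fix_image()
  expect_equal(locate_reference_point(img), img$origin_px)
})

test_that("reference point is translation-equivariant", {
  img <- fix_image()
  shifted <- img$pixels[, c(ncol(img$pixels) - 1:0,
                            1:(ncol(img$pixels) - 2))]  # shift right by 2
  ref0 <- locate_reference_point(img$pixels)
  ref2 <- locate_reference_point(shifted)
  expect_equal(ref2[["col"]], ref0[["col"]] + 2)
  expect_equal(ref2[["row"]], ref0[["row"]])
})

test_that("localization fails cleanly on uniform frames", {
  expect_error(locate_reference_point(matrix(1000L, 64, 64)),
               "localization failure")
})

test_that("extract_rois yields 16 ordered crops with propagated truth", {
  img <- fix_image()
  crops <- extract_rois(img, crop_size = 56)
  expect_length(crops, 16L)
  expect_equal(vapply(crops, `[[`, "", "kind"),
               c(rep("fiber", 6), rep("speck_group", 5), rep("mass", 5)))
  expect_equal(vapply(crops, `[[`, 0L, "rank"), c(1:6, 1:5, 1:5))
  expect_true(all(vapply(crops, function(cr) nrow(cr$pixels) == 56, TRUE)))
  expect_equal(vapply(crops, `[[`, 0, "truth_score"),
               img$truth_scores$score)
  # the rank-1 fiber crop actually contains its fiber: bright centre
  cr <- crops[[1]]$pixels
  expect_gt(mean(cr[24:32, 24:32]), mean(cr[1:8, 1:8]))
})

test_that("crop counts scale as 16 per image (6/5/5 by kind)", {
  crops <- unlist(lapply(c(101, 202, 303), function(s)
    extract_rois(fix_image(100, 28, seed = s))), recursive = FALSE)
  kinds <- vapply(crops, `[[`, "", "kind")
  expect_length(crops, 48L)
  expect_equal(sum(kinds == "fiber"), 18L)
  expect_equal(sum(kinds == "speck_group"), 15L)
  expect_equal(sum(kinds == "mass"), 15L)
})

test_that("oversized crops raise a geometry error naming the target", {
  img <- fix_image()
  expect_error(extract_rois(img, crop_size = 1000), "exceeds")
  expect_error(extract_rois(img, crop_size = 500), "fiber rank 1")
})

test_that("percentile rescaling maps the range and handles degeneracy", {
  m <- matrix(as.integer(seq(0, 65535, length.out = 64)), 8)
  cr <- shape_crop(m, "mass", 1L)
  out <- rescale_intensity(cr, 0, 100)
  expect_equal(out$pixels, m)  # full-range crop unchanged at (0, 100)
  expect_identical(rescale_intensity(rescale_intensity(cr, 0, 100), 0, 100),
                   rescale_intensity(cr, 0, 100))  # idempotent
  const <- shape_crop(matrix(1234L, 8, 8), "mass", 1L)
  expect_true(all(rescale_intensity(const)$pixels == 0L))
  two <- matrix(c(100L, 200L), 4, 4)
  r2 <- rescale_intensity(two, 0, 100)
  expect_setequal(unique(as.vector(r2)), c(0L, 65535L))
  expect_error(rescale_intensity(cr, 50, 10), "p_low")
})

test_that("partition reproduces the 80:20 / 80:20 bookkeeping", {
  f <- partition_dataset(make_stub_crops(3258), seed = 1)
  expect_equal(unname(f$sizes), c(2084L, 522L, 652L))
  s <- partition_dataset(make_stub_crops(2715), seed = 1)
  expect_equal(unname(s$sizes), c(1737L, 435L, 543L))
  tiny <- partition_dataset(make_stub_crops(5), seed = 1)
  expect_equal(unname(tiny$sizes), c(3L, 1L, 1L))
  expect_error(partition_dataset(list()), "empty")
})

test_that("partitions conserve and never share a crop", {
  set.seed(17)
  for (n in sample(1:400, 20)) {
    p <- partition_dataset(make_stub_crops(n), seed = n)
    ids <- lapply(p[c("training", "validation", "holdout")],
                  function(g) vapply(g, `[[`, "", "image_id"))
    expect_equal(sum(lengths(ids)), n)
    expect_equal(anyDuplicated(unlist(ids)), 0L)
    expect_equal(unname(p$sizes[["holdout"]]), ceiling(0.2 * n))
  }
})

test_that("partitioning mixed kinds is refused", {
  crops <- c(make_stub_crops(4, "fiber"), make_stub_crops(4, "mass"))
  expect_error(partition_dataset(crops), "single kind")
})

test_that("flip augmentation enumerates the 4-element flip group", {
  crops <- extract_rois(fix_image(), crop_size = 56)
  aug <- augment(crops[[12]])
  expect_length(aug, 4L)
  expect_identical(aug[[1]]$pixels, crops[[12]]$pixels)
  expect_true(all(vapply(aug, `[[`, 0, "truth_score") ==
                    crops[[12]]$truth_score))
  # double flip is an involution: augmenting it recovers the original
  back <- augment(aug[[4]])
  expect_identical(back[[4]]$pixels, crops[[12]]$pixels)
  # a symmetric crop is invariant under horizontal flip
  sym <- shape_crop(matrix(as.integer(outer(1:8, c(1:4, 4:1))), 8), "mass", 1L)
  expect_identical(augment(sym)[[2]]$pixels, sym$pixels)
})
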